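## Readers/writers for SBS catalogs, annotation tracks, and result tables.

## Harmonize external chromosome names against the genome build: match after
## stripping any "chr" prefix from both sides, then report in build naming.
.harmonizeChrom <- function(x, genome) {
  x <- as.character(x)
  build <- chromNames(genome)
  key <- sub("^chr", "", build)
  m <- match(sub("^chr", "", x), key)
  out <- build[m]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("chromosome(s) not in genome build: ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct an SbsCatalog from a data frame of SBS records
#'
#' Records are harmonized to the genome build's chromosome naming (a
#' \code{"chr"} prefix on either side is tolerated), sorted by (sample,
#' chromosome order, position), deduplicated (exact duplicates of sample,
#' position, ref, alt are dropped with a logged count; same-position records
#' with different alternate alleles are kept), and annotated with the
#' pyrimidine-normalized substitution class.
#'
#' @param records \code{data.frame} with columns \code{sample},
#'   \code{chromosome}, \code{position} (1-based), \code{ref}, \code{alt}.
#' @param genome A \code{\link{GenomeBuild}}.
#' @return An \code{\link{SbsCatalog}}. The number of removed duplicates is
#'   recorded in \code{metadata(variants(x))$duplicatesRemoved}.
#' @export
sbsCatalog <- function(records, genome) {
  need <- c("sample", "chromosome", "position", "ref", "alt")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records)) {
    if (any(records$position < 1)) stop("positions must be >= 1")
    chrom <- .harmonizeChrom(records$chromosome, genome)
    lens <- chromLengths(genome)
    if (any(records$position > lens[chrom])) {
      stop("position beyond chromosome length")
    }
  } else {
    chrom <- character(0)
  }
  smp <- factor(as.character(records$sample))
  ref <- toupper(as.character(records$ref))
  alt <- toupper(as.character(records$alt))
  chromF <- factor(chrom, levels = chromNames(genome))
  o <- order(as.integer(smp), as.integer(chromF), records$position, ref, alt)
  smp <- smp[o]; chromF <- chromF[o]; pos <- records$position[o]
  ref <- ref[o]; alt <- alt[o]
  dup <- duplicated(data.frame(smp, chromF, pos, ref, alt))
  nDup <- sum(dup)
  if (nDup > 0L) {
    message("sbsCatalog: removed ", nDup, " exact duplicate record(s)")
    smp <- smp[!dup]; chromF <- chromF[!dup]; pos <- pos[!dup]
    ref <- ref[!dup]; alt <- alt[!dup]
  }
  v <- GenomicRanges::GRanges(
    seqnames = chromF,
    ranges = IRanges::IRanges(start = pos, width = 1L),
    seqinfo = genome@seqinfo)
  S4Vectors::mcols(v)$sample <- droplevels(smp)
  S4Vectors::mcols(v)$ref <- ref
  S4Vectors::mcols(v)$alt <- alt
  S4Vectors::mcols(v)$class <-
    factor(if (length(v)) normalizeSubstitution(ref, alt) else character(0),
           levels = substitutionClasses())
  S4Vectors::metadata(v)$duplicatesRemoved <- nDup
  methods::new("SbsCatalog", variants = v, genome = genome)
}

#' @describeIn sbsCatalog The SBS records as a \code{GRanges}.
#' @param x An \code{\link{SbsCatalog}}.
#' @export
variants <- function(x) {
  x@variants
}

#' @describeIn sbsCatalog Sample identifiers present in the catalog.
#' @export
sampleIds <- function(x) {
  levels(S4Vectors::mcols(x@variants)$sample)
}

#' @describeIn sbsCatalog The catalog's \code{\link{GenomeBuild}}.
#' @export
catalogGenome <- function(x) {
  x@genome
}

setMethod("show", "SbsCatalog", function(object) {
  cat("SbsCatalog: ", length(object@variants), " SBS records, ",
      length(sampleIds(object)), " sample(s), genome '",
      object@genome@name, "'\n", sep = "")
})

#' Read per-sample SBS catalogs from VCF, MAF-like, or plain TSV files
#'
#' Non-SBS rows (indels, multi-base alleles, non-ACGT alleles) are skipped
#' with a logged count; multi-allelic VCF rows are split into one record per
#' alternate allele. Gzip-compressed inputs are read transparently.
#'
#' @param path Input file.
#' @param genome A \code{\link{GenomeBuild}}.
#' @param format \code{"tsv"} (columns \code{sample, chromosome, position,
#'   ref, alt}), \code{"maf"} (columns \code{Tumor_Sample_Barcode,
#'   Chromosome, Start_Position, Reference_Allele, Tumor_Seq_Allele2}), or
#'   \code{"vcf"}.
#' @param sampleField For \code{"tsv"}: name of the sample column. Ignored
#'   otherwise.
#' @param sampleId For \code{"vcf"}: sample identifier to assign to the
#'   records (default: the file base name).
#' @return An \code{\link{SbsCatalog}} (possibly covering many samples).
#' @export
readSbsCatalogs <- function(path, genome, format = c("tsv", "maf", "vcf"),
                            sampleField = "sample", sampleId = NULL) {
  format <- match.arg(format)
  df <- switch(format,
    tsv = {
      d <- utils::read.delim(path, stringsAsFactors = FALSE)
      need <- c(sampleField, "chromosome", "position", "ref", "alt")
      if (!all(need %in% names(d))) {
        stop("TSV must have columns: ", paste(need, collapse = ", "))
      }
      data.frame(sample = d[[sampleField]], chromosome = d$chromosome,
                 position = d$position, ref = d$ref, alt = d$alt,
                 stringsAsFactors = FALSE)
    },
    maf = {
      d <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
      need <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2")
      if (!all(need %in% names(d))) {
        stop("MAF must have columns: ", paste(need, collapse = ", "))
      }
      data.frame(sample = d$Tumor_Sample_Barcode, chromosome = d$Chromosome,
                 position = d$Start_Position, ref = d$Reference_Allele,
                 alt = d$Tumor_Seq_Allele2, stringsAsFactors = FALSE)
    },
    vcf = {
      vcf <- VariantAnnotation::readVcf(path, genome = genome@name)
      vcf <- VariantAnnotation::expand(vcf)  # multi-allelic split
      rr <- SummarizedExperiment::rowRanges(vcf)
      if (is.null(sampleId)) {
        sampleId <- sub("\\.vcf(\\.gz)?$", "", basename(path))
      }
      data.frame(sample = sampleId,
                 chromosome = as.character(GenomicRanges::seqnames(rr)),
                 position = GenomicRanges::start(rr),
                 ref = as.character(rr$REF),
                 alt = as.character(rr$ALT),
                 stringsAsFactors = FALSE)
    })
  if (nrow(df) == 0L) {
    warning("no records read from ", path)
    return(sbsCatalog(df, genome))
  }
  isSbs <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    toupper(df$ref) %in% c("A", "C", "G", "T") &
    toupper(df$alt) %in% c("A", "C", "G", "T") &
    toupper(df$ref) != toupper(df$alt)
  nSkip <- sum(!isSbs)
  if (nSkip > 0L) {
    message("readSbsCatalogs: skipped ", nSkip, " non-SBS row(s)")
  }
  sbsCatalog(df[isSbs, , drop = FALSE], genome)
}

#' Write an SbsCatalog as a plain TSV
#'
#' Columns \code{sample, chromosome, position, ref, alt} in catalog order;
#' \code{readSbsCatalogs(..., format = "tsv")} round-trips losslessly.
#'
#' @param catalog An \code{\link{SbsCatalog}}.
#' @param path Output path.
#' @export
writeSbsTable <- function(catalog, path) {
  v <- catalog@variants
  df <- data.frame(
    sample = as.character(S4Vectors::mcols(v)$sample),
    chromosome = as.character(GenomicRanges::seqnames(v)),
    position = GenomicRanges::start(v),
    ref = S4Vectors::mcols(v)$ref,
    alt = S4Vectors::mcols(v)$alt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation track from a BED file
#'
#' BED intervals are 0-based half-open; they are imported, sorted, and
#' merged per chromosome (overlapping or book-ended intervals collapse), so
#' membership queries see disjoint intervals.
#'
#' @param path BED3+ file (gzip transparent).
#' @param name Track name stored in \code{metadata(track)$trackName}.
#' @param genome Optional \code{\link{GenomeBuild}} used to harmonize
#'   chromosome naming.
#' @return A merged \code{GRanges} annotation track.
#' @export
readBedTrack <- function(path, name = basename(path), genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(GenomicRanges::width(gr) < 1L)) {
    stop("BED intervals must satisfy start < end")
  }
  if (!is.null(genome)) {
    newNames <- .harmonizeChrom(as.character(GenomicRanges::seqnames(gr)),
                                genome)
    gr <- GenomicRanges::GRanges(
      seqnames = factor(newNames, levels = chromNames(genome)),
      ranges = IRanges::ranges(gr), seqinfo = genome@seqinfo)
  }
  gr <- GenomicRanges::reduce(gr)
  S4Vectors::metadata(gr)$trackName <- name
  gr
}

#' Read a directory of BED tracks
#'
#' @param dir Directory containing one BED file per track; track names are
#'   the file names without extension.
#' @param genome Optional \code{\link{GenomeBuild}} for naming harmonization.
#' @return Named list of merged \code{GRanges} tracks.
#' @export
readTrackDir <- function(dir, genome = NULL) {
  files <- list.files(dir, pattern = "\\.bed(\\.gz)?$", full.names = TRUE)
  names(files) <- sub("\\.bed(\\.gz)?$", "", basename(files))
  lapply(stats::setNames(names(files), names(files)), function(nm) {
    readBedTrack(files[[nm]], name = nm, genome = genome)
  })
}

#' Per-SBS rainfall table (intermutation distances)
#'
#' Companion table of rainfall plots: each SBS with its distance to the
#' previous SBS of the same sample on the same chromosome (\code{NA} for the
#' first SBS per sample-chromosome) and its substitution class.
#'
#' @param catalog An \code{\link{SbsCatalog}}.
#' @return \code{data.frame} with columns \code{sample, chromosome,
#'   position, imd, class} in catalog order.
#' @export
rainfallTable <- function(catalog) {
  v <- catalog@variants
  mc <- S4Vectors::mcols(v)
  pos <- GenomicRanges::start(v)
  grp <- cumsum(c(TRUE, diff(as.integer(mc$sample)) != 0L |
                    diff(as.integer(GenomicRanges::seqnames(v))) != 0L))
  imd <- c(NA, diff(pos))
  imd[c(TRUE, diff(grp) != 0L)] <- NA
  data.frame(
    sample = as.character(mc$sample),
    chromosome = as.character(GenomicRanges::seqnames(v)),
    position = pos,
    imd = imd,
    class = as.character(mc$class),
    stringsAsFactors = FALSE)
}

#' Write a kataegis locus table as TSV
#'
#' Columns \code{sample, chromosome, start, end, n_sbs, span_bp, mean_imd,
#' max_imd, confidence}, sorted by (sample, chromosome, start) for
#' deterministic output.
#'
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}}.
#' @param path Output path.
#' @export
writeLociTable <- function(loci, path) {
  df <- lociTable(loci)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn writeLociTable Locus table as a \code{data.frame} (no file).
#' @export
lociTable <- function(loci) {
  mc <- S4Vectors::mcols(loci)
  df <- data.frame(
    sample = as.character(mc$sample),
    chromosome = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci),
    end = GenomicRanges::end(loci),
    n_sbs = mc$nSbs,
    span_bp = mc$spanBp,
    mean_imd = mc$meanImd,
    max_imd = mc$maxImd,
    confidence = mc$confidence,
    stringsAsFactors = FALSE)
  df[order(df$sample, df$chromosome, df$start), , drop = FALSE]
}

#' @describeIn writeLociTable Read a locus table written by
#'   \code{writeLociTable}.
#' @export
readLociTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
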