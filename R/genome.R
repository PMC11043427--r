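## Genome coordinate system, binning, and substitution normalization.

#' Construct a GenomeBuild
#'
#' @param name Build label (e.g. \code{"hg19"}, \code{"synthetic"}).
#' @param chromosomes Character vector of chromosome names, in the order that
#'   defines global coordinates and bin indexing.
#' @param lengths Numeric vector of chromosome lengths in bp, parallel to
#'   \code{chromosomes}.
#' @param sequences Optional \code{DNAStringSet} named by chromosome, used
#'   for trinucleotide-context lookup. When absent, spectra are reported at
#'   6-class resolution only.
#' @return A \code{\link{GenomeBuild}}.
#' @examples
#' gb <- genomeBuild("toy", c("chr1", "chr2"), c(3e6, 1e6))
#' chromLengths(gb)
#' @export
genomeBuild <- function(name, chromosomes, lengths, sequences = NULL) {
  chromosomes <- as.character(chromosomes)
  if (length(chromosomes) != length(lengths)) {
    stop("chromosomes and lengths must be parallel")
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = chromosomes,
                              seqlengths = as.integer(lengths),
                              genome = name)
  ord <- .chromOrdinal(chromosomes)
  ord[is.na(ord)] <- seq_along(chromosomes)[is.na(ord)]
  methods::new("GenomeBuild", name = name, seqinfo = si,
               ordinals = ord, sequences = sequences)
}

#' Read a genome description from a two-column TSV
#'
#' Expects columns \code{chromosome} and \code{length} (header required);
#' gzip-compressed files are read transparently.
#'
#' @param path Path to the TSV.
#' @param name Build label for the resulting object.
#' @return A \code{\link{GenomeBuild}}.
#' @export
readGenomeTsv <- function(path, name = "genome") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "length")
  if (!all(need %in% names(df))) {
    stop("genome TSV must have columns: ", paste(need, collapse = ", "))
  }
  genomeBuild(name, df$chromosome, df$length)
}

#' Attach chromosome sequences from a FASTA file
#'
#' @param genome A \code{\link{GenomeBuild}}.
#' @param path FASTA file (optionally gzip-compressed); sequence names must
#'   match the build's chromosome names.
#' @return The \code{GenomeBuild} with sequences attached.
#' @export
attachSequences <- function(genome, path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(chromNames(genome), names(seqs))
  if (length(missing)) {
    stop("FASTA lacks sequences for: ", paste(missing, collapse = ", "))
  }
  genome@sequences <- seqs[chromNames(genome)]
  methods::validObject(genome)
  genome
}

#' @describeIn genomeBuild Chromosome names, in build order.
#' @param genome A \code{\link{GenomeBuild}}.
#' @export
chromNames <- function(genome) {
  GenomeInfoDb::seqnames(genome@seqinfo)
}

#' @describeIn genomeBuild Named chromosome lengths in bp.
#' @export
chromLengths <- function(genome) {
  sl <- GenomeInfoDb::seqlengths(genome@seqinfo)
  stats::setNames(as.numeric(sl), GenomeInfoDb::seqnames(genome@seqinfo))
}

#' @describeIn genomeBuild Total genome size in bp.
#' @export
genomeSize <- function(genome) {
  sum(chromLengths(genome))
}

#' @describeIn genomeBuild Canonical chromosome ordinals (X = 23, Y = 24),
#'   named by chromosome.
#' @export
chromOrdinals <- function(genome) {
  stats::setNames(genome@ordinals, chromNames(genome))
}

setMethod("show", "GenomeBuild", function(object) {
  cat("GenomeBuild '", object@name, "': ",
      length(object@ordinals), " chromosomes, ",
      format(genomeSize(object), big.mark = ","), " bp",
      if (!is.null(object@sequences)) " (with sequence)" else "",
      "\n", sep = "")
})

#' Tile a genome into fixed-width bins
#'
#' Bins are half-open intervals of constant width tiling each chromosome in
#' order; the final bin of each chromosome is truncated at the chromosome
#' length. Global bin indices run contiguously across chromosomes, so the
#' total bin count is \code{sum(ceiling(lengths / width))}.
#'
#' @param genome A \code{\link{GenomeBuild}}.
#' @param width Bin width in bp (default 2 Mb, the resolution used for
#'   kataegis recurrence maps).
#' @return A \code{\link{BinScheme}}.
#' @examples
#' gb <- genomeBuild("toy", "chr1", 5e6)
#' nBins(makeBins(gb, 2e6))  # 3 bins: [0,2M), [2M,4M), [4M,5M)
#' @export
makeBins <- function(genome, width = 2e6) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("width must be a single positive number")
  }
  tiles <- GenomicRanges::tileGenome(genome@seqinfo, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  nPer <- ceiling(chromLengths(genome) / width)
  offsets <- c(0L, cumsum(as.integer(nPer)))[seq_along(nPer)]
  methods::new("BinScheme", bins = tiles, binWidth = width,
               offsets = stats::setNames(offsets, chromNames(genome)))
}

#' @describeIn makeBins Number of bins in the scheme.
#' @param scheme A \code{\link{BinScheme}}.
#' @export
nBins <- function(scheme) {
  length(scheme@bins)
}

#' @describeIn makeBins The bins as a \code{GRanges} in global index order.
#' @export
binRanges <- function(scheme) {
  scheme@bins
}

setMethod("show", "BinScheme", function(object) {
  cat("BinScheme: ", length(object@bins), " bins of width ",
      format(object@binWidth, big.mark = ","), " bp over ",
      length(object@offsets), " chromosomes\n", sep = "")
})

#' Locate the bin containing a genomic position
#'
#' Positions are 1-based; the bin containing a position is the half-open
#' 0-based interval containing \code{position - 1}.
#'
#' @param scheme A \code{\link{BinScheme}}.
#' @param chromosome Character vector of chromosome names.
#' @param position Numeric vector of 1-based positions (recycled against
#'   \code{chromosome}).
#' @return Integer vector of 1-based global bin indices.
#' @examples
#' gb <- genomeBuild("toy", "chr1", 5e6)
#' sc <- makeBins(gb, 2e6)
#' locateBin(sc, "chr1", c(2e6, 2e6 + 1))  # 1, 2
#' @export
locateBin <- function(scheme, chromosome, position) {
  chromosome <- as.character(chromosome)
  lens <- stats::setNames(
    as.numeric(GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(scheme@bins))),
    GenomeInfoDb::seqlevels(scheme@bins))
  if (any(bad <- !chromosome %in% names(lens))) {
    stop("unknown chromosome(s): ",
         paste(unique(chromosome[bad]), collapse = ", "))
  }
  if (any(position < 1 | position > lens[chromosome])) {
    stop("position outside chromosome length")
  }
  as.integer(scheme@offsets[chromosome] +
               (position - 1) %/% scheme@binWidth + 1)
}

#' Normalize substitutions to pyrimidine reference classes
#'
#' Purine-reference substitutions (ref A or G) are reverse-complemented,
#' jointly with their trinucleotide context when one is supplied, so that
#' the reference base of every class is C or T. The mapping is a 2-to-1
#' surjection from the 12 ordered base pairs onto the 6 classes and is
#' idempotent on its own output.
#'
#' @param ref,alt Character vectors of single bases in \code{A,C,G,T};
#'   \code{ref != alt} elementwise.
#' @param context Optional character vector of 3-mers centered on \code{ref}
#'   (genomic strand); reverse-complemented together with the substitution.
#' @return With \code{context = NULL}, a character vector of classes (see
#'   \code{\link{substitutionClasses}}); otherwise a \code{data.frame} with
#'   columns \code{class} and \code{context} (pyrimidine-strand context).
#' @examples
#' normalizeSubstitution("G", "A")                 # "C>T"
#' normalizeSubstitution("G", "A", context = "TGA")  # T[C>T]A context "TCA"
#' @export
normalizeSubstitution <- function(ref, alt, context = NULL) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!all(ref %in% c("A", "C", "G", "T")) ||
      !all(alt %in% c("A", "C", "G", "T"))) {
    stop("ref and alt must be single bases in A, C, G, T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  nref <- ifelse(flip, comp(ref), ref)
  nalt <- ifelse(flip, comp(alt), alt)
  cls <- paste0(nref, ">", nalt)
  if (is.null(context)) {
    return(cls)
  }
  context <- toupper(as.character(context))
  if (any(nchar(context) != 3L, na.rm = TRUE)) {
    stop("context must be 3-mers")
  }
  revcomp <- function(x) {
    vapply(strsplit(comp(x), ""), function(b) paste(rev(b), collapse = ""),
           character(1))
  }
  nctx <- ifelse(flip & !is.na(context), revcomp(context), context)
  data.frame(class = cls, context = nctx, stringsAsFactors = FALSE)
}

#' Look up trinucleotide context from attached genome sequence
#'
#' @param genome A \code{\link{GenomeBuild}} with sequences attached.
#' @param chromosome,position Vectors naming the SBS positions (1-based).
#' @return Character vector of genomic-strand 3-mers (\code{NA} at
#'   chromosome ends).
#' @export
lookupContext <- function(genome, chromosome, position) {
  if (is.null(genome@sequences)) {
    stop("genome has no attached sequences")
  }
  chromosome <- as.character(chromosome)
  lens <- chromLengths(genome)
  out <- rep(NA_character_, length(position))
  ok <- position > 1 & position < lens[chromosome]
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::subseq(
      genome@sequences[chromosome[ok]],
      start = position[ok] - 1, width = 3))
  }
  out
}
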