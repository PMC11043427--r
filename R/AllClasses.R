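## S4 classes shared across all stages.

#' The six pyrimidine-normalized substitution classes
#'
#' Somatic single base substitutions are conventionally reported with the
#' reference base normalized to a pyrimidine (C or T); purine-reference
#' changes are reverse-complemented. This collapses the 12 ordered base pairs
#' onto 6 classes.
#'
#' @return Character vector \code{c("C>A","C>G","C>T","T>A","T>C","T>G")}.
#' @examples
#' substitutionClasses()
#' @export
substitutionClasses <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

## canonical chromosome ordinal: strip "chr", X -> 23, Y -> 24, M/MT -> 25.
## Names that parse to none of these get NA (callers fall back to list order).
.chromOrdinal <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x == "X"] <- "23"
  x[x == "Y"] <- "24"
  x[x %in% c("M", "MT")] <- "25"
  suppressWarnings(as.integer(x))
}

#' GenomeBuild: chromosome names, lengths, and optional sequence
#'
#' A minimal description of a genome build: an ordered set of chromosomes
#' with lengths (held as a \code{Seqinfo}), a canonical ordinal per
#' chromosome (1-22, X = 23, Y = 24, used for the "chromosomes 1-23" binary
#' status rule and the "1-22" per-chromosome views), and an optional
#' \code{DNAStringSet} for trinucleotide-context lookup.
#'
#' @slot name Build label, e.g. \code{"hg19"} or \code{"synthetic"}.
#' @slot seqinfo \code{Seqinfo} with the chromosome names and lengths, in a
#'   fixed, reproducible order.
#' @slot ordinals Integer ordinal per chromosome (parallel to the seqinfo);
#'   chromosomes whose name does not parse fall back to their list position.
#' @slot sequences \code{DNAStringSet} named by chromosome, or \code{NULL}.
#'
#' @seealso \code{\link{genomeBuild}}, \code{\link{readGenomeTsv}}
#' @export
setClass("GenomeBuild",
  slots = c(
    name = "character",
    seqinfo = "Seqinfo",
    ordinals = "integer",
    sequences = "ANY"
  )
)

setValidity("GenomeBuild", function(object) {
  sn <- GenomeInfoDb::seqnames(object@seqinfo)
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (anyDuplicated(sn)) {
    return("chromosome names must be unique")
  }
  if (any(is.na(sl)) || any(sl <= 0)) {
    return("all chromosome lengths must be positive")
  }
  if (length(object@ordinals) != length(sn)) {
    return("ordinals must be parallel to the chromosome list")
  }
  if (!is.null(object@sequences) &&
      !methods::is(object@sequences, "DNAStringSet")) {
    return("sequences must be NULL or a DNAStringSet")
  }
  TRUE
})

#' BinScheme: fixed-width tiling of a genome
#'
#' Consecutive half-open bins of constant width tile each chromosome; the
#' last bin of a chromosome is truncated at the chromosome end (never
#' dropped), so every base belongs to exactly one bin. Global bin indices
#' are contiguous in chromosome order.
#'
#' @slot bins \code{GRanges} of the tiles, in global index order.
#' @slot binWidth Bin width in base pairs.
#' @slot offsets Integer: number of bins preceding each chromosome.
#'
#' @seealso \code{\link{makeBins}}, \code{\link{locateBin}}
#' @export
setClass("BinScheme",
  slots = c(bins = "GRanges", binWidth = "numeric", offsets = "integer")
)

#' SbsCatalog: position-sorted somatic SBS records for one or more samples
#'
#' Holds width-1 \code{GRanges} with metadata columns \code{sample} (factor),
#' \code{ref}, \code{alt} (single bases, \code{ref != alt}), and \code{class}
#' (one of \code{\link{substitutionClasses}}), sorted by (sample, chromosome
#' order, position, ref, alt). Exact duplicate records are removed on
#' construction with a logged count; same-position records with different
#' alternate alleles are kept (they contribute an intermutation distance of
#' zero).
#'
#' @slot variants The \code{GRanges} of SBS records.
#' @slot genome The \code{\link{GenomeBuild}} the positions refer to.
#'
#' @seealso \code{\link{sbsCatalog}}, \code{\link{readSbsCatalogs}}
#' @export
setClass("SbsCatalog",
  slots = c(variants = "GRanges", genome = "GenomeBuild")
)

setValidity("SbsCatalog", function(object) {
  v <- object@variants
  mc <- S4Vectors::mcols(v)
  need <- c("sample", "ref", "alt", "class")
  if (!all(need %in% colnames(mc))) {
    return(paste("variants must carry mcols:", paste(need, collapse = ", ")))
  }
  if (length(v)) {
    if (any(GenomicRanges::width(v) != 1L)) {
      return("all SBS records must have width 1")
    }
    if (any(as.character(mc$ref) == as.character(mc$alt))) {
      return("ref and alt must differ")
    }
    o <- order(as.integer(mc$sample), as.integer(GenomicRanges::seqnames(v)),
               GenomicRanges::start(v), as.character(mc$ref),
               as.character(mc$alt))
    if (!identical(o, seq_along(v))) {
      return("variants must be sorted by (sample, chromosome, position)")
    }
  }
  TRUE
})

#' DetectionParams: settings of the kataegis detector
#'
#' @slot minSbs Minimum number of consecutive SBSs in a locus (default 6).
#' @slot imdThreshold Intermutation-distance threshold in bp (default 1000).
#' @slot imdRule \code{"max"} (every adjacent IMD within a locus at or below
#'   the threshold; the rule used by the headline analyses) or \code{"mean"}
#'   (windows qualify by mean IMD; overlapping qualifying windows are merged).
#' @slot minConfidence Minimum confidence tier kept by
#'   \code{\link{filterLoci}} (default 1, i.e. every detected locus).
#' @slot chromosomes Integer set of canonical chromosome ordinals retained by
#'   \code{\link{filterLoci}} (default 1-23, i.e. autosomes plus X).
#'
#' @seealso \code{\link{detectionParams}}, \code{\link{detectKataegis}}
#' @export
setClass("DetectionParams",
  slots = c(
    minSbs = "integer",
    imdThreshold = "numeric",
    imdRule = "character",
    minConfidence = "integer",
    chromosomes = "integer"
  )
)

setValidity("DetectionParams", function(object) {
  if (object@minSbs < 2L) return("minSbs must be >= 2")
  if (object@imdThreshold <= 0) return("imdThreshold must be > 0")
  if (!object@imdRule %in% c("max", "mean")) {
    return("imdRule must be 'max' or 'mean'")
  }
  if (object@minConfidence < 1L || object@minConfidence > 3L) {
    return("minConfidence must be in 1..3")
  }
  TRUE
})
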