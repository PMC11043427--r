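## Genomic-context annotation of SBSs and kataegis/all enrichment ratios.

#' Flag SBSs falling inside an annotation track
#'
#' An SBS at 1-based position p is a member of the track when its 0-based
#' coordinate p - 1 lies in one of the track's half-open intervals, i.e.
#' when the 1-based position overlaps the imported interval. Chromosomes
#' absent from the track yield \code{FALSE} flags.
#'
#' @param catalog An \code{\link{SbsCatalog}}.
#' @param track Merged \code{GRanges} track from \code{\link{readBedTrack}}.
#' @return Logical vector parallel to \code{variants(catalog)}.
#' @export
annotateSbs <- function(catalog, track) {
  v <- catalog@variants
  trackChrom <- GenomeInfoDb::seqlevels(track)
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(v))),
                     trackChrom)
  if (length(missing)) {
    message("annotateSbs: no track intervals on ",
            length(missing), " chromosome(s)")
  }
  IRanges::overlapsAny(v, track, ignore.strand = TRUE)
}

#' Context proportions of kataegis SBSs and the all-SBS background
#'
#' For one annotation track and one sample set (typically a clinical
#' subgroup), computes the proportion of SBSs mapped to the track in three
#' pools: (1) the kataegis-associated SBSs (members of all loci) of
#' kataegis-positive samples, (2) all SBSs of kataegis-positive samples,
#' and (3) all SBSs of kataegis-negative samples. SBSs are pooled across
#' tumors (not weighted per tumor), matching the construction of
#' subgroup-level context bars.
#'
#' @param catalog An \code{\link{SbsCatalog}}.
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}} (after
#'   \code{\link{filterLoci}}).
#' @param track Merged \code{GRanges} annotation track.
#' @param samples Sample identifiers defining the subgroup (default: all
#'   catalog samples).
#' @param status Named logical of binary kataegis status per sample;
#'   computed with \code{\link{classifyBinary}} defaults when absent.
#' @return \code{data.frame} with rows \code{kataegis_sbs},
#'   \code{all_sbs_positive}, \code{all_sbs_negative} and columns
#'   \code{set, n_mapped, n_total, proportion, defined}; empty pools have
#'   \code{defined = FALSE} and \code{NA} proportion.
#' @export
contextProportions <- function(catalog, loci, track,
                               samples = sampleIds(catalog),
                               status = NULL) {
  v <- catalog@variants
  smp <- as.character(S4Vectors::mcols(v)$sample)
  if (is.null(status)) {
    status <- classifyBinary(loci, samples, genome = catalog@genome)
  }
  if (!all(samples %in% names(status))) {
    stop("status must be named for every sample")
  }
  inTrack <- annotateSbs(catalog, track)
  posSamples <- samples[status[samples]]
  negSamples <- samples[!status[samples]]
  mc <- S4Vectors::mcols(loci)
  lociKeep <- which(mc$sample %in% posSamples)
  katIdx <- if (length(lociKeep)) {
    sequence(mc$nSbs[lociKeep], from = mc$memberFirst[lociKeep])
  } else {
    integer(0)
  }
  pools <- list(
    kataegis_sbs = katIdx,
    all_sbs_positive = which(smp %in% posSamples),
    all_sbs_negative = which(smp %in% negSamples))
  rows <- lapply(names(pools), function(nm) {
    idx <- pools[[nm]]
    nTotal <- length(idx)
    nMapped <- sum(inTrack[idx])
    data.frame(set = nm, n_mapped = nMapped, n_total = nTotal,
               proportion = if (nTotal > 0) nMapped / nTotal else NA_real_,
               defined = nTotal > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "track") <- S4Vectors::metadata(track)$trackName
  out
}

#' Kataegis/all-SBS enrichment ratio
#'
#' The proportion of kataegis-associated SBSs in a track divided by the
#' all-SBS proportion of the kataegis-positive tumors of the same subgroup;
#' a ratio of 1 means kataegis SBSs fall in the track no more often than
#' the tumor's SBSs at large.
#'
#' @param proportions Output of \code{\link{contextProportions}}.
#' @return One-row \code{data.frame} with \code{ratio},
#'   \code{p_kataegis}, \code{p_all_positive}, and \code{defined}
#'   (\code{FALSE}, with \code{NA} ratio, when the denominator proportion
#'   is zero or undefined).
#' @export
enrichmentRatio <- function(proportions) {
  pk <- proportions[proportions$set == "kataegis_sbs", ]
  pa <- proportions[proportions$set == "all_sbs_positive", ]
  if (nrow(pk) != 1L || nrow(pa) != 1L) {
    stop("proportions must contain the kataegis and all-positive pools")
  }
  ok <- isTRUE(pk$defined) && isTRUE(pa$defined) && pa$proportion > 0
  data.frame(
    ratio = if (ok) pk$proportion / pa$proportion else NA_real_,
    p_kataegis = pk$proportion,
    p_all_positive = pa$proportion,
    defined = ok)
}
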