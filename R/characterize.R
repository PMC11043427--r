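## Subgroup-level characterization of detected loci: merged spectra, size
## distributions, per-chromosome counts, and fixed-bin recurrence.

#' Merged substitution spectrum of kataegis loci
#'
#' Pools every member SBS of every supplied locus into a single set and
#' tabulates the six pyrimidine-normalized substitution classes. For
#' APOBEC-driven kataegis the pooled spectrum is dominated by C>T and C>G.
#' Grouping (e.g. per clinical subgroup) is done by subsetting the loci
#' before the call; spectra are additive over disjoint locus sets.
#'
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}}.
#' @param scope Optional label stored on the result.
#' @return List with \code{scope}, integer \code{counts} (named by class),
#'   \code{proportions} (\code{NA} and \code{defined = FALSE} when the pool
#'   is empty), \code{total}, and \code{defined}.
#' @export
mergedSpectrum <- function(loci, scope = "all") {
  cc <- S4Vectors::mcols(loci)$classCounts
  counts <- if (length(loci)) {
    stats::setNames(as.integer(colSums(cc)), substitutionClasses())
  } else {
    stats::setNames(integer(6L), substitutionClasses())
  }
  total <- sum(counts)
  props <- if (total > 0) counts / total else
    stats::setNames(rep(NA_real_, 6L), substitutionClasses())
  list(scope = scope, counts = counts, proportions = props,
       total = total, defined = total > 0)
}

#' Locus size and SBS-count distributions
#'
#' Raw per-locus span (bp) and member SBS count, plus summary quantiles.
#' No smoothing is applied (density-kernel smoothing of such distributions
#' is a plotting device, not a statistic).
#'
#' @param loci Locus \code{GRanges}.
#' @param probs Quantile probabilities for the summary.
#' @return List with vectors \code{spanBp} and \code{nSbs} and a
#'   \code{quantiles} matrix (rows \code{spanBp}, \code{nSbs}).
#' @export
locusSizeSummary <- function(loci, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  mc <- S4Vectors::mcols(loci)
  spanBp <- as.numeric(mc$spanBp)
  nSbs <- as.numeric(mc$nSbs)
  q <- if (length(loci)) {
    rbind(spanBp = stats::quantile(spanBp, probs),
          nSbs = stats::quantile(nSbs, probs))
  } else {
    matrix(NA_real_, 2L, length(probs),
           dimnames = list(c("spanBp", "nSbs"),
                           paste0(probs * 100, "%")))
  }
  list(spanBp = spanBp, nSbs = nSbs, quantiles = q)
}

#' Kataegis events per chromosome
#'
#' Counts loci by chromosome over a canonical-ordinal chromosome set
#' (default 1-22: the per-chromosome view conventionally excludes the sex
#' chromosomes). Chromosomes with no events report zero.
#'
#' @param loci Locus \code{GRanges}.
#' @param genome \code{\link{GenomeBuild}} defining chromosome ordinals.
#' @param chromosomes Integer ordinal set (default \code{1:22}).
#' @return Named integer vector of counts, one entry per chromosome of the
#'   set in genome order.
#' @export
eventsPerChromosome <- function(loci, genome, chromosomes = 1:22) {
  ords <- chromOrdinals(genome)
  keepChrom <- names(ords)[ords %in% chromosomes]
  cn <- as.character(GenomicRanges::seqnames(loci))
  counts <- table(factor(cn[cn %in% keepChrom], levels = keepChrom))
  stats::setNames(as.integer(counts), keepChrom)
}

#' Recurrence of kataegis events in fixed-width genome bins
#'
#' Maps each locus to exactly one bin by the bin containing its midpoint
#' (0-based \code{floor((start - 1 + end) / 2)}; spans are far smaller than
#' the bin width so loci are never split), accumulates event counts per bin
#' over all tumors of each group, and divides by the group size (all tumors
#' of the group, kataegis-negative included) to obtain event frequencies.
#' Multiple loci of one tumor falling in one bin count as multiple events.
#'
#' @param loci Locus \code{GRanges}.
#' @param scheme A \code{\link{BinScheme}}.
#' @param groups Factor (or character) of group labels parallel to
#'   \code{loci} (e.g. the subgroup of each locus's sample). Default: a
#'   single group \code{"all"}.
#' @param groupSizes Named numeric vector giving the number of tumors per
#'   group (names must cover the group levels); required for frequencies.
#' @return List with matrices \code{counts} and \code{frequency} (bins x
#'   groups) and the bin \code{GRanges}.
#' @export
binRecurrence <- function(loci, scheme, groups = NULL, groupSizes = NULL) {
  if (is.null(groups)) {
    groups <- factor(rep("all", length(loci)))
  }
  groups <- as.factor(groups)
  if (length(groups) != length(loci)) {
    stop("groups must be parallel to loci")
  }
  if (is.null(groupSizes)) {
    stop("groupSizes is required (all tumors per group, negatives included)")
  }
  if (!all(levels(groups) %in% names(groupSizes))) {
    stop("groupSizes must name every group level")
  }
  if (any(groupSizes[levels(groups)] <= 0)) {
    stop("group sizes must be positive")
  }
  mid1 <- floor((GenomicRanges::start(loci) - 1 +
                   GenomicRanges::end(loci)) / 2) + 1
  bin <- if (length(loci)) {
    locateBin(scheme, as.character(GenomicRanges::seqnames(loci)), mid1)
  } else {
    integer(0)
  }
  counts <- unclass(table(factor(bin, levels = seq_len(nBins(scheme))),
                          groups))
  dimnames(counts) <- list(NULL, levels(groups))
  storage.mode(counts) <- "integer"
  freq <- sweep(counts, 2L, groupSizes[colnames(counts)], "/")
  list(counts = counts, frequency = freq, bins = binRanges(scheme))
}
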