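## Binary kataegis classification, frequency curves, TMB, metagene rank
## scores, and the cohort association statistics.

#' Kataegis event counts per sample
#'
#' @param loci Locus \code{GRanges} (after \code{\link{filterLoci}} if a
#'   confidence filter is wanted).
#' @param samples Character vector of sample identifiers to report
#'   (samples without loci report zero).
#' @param chromosomes Canonical chromosome ordinals counted (default 1-23,
#'   the set used by the binary status rule).
#' @param genome Optional \code{\link{GenomeBuild}} supplying ordinals.
#' @return Named integer vector of event counts.
#' @export
eventCounts <- function(loci, samples, chromosomes = 1:23, genome = NULL) {
  ords <- .ordinalMap(loci, genome)
  keep <- ords[as.character(GenomicRanges::seqnames(loci))] %in% chromosomes
  smp <- S4Vectors::mcols(loci)$sample[keep]
  counts <- table(factor(smp, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Binary kataegis status at an event cut-off
#'
#' A tumor is kataegis-positive when its event count on the chromosome set
#' (default ordinals 1-23, i.e. autosomes plus X) reaches the cut-off
#' (default 1).
#'
#' @inheritParams eventCounts
#' @param cutoff Minimum event count for positivity (default 1).
#' @return Named logical vector per sample.
#' @export
classifyBinary <- function(loci, samples, cutoff = 1L, chromosomes = 1:23,
                           genome = NULL) {
  if (cutoff < 1L) stop("cutoff must be >= 1")
  eventCounts(loci, samples, chromosomes, genome) >= cutoff
}

#' Binary kataegis frequency across event cut-offs
#'
#' The positive fraction of a sample set at each cut-off; non-increasing in
#' the cut-off by construction (the positive set at a higher cut-off is a
#' subset of the positive set at any lower one).
#'
#' @inheritParams eventCounts
#' @param cutoffs Integer cut-offs (default \code{1:5}).
#' @return Named numeric vector of frequencies, one per cut-off.
#' @export
frequencyByCutoff <- function(loci, samples, cutoffs = 1:5,
                              chromosomes = 1:23, genome = NULL) {
  if (!length(samples)) stop("samples must be non-empty")
  counts <- eventCounts(loci, samples, chromosomes, genome)
  stats::setNames(vapply(cutoffs, function(k) mean(counts >= k), numeric(1)),
                  as.character(cutoffs))
}

#' Tumor mutational burden
#'
#' TMB = (number of SBSs + number of indels) per megabase of genome.
#'
#' @param nSbs,nIndel Mutation counts (scalars or parallel vectors).
#' @param genomeSize Genome size in bp (e.g. \code{genomeSize(genome)});
#'   the callable-genome size is the caller's choice.
#' @return Mutations per Mb.
#' @examples
#' computeTmb(3000, 0, 3e9)  # 1 per Mb
#' @export
computeTmb <- function(nSbs, nIndel = 0, genomeSize) {
  if (any(genomeSize <= 0)) stop("genomeSize must be > 0")
  (nSbs + nIndel) / (genomeSize / 1e6)
}

#' @describeIn computeTmb Per-sample TMB from a catalog and optional indel
#'   counts (named by sample; missing samples count zero indels).
#' @param catalog An \code{\link{SbsCatalog}}.
#' @param indelCounts Named integer vector of indel counts per sample.
#' @export
tmbPerSample <- function(catalog, indelCounts = NULL, genomeSize = NULL) {
  if (is.null(genomeSize)) {
    genomeSize <- sum(chromLengths(catalog@genome))
  }
  ids <- sampleIds(catalog)
  nSbs <- stats::setNames(as.integer(table(
    S4Vectors::mcols(catalog@variants)$sample)), ids)
  nInd <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(indelCounts)) {
    hit <- intersect(names(indelCounts), ids)
    nInd[hit] <- indelCounts[hit]
  }
  computeTmb(nSbs, nInd, genomeSize)
}

#' Single-sample metagene rank scores
#'
#' For each sample, all measured genes are ranked ascending by expression
#' (average ranks for ties) and a metagene's score is the mean rank of its
#' member genes divided by the total gene count, yielding a score in (0, 1]
#' where higher expression of the module gives a higher score. Scores are
#' computed per sample with no cross-sample normalization or centering.
#'
#' @param expression Numeric matrix, genes x samples, with gene rownames.
#' @param geneSets Named list of character vectors of member genes.
#' @return Numeric matrix, samples x metagenes. Metagenes with no member
#'   among the measured genes yield \code{NA} with a warning.
#' @export
metageneRankScore <- function(expression, geneSets) {
  if (is.null(rownames(expression))) stop("expression needs gene rownames")
  if (!length(geneSets)) stop("geneSets must be non-empty")
  G <- nrow(expression)
  ranks <- apply(expression, 2L, rank)  # genes x samples, average ties
  out <- matrix(NA_real_, ncol(expression), length(geneSets),
                dimnames = list(colnames(expression), names(geneSets)))
  for (m in names(geneSets)) {
    members <- intersect(geneSets[[m]], rownames(expression))
    if (!length(members)) {
      warning("metagene '", m, "' has no measured member genes")
      next
    }
    out[, m] <- colMeans(ranks[members, , drop = FALSE]) / G
  }
  out
}

.testResult <- function(test, statistic, p, groupSizes, degenerate = FALSE) {
  data.frame(test = test, statistic = as.numeric(statistic),
             p_value = as.numeric(p),
             n = paste(groupSizes, collapse = "/"),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration is used when both groups have at most 8 observations
#' and the pooled data are tie-free; otherwise the normal approximation
#' with tie and continuity corrections. Two-sided throughout. The
#' computation is delegated to \code{stats::wilcox.test}.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact Override the exact/approximate choice.
#' @param correct Continuity correction for the normal approximation.
#' @return One-row \code{data.frame}: \code{test, statistic, p_value, n,
#'   degenerate}.
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL, correct = TRUE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (is.null(exact)) {
    exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = correct))
  .testResult("wilcoxon_rank_sum", ht$statistic, ht$p.value,
              c(length(x), length(y)))
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic against a chi-squared reference with k - 1
#' degrees of freedom, via \code{stats::kruskal.test}. When every pooled
#' observation is identical the statistic is 0 and the p-value is flagged
#' degenerate.
#'
#' @param values List of numeric vectors (at least two non-empty groups),
#'   or a single numeric vector accompanied by \code{groups}.
#' @param groups Optional grouping factor when \code{values} is a vector.
#' @return One-row \code{data.frame} as in \code{\link{wilcoxonRankSum}}.
#' @export
kruskalWallis <- function(values, groups = NULL) {
  if (!is.null(groups)) {
    values <- split(as.numeric(values), groups)
  }
  values <- values[lengths(values) > 0L]
  if (length(values) < 2L) stop("need at least two non-empty groups")
  pooled <- unlist(values, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(.testResult("kruskal_wallis", 0, NA_real_, lengths(values),
                       degenerate = TRUE))
  }
  ht <- stats::kruskal.test(values)
  .testResult("kruskal_wallis", ht$statistic, ht$p.value, lengths(values))
}

#' Pearson chi-square test on a contingency table
#'
#' Continuity (Yates) correction is OFF by default for every table size, a
#' single consistent rule; enable it with \code{correct = TRUE} for 2x2
#' tables. Tables with a zero row or column marginal are flagged degenerate
#' (statistic and p \code{NA}) rather than tested.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @param correct Apply the Yates correction (2x2 only).
#' @return One-row \code{data.frame} as in \code{\link{wilcoxonRankSum}}.
#' @export
chiSquareTest <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("need at least a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(.testResult("chi_square", NA_real_, NA_real_, sum(table),
                       degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  .testResult("chi_square", ht$statistic, ht$p.value, sum(table))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, clipped
#' at 1, monotone in the input ranks, returned in the input order (via
#' \code{stats::p.adjust}).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene driver-alteration association with binary kataegis status
#'
#' For each gene, a 2x2 chi-square test of alteration status against
#' binary kataegis status over the supplied samples, with BH adjustment
#' across the non-degenerate genes of the panel (genes with a zero marginal
#' — e.g. altered in every sample — are flagged and excluded from the BH
#' family, with a logged count).
#'
#' @param flags 0/1 matrix, samples x genes, with sample rownames.
#' @param status Named logical of binary kataegis status; must cover all
#'   rows of \code{flags}.
#' @param correct Yates correction flag passed to
#'   \code{\link{chiSquareTest}}.
#' @return \code{data.frame} with one row per gene: \code{gene, n,
#'   statistic, p_value, p_adjusted, degenerate}.
#' @export
driverAssociation <- function(flags, status, correct = FALSE) {
  flags <- as.matrix(flags)
  if (is.null(rownames(flags)) || is.null(colnames(flags))) {
    stop("flags needs sample rownames and gene colnames")
  }
  if (!all(rownames(flags) %in% names(status))) {
    stop("status must be defined for every sample")
  }
  st <- factor(status[rownames(flags)], levels = c(FALSE, TRUE))
  res <- lapply(colnames(flags), function(g) {
    tb <- table(factor(flags[, g], levels = 0:1), st)
    r <- chiSquareTest(tb, correct = correct)
    data.frame(gene = g, n = nrow(flags), statistic = r$statistic,
               p_value = r$p_value, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  ok <- !out$degenerate
  if (any(!ok)) {
    message("driverAssociation: ", sum(!ok),
            " degenerate gene(s) excluded from the BH family")
  }
  if (any(ok)) {
    out$p_adjusted[ok] <- bhAdjust(out$p_value[ok])
  }
  out
}
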