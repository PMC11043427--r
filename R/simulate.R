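## Ground-truth cohort simulator: uniform background SBSs plus injected
## APOBEC-like clusters, annotation tracks, metadata, driver flags, and an
## expression matrix with metagene structure.

#' Simulation configuration
#'
#' Defaults describe a desk-scale breast-cancer-like cohort: a synthetic
#' genome of 23 chromosomes totaling ~300 Mb (rates are per Mb, so results
#' transfer to larger genomes), uniform background SBSs at 1 per Mb per
#' sample, four clinical subgroups with kataegis positivity probabilities
#' mirroring reported binary frequencies (TNBC 0.38, ERpHER2n 0.48,
#' ERpHER2p 0.94, ERnHER2p 0.89), injected clusters of 6-25 SBSs with
#' 10-300 bp adjacent spacing and an APOBEC-like class distribution
#' (C>T 0.45, C>G 0.40, remaining 0.15 split evenly), strand-coordinated
#' clusters, a 25\% higher background burden in kataegis-positive samples,
#' an open-chromatin-like track covering 10\% of the genome with
#' cluster-placement enrichment factor 2, one driver gene with odds ratio 4
#' against kataegis status among null genes, and two status-shifted
#' metagenes in a log-scale Gaussian expression matrix.
#'
#' @param seed Integer seed; every simulator output is bit-reproducible
#'   given the seed.
#' @param chromosomeLengths Named or unnamed numeric vector of chromosome
#'   lengths in bp (chromosomes are named \code{chr1..chrN}).
#' @param backgroundRate Background SBS rate per Mb per sample.
#' @param backgroundClassProbs Named probabilities over the 6 classes for
#'   background SBSs.
#' @param subgroupSizes Named integer vector of samples per subgroup.
#' @param positivity Named kataegis positivity probability per subgroup.
#' @param lociPerPositive Function n -> integer vector: locus count draw
#'   for n positive samples (default 1 + geometric, mean 2).
#' @param clusterSizeRange Integer range of member SBSs per cluster.
#' @param clusterSpacingRange Integer range of adjacent spacing in bp.
#' @param clusterClassProbs Named class probabilities for cluster SBSs.
#' @param strandCoordinated One strand per cluster (\code{TRUE}, mimicking
#'   processive deamination) or an independent strand per SBS.
#' @param tmbEffect Fractional increase of the background rate in
#'   kataegis-positive samples (TMB-kataegis association).
#' @param tracks \code{data.frame(name, coverage, enrichment)}; at most one
#'   track may have \code{enrichment != 1} (cluster placement is steered
#'   into that track with probability \code{min(1, enrichment * coverage)}).
#' @param hotspot Optional \code{list(chromosome, start, end, probability)}:
#'   clusters land in this window with the given probability (recurrence
#'   hotspot).
#' @param indelRate Indels per Mb per sample (count only; no positions).
#' @param driverBaseRate Baseline alteration probability per driver gene.
#' @param driverOddsRatios Named odds ratios of alteration given positive
#'   kataegis status; unnamed genes are filled as null (OR 1) up to
#'   \code{nDriverGenes}.
#' @param nDriverGenes Total number of driver genes emitted.
#' @param nGenes Number of expression genes.
#' @param metagenes Named list of member-gene vectors.
#' @param metageneEffects Named log-scale mean shift per metagene in
#'   kataegis-positive samples.
#' @return A list of class \code{"SimulationConfig"}.
#' @seealso \code{\link{simulateCohort}}
#' @export
simulationConfig <- function(
    seed = 1L,
    chromosomeLengths = round(seq(23.5e6, 2.5e6, length.out = 23)),
    backgroundRate = 1,
    backgroundClassProbs = c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.32,
                             "T>A" = 0.08, "T>C" = 0.33, "T>G" = 0.09),
    subgroupSizes = c(TNBC = 60L, ERpHER2n = 80L,
                      ERpHER2p = 12L, ERnHER2p = 8L),
    positivity = c(TNBC = 0.38, ERpHER2n = 0.48,
                   ERpHER2p = 0.94, ERnHER2p = 0.89),
    lociPerPositive = function(n) 1L + stats::rgeom(n, 0.5),
    clusterSizeRange = c(6L, 25L),
    clusterSpacingRange = c(10L, 300L),
    clusterClassProbs = c("C>A" = 0.0375, "C>G" = 0.40, "C>T" = 0.45,
                          "T>A" = 0.0375, "T>C" = 0.0375, "T>G" = 0.0375),
    strandCoordinated = TRUE,
    tmbEffect = 0.25,
    tracks = data.frame(name = "ATAC", coverage = 0.10, enrichment = 2.0,
                        stringsAsFactors = FALSE),
    hotspot = NULL,
    indelRate = 0.1,
    driverBaseRate = 0.2,
    driverOddsRatios = c(TP53 = 4),
    nDriverGenes = 20L,
    nGenes = 200L,
    metagenes = list(
      mitotic_progression = sprintf("gene%03d", 1:20),
      immune_response = sprintf("gene%03d", 21:40)),
    metageneEffects = c(mitotic_progression = 0.8, immune_response = -0.4)) {
  stopifnot(all(chromosomeLengths > 0),
            backgroundRate >= 0,
            abs(sum(backgroundClassProbs) - 1) < 1e-8,
            abs(sum(clusterClassProbs) - 1) < 1e-8,
            all(names(positivity)[match(names(subgroupSizes),
                                        names(positivity))] ==
                  names(subgroupSizes)),
            all(positivity >= 0 & positivity <= 1),
            clusterSizeRange[1] >= 2L,
            clusterSpacingRange[1] >= 1L)
  if (!is.null(tracks)) {
    if (sum(tracks$enrichment != 1) > 1L) {
      stop("at most one track may have enrichment != 1")
    }
    if (any(tracks$coverage <= 0 | tracks$coverage >= 1)) {
      stop("track coverage must be in (0, 1)")
    }
    if (any(tracks$enrichment * tracks$coverage > 1)) {
      stop("enrichment * coverage must not exceed 1")
    }
  }
  structure(
    list(seed = as.integer(seed), chromosomeLengths = chromosomeLengths,
         backgroundRate = backgroundRate,
         backgroundClassProbs = backgroundClassProbs,
         subgroupSizes = subgroupSizes, positivity = positivity,
         lociPerPositive = lociPerPositive,
         clusterSizeRange = as.integer(clusterSizeRange),
         clusterSpacingRange = as.integer(clusterSpacingRange),
         clusterClassProbs = clusterClassProbs,
         strandCoordinated = strandCoordinated, tmbEffect = tmbEffect,
         tracks = tracks, hotspot = hotspot, indelRate = indelRate,
         driverBaseRate = driverBaseRate,
         driverOddsRatios = driverOddsRatios,
         nDriverGenes = as.integer(nDriverGenes),
         nGenes = as.integer(nGenes), metagenes = metagenes,
         metageneEffects = metageneEffects),
    class = "SimulationConfig")
}

## ref/alt emission for a class on a chosen strand: the pyrimidine-strand
## representation, or its reverse complement when flip is TRUE.
.emitRefAlt <- function(class, flip) {
  ref <- substr(class, 1L, 1L)
  alt <- substr(class, 3L, 3L)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  data.frame(ref = ifelse(flip, comp(ref), ref),
             alt = ifelse(flip, comp(alt), alt),
             stringsAsFactors = FALSE)
}

## Sample a start so that [start, start + span - 1] fits inside one of the
## regions; regions chosen with probability proportional to available room.
.placeSpan <- function(regions, span) {
  w <- GenomicRanges::width(regions)
  avail <- w - span
  ok <- which(avail > 0)
  if (!length(ok)) {
    stop("no region can host a cluster of span ", span, " bp")
  }
  idx <- if (length(ok) == 1L) ok else {
    ok[sample.int(length(ok), 1L, prob = avail[ok])]
  }
  start <- GenomicRanges::start(regions)[idx] +
    floor(stats::runif(1) * avail[idx])
  list(chromosome = as.character(GenomicRanges::seqnames(regions))[idx],
       start = as.integer(start))
}

#' Simulate a cohort with known kataegis ground truth
#'
#' Background SBS positions are drawn uniformly per chromosome at the
#' configured per-Mb rate (higher in kataegis-positive samples by the TMB
#' effect). For each kataegis-positive sample a locus count is drawn and
#' each cluster is placed — in the hotspot window with its configured
#' probability, inside the enriched track with probability
#' \code{enrichment * coverage}, otherwise uniformly — and built by
#' cumulative adjacent-spacing draws, with member classes from the cluster
#' class distribution and (by default) a single strand per cluster.
#' Metadata, driver flags, and the expression matrix are drawn from the
#' configured conditional models. All output is deterministic given the
#' config seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List with elements \code{genome} (\code{\link{GenomeBuild}}),
#'   \code{catalog} (\code{\link{SbsCatalog}}, all samples),
#'   \code{tracks} (named list of merged \code{GRanges}),
#'   \code{metadata} (\code{data.frame}: sample, subgroup, n_indel),
#'   \code{expression} (genes x samples), \code{metagenes},
#'   \code{drivers} (samples x genes 0/1), and \code{truth} (per-sample
#'   status/counts, per-locus table with member positions, and the injected
#'   effect sizes).
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nC <- length(config$chromosomeLengths)
  genome <- genomeBuild("synthetic", paste0("chr", seq_len(nC)),
                        config$chromosomeLengths)
  lens <- chromLengths(genome)
  totalMb <- sum(lens) / 1e6
  classes <- substitutionClasses()

  subgroup <- rep(names(config$subgroupSizes), config$subgroupSizes)
  nS <- length(subgroup)
  ids <- sprintf("S%04d", seq_len(nS))
  status <- stats::rbinom(nS, 1L, config$positivity[subgroup]) == 1L

  ## annotation tracks; placement regions for the (single) enriched track
  tracks <- list()
  enrichedRegions <- NULL
  outsideRegions <- NULL
  enrichedProb <- 0
  wholeGenome <- GenomicRanges::GRanges(
    seqnames = chromNames(genome),
    ranges = IRanges::IRanges(1L, as.integer(lens)),
    seqinfo = genome@seqinfo)
  if (!is.null(config$tracks)) {
    for (k in seq_len(nrow(config$tracks))) {
      cov <- config$tracks$coverage[k]
      intLen <- pmax(1L, as.integer(round(cov * lens)))
      starts <- 1L + floor(stats::runif(nC) * (lens - intLen + 1))
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        seqnames = chromNames(genome),
        ranges = IRanges::IRanges(as.integer(starts),
                                  width = intLen),
        seqinfo = genome@seqinfo))
      S4Vectors::metadata(gr)$trackName <- config$tracks$name[k]
      tracks[[config$tracks$name[k]]] <- gr
      if (config$tracks$enrichment[k] != 1) {
        enrichedRegions <- gr
        outsideRegions <- GenomicRanges::setdiff(wholeGenome, gr)
        enrichedProb <- min(1, config$tracks$enrichment[k] * cov)
      }
    }
  }

  ## background SBSs, drawn for all samples at once
  bgRate <- config$backgroundRate * ifelse(status, 1 + config$tmbEffect, 1)
  nBg <- stats::rpois(nS, bgRate * totalMb)
  totBg <- sum(nBg)
  bgSample <- rep(ids, nBg)
  bgChrom <- sample.int(nC, totBg, replace = TRUE, prob = lens)
  bgPos <- 1L + floor(stats::runif(totBg) * lens[bgChrom])
  bgClass <- classes[sample.int(6L, totBg, replace = TRUE,
                                prob = config$backgroundClassProbs[classes])]
  bgFlip <- stats::runif(totBg) < 0.5
  bgRA <- .emitRefAlt(bgClass, bgFlip)

  ## injected clusters
  nLociDraw <- config$lociPerPositive(nS)
  nLoci <- ifelse(status, nLociDraw, 0L)
  truthLoci <- list()
  members <- list()
  clSample <- clChrom <- clRef <- clAlt <- list()
  li <- 0L
  for (i in which(nLoci > 0L)) {
    for (l in seq_len(nLoci[i])) {
      ## sample.int avoids the sample(scalar) pitfall for degenerate ranges
      size <- config$clusterSizeRange[1] - 1L +
        sample.int(config$clusterSizeRange[2] -
                     config$clusterSizeRange[1] + 1L, 1L)
      spacing <- config$clusterSpacingRange[1] - 1L +
        sample.int(config$clusterSpacingRange[2] -
                     config$clusterSpacingRange[1] + 1L,
                   size - 1L, replace = TRUE)
      span <- sum(spacing) + 1L
      placement <- "uniform"
      if (!is.null(config$hotspot) &&
          stats::runif(1) < config$hotspot$probability) {
        hs <- config$hotspot
        start <- hs$start + floor(stats::runif(1) *
                                    max(1, hs$end - hs$start - span))
        chrom <- hs$chromosome
        placement <- "hotspot"
      } else if (!is.null(enrichedRegions) &&
                 stats::runif(1) < enrichedProb) {
        pl <- .placeSpan(enrichedRegions, span)
        chrom <- pl$chromosome
        start <- pl$start
        placement <- "track"
      } else if (!is.null(enrichedRegions)) {
        pl <- .placeSpan(outsideRegions, span)
        chrom <- pl$chromosome
        start <- pl$start
      } else {
        pl <- .placeSpan(wholeGenome, span)
        chrom <- pl$chromosome
        start <- pl$start
      }
      pos <- start + c(0L, cumsum(spacing))
      cls <- classes[sample.int(6L, size, replace = TRUE,
                                prob = config$clusterClassProbs[classes])]
      flip <- if (config$strandCoordinated) {
        rep(stats::runif(1) < 0.5, size)
      } else {
        stats::runif(size) < 0.5
      }
      ra <- .emitRefAlt(cls, flip)
      li <- li + 1L
      truthLoci[[li]] <- data.frame(
        sample = ids[i], chromosome = chrom,
        start = min(pos), end = max(pos), nSbs = size,
        placement = placement, stringsAsFactors = FALSE)
      members[[li]] <- pos
      clSample[[li]] <- rep(ids[i], size)
      clChrom[[li]] <- rep(chrom, size)
      clRef[[li]] <- ra$ref
      clAlt[[li]] <- ra$alt
    }
  }

  records <- data.frame(
    sample = c(bgSample, unlist(clSample)),
    chromosome = c(chromNames(genome)[bgChrom], unlist(clChrom)),
    position = c(bgPos, unlist(members)),
    ref = c(bgRA$ref, unlist(clRef)),
    alt = c(bgRA$alt, unlist(clAlt)),
    stringsAsFactors = FALSE)
  catalog <- sbsCatalog(records, genome)

  nIndel <- stats::rpois(nS, config$indelRate * totalMb)
  metadata <- data.frame(sample = ids, subgroup = subgroup,
                         n_indel = nIndel, stringsAsFactors = FALSE)

  ## driver flags: logistic model on true status
  geneNames <- names(config$driverOddsRatios)
  if (length(geneNames) < config$nDriverGenes) {
    geneNames <- c(geneNames,
                   sprintf("G%02d", seq_len(config$nDriverGenes -
                                              length(geneNames))))
  }
  ors <- stats::setNames(rep(1, length(geneNames)), geneNames)
  ors[names(config$driverOddsRatios)] <- config$driverOddsRatios
  q0 <- stats::qlogis(config$driverBaseRate)
  drivers <- vapply(geneNames, function(g) {
    stats::rbinom(nS, 1L, stats::plogis(q0 + log(ors[g]) * status))
  }, integer(nS))
  rownames(drivers) <- ids

  ## expression: log-scale Gaussian with status-conditional metagene shifts
  genes <- sprintf("gene%03d", seq_len(config$nGenes))
  expression <- matrix(stats::rnorm(config$nGenes * nS, mean = 5, sd = 1),
                       nrow = config$nGenes,
                       dimnames = list(genes, ids))
  for (m in names(config$metagenes)) {
    mem <- intersect(config$metagenes[[m]], genes)
    eff <- config$metageneEffects[[m]]
    if (length(mem) && any(status)) {
      expression[mem, status] <- expression[mem, status] + eff
    }
  }

  truth <- list(
    status = stats::setNames(status, ids),
    subgroup = stats::setNames(subgroup, ids),
    nBackground = stats::setNames(nBg, ids),
    nIndel = stats::setNames(nIndel, ids),
    nLoci = stats::setNames(as.integer(nLoci), ids),
    loci = if (li > 0L) do.call(rbind, truthLoci) else
      data.frame(sample = character(0), chromosome = character(0),
                 start = integer(0), end = integer(0), nSbs = integer(0),
                 placement = character(0)),
    members = members,
    tracks = config$tracks,
    positivity = config$positivity,
    driverOddsRatios = ors,
    metageneEffects = config$metageneEffects)

  list(genome = genome, catalog = catalog, tracks = tracks,
       metadata = metadata, expression = expression,
       metagenes = config$metagenes, drivers = drivers,
       truth = truth, config = config)
}

#' Match detected loci against simulation ground truth
#'
#' A truth locus is recovered when some detected locus of the same sample
#' and chromosome either overlaps it reciprocally by at least 50\% or
#' contains all of its member positions (within \code{slack} bp at the
#' boundaries). Detected loci matching no truth locus are false calls.
#'
#' @param loci Detected locus \code{GRanges}.
#' @param truth The \code{truth} element of \code{\link{simulateCohort}}
#'   output.
#' @param slack Boundary slack in bp for the containment check.
#' @return List with \code{sensitivity}, \code{nTruth}, \code{nRecovered},
#'   \code{nFalse}, a \code{boundary} \code{data.frame} (start/end error in
#'   bp per recovered locus), and \code{perSample} recovery counts.
#' @export
truthMatch <- function(loci, truth, slack = 0) {
  tl <- truth$loci
  nTruth <- nrow(tl)
  detKey <- paste(S4Vectors::mcols(loci)$sample,
                  as.character(GenomicRanges::seqnames(loci)))
  detIdx <- split(seq_along(loci), detKey)
  detStart <- GenomicRanges::start(loci)
  detEnd <- GenomicRanges::end(loci)
  detMatched <- rep(FALSE, length(loci))
  recovered <- rep(FALSE, nTruth)
  bStart <- bEnd <- rep(NA_real_, nTruth)
  for (k in seq_len(nTruth)) {
    cand <- detIdx[[paste(tl$sample[k], tl$chromosome[k])]]
    if (is.null(cand)) next
    ts <- tl$start[k]; te <- tl$end[k]
    ov <- pmin(detEnd[cand], te) - pmax(detStart[cand], ts) + 1
    recip <- ov >= 0.5 * (te - ts + 1) &
      ov >= 0.5 * (detEnd[cand] - detStart[cand] + 1)
    pos <- truth$members[[k]]
    contain <- vapply(cand, function(d) {
      all(pos >= detStart[d] - slack & pos <= detEnd[d] + slack)
    }, logical(1))
    hit <- cand[recip | contain]
    if (length(hit)) {
      recovered[k] <- TRUE
      detMatched[hit] <- TRUE
      best <- hit[which.max(pmin(detEnd[hit], te) -
                              pmax(detStart[hit], ts))]
      bStart[k] <- detStart[best] - min(pos)
      bEnd[k] <- detEnd[best] - max(pos)
    }
  }
  perSample <- data.frame(
    sample = names(truth$status),
    nTruth = as.integer(table(factor(tl$sample,
                                     levels = names(truth$status)))),
    nRecovered = as.integer(table(factor(tl$sample[recovered],
                                         levels = names(truth$status)))),
    stringsAsFactors = FALSE)
  list(
    sensitivity = if (nTruth > 0) mean(recovered) else NA_real_,
    nTruth = nTruth,
    nRecovered = sum(recovered),
    nFalse = sum(!detMatched),
    boundary = data.frame(sample = tl$sample[recovered],
                          startError = bStart[recovered],
                          endError = bEnd[recovered],
                          stringsAsFactors = FALSE),
    perSample = perSample)
}
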