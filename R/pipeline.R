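## End-to-end orchestration: detect -> characterize -> enrich -> associate,
## with deterministic TSV outputs and a JSON run manifest.

.writeTsv <- function(df, dir, file) {
  path <- file.path(dir, file)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full kataegis analysis pipeline
#'
#' Executes detection, locus characterization, context enrichment, and the
#' cohort association stages in order, writing one TSV per result table
#' plus a JSON manifest with per-stage row counts. Stages whose optional
#' inputs are missing (tracks, expression, drivers) are skipped with a
#' logged notice. Re-running with identical inputs produces byte-identical
#' outputs (no timestamps are written).
#'
#' @param catalog An \code{\link{SbsCatalog}} covering all samples.
#' @param metadata \code{data.frame} with columns \code{sample} and the
#'   subgroup column (plus optionally \code{n_indel}).
#' @param outDir Output directory (created if needed).
#' @param tracks Optional named list of annotation-track \code{GRanges}.
#' @param expression Optional genes x samples matrix.
#' @param metagenes Optional named list of metagene member genes.
#' @param drivers Optional samples x genes 0/1 matrix.
#' @param params \code{\link{DetectionParams}} for detection and filtering.
#' @param binWidth Recurrence bin width in bp (default 2 Mb).
#' @param cutoffs Event cut-offs for the binary frequency curves.
#' @param subgroupColumn Name of the subgroup column in \code{metadata}.
#' @param seed Recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(catalog, metadata, outDir, tracks = NULL,
                        expression = NULL, metagenes = NULL, drivers = NULL,
                        params = detectionParams(), binWidth = 2e6,
                        cutoffs = 1:5, subgroupColumn = "subgroup",
                        seed = NA) {
  stopifnot(methods::is(catalog, "SbsCatalog"),
            all(c("sample", subgroupColumn) %in% names(metadata)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  genome <- catalogGenome(catalog)
  samples <- metadata$sample
  subgroup <- stats::setNames(as.character(metadata[[subgroupColumn]]),
                              samples)
  rows <- list()

  ## detection
  loci <- filterLoci(detectKataegis(catalog, params), params, genome)
  rows$loci <- .writeTsv(lociTable(loci), outDir, "loci.tsv")

  ## binary status, TMB, frequency curves
  counts <- eventCounts(loci, samples, params@chromosomes, genome)
  indels <- if ("n_indel" %in% names(metadata)) {
    stats::setNames(metadata$n_indel, samples)
  } else {
    stats::setNames(rep(0, length(samples)), samples)
  }
  tmb <- tmbPerSample(catalog, indels)
  tmb <- stats::setNames(tmb[match(samples, names(tmb))], samples)
  tmb[is.na(tmb)] <- computeTmb(0, indels[is.na(tmb)],
                                sum(chromLengths(genome)))
  statusDf <- data.frame(sample = samples, subgroup = subgroup[samples],
                         n_events = counts[samples],
                         status = counts[samples] >= cutoffs[1],
                         n_indel = indels[samples], tmb = tmb,
                         stringsAsFactors = FALSE)
  rows$binary_status <- .writeTsv(statusDf, outDir, "binary_status.tsv")
  freq <- do.call(rbind, lapply(unique(subgroup), function(g) {
    f <- frequencyByCutoff(loci, samples[subgroup == g], cutoffs,
                           params@chromosomes, genome)
    data.frame(subgroup = g, cutoff = cutoffs, frequency = as.numeric(f),
               stringsAsFactors = FALSE)
  }))
  rows$frequency_curves <- .writeTsv(freq, outDir, "frequency_curves.tsv")

  ## characterization per subgroup
  lociSub <- subgroup[S4Vectors::mcols(loci)$sample]
  spec <- do.call(rbind, lapply(unique(subgroup), function(g) {
    sp <- mergedSpectrum(loci[lociSub == g], scope = g)
    data.frame(subgroup = g, class = names(sp$counts),
               count = as.integer(sp$counts),
               proportion = as.numeric(sp$proportions),
               stringsAsFactors = FALSE)
  }))
  rows$spectrum <- .writeTsv(spec, outDir, "spectrum.tsv")
  sizes <- lociTable(loci)
  sizes$subgroup <- subgroup[sizes$sample]
  rows$loci_sizes <- .writeTsv(
    sizes[, c("subgroup", "sample", "chromosome", "start", "end",
              "span_bp", "n_sbs")], outDir, "loci_sizes.tsv")
  chromCounts <- do.call(rbind, lapply(unique(subgroup), function(g) {
    cc <- eventsPerChromosome(loci[lociSub == g], genome)
    data.frame(subgroup = g, chromosome = names(cc),
               n_events = as.integer(cc), stringsAsFactors = FALSE)
  }))
  rows$chrom_counts <- .writeTsv(chromCounts, outDir, "chrom_counts.tsv")
  scheme <- makeBins(genome, binWidth)
  groupSizes <- table(subgroup)
  rec <- binRecurrence(loci, scheme,
                       groups = factor(lociSub, levels = names(groupSizes)),
                       groupSizes = as.numeric(groupSizes) |>
                         stats::setNames(names(groupSizes)))
  bins <- binRanges(scheme)
  recDf <- data.frame(bin = seq_len(nBins(scheme)),
                      chromosome = as.character(
                        GenomicRanges::seqnames(bins)),
                      start = GenomicRanges::start(bins) - 1L,
                      end = GenomicRanges::end(bins),
                      stringsAsFactors = FALSE)
  for (g in colnames(rec$counts)) {
    recDf[[paste0("count_", g)]] <- rec$counts[, g]
    recDf[[paste0("frequency_", g)]] <- rec$frequency[, g]
  }
  rows$bin_recurrence <- .writeTsv(recDf, outDir, "bin_recurrence.tsv")

  ## context enrichment
  if (!is.null(tracks) && length(tracks)) {
    status <- classifyBinary(loci, samples, cutoffs[1],
                             params@chromosomes, genome)
    cp <- list()
    er <- list()
    for (g in unique(subgroup)) {
      for (tn in names(tracks)) {
        p <- contextProportions(catalog, loci, tracks[[tn]],
                                samples = samples[subgroup == g],
                                status = status)
        p$subgroup <- g
        p$track <- tn
        cp[[paste(g, tn)]] <- p
        r <- enrichmentRatio(p)
        r$subgroup <- g
        r$track <- tn
        er[[paste(g, tn)]] <- r
      }
    }
    rows$context_proportions <- .writeTsv(do.call(rbind, cp), outDir,
                                          "context_proportions.tsv")
    rows$enrichment_ratios <- .writeTsv(do.call(rbind, er), outDir,
                                        "enrichment_ratios.tsv")
  } else {
    message("runPipeline: no annotation tracks; enrichment stage skipped")
  }

  ## association statistics
  status <- classifyBinary(loci, samples, cutoffs[1],
                           params@chromosomes, genome)
  assoc <- do.call(rbind, lapply(unique(subgroup), function(g) {
    sg <- samples[subgroup == g]
    pos <- sg[status[sg]]
    neg <- sg[!status[sg]]
    if (!length(pos) || !length(neg)) {
      return(data.frame(subgroup = g, variable = "tmb",
                        test = "wilcoxon_rank_sum", statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    r <- wilcoxonRankSum(tmb[pos], tmb[neg])
    data.frame(subgroup = g, variable = "tmb", test = r$test,
               statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  }))
  rows$association_tests <- .writeTsv(assoc, outDir,
                                      "association_tests.tsv")
  if (!is.null(drivers)) {
    dr <- do.call(rbind, lapply(unique(subgroup), function(g) {
      sg <- intersect(samples[subgroup == g], rownames(drivers))
      if (length(sg) < 2L) return(NULL)
      d <- driverAssociation(drivers[sg, , drop = FALSE], status[sg])
      d$subgroup <- g
      d
    }))
    rows$driver_association <- .writeTsv(dr, outDir,
                                         "driver_association.tsv")
  } else {
    message("runPipeline: no driver matrix; driver stage skipped")
  }
  if (!is.null(expression) && !is.null(metagenes)) {
    sc <- metageneRankScore(expression, metagenes)
    scDf <- data.frame(sample = rownames(sc), sc, check.names = FALSE,
                       stringsAsFactors = FALSE)
    rows$metagene_scores <- .writeTsv(scDf, outDir, "metagene_scores.tsv")
  } else {
    message("runPipeline: no expression/metagenes; metagene stage skipped")
  }

  manifest <- list(
    tool = "katascan",
    version = as.character(utils::packageVersion("katascan")),
    seed = seed,
    params = list(minSbs = params@minSbs,
                  imdThreshold = params@imdThreshold,
                  imdRule = params@imdRule,
                  minConfidence = params@minConfidence,
                  chromosomes = params@chromosomes),
    binWidth = binWidth,
    cutoffs = cutoffs,
    nSamples = length(samples),
    rowCounts = rows)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
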