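locusSetFromClasses <- function(perLocusClasses, genome = toyGenome()) {
  dfs <- lapply(seq_along(perLocusClasses), function(k) {
    cls <- perLocusClasses[[k]]
    data.frame(sample = paste0("s", k), chromosome = "chr1",
               position = seq(1000, by = 100, length.out = length(cls)),
               ref = substr(cls, 1, 1), alt = substr(cls, 3, 3),
               stringsAsFactors = FALSE)
  })
  detectKataegis(sbsCatalog(do.call(rbind, dfs), genome))
}

test_that("merged spectra strand-normalize and pool member SBSs", {
  # 6 G>A members: all collapse to C>T
  gb <- toyGenome()
  df <- data.frame(sample = "s1", chromosome = "chr1",
                   position = seq(1000, by = 100, length.out = 6),
                   ref = "G", alt = "A")
  sp <- mergedSpectrum(detectKataegis(sbsCatalog(df, gb)))
  expect_equal(unname(sp$proportions["C>T"]), 1.0)

  sp2 <- mergedSpectrum(locusSetFromClasses(
    list(c(rep("C>T", 3), rep("C>G", 3)))))
  expect_equal(unname(sp2$proportions[c("C>T", "C>G")]), c(0.5, 0.5))
  expect_equal(sum(sp2$proportions), 1)

  empty <- locusSetFromClasses(list(c("C>T", "C>T")))  # below minSbs
  spE <- mergedSpectrum(empty)
  expect_false(spE$defined)
  expect_true(all(is.na(spE$proportions)))
  expect_equal(sum(spE$counts), 0L)
})

test_that("merged spectrum is additive over per-tumor spectra", {
  loci <- locusSetFromClasses(list(
    rep("C>T", 8), c(rep("C>G", 6), "T>A", "T>C"), rep("T>C", 6)))
  all <- mergedSpectrum(loci)
  bySample <- lapply(unique(S4Vectors::mcols(loci)$sample), function(s) {
    mergedSpectrum(loci[S4Vectors::mcols(loci)$sample == s])$counts
  })
  expect_equal(all$counts, Reduce(`+`, bySample))
  expect_equal(sum(all$proportions), 1, tolerance = 1e-9)
})

test_that("locus size summaries return raw vectors and sort-based quantiles", {
  loci <- detectKataegis(catalogFromPositions(seq(100, 2600, by = 500)))
  ls <- locusSizeSummary(loci)
  expect_equal(ls$spanBp, 2501)
  expect_equal(ls$nSbs, 6)

  expect_length(locusSizeSummary(loci[0])$spanBp, 0L)

  set.seed(71)
  sim <- simulateCohort(simulationConfig(
    seed = 71, subgroupSizes = c(TNBC = 20L), positivity = c(TNBC = 1),
    backgroundRate = 0.2))
  loci2 <- detectKataegis(sim$catalog)
  ls2 <- locusSizeSummary(loci2)
  # sort-based oracle for the median
  srt <- sort(ls2$spanBp)
  n <- length(srt)
  oracleMedian <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    mean(srt[n / 2 + 0:1])
  expect_equal(unname(ls2$quantiles["spanBp", "50%"]), oracleMedian)
})

test_that("per-chromosome counts conserve totals over chromosomes 1-22", {
  gb <- genomeBuild("hg-like", paste0("chr", c(1:22, "X")), rep(2e6, 23))
  mkloci <- function(chrom, n) {
    do.call(rbind, lapply(seq_len(n), function(k) {
      data.frame(sample = paste0("s", chrom, k), chromosome = chrom,
                 position = seq(1000, by = 100, length.out = 6),
                 ref = "C", alt = "T")
    }))
  }
  df <- rbind(mkloci("chr17", 3), mkloci("chr8", 1), mkloci("chrX", 2))
  loci <- detectKataegis(sbsCatalog(df, gb))
  counts <- eventsPerChromosome(loci, gb)
  expect_equal(unname(counts["chr17"]), 3L)
  expect_equal(unname(counts["chr8"]), 1L)
  expect_false("chrX" %in% names(counts))  # default view excludes X
  expect_equal(sum(counts), 4L)            # conservation on 1-22
  expect_equal(sum(eventsPerChromosome(loci, gb, chromosomes = 1:23)), 6L)
})

test_that("bin recurrence counts events per bin and divides by group size", {
  gb <- toyGenome(len = 6e6)
  sc <- makeBins(gb, 2e6)
  # two tumors, one locus each, midpoints in the same bin; group of 4
  df <- rbind(
    data.frame(sample = "t1", chromosome = "chr1",
               position = seq(2.5e6, by = 100, length.out = 6),
               ref = "C", alt = "T"),
    data.frame(sample = "t2", chromosome = "chr1",
               position = seq(2.6e6, by = 100, length.out = 6),
               ref = "C", alt = "T"))
  loci <- detectKataegis(sbsCatalog(df, gb))
  rec <- binRecurrence(loci, sc, groups = rep("g", 2),
                       groupSizes = c(g = 4))
  expect_equal(as.integer(rec$counts[, "g"]), c(0L, 2L, 0L))
  expect_equal(unname(rec$frequency[2, "g"]), 0.5)

  # one tumor with two loci in one bin counts two events
  df2 <- rbind(
    data.frame(sample = "t1", chromosome = "chr1",
               position = seq(2.1e6, by = 100, length.out = 6),
               ref = "C", alt = "T"),
    data.frame(sample = "t1", chromosome = "chr1",
               position = seq(3.9e6, by = 100, length.out = 6),
               ref = "C", alt = "T"))
  loci2 <- detectKataegis(sbsCatalog(df2, gb))
  rec2 <- binRecurrence(loci2, sc, groups = rep("g", 2),
                        groupSizes = c(g = 1))
  expect_equal(sum(rec2$counts), 2L)
  expect_equal(as.integer(rec2$counts[, "g"]), c(0L, 2L, 0L))
})

test_that("bin and chromosome recurrence conserve the locus total", {
  set.seed(73)
  sim <- simulateCohort(simulationConfig(
    seed = 73, subgroupSizes = c(A = 15L, B = 10L),
    positivity = c(A = 0.9, B = 0.6), backgroundRate = 0.5))
  loci <- filterLoci(detectKataegis(sim$catalog), genome = sim$genome)
  sc <- makeBins(sim$genome, 2e6)
  sub <- sim$truth$subgroup[S4Vectors::mcols(loci)$sample]
  sizes <- table(sim$truth$subgroup)
  rec <- binRecurrence(loci, sc, groups = factor(sub, names(sizes)),
                       groupSizes = setNames(as.numeric(sizes),
                                             names(sizes)))
  expect_equal(sum(rec$counts), length(loci))
  perChrom <- eventsPerChromosome(loci, sim$genome, chromosomes = 1:23)
  expect_equal(sum(perChrom), length(loci))
  for (g in names(sizes)) {
    expect_equal(sum(rec$counts[, g]), sum(sub == g))
  }
  expect_true(all(rec$frequency >= 0))
})

test_that("a simulated hotspot bin attains the group's maximum frequency", {
  cfg <- simulationConfig(
    seed = 79, subgroupSizes = c(A = 40L), positivity = c(A = 1),
    backgroundRate = 0.2, tracks = NULL,
    hotspot = list(chromosome = "chr5", start = 4.2e6, end = 4.6e6,
                   probability = 0.5))
  sim <- simulateCohort(cfg)
  loci <- filterLoci(detectKataegis(sim$catalog), genome = sim$genome)
  sc <- makeBins(sim$genome, 2e6)
  rec <- binRecurrence(loci, sc, groups = rep("A", length(loci)),
                       groupSizes = c(A = 40))
  hotBin <- locateBin(sc, "chr5", 4.4e6)
  expect_equal(unname(which.max(rec$frequency[, "A"])), hotBin)
})
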