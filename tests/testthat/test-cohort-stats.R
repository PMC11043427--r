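sixRun <- function(sample, chromosome, at = 1000) {
  data.frame(sample = sample, chromosome = chromosome,
             position = seq(at, by = 100, length.out = 6),
             ref = "C", alt = "T", stringsAsFactors = FALSE)
}

test_that("binary classification counts events on the 1-23 ordinal set", {
  gb <- genomeBuild("hg-like", c("chr1", "chrX", "chrY"), rep(1e6, 3))
  df <- rbind(sixRun("a", "chrX"), sixRun("b", "chrY"),
              sixRun("c", "chr1"), sixRun("c", "chr1", at = 5e5))
  loci <- detectKataegis(sbsCatalog(df, gb))
  samples <- c("a", "b", "c", "d")
  status <- classifyBinary(loci, samples, genome = gb)
  # X (ordinal 23) counts; Y does not; absent sample is negative
  expect_equal(unname(status), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(eventCounts(loci, samples, genome = gb)),
               c(1L, 0L, 2L, 0L))
  expect_equal(unname(classifyBinary(loci, samples, cutoff = 2,
                                     genome = gb)),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_error(classifyBinary(loci, samples, cutoff = 0), ">= 1")
})

test_that("frequency curves are monotone non-increasing and match counting", {
  set.seed(97)
  sim <- simulateCohort(simulationConfig(
    seed = 97, subgroupSizes = c(A = 30L, B = 30L),
    positivity = c(A = 0.8, B = 0.3)))
  loci <- filterLoci(detectKataegis(sim$catalog), genome = sim$genome)
  for (g in c("A", "B")) {
    sg <- names(sim$truth$subgroup)[sim$truth$subgroup == g]
    f <- frequencyByCutoff(loci, sg, cutoffs = 1:5, genome = sim$genome)
    expect_true(all(diff(f) <= 0))
    # direct counting oracle at each cutoff
    counts <- eventCounts(loci, sg, genome = sim$genome)
    for (k in 1:5) {
      expect_equal(unname(f[as.character(k)]),
                   sum(counts >= k) / length(sg))
    }
    # positive set at higher cutoffs is nested in the cutoff-1 set
    s1 <- classifyBinary(loci, sg, 1, genome = sim$genome)
    s3 <- classifyBinary(loci, sg, 3, genome = sim$genome)
    expect_true(all(names(which(s3)) %in% names(which(s1))))
  }
})

test_that("TMB is mutations per megabase", {
  expect_equal(computeTmb(3000, 0, 3e9), 1.0)
  expect_equal(computeTmb(0, 0, 3e9), 0.0)
  expect_equal(computeTmb(100, 50, 50e6), 3.0)
  expect_error(computeTmb(1, 0, 0), "> 0")

  set.seed(101)
  sim <- simulateCohort(simulationConfig(
    seed = 101, subgroupSizes = c(A = 40L), positivity = c(A = 0),
    backgroundRate = 2, tmbEffect = 0, indelRate = 0))
  tmb <- tmbPerSample(sim$catalog)
  # Poisson rate recovery: mean TMB within 4 SD of 2 per Mb
  gsize <- genomeSize(sim$genome)
  se <- sqrt(2 / (gsize / 1e6)) / sqrt(40)
  expect_lt(abs(mean(tmb) - 2), 4 * se)
})

test_that("metagene rank scores are single-sample mean-rank fractions", {
  expr <- matrix(c(1, 2, 3, 4, 5), nrow = 5,
                 dimnames = list(paste0("g", 1:5), "s1"))
  sc <- metageneRankScore(expr, list(top = c("g4", "g5")))
  expect_equal(sc["s1", "top"], (4 + 5) / 2 / 5)  # 0.9
  scAll <- metageneRankScore(expr, list(all = paste0("g", 1:5)))
  G <- 5
  expect_equal(scAll["s1", "all"], (G + 1) / (2 * G))
  # adding other samples does not change a sample's score
  expr2 <- cbind(expr, s2 = c(9, 1, 4, 2, 7))
  sc2 <- metageneRankScore(expr2, list(top = c("g4", "g5")))
  expect_equal(sc2["s1", "top"], sc["s1", "top"])
  expect_warning(metageneRankScore(expr, list(none = "gX")), "no measured")
})

test_that("wilcoxon wrapper is exact for small tie-free data, else corrected", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 2 / 6)  # most extreme of C(4,2) orderings
  # identical multisets sit at the null center
  r2 <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r2$p_value, 0.9)
  # monotone-transform invariance of the rank statistic
  set.seed(103)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  expect_equal(wilcoxonRankSum(x, y)$p_value,
               wilcoxonRankSum(exp(x), exp(y))$p_value)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("kruskal-wallis ties out against the two-group wilcoxon z^2", {
  set.seed(107)
  x <- rnorm(25); y <- rnorm(25, 0.4)
  kw <- kruskalWallis(list(x, y))
  wx <- wilcoxonRankSum(x, y, exact = FALSE, correct = FALSE)
  expect_equal(kw$p_value, wx$p_value, tolerance = 1e-10)
  # monotone-transform invariance
  z <- rnorm(20)
  expect_equal(kruskalWallis(list(x, y, z))$p_value,
               kruskalWallis(list(exp(x), exp(y), exp(z)))$p_value)
  deg <- kruskalWallis(list(rep(1, 5), rep(1, 6)))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_error(kruskalWallis(list(1:3)), "two non-empty")
})

test_that("chi-square statistic matches the hand-computed Pearson sum", {
  flat <- chiSquareTest(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  r <- chiSquareTest(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3)  # all E = 15: 4 * 25/15
  rY <- chiSquareTest(matrix(c(20, 10, 10, 20), 2), correct = TRUE)
  expect_lt(rY$statistic, r$statistic)
  deg <- chiSquareTest(matrix(c(0, 0, 10, 20), 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("BH adjustment matches a longhand step-up oracle", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(109)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("driver association flags degenerate genes and ranks true signal", {
  set.seed(113)
  n <- 200
  status <- setNames(rbinom(n, 1, 0.5) == 1, sprintf("s%03d", 1:n))
  # gene altered in every sample: degenerate, excluded from BH
  flagsDeg <- matrix(1L, n, 1, dimnames = list(names(status), "allAltered"))
  suppressMessages(dg <- driverAssociation(flagsDeg, status))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p_adjusted))

  # one enriched gene (OR 4) among null genes: smallest adjusted p in most
  # replicates; permuting status destroys the signal
  nGenes <- 30
  hits <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    st <- rbinom(n, 1, 0.5) == 1
    flags <- vapply(seq_len(nGenes), function(g) {
      or <- if (g == 1) 4 else 1
      rbinom(n, 1, plogis(qlogis(0.2) + log(or) * st))
    }, integer(n))
    dimnames(flags) <- list(sprintf("s%03d", 1:n),
                            sprintf("g%02d", seq_len(nGenes)))
    res <- driverAssociation(flags, setNames(st, rownames(flags)))
    if (which.min(res$p_adjusted) == 1L) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)

  # permutation null: adjusted p for the enriched gene is typically large
  st <- rbinom(n, 1, 0.5) == 1
  flags <- vapply(seq_len(nGenes), function(g) {
    or <- if (g == 1) 4 else 1
    rbinom(n, 1, plogis(qlogis(0.2) + log(or) * st))
  }, integer(n))
  dimnames(flags) <- list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:nGenes))
  perm <- replicate(20, {
    stP <- setNames(sample(st), rownames(flags))
    driverAssociation(flags, stP)$p_value[1]
  })
  expect_gt(mean(perm > 0.05), 0.5)  # uniform-like under permutation
})
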