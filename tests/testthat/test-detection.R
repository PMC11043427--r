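test_that("the max-IMD run rule finds textbook clusters", {
  loci <- detectKataegis(catalogFromPositions(seq(100, 2600, by = 500)))
  expect_equal(length(loci), 1L)
  mc <- S4Vectors::mcols(loci)
  expect_equal(GenomicRanges::start(loci), 100)
  expect_equal(GenomicRanges::end(loci), 2600)
  expect_equal(mc$nSbs, 6L)
  expect_equal(mc$maxImd, 500)
  expect_equal(mc$meanImd, 500)
  expect_equal(mc$spanBp, 2501)

  # below the run-length floor
  expect_length(detectKataegis(catalogFromPositions(
    seq(100, 500, by = 100))), 0L)
})

test_that("max and mean rules discriminate the canonical two-burst catalog", {
  pos <- c(1, 101, 201, 301, 5301, 5401, 5501)  # gaps 100x3, 5000, 100x2
  cat1 <- catalogFromPositions(pos)
  expect_length(detectKataegis(cat1, detectionParams(imdRule = "max")), 0L)
  lm <- detectKataegis(cat1, detectionParams(imdRule = "mean"))
  expect_length(lm, 1L)
  expect_equal(S4Vectors::mcols(lm)$nSbs, 7L)
  expect_equal(S4Vectors::mcols(lm)$meanImd, 5500 / 6)
})

test_that("both rules match brute-force window enumeration on random catalogs", {
  set.seed(53)
  pm <- detectionParams(imdRule = "max")
  pn <- detectionParams(imdRule = "mean")
  # exhaustive-scale catalogs (n <= 25) plus larger sampled ones
  sizes <- c(rep(0:25, 4), sample(26:300, 30, replace = TRUE))
  for (n in sizes) {
    pos <- if (n > 0) sort(sample.int(2e5, n, replace = TRUE)) else integer(0)
    cat1 <- if (n > 0) catalogFromPositions(unique(pos)) else
      catalogFromPositions(integer(0))
    p <- GenomicRanges::start(variants(cat1))
    expect_identical(lociIndexMatrix(detectKataegis(cat1, pm)),
                     oracleMaxRule(p, 1000, 6L))
    expect_identical(lociIndexMatrix(detectKataegis(cat1, pn)),
                     oracleMeanRule(p, 1000, 6L))
  }
})

test_that("member sets partition and ignore catalog read order", {
  set.seed(59)
  pos <- sort(c(randomPositions(120, 5e5),
                seq(2e6, 2e6 + 5 * 200, by = 200)))
  df <- data.frame(sample = "s1", chromosome = "chr1", position = pos,
                   ref = "C", alt = "T")
  cat1 <- sbsCatalog(df, toyGenome())
  catShuffled <- sbsCatalog(df[sample(nrow(df)), ], toyGenome())
  for (rule in c("max", "mean")) {
    p <- detectionParams(imdRule = rule)
    l1 <- detectKataegis(cat1, p)
    l2 <- detectKataegis(catShuffled, p)
    expect_identical(lociIndexMatrix(l1), lociIndexMatrix(l2))
    members <- unlist(lociMembers(l1))
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("relaxing max-rule parameters never removes member SBSs", {
  set.seed(61)
  for (rep in 1:20) {
    pos <- sort(sample.int(3e5, 150))
    cat1 <- catalogFromPositions(pos)
    memberPos <- function(params) {
      l <- detectKataegis(cat1, params)
      pos[unlist(lociMembers(l))]
    }
    base <- memberPos(detectionParams(imdThreshold = 1000, minSbs = 6))
    wider <- memberPos(detectionParams(imdThreshold = 2000, minSbs = 6))
    shorter <- memberPos(detectionParams(imdThreshold = 1000, minSbs = 5))
    expect_true(all(base %in% wider))
    expect_true(all(base %in% shorter))
  }
})

test_that("deleting a non-member SBS leaves max-rule loci unchanged", {
  set.seed(67)
  pos <- sort(c(sample.int(9e6, 40), seq(5e6, 5e6 + 7 * 150, by = 150)))
  pos <- unique(pos)
  cat1 <- catalogFromPositions(pos)
  loci <- detectKataegis(cat1)
  memberPositions <- pos[unlist(lociMembers(loci))]
  nonMembers <- setdiff(pos, memberPositions)
  for (del in nonMembers[seq_len(min(10, length(nonMembers)))]) {
    cat2 <- catalogFromPositions(setdiff(pos, del))
    loci2 <- detectKataegis(cat2)
    expect_equal(GenomicRanges::start(loci2), GenomicRanges::start(loci))
    expect_equal(GenomicRanges::end(loci2), GenomicRanges::end(loci))
  }
})

test_that("IMDs never cross sample or chromosome boundaries", {
  gb <- toyGenome(n = 2L)
  # 3 + 3 SBSs adjacent across a chromosome boundary would merge if the
  # boundary were ignored; they must not
  df <- data.frame(sample = "s1",
                   chromosome = rep(c("chr1", "chr2"), each = 3),
                   position = c(9e6 + c(0, 100, 200), c(1, 101, 201)),
                   ref = "C", alt = "T")
  expect_length(detectKataegis(sbsCatalog(df, gb)), 0L)
  # same positions split across two samples must not merge either
  df2 <- data.frame(sample = rep(c("a", "b"), each = 3),
                    chromosome = "chr1",
                    position = rep(c(1, 101, 201), 2),
                    ref = "C", alt = "T")
  expect_length(detectKataegis(sbsCatalog(df2, gb)), 0L)
})

test_that("same-position multi-allelic records contribute an IMD of zero", {
  df <- data.frame(sample = "s1", chromosome = "chr1",
                   position = c(100, 100, 300, 500, 700, 900),
                   ref = "C", alt = c("T", "G", "T", "T", "T", "T"))
  loci <- detectKataegis(sbsCatalog(df, toyGenome()))
  expect_length(loci, 1L)
  expect_equal(S4Vectors::mcols(loci)$nSbs, 6L)
})

test_that("confidence tiers follow the APOBEC-consistency surrogate", {
  mk <- function(classes, spacing = 100) {
    ref <- substr(classes, 1, 1)
    alt <- substr(classes, 3, 3)
    df <- data.frame(sample = "s1", chromosome = "chr1",
                     position = seq(1000, by = spacing,
                                    length.out = length(classes)),
                     ref = ref, alt = alt)
    detectKataegis(sbsCatalog(df, toyGenome()))
  }
  # 6 all C>T: APOBEC-consistent but below 10 members -> tier 2
  expect_equal(S4Vectors::mcols(mk(rep("C>T", 6)))$confidence, 2L)
  # 12 members, 11 C>G: 91.7% C>N and n >= 10 -> tier 3
  expect_equal(S4Vectors::mcols(mk(c(rep("C>G", 11), "T>A")))$confidence, 3L)
  # 3 C>T + 3 T>A: 50% < 70% -> tier 1
  expect_equal(S4Vectors::mcols(mk(c(rep("C>T", 3),
                                     rep("T>A", 3))))$confidence, 1L)
  # confidenceScore() recomputes identically from class counts
  l <- mk(c(rep("C>G", 11), "T>A"))
  expect_equal(confidenceScore(l), S4Vectors::mcols(l)$confidence)
})

test_that("filterLoci applies confidence and chromosome-set rules", {
  gb <- genomeBuild("hg-like", c("chr1", "chrX", "chrY"), rep(1e6, 3))
  df <- data.frame(sample = "s1",
                   chromosome = rep(c("chr1", "chrX", "chrY"), each = 6),
                   position = rep(seq(100, 600, by = 100), 3),
                   ref = "C", alt = "T")
  loci <- detectKataegis(sbsCatalog(df, gb))
  expect_length(loci, 3L)
  kept <- filterLoci(loci, detectionParams(), gb)
  # default chromosomes 1-23: X kept, Y always removed
  expect_setequal(as.character(GenomicRanges::seqnames(kept)),
                  c("chr1", "chrX"))
  # min confidence 3 removes 6-member loci (tier 2)
  expect_length(filterLoci(loci, detectionParams(minConfidence = 3), gb), 0L)
})
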