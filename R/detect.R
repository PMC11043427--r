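## Core kataegis detector: intermutation-distance run rules, confidence
## tiers, and locus filtering.

#' Construct detection parameters
#'
#' Defaults reproduce the standard kataegis definition: at least six
#' consecutive SBSs with a maximum intermutation distance of 1000 bp
#' (\code{imdRule = "max"}). The textbook mean-IMD variant ("six or more
#' consecutive mutations with an average intermutation distance of
#' <= 1000 bp") is available as \code{imdRule = "mean"}.
#'
#' @param minSbs Minimum run length (default 6).
#' @param imdThreshold IMD threshold in bp (default 1000).
#' @param imdRule \code{"max"} or \code{"mean"}.
#' @param minConfidence Minimum confidence tier for \code{\link{filterLoci}}
#'   (default 1).
#' @param chromosomes Canonical chromosome ordinals retained by
#'   \code{\link{filterLoci}} (default \code{1:23}: autosomes plus X; Y is
#'   always excluded).
#' @return A \code{\link{DetectionParams}}.
#' @examples
#' detectionParams(imdRule = "mean")
#' @export
detectionParams <- function(minSbs = 6L, imdThreshold = 1000,
                            imdRule = c("max", "mean"),
                            minConfidence = 1L, chromosomes = 1:23) {
  imdRule <- match.arg(imdRule)
  methods::new("DetectionParams",
               minSbs = as.integer(minSbs),
               imdThreshold = as.numeric(imdThreshold),
               imdRule = imdRule,
               minConfidence = as.integer(minConfidence),
               chromosomes = as.integer(chromosomes))
}

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams: rule=", object@imdRule,
      ", minSbs=", object@minSbs,
      ", imdThreshold=", object@imdThreshold, " bp",
      ", minConfidence=", object@minConfidence, "\n", sep = "")
})

## Maximal runs where every adjacent gap qualifies. `ok[k]` flags the gap
## between records k and k+1 (within one sample-chromosome group).
.maxRuleRuns <- function(ok, minSbs) {
  if (!length(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= (minSbs - 1L)
  if (!any(sel)) return(NULL)
  cbind(first = starts[sel], last = ends[sel] + 1L)
}

## Mean-rule loci for one position-sorted vector. A window [i, j] qualifies
## when j - i + 1 >= minSbs and (p[j] - p[i]) / (j - i) <= thr. Windows that
## share the left index i union to the contiguous interval [i, lastq(i)];
## overlapping intervals (sharing at least one index) merge into loci.
.meanRuleRuns <- function(p, thr, minSbs) {
  n <- length(p)
  if (n < minSbs) return(NULL)
  lastq <- rep.int(NA_integer_, n)
  for (i in seq_len(n - minSbs + 1L)) {
    j <- (i + minSbs - 1L):n
    hit <- j[(p[j] - p[i]) <= thr * (j - i)]
    if (length(hit)) lastq[i] <- hit[length(hit)]
  }
  idx <- which(!is.na(lastq))
  if (!length(idx)) return(NULL)
  s <- idx
  e <- lastq[idx]
  firsts <- s[1L]
  lasts <- e[1L]
  k <- 1L
  for (t in seq_along(s)[-1L]) {
    if (s[t] <= lasts[k]) {  # shares an index with the open locus
      lasts[k] <- max(lasts[k], e[t])
    } else {
      k <- k + 1L
      firsts[k] <- s[t]
      lasts[k] <- e[t]
    }
  }
  cbind(first = firsts, last = lasts)
}

## Assemble locus GRanges from member index ranges into the catalog.
.buildLoci <- function(catalog, memberFirst, memberLast) {
  v <- catalog@variants
  genome <- catalog@genome
  cls <- S4Vectors::mcols(v)$class
  if (length(memberFirst) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = genome@seqinfo)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      sample = character(0), nSbs = integer(0), spanBp = numeric(0),
      meanImd = numeric(0), maxImd = numeric(0), confidence = integer(0),
      memberFirst = integer(0), memberLast = integer(0))
    S4Vectors::mcols(gr)$classCounts <-
      matrix(0L, nrow = 0L, ncol = 6L,
             dimnames = list(NULL, substitutionClasses()))
    return(gr)
  }
  memberFirst <- as.integer(unname(memberFirst))
  memberLast <- as.integer(unname(memberLast))
  pos <- GenomicRanges::start(v)
  d <- diff(pos)
  n <- memberLast - memberFirst + 1L
  st <- pos[memberFirst]
  en <- pos[memberLast]
  maxImd <- mapply(function(f, l) max(d[f:(l - 1L)]), memberFirst, memberLast)
  locusId <- rep(seq_along(memberFirst), n)
  vIdx <- sequence(n, from = memberFirst)
  cc <- unclass(table(factor(locusId, levels = seq_along(memberFirst)),
                      cls[vIdx]))
  dimnames(cc) <- list(NULL, substitutionClasses())
  storage.mode(cc) <- "integer"
  cFrac <- rowSums(cc[, c("C>A", "C>G", "C>T"), drop = FALSE]) / n
  conf <- ifelse(cFrac >= 0.7, ifelse(n >= 10L, 3L, 2L), 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(v)[memberFirst],
    ranges = IRanges::IRanges(start = st, end = en),
    seqinfo = genome@seqinfo)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample = as.character(S4Vectors::mcols(v)$sample[memberFirst]),
    nSbs = as.integer(n),
    spanBp = as.numeric(en - st + 1),
    meanImd = (en - st) / (n - 1),
    maxImd = as.numeric(maxImd),
    confidence = as.integer(conf),
    memberFirst = as.integer(memberFirst),
    memberLast = as.integer(memberLast))
  S4Vectors::mcols(gr)$classCounts <- cc
  gr
}

#' Detect kataegis loci in an SBS catalog
#'
#' Under \code{imdRule = "max"}, loci are the maximal runs of consecutive
#' SBSs (per sample and chromosome) in which every adjacent intermutation
#' distance is at most \code{imdThreshold}, with run length at least
#' \code{minSbs}. Under \code{imdRule = "mean"}, every window of at least
#' \code{minSbs} consecutive SBSs whose mean adjacent IMD (which telescopes
#' to \code{(last - first) / (n - 1)}) is at most the threshold qualifies,
#' and overlapping qualifying windows are merged by union into maximal
#' disjoint loci. IMDs are never computed across chromosome or sample
#' boundaries; same-position multi-allelic records contribute an IMD of 0.
#'
#' Every locus carries a deterministic confidence tier (see
#' \code{\link{confidenceScore}}); no chromosome or confidence filtering is
#' applied here — use \code{\link{filterLoci}}.
#'
#' @param catalog An \code{\link{SbsCatalog}} (sorted by construction).
#' @param params A \code{\link{DetectionParams}}.
#' @return A \code{GRanges} of loci with metadata columns \code{sample},
#'   \code{nSbs}, \code{spanBp}, \code{meanImd}, \code{maxImd},
#'   \code{confidence}, \code{memberFirst}/\code{memberLast} (index range of
#'   member SBSs in the catalog), and a 6-column \code{classCounts} matrix,
#'   ordered by (sample, chromosome, start).
#' @examples
#' gb <- genomeBuild("toy", "chr1", 1e6)
#' cat1 <- sbsCatalog(data.frame(sample = "s1", chromosome = "chr1",
#'                               position = seq(100, 2600, by = 500),
#'                               ref = "C", alt = "T"), gb)
#' detectKataegis(cat1)
#' @export
detectKataegis <- function(catalog, params = detectionParams()) {
  stopifnot(methods::is(catalog, "SbsCatalog"),
            methods::is(params, "DetectionParams"))
  methods::validObject(params)
  v <- catalog@variants
  if (length(v) < params@minSbs) {
    return(.buildLoci(catalog, integer(0), integer(0)))
  }
  pos <- GenomicRanges::start(v)
  grp <- cumsum(c(
    TRUE,
    diff(as.integer(S4Vectors::mcols(v)$sample)) != 0L |
      diff(as.integer(GenomicRanges::seqnames(v))) != 0L))
  sameGrp <- diff(grp) == 0L
  gapOk <- sameGrp & diff(pos) <= params@imdThreshold
  if (params@imdRule == "max") {
    runs <- .maxRuleRuns(gapOk, params@minSbs)
  } else {
    ## A qualifying mean-IMD window necessarily contains a gap <= threshold,
    ## so only groups with at least one qualifying gap can host a locus.
    candGrp <- unique(grp[c(gapOk, FALSE)])
    runs <- NULL
    for (g in candGrp) {
      at <- which(grp == g)
      r <- .meanRuleRuns(pos[at], params@imdThreshold, params@minSbs)
      if (!is.null(r)) {
        runs <- rbind(runs, r + at[1L] - 1L)
      }
    }
    if (!is.null(runs)) {
      runs <- runs[order(runs[, "first"]), , drop = FALSE]
    }
  }
  if (is.null(runs)) {
    return(.buildLoci(catalog, integer(0), integer(0)))
  }
  .buildLoci(catalog, runs[, "first"], runs[, "last"])
}

#' Confidence tier of detected loci
#'
#' A deterministic three-tier surrogate score based on the APOBEC
#' consistency of the member substitutions: tier 1 = passes detection;
#' tier 2 = at least 70\% of member substitutions are pyrimidine C>N after
#' normalization; tier 3 = tier 2 and at least 10 member SBSs.
#'
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}}.
#' @return Integer vector of tiers in 1..3.
#' @export
confidenceScore <- function(loci) {
  mc <- S4Vectors::mcols(loci)
  if (!length(loci)) return(integer(0))
  cc <- mc$classCounts
  n <- mc$nSbs
  cFrac <- rowSums(cc[, c("C>A", "C>G", "C>T"), drop = FALSE]) / n
  as.integer(ifelse(cFrac >= 0.7, ifelse(n >= 10L, 3L, 2L), 1L))
}

#' Filter detected loci by confidence and chromosome set
#'
#' With the default \code{minConfidence = 1} this is a chromosome filter
#' only: loci on chromosomes outside \code{params@chromosomes} (canonical
#' ordinals; default 1-23, so Y is always removed) are dropped.
#'
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}}.
#' @param params A \code{\link{DetectionParams}}.
#' @param genome Optional \code{\link{GenomeBuild}} supplying chromosome
#'   ordinals; when absent, ordinals are parsed from the locus seqlevels.
#' @return The filtered locus \code{GRanges}.
#' @export
filterLoci <- function(loci, params = detectionParams(), genome = NULL) {
  if (!length(loci)) return(loci)
  ords <- .ordinalMap(loci, genome)
  keep <- S4Vectors::mcols(loci)$confidence >= params@minConfidence &
    ords[as.character(GenomicRanges::seqnames(loci))] %in% params@chromosomes
  loci[keep]
}

## Ordinal lookup named by seqlevel, from a GenomeBuild when available.
.ordinalMap <- function(loci, genome = NULL) {
  if (!is.null(genome)) return(chromOrdinals(genome))
  lv <- GenomeInfoDb::seqlevels(loci)
  ord <- .chromOrdinal(lv)
  ord[is.na(ord)] <- seq_along(lv)[is.na(ord)]
  stats::setNames(ord, lv)
}

#' Member SBS indices of loci
#'
#' @param loci Locus \code{GRanges} from \code{\link{detectKataegis}}.
#' @return \code{IntegerList}, one element per locus, of row indices into
#'   the catalog's \code{\link{variants}}.
#' @export
lociMembers <- function(loci) {
  mc <- S4Vectors::mcols(loci)
  IRanges::IntegerList(mapply(seq.int, mc$memberFirst, mc$memberLast,
                              SIMPLIFY = FALSE))
}
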