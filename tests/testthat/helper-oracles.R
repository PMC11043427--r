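# Independent brute-force oracles used across the suite. These enumerate
# windows / intervals directly and share no code with the package internals.

# Merge index windows (first, last) that share at least one index.
mergeWindowsOracle <- function(w) {
  if (is.null(w) || nrow(w) == 0L) {
    return(matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("first", "last"))))
  }
  w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
  out <- list(w[1L, ])
  for (k in seq_len(nrow(w))[-1L]) {
    cur <- out[[length(out)]]
    if (w[k, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], w[k, 2L])
      out[[length(out)]] <- cur
    } else {
      out[[length(out) + 1L]] <- w[k, ]
    }
  }
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("first", "last"))
  m
}

# Max-IMD rule by full window enumeration: a window qualifies when every
# adjacent gap is <= thr and it has >= minSbs members.
oracleMaxRule <- function(pos, thr, minSbs) {
  n <- length(pos)
  wins <- list()
  if (n >= minSbs) {
    for (i in seq_len(n - minSbs + 1L)) {
      for (j in (i + minSbs - 1L):n) {
        gaps <- pos[(i + 1L):j] - pos[i:(j - 1L)]
        if (all(gaps <= thr)) {
          wins[[length(wins) + 1L]] <- c(i, j)
        } else if (gaps[length(gaps)] > thr) {
          break  # extending further keeps the violating gap
        }
      }
    }
  }
  mergeWindowsOracle(do.call(rbind, wins))
}

# Mean-IMD rule by full window enumeration; mean of adjacent gaps.
oracleMeanRule <- function(pos, thr, minSbs) {
  n <- length(pos)
  wins <- list()
  if (n >= minSbs) {
    for (i in seq_len(n - minSbs + 1L)) {
      for (j in (i + minSbs - 1L):n) {
        gaps <- pos[(i + 1L):j] - pos[i:(j - 1L)]
        if (mean(gaps) <= thr) {
          wins[[length(wins) + 1L]] <- c(i, j)
        }
      }
    }
  }
  mergeWindowsOracle(do.call(rbind, wins))
}

# Vectorized full window enumeration (same semantics as the loop oracles,
# derived independently of the package internals; used where thousands of
# catalogs are checked). Max rule: a window has no over-threshold gap iff
# the cumulative count of bad gaps is equal at both ends.
oracleMaxRuleEnum <- function(pos, thr, minSbs) {
  n <- length(pos)
  if (n < minSbs) return(mergeWindowsOracle(NULL))
  badcum <- c(0L, cumsum(pos[-1] - pos[-n] > thr))
  I <- rep(seq_len(n), times = n)
  J <- rep(seq_len(n), each = n)
  ok <- (J - I + 1L) >= minSbs & badcum[J] == badcum[I]
  mergeWindowsOracle(cbind(I[ok], J[ok]))
}

oracleMeanRuleEnum <- function(pos, thr, minSbs) {
  n <- length(pos)
  if (n < minSbs) return(mergeWindowsOracle(NULL))
  I <- rep(seq_len(n), times = n)
  J <- rep(seq_len(n), each = n)
  ok <- (J - I + 1L) >= minSbs & (pos[J] - pos[I]) <= thr * (J - I)
  mergeWindowsOracle(cbind(I[ok], J[ok]))
}

# Naive O(n^2) interval merge (1-based closed intervals; adjacency merges).
oracleMergeIntervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  merged <- cbind(starts, ends)
  repeat {
    done <- TRUE
    k <- 1L
    while (k < nrow(merged)) {
      for (j in (k + 1L):nrow(merged)) {
        if (merged[j, 1L] <= merged[k, 2L] + 1L &&
            merged[k, 1L] <= merged[j, 2L] + 1L) {
          merged[k, ] <- c(min(merged[k, 1L], merged[j, 1L]),
                           max(merged[k, 2L], merged[j, 2L]))
          merged <- merged[-j, , drop = FALSE]
          done <- FALSE
          break
        }
      }
      if (!done) break
      k <- k + 1L
    }
    if (done) break
  }
  merged[order(merged[, 1L]), , drop = FALSE]
}

# Step-up BH adjustment written out longhand.
oracleBh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- Inf
  for (r in m:1) {
    val <- min(prev, m * p[o[r]] / r)
    adj[o[r]] <- min(val, 1)
    prev <- val
  }
  adj
}

# A single-sample single-chromosome catalog from sorted unique positions.
toyGenome <- function(len = 1e7, n = 1L) {
  genomeBuild("toy", paste0("chr", seq_len(n)), rep(len, n))
}

catalogFromPositions <- function(pos, genome = toyGenome(),
                                 sample = "s1", chromosome = "chr1",
                                 ref = "C", alt = "T") {
  df <- if (length(pos)) {
    data.frame(sample = sample, chromosome = chromosome,
               position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample = character(0), chromosome = character(0),
               position = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  }
  sbsCatalog(df, genome)
}

# Member index matrix of detected loci, for oracle comparison.
lociIndexMatrix <- function(loci) {
  mc <- S4Vectors::mcols(loci)
  m <- cbind(first = mc$memberFirst, last = mc$memberLast)
  m[order(m[, 1L]), , drop = FALSE]
}

randomPositions <- function(n, maxPos = 1e7) {
  sort(sample.int(maxPos, n))
}
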