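# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms from the package implementations they check.

rand_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Affine-gap Smith-Waterman by explicit Gotoh dynamic programming (a gap of
# length L costs gap_open + L * gap_extend, matching the package scheme).
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                      gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force perfect-microsatellite finder: per unit length, walk every
# left-maximal start and extend the perfect period-u region base by base.
# Reports maximal runs with a primitive unit and >= min_units complete
# units, 0-based half-open, like the scanner.
microsat_oracle <- function(x, unit_min = 2, unit_max = 4, min_units = 3) {
  chars <- strsplit(toupper(x), "")[[1]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  prim <- function(u) {
    k <- nchar(u)
    if (k == 1) return(TRUE)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && strrep(substr(u, 1, d), k / d) == u) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (u in unit_min:unit_max) {
    i <- 1
    while (i + u - 1 <= n) {
      # left-maximal: position i-1 must not extend the same period
      if (i > 1 && i + u - 1 <= n && valid[i - 1] && valid[i + u - 1] &&
          chars[i - 1] == chars[i - 1 + u]) {
        i <- i + 1
        next
      }
      j <- i
      while (j + u <= n && valid[j] && valid[j + u] && chars[j] == chars[j + u]) {
        j <- j + 1
      }
      # perfect region is [i, j + u - 1] when any periodic extension happened
      region_len <- (j - i) + u
      if (j > i && all(valid[i:(j + u - 1)])) {
        n_units <- region_len %/% u
        unit <- paste(chars[i:(i + u - 1)], collapse = "")
        if (n_units >= min_units && prim(unit)) {
          out[[length(out) + 1]] <- data.frame(
            start = i - 1L, end = i + region_len - 1L, unit = unit,
            unit_len = u, n_units = as.integer(n_units),
            length_bp = as.integer(region_len), stringsAsFactors = FALSE)
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  res <- if (length(out) == 0) {
    data.frame(start = integer(), end = integer(), unit = character(),
               unit_len = integer(), n_units = integer(),
               length_bp = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res[order(res$start, res$unit_len), , drop = FALSE]
}

# Clopper-Pearson bounds found by direct search on the binomial tail
# probabilities (independent of the qbeta identity the package uses).
cp_oracle <- function(x, n, conf = 0.95, grid = 1e-5) {
  alpha <- 1 - conf
  ps <- seq(0, 1, by = grid)
  lo <- if (x == 0) 0 else {
    # smallest p with P(X >= x | p) >= alpha/2
    min(ps[stats::pbinom(x - 1, n, ps, lower.tail = FALSE) >= alpha / 2])
  }
  hi <- if (x == n) 1 else {
    # largest p with P(X <= x | p) >= alpha/2
    max(ps[stats::pbinom(x, n, ps) >= alpha / 2])
  }
  c(lo, hi)
}

# Shared LTR-element fixture (deterministic).
fixture_ltr <- function(ltr_bp = 400, internal = c(gag = 600, pol = 900),
                        seed = 101) {
  ltr_consensus(ltr_bp, internal, seed = seed)
}

# Geometric detection oracle for the end-to-end recovery study: the
# sampling-model expectation of the one-clone-one-hit screening count,
# computed purely from placement truth and the insert-length model (no
# alignment). A virtual clone is detected by the family with which it
# shares the largest overlap, provided that overlap reaches min_overlap --
# mirroring the best-hit single-assignment convention. Accounts for both
# clone multiplicity (a clone spanning two copies counts once) and
# between-family competition.
geo_detection_prob <- function(truth, genome_size_bp, n_virtual = 2e5,
                               insert_mean = 300, insert_sd = 50,
                               min_insert = 50, min_overlap = 100,
                               seed = 1) {
  fams <- unique(truth$family)
  withr::with_seed(seed, {
    lens <- pmin(pmax(round(stats::rnorm(n_virtual, insert_mean, insert_sd)),
                      min_insert), genome_size_bp)
    starts <- floor(stats::runif(n_virtual) * (genome_size_bp - lens + 1)) + 1
  })
  ir_c <- IRanges::IRanges(start = starts, width = lens)
  ovmax <- sapply(fams, function(fam) {
    trf <- truth[truth$family == fam, ]
    ir_t <- IRanges::IRanges(trf$start + 1, trf$end)
    hits <- IRanges::findOverlaps(ir_c, ir_t)
    w <- IRanges::width(IRanges::pintersect(
      ir_c[S4Vectors::queryHits(hits)], ir_t[S4Vectors::subjectHits(hits)]))
    out <- numeric(n_virtual)
    if (length(w) > 0) {
      agg <- tapply(w, S4Vectors::queryHits(hits), max)
      out[as.integer(names(agg))] <- agg
    }
    out
  })
  ovmax[ovmax < min_overlap] <- 0
  winner <- ifelse(apply(ovmax, 1, max) == 0, NA_character_,
                   fams[apply(ovmax, 1, which.max)])
  stats::setNames(vapply(fams, function(f) {
    mean(!is.na(winner) & winner == f)
  }, numeric(1)), fams)
}
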