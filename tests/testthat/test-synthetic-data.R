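# Synthetic-genome generator: placement truth, sampling, reproducibility.

test_that("background-only genome has the requested length and empty truth", {
  g <- build_genome(genome_spec(10000, seed = 1))
  expect_equal(nchar(g$sequence), 10000)
  expect_equal(nrow(tidy(g)), 0)
  expect_false(grepl("[^ACGT]", g$sequence))
})

test_that("tandem arrays are placed at exact full lengths with disjoint truth", {
  unit <- rand_dna(120)
  fam <- repeat_family("sat", "tandem-satellite", unit, copies = 10,
                       units_per_array = 10)
  g <- build_genome(genome_spec(100000, fam, seed = 5))
  tr <- tidy(g)
  expect_equal(nrow(tr), 10)
  expect_true(all(tr$end - tr$start == 1200))
  # conservation: occupied bp equals the declared layout exactly at divergence 0
  expect_equal(sum(tr$end - tr$start), 10 * 1200)
  # non-overlap and bounds
  tr <- tr[order(tr$start), ]
  expect_true(all(tr$start >= 0 & tr$end <= 100000))
  expect_true(all(head(tr$end, -1) <= tail(tr$start, -1)))
  # inserted subsequence is the array (or its reverse complement) verbatim
  array_seq <- strrep(unit, 10)
  for (k in seq_len(nrow(tr))) {
    sub <- substr(g$sequence, tr$start[k] + 1, tr$end[k])
    expected <- if (tr$strand[k] == "+") array_seq else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(array_seq)))
    }
    expect_identical(sub, expected)
  }
})

test_that("zero-divergence LTR family yields exact consensus matches, solo LTRs excepted", {
  lc <- fixture_ltr()
  fam <- repeat_family("gyp", "gypsy-LTR", lc$consensus, copies = 12,
                       structure = lc$structure, solo_ltr_fraction = 0.5)
  g <- build_genome(genome_spec(2e5, fam, seed = 9))
  tr <- tidy(g)
  expect_equal(nrow(tr), 12)
  n_solo <- sum(tr$is_solo_ltr)
  full_len <- nchar(lc$consensus)
  ltr_len <- lc$structure$length[1]
  expect_true(all((tr$end - tr$start)[tr$is_solo_ltr] == ltr_len))
  expect_true(all((tr$end - tr$start)[!tr$is_solo_ltr] == full_len))
  # brute-force substring count over both strands finds exactly the
  # full-length insertions
  count_hits <- function(hay, needle) {
    length(Biostrings::matchPattern(needle, Biostrings::DNAString(hay)))
  }
  hits <- count_hits(g$sequence, lc$consensus) +
    count_hits(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g$sequence))), lc$consensus)
  expect_equal(hits, 12 - n_solo)
})

test_that("per-copy divergence stays within the binomial regime", {
  lc <- fixture_ltr()
  fam <- repeat_family("gyp", "gypsy-LTR", lc$consensus, copies = 10,
                       structure = lc$structure, divergence = 0.05)
  g <- build_genome(genome_spec(1.5e5, fam, seed = 3))
  tr <- dplyr::filter(tidy(g), !is_solo_ltr)
  mism <- vapply(seq_len(nrow(tr)), function(k) {
    sub <- substr(g$sequence, tr$start[k] + 1, tr$end[k])
    if (tr$strand[k] == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    sum(strsplit(sub, "")[[1]] != strsplit(lc$consensus, "")[[1]])
  }, numeric(1))
  n <- nchar(lc$consensus)
  # each copy: Binomial(n, 0.05); 5-sigma individual bound, mean within 4 SE
  expect_true(all(mism <= 0.05 * n + 5 * sqrt(n * 0.05 * 0.95)))
  expect_lt(abs(mean(mism) - 0.05 * n),
            4 * sqrt(n * 0.05 * 0.95 / nrow(tr)))
})

test_that("over-full family layouts are rejected with a capacity report", {
  fam <- repeat_family("sat", "tandem-satellite", rand_dna(100), copies = 20,
                       units_per_array = 10)
  expect_error(genome_spec(10000, fam), "over-full")
  expect_error(genome_spec(10000, fam), "20000")
})

test_that("identical spec and seed reproduce the genome byte for byte", {
  fam <- repeat_family("sat", "tandem-satellite", rand_dna(50), copies = 4,
                       units_per_array = 5, divergence = 0.1)
  g1 <- build_genome(genome_spec(20000, fam, seed = 77))
  g2 <- build_genome(genome_spec(20000, fam, seed = 77))
  g3 <- build_genome(genome_spec(20000, fam, seed = 78))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(tidy(g1), tidy(g2))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("clones are verbatim genome substrings and coverage arithmetic is exact", {
  g <- build_genome(genome_spec(1102500, seed = 2))
  lib <- sample_clone_library(g, 8, insert_mean = 603, insert_sd = 0, seed = 2)
  expect_equal(nrow(lib), 8)
  expect_true(all(lib$length == 603))
  # f ~ 8 x 603 / 1102500 = 0.44%: the survey design scaled down 1/1000
  expect_equal(attr(lib, "coverage_fraction"), 8 * 603 / 1102500)
  expect_equal(round_half_up(100 * attr(lib, "coverage_fraction"), 2), 0.44)
  # substring membership, both via coordinates and via exact search
  for (k in seq_len(nrow(lib))) {
    expect_identical(lib$sequence[k],
                     substr(g$sequence, lib$start[k] + 1, lib$end[k]))
  }
  expect_true(all(vapply(lib$sequence, grepl, logical(1),
                         x = g$sequence, fixed = TRUE)))
  # empty library
  lib0 <- sample_clone_library(g, 0, seed = 2)
  expect_equal(nrow(lib0), 0)
  expect_equal(attr(lib0, "coverage_fraction"), 0)
  expect_equal(glance(lib0)$total_insert_bp, 0)
})

test_that("library sampling rejects impossible parameters by name", {
  g <- build_genome(genome_spec(5000, seed = 1))
  expect_error(sample_clone_library(g, -1, seed = 1), "n_clones")
  expect_error(sample_clone_library(g, 5, insert_mean = 6000, seed = 1),
               "exceeds the genome")
})

test_that("error-free reads are genome substrings with the requested depth", {
  g <- build_genome(genome_spec(50000, seed = 4))
  # n_reads x mean_len / G = 2.0
  rs <- simulate_reads(g, 250, read_len_mean = 400, read_len_sd = 40,
                       error_rate = 0, seed = 4)
  expect_true(all(vapply(rs$sequence[1:50], grepl, logical(1),
                         x = g$sequence, fixed = TRUE)))
  depth <- attr(rs, "total_read_bp") / 50000
  se <- sqrt(250) * 40 / 50000
  expect_lt(abs(depth - 2.0), 3 * se)
  # empty set
  rs0 <- simulate_reads(g, 0, seed = 4)
  expect_equal(nrow(rs0), 0)
  expect_equal(attr(rs0, "total_read_bp"), 0)
  expect_error(simulate_reads(g, -2, seed = 1), "n_reads")
  expect_error(simulate_reads(g, 5, error_rate = 0.5, seed = 1), "error_rate")
})

test_that("clone sampling is unbiased for family genome fractions", {
  unit <- rand_dna(100)
  fam <- repeat_family("sat", "tandem-satellite", unit, copies = 8,
                       units_per_array = 5)
  g <- build_genome(genome_spec(20000, fam, seed = 21))
  tr <- tidy(g)
  true_frac <- sum(tr$end - tr$start) / 20000
  ir_truth <- IRanges::IRanges(tr$start + 1, tr$end)
  fracs <- vapply(1:200, function(rep) {
    lib <- sample_clone_library(g, 40, insert_mean = 200, insert_sd = 30,
                                seed = 1000 + rep)
    ir_clones <- IRanges::IRanges(lib$start + 1, lib$end)
    # clone bp overlapping truth: count per-base with clone multiplicity
    hits <- IRanges::findOverlaps(ir_clones, ir_truth)
    bp <- sum(IRanges::width(IRanges::pintersect(
      ir_clones[S4Vectors::queryHits(hits)], ir_truth[S4Vectors::subjectHits(hits)])))
    bp / sum(lib$length)
  }, numeric(1))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - true_frac), 3 * se)
})
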