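# Read-hit mapping, depth -> copy-number normalisation, profile comparison.

test_that("Karlin-Altschul lambda solves the ungapped identity", {
  ka <- karlin_altschul_params(1, -1)
  expect_equal(ka$lambda, log(3), tolerance = 1e-6)
  expect_equal(0.25 * exp(ka$lambda) + 0.75 * exp(-ka$lambda), 1,
               tolerance = 1e-6)
  expect_equal(karlin_altschul_params(gapped = TRUE),
               list(lambda = 1.37, K = 0.711))
  expect_error(karlin_altschul_params(-1, 1), "Karlin-Altschul")
})

test_that("an exact substring read maps to exactly its source interval", {
  set.seed(701)
  el <- rand_dna(2000)
  read <- substr(el, 1001, 1400)
  hits <- map_read_hits(el, tibble::tibble(id = "r1", sequence = read))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1000L)
  expect_equal(hits$end, 1400L)
  expect_equal(hits$score, 400)
  # reverse-complement reads map to the same interval
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits_rc <- map_read_hits(el, tibble::tibble(id = "r1", sequence = rc))
  expect_equal(hits_rc$start, 1000L)
  expect_equal(hits_rc$strand, "-")
})

test_that("unrelated random reads never clear the E-value cutoff", {
  set.seed(702)
  el <- rand_dna(10000)
  reads <- tibble::tibble(id = sprintf("r%03d", 1:100),
                          sequence = vapply(1:100, function(i) rand_dna(400),
                                            character(1)))
  hits <- map_read_hits(el, reads, e_cutoff = 1e-15, seed_length = 0)
  expect_equal(nrow(hits), 0)
})

test_that("retained hits equal the DP-oracle significant set", {
  set.seed(703)
  el <- rand_dna(2000)
  # mixture: true fragments (some mutated), reverse-complement, noise
  mk_read <- function(i) {
    if (i <= 8) {
      s <- sample(1:1600, 1)
      substr(el, s, s + 299)
    } else if (i <= 12) {
      s <- sample(1:1600, 1)
      frag <- substr(el, s, s + 299)
      chars <- strsplit(frag, "")[[1]]
      pos <- sample(300, 30)
      chars[pos] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
      paste(chars, collapse = "")
    } else if (i <= 16) {
      s <- sample(1:1600, 1)
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(el, s, s + 299))))
    } else {
      rand_dna(300)
    }
  }
  reads <- tibble::tibble(id = sprintf("r%02d", 1:20),
                          sequence = vapply(1:20, mk_read, character(1)))
  hits <- map_read_hits(el, reads, e_cutoff = 1e-15, seed_length = 0)
  ka <- karlin_altschul_params(1, -1)
  m <- sum(nchar(reads$sequence))
  for (i in 1:20) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reads$sequence[i])))
    s_or <- max(sw_oracle(reads$sequence[i], el), sw_oracle(rc, el))
    e_or <- ka$K * m * nchar(el) * exp(-ka$lambda * s_or)
    in_hits <- reads$id[i] %in% hits$read_id
    expect_equal(in_hits, e_or <= 1e-15, info = reads$id[i])
    if (in_hits) {
      expect_equal(hits$score[hits$read_id == reads$id[i]], s_or)
    }
  }
})

test_that("copy-number normalisation follows the depth formula exactly", {
  hits <- tibble::tibble(read_id = c("a", "b"), start = c(0L, 100L),
                         end = c(200L, 300L))
  prof <- depth_to_copies(hits, genome_size_bp = 1e6, window_bp = 100,
                          total_read_bp = 4e5, element_len = 300)
  # expected depth 0.4; window means: [0,100)=1, [100,200)=2, [200,300)=1
  expect_equal(prof$copies, c(1, 2, 1) / 0.4)
  expect_equal(prof$n_hits, c(1L, 2L, 1L))
  # halving the read database doubles copies, exactly
  prof2 <- depth_to_copies(hits, genome_size_bp = 1e6, window_bp = 100,
                           total_read_bp = 2e5, element_len = 300)
  expect_equal(prof2$copies, 2 * prof$copies)
  # no hits: all-zero profile
  prof0 <- depth_to_copies(hits[0, ], genome_size_bp = 1e6, window_bp = 100,
                           total_read_bp = 4e5, element_len = 300)
  expect_equal(prof0$copies, c(0, 0, 0))
  expect_error(depth_to_copies(hits, 1e6, window_bp = 0,
                               total_read_bp = 1, element_len = 300),
               "window_bp")
})

test_that("profiles are invariant to read order", {
  lc <- fixture_ltr(ltr_bp = 300, internal = c(gag = 1000))
  fam <- repeat_family("el", "gypsy-LTR", lc$consensus, copies = 3,
                       structure = lc$structure)
  g <- build_genome(genome_spec(5e4, fam, seed = 71))
  reads <- simulate_reads(g, 400, read_len_mean = 300, seed = 71)
  p1 <- coverage_profile(lc$consensus, reads, genome_size_bp = 5e4,
                         window_bp = 200)
  shuffled <- reads[sample(nrow(reads)), ]
  attr(shuffled, "total_read_bp") <- attr(reads, "total_read_bp")
  p2 <- coverage_profile(lc$consensus, shuffled, genome_size_bp = 5e4,
                         window_bp = 200)
  expect_equal(p1$copies, p2$copies)
})

test_that("estimated copies scale linearly with spiked copy number", {
  lc <- fixture_ltr(ltr_bp = 200, internal = c(gag = 1100), seed = 72)
  est <- vapply(c(1, 5, 20), function(cp) {
    fam <- repeat_family("el", "gypsy-LTR", lc$consensus, copies = cp,
                         structure = lc$structure)
    g <- build_genome(genome_spec(2e5, fam, seed = 72 + cp))
    reads <- simulate_reads(g, 2000, read_len_mean = 400, seed = 72 + cp)
    prof <- coverage_profile(lc$consensus, reads, genome_size_bp = 2e5,
                             window_bp = 300)
    # central windows avoid element-edge attrition
    mean(prof$copies[2:(nrow(prof) - 1)])
  }, numeric(1))
  fit <- stats::lm(est ~ c(1, 5, 20))
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.1)
})

test_that("identical elements compare with identity one and unchanged tracks", {
  set.seed(704)
  el <- rand_dna(1500)
  hits <- tibble::tibble(read_id = "a", start = 100L, end = 600L)
  prof <- depth_to_copies(hits, genome_size_bp = 1e6, window_bp = 100,
                          total_read_bp = 1e5, element_len = 1500)
  cmp <- compare_profiles(prof, prof, el, el, window_bp = 100)
  expect_true(all(cmp$identity_window == 1))
  expect_equal(cmp$pos_a, 0:1499)
  per_base <- attr(prof, "depth_per_base") / (1e5 / 1e6)
  expect_equal(cmp$copies_a, per_base)
  expect_equal(cmp$copies_b, per_base)
  # projection conserves each track's total mass over non-gap columns
  expect_equal(sum(cmp$copies_a, na.rm = TRUE), sum(per_base))
})

test_that("a conserved core shows as a high-identity central stripe", {
  set.seed(705)
  a <- rand_dna(2000)
  b <- paste0(rand_dna(600), substr(a, 601, 1400), rand_dna(600))
  hits <- tibble::tibble(read_id = "x", start = 0L, end = 2000L)
  prof <- depth_to_copies(hits, 1e6, window_bp = 100, total_read_bp = 1e5,
                          element_len = 2000)
  cmp <- compare_profiles(prof, prof, a, b, window_bp = 100)
  mid_cols <- !is.na(cmp$pos_a) & cmp$pos_a >= 700 & cmp$pos_a < 1300
  flank_cols <- !is.na(cmp$pos_a) & (cmp$pos_a < 500 | cmp$pos_a >= 1500)
  expect_gt(mean(cmp$identity_window[mid_cols]), 0.9)
  expect_lt(mean(cmp$identity_window[flank_cols]), 0.7)
})

test_that("solo-LTR accumulation elevates LTR windows relative to the internal region", {
  # 20 full-length insertions plus 40 solo LTRs: the reference carries two
  # LTR windows, so each receives half of the 80 genomic LTR units' read
  # mass under one-best-hit counting -> expected LTR/internal ratio
  # (2*20+40)/(2*20) = 2
  ratios <- vapply(1:3, function(s) {
    lc <- fixture_ltr(ltr_bp = 400, internal = c(gag = 700, pol = 600),
                      seed = 73)
    fam <- repeat_family("el", "gypsy-LTR", lc$consensus, copies = 60,
                         structure = lc$structure, solo_ltr_fraction = 2 / 3,
                         divergence = 0.03)
    g <- build_genome(genome_spec(3e5, fam, seed = 730 + s))
    reads <- simulate_reads(g, 2200, read_len_mean = 350, seed = 730 + s)
    prof <- coverage_profile(lc$consensus, reads, genome_size_bp = 3e5,
                             window_bp = 100)
    pos <- (prof$window_start + prof$window_end) / 2
    ltr <- prof$copies[pos < 400 | pos > 1700]
    internal <- prof$copies[pos >= 500 & pos <= 1600]
    mean(ltr) / mean(internal)
  }, numeric(1))
  expect_gt(mean(ratios), 1.6)
  expect_lt(mean(ratios), 2.4)
})
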