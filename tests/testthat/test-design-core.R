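test_that("Boulder-IO parameter parsing: keys, defaults, ranges, errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRIMER_OPT_SIZE=20", "PRIMER_MIN_SIZE=18",
               "PRIMER_MAX_SIZE=23",
               "PRIMER_PRODUCT_SIZE_RANGE=80-150 150-250", "="), f)
  p <- parse_parameter_file(f)
  expect_identical(p$size_opt, 20L)
  expect_identical(p$product_size_ranges, list(c(80L, 150L), c(150L, 250L)))

  writeLines(character(0), f)
  expect_identical(unclass(parse_parameter_file(f)),
                   unclass(design_parameters()))

  writeLines("PRIMER_OPT_TM=abc", f)
  expect_error(parse_parameter_file(f), "PRIMER_OPT_TM")

  writeLines(c("PRIMER_SOME_UNKNOWN_KEY=1", "PRIMER_OPT_TM=59"), f)
  expect_warning(p <- parse_parameter_file(f), "PRIMER_SOME_UNKNOWN_KEY")
  expect_identical(p$tm_opt, 59)

  # keys after the Boulder-IO record terminator are ignored
  writeLines(c("=", "PRIMER_OPT_TM=99"), f)
  expect_identical(parse_parameter_file(f)$tm_opt, 60)
})

test_that("self-complementarity equals the exhaustive-offset oracle", {
  expect_identical(complementarity_scores("ACGTACGT")$self_any, 8)
  expect_identical(complementarity_scores("AAAAAA")$self_any, 0)
  set.seed(31)
  for (i in 1:40) {
    s <- random_dna_str(sample(4:25, 1))
    got <- complementarity_scores(s)
    want <- oracle_self_scores(s)
    expect_identical(got$self_any, unname(want["self_any"]), label = s)
    expect_identical(got$self_end, unname(want["self_end"]), label = s)
    expect_lte(got$self_end, got$self_any)
  }
})

relaxed_params <- function(...) {
  design_parameters(tm_min = -1000, tm_max = 1000, gc_min = 0, gc_max = 100,
                    self_any_max = 1000, self_end_max = 1000,
                    poly_x_max = 1000L, ...)
}

test_that("candidate enumeration is exhaustive over (position, length) windows", {
  # with all soft constraints relaxed, the candidate count is the closed-form
  # number of windows per strand
  p <- relaxed_params(size_min = 18L, size_opt = 20L, size_max = 22L,
                      product_size_ranges = list(c(36L, 60L)))
  seq30 <- random_dna_str(30)
  cand <- candidate_primers(seq30, p)
  n_windows <- sum(vapply(18:22, function(L) 30 - L + 1, numeric(1)))
  expect_identical(nrow(cand), as.integer(2 * n_windows))
  expect_setequal(unique(cand$strand), c("forward", "reverse"))
})

test_that("candidates never contain N and a short target yields none", {
  p <- relaxed_params(size_min = 18L, size_opt = 20L, size_max = 22L,
                      product_size_ranges = list(c(36L, 60L)))
  cand <- candidate_primers(paste0(random_dna_str(14), "N", random_dna_str(15)),
                            p)
  expect_false(any(grepl("N", cand$sequence, fixed = TRUE)))
  expect_identical(nrow(candidate_primers(random_dna_str(10), p)), 0L)
})

test_that("candidate set equals brute-force enumeration on small targets", {
  set.seed(32)
  p <- design_parameters(size_min = 18L, size_opt = 20L, size_max = 22L,
                         tm_min = 40, tm_opt = 55, tm_max = 70,
                         product_size_ranges = list(c(36L, 60L)))
  for (i in 1:8) {
    seq <- random_dna_str(sample(30:60, 1), gc = runif(1, 0.35, 0.65))
    got <- candidate_primers(seq, p)
    want <- oracle_candidates(seq, p)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
      next
    }
    key <- function(d) paste(d$strand, d$win_start, d$win_end)
    expect_setequal(key(got), key(want))
    m <- match(key(got), key(want))
    expect_equal(got$tm, want$tm[m], tolerance = 1e-9)
    expect_equal(got$penalty, want$penalty[m], tolerance = 1e-9)
    expect_identical(got$sequence, want$sequence[m])
  }
})

test_that("every emitted candidate re-passes every hard constraint", {
  set.seed(33)
  p <- design_parameters()
  seq <- random_dna_str(400, gc = 0.55)
  cand <- candidate_primers(seq, p)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$length >= p$size_min & cand$length <= p$size_max))
  expect_true(all(cand$tm >= p$tm_min & cand$tm <= p$tm_max))
  expect_true(all(cand$gc_percent >= p$gc_min & cand$gc_percent <= p$gc_max))
  expect_true(all(cand$self_any <= p$self_any_max))
  expect_true(all(cand$self_end <= p$self_end_max))
  runs <- vapply(strsplit(cand$sequence, ""), function(b) max(rle(b)$lengths),
                 numeric(1))
  expect_true(all(runs <= p$poly_x_max))
  # the stored sequence is the window (reverse-complemented as needed)
  win <- substr(rep(seq, nrow(cand)), cand$win_start + 1, cand$win_end)
  expect_identical(cand$sequence,
                   ifelse(cand$strand == "forward", win,
                          reverse_complement(win)))
})

test_that("pair enumeration matches brute force and is sorted by penalty", {
  set.seed(34)
  p <- design_parameters(size_min = 18L, size_opt = 20L, size_max = 22L,
                         tm_min = 40, tm_opt = 55, tm_max = 70,
                         product_size_ranges = list(c(40L, 60L)))
  n_checked <- 0
  for (i in 1:10) {
    seq <- random_dna_str(60, gc = runif(1, 0.4, 0.6))
    cand <- candidate_primers(seq, p)
    got <- enumerate_pairs(cand, p, n_return = 5L)
    want <- oracle_best_pairs(cand, p, 5L)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
      next
    }
    n_checked <- n_checked + 1
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$pair_penalty, want$pair_penalty, tolerance = 1e-9)
    expect_identical(got$amplicon_start, want$fwd_win_start)
    expect_identical(got$product_size, want$product_size)
    expect_false(is.unsorted(got$pair_penalty))
    # amplicon arithmetic: product size is the half-open span
    expect_identical(got$product_size, got$amplicon_end - got$amplicon_start)
    # forward 5' strictly left of reverse 5'
    expect_true(all(got$fwd_start < got$rev_start))
  }
  expect_gt(n_checked, 2)
})

test_that("pair enumeration is deterministic and respects n_return", {
  set.seed(35)
  seq <- random_dna_str(300, gc = 0.5)
  p <- design_parameters()
  cand <- candidate_primers(seq, p)
  a <- enumerate_pairs(cand, p, n_return = 3L)
  b <- enumerate_pairs(cand, p, n_return = 3L)
  expect_identical(a, b)
  expect_lte(nrow(a), 3L)
  expect_identical(nrow(enumerate_pairs(cand[0, ], p)), 0L)
})

test_that("internal oligo lies strictly between the primers when designed", {
  set.seed(36)
  seq <- random_dna_str(400, gc = 0.55)
  p <- design_parameters(design_internal_oligo = TRUE,
                         product_size_ranges = list(c(100L, 300L)))
  cand <- candidate_primers(seq, p)
  pairs <- enumerate_pairs(cand, p, n_return = 5L, target_sequence = seq)
  with_oligo <- pairs[!is.na(pairs$oligo_seq), , drop = FALSE]
  skip_if(nrow(with_oligo) == 0, "no feasible oligo on this fixture")
  expect_true(all(with_oligo$oligo_win_start >= with_oligo$fwd_win_end))
  expect_true(all(with_oligo$oligo_win_end <= with_oligo$rev_win_start))
})
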