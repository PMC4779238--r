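mk_pairs <- function(df) {
  # minimal annotated-pairs table for selector tests
  base <- data.frame(target_id = "T1", pair_id = sprintf("pair_%02d",
                                                         seq_len(nrow(df))),
                     pair_penalty = seq_len(nrow(df)),
                     stringsAsFactors = FALSE)
  cbind(base[, setdiff(names(base), names(df))], df)
}

test_that("quality-matrix parsing: operators, ranges, ranks, errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# MSRE defaults",
               "n_cutsites_amplicon\t>=\t1\t1",
               "n_snps_fwd\t<=\t0\t1",
               "product_size\t-\t80,150\t2"), f)
  r <- parse_quality_matrix(f)
  expect_identical(nrow(r), 3L)
  expect_identical(r$operator, c(">=", "<=", "-"))
  expect_identical(r$lo[3], 80)
  expect_identical(r$hi[3], 150)
  expect_identical(r$rank, c(1L, 1L, 2L))

  writeLines("no_such_column\t>=\t1\t1", f)
  expect_error(parse_quality_matrix(f), "no_such_column.*valid columns")
  writeLines("product_size\t~\t1\t1", f)
  expect_error(parse_quality_matrix(f), "bad operator")
  writeLines("product_size\t>=\t1\t11", f)
  expect_error(parse_quality_matrix(f), "rank")
  writeLines("product_size\t-\t150,80\t1", f)
  expect_error(parse_quality_matrix(f), "lo <= hi")
})

test_that("cumulative quality levels require every rule of rank <= r", {
  rules <- data.frame(column = c("n_cutsites_amplicon", "product_size"),
                      operator = c(">=", "-"), lo = c(1, 80), hi = c(NA, 150),
                      rank = c(1L, 2L), stringsAsFactors = FALSE)
  pairs <- mk_pairs(data.frame(n_cutsites_amplicon = c(1L, 0L, 2L),
                               product_size = c(100L, 100L, 400L)))
  got <- assign_quality_levels(pairs, rules, mode = "cumulative")
  # pair 1 passes rank-1 rules -> level 1; pair 2 fails rank 1 -> no level;
  # pair 3 passes rank 1 but its rank-2 prefix fails -> stays level 1
  expect_identical(got$levels, c(1L, NA_integer_, 1L))
  # audit: every excluded pair has a recorded violated rule
  bad <- subset(got$audit, pair == 2 & !passed)
  expect_gt(nrow(bad), 0)
  expect_identical(bad$column[1], "n_cutsites_amplicon")
})

test_that("independent mode treats rank tiers as a relaxation ladder", {
  rules <- data.frame(column = c("product_size", "product_size"),
                      operator = c("-", "-"), lo = c(80, 80),
                      hi = c(120, 200), rank = c(1L, 2L),
                      stringsAsFactors = FALSE)
  pairs <- mk_pairs(data.frame(product_size = c(100L, 150L, 400L)))
  got <- assign_quality_levels(pairs, rules, mode = "independent")
  expect_identical(got$levels, c(1L, 2L, NA_integer_))
})

test_that("level assignment equals brute-force rule evaluation on random data", {
  set.seed(71)
  cols <- c("product_size", "n_snps_fwd", "n_cutsites_amplicon")
  for (rep in 1:15) {
    n_rules <- sample(2:6, 1)
    rules <- data.frame(
      column = sample(cols, n_rules, replace = TRUE),
      operator = sample(c(">", "<", ">=", "<=", "-"), n_rules, replace = TRUE),
      lo = sample(0:150, n_rules, replace = TRUE), hi = NA_real_,
      rank = sample(1:4, n_rules, replace = TRUE), stringsAsFactors = FALSE)
    rules$hi[rules$operator == "-"] <- rules$lo[rules$operator == "-"] +
      sample(0:100, sum(rules$operator == "-"), replace = TRUE)
    rules <- rules[order(rules$rank), ]
    pairs <- mk_pairs(data.frame(
      product_size = sample(50:200, 12, replace = TRUE),
      n_snps_fwd = sample(0:2, 12, replace = TRUE),
      n_cutsites_amplicon = sample(0:3, 12, replace = TRUE)))
    for (mode in c("cumulative", "independent")) {
      got <- assign_quality_levels(pairs, rules, mode = mode)$levels
      want <- vapply(seq_len(nrow(pairs)), function(i) {
        ok_rule <- vapply(seq_len(nrow(rules)), function(j) {
          v <- pairs[[rules$column[j]]][i]
          switch(rules$operator[j],
                 ">" = v > rules$lo[j], "<" = v < rules$lo[j],
                 ">=" = v >= rules$lo[j], "<=" = v <= rules$lo[j],
                 "-" = v >= rules$lo[j] && v <= rules$hi[j])
        }, logical(1))
        for (r in sort(unique(rules$rank))) {
          sel <- if (mode == "cumulative") rules$rank <= r else rules$rank == r
          if (all(ok_rule[sel])) return(r)
        }
        NA_integer_
      }, integer(1))
      expect_identical(got, as.integer(want), label = mode)
    }
  }
})

test_that("rule deletion never worsens a level; rule addition never improves", {
  set.seed(72)
  rules <- data.frame(column = c("product_size", "n_snps_fwd",
                                 "n_cutsites_amplicon"),
                      operator = c("-", "<=", ">="), lo = c(80, 0, 1),
                      hi = c(150, NA, NA), rank = c(1L, 1L, 2L),
                      stringsAsFactors = FALSE)
  pairs <- mk_pairs(data.frame(
    product_size = sample(50:200, 20, replace = TRUE),
    n_snps_fwd = sample(0:2, 20, replace = TRUE),
    n_cutsites_amplicon = sample(0:2, 20, replace = TRUE)))
  full <- assign_quality_levels(pairs, rules)$levels
  for (drop in seq_len(nrow(rules))) {
    fewer <- assign_quality_levels(pairs, rules[-drop, ])$levels
    # with one rule fewer, a level never disappears and never increases
    expect_true(all(is.na(full) | (!is.na(fewer) & fewer <= full)))
  }
})

test_that("without rules, selection order is pure penalty order", {
  pairs <- mk_pairs(data.frame(product_size = c(100L, 90L, 95L)))
  pairs$pair_penalty <- c(3, 1, 2)
  got <- assign_quality_levels(pairs, NULL)
  expect_true(all(is.na(got$levels)))
  expect_true(all(got$selected))
  ord <- order(pairs$pair_penalty)
  expect_identical(pairs$pair_id[ord], c("pair_02", "pair_03", "pair_01"))
})

test_that("MSRE validation filter enforces all four criteria with reasons", {
  base <- data.frame(n_cutsites_amplicon = 1L, n_snps_fwd = 0L,
                     n_snps_rev = 0L, n_repeats = 0L, target_dist = 0L)
  ok <- msre_validation_filter(base)
  expect_true(ok$pass)
  expect_identical(ok$reasons, "")

  bad <- base
  bad$n_repeats <- 1L
  r <- msre_validation_filter(bad)
  expect_false(r$pass)
  expect_identical(r$reasons, "repeat_in_assay")

  bad <- base
  bad$n_cutsites_amplicon <- 0L
  bad$n_snps_rev <- 1L
  r <- msre_validation_filter(bad)
  expect_identical(r$reasons, "no_cutsite_in_amplicon;snp_in_primer")

  # proximity boundary at +/- 50 bp around the amplicon
  near <- base; near$target_dist <- 49L
  far <- base; far$target_dist <- -51L
  at <- base; at$target_dist <- 50L
  expect_true(msre_validation_filter(near)$pass)
  expect_true(msre_validation_filter(at)$pass)
  expect_false(msre_validation_filter(far)$pass)
  expect_identical(msre_validation_filter(far)$reasons, "target_not_proximal")
})
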