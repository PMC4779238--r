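mk_range <- function(chrom = "chr1", t_start = 1100L, t_end = 1200L,
                     r_start = 1000L, r_end = 1300L, id = "T1") {
  structure(list(chrom = chrom, target_id = id, target_start = t_start,
                 target_end = t_end, range_start = r_start, range_end = r_end,
                 target_offset = t_start - r_start),
            class = "msre_design_range")
}

ann_set <- function(kind, chrom, start, end, name = NULL, strand = NULL) {
  n <- length(start)
  rec <- data.frame(chrom = rep(chrom, length.out = n), start = start,
                    end = end,
                    name = if (is.null(name)) paste0(kind, seq_len(n)) else name,
                    strand = if (is.null(strand)) rep(NA_character_, n)
                             else strand,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$chrom, rec$start), ]
  rownames(rec) <- NULL
  structure(list(kind = kind, records = rec), class = "msre_annotation")
}

empty_set <- function(kind) {
  structure(list(kind = kind,
                 records = data.frame(chrom = character(), start = integer(),
                                      end = integer(), name = character(),
                                      strand = character(),
                                      stringsAsFactors = FALSE)),
            class = "msre_annotation")
}

basic_annotations <- function(snp = empty_set("snp"),
                              cpg = empty_set("cpg_island"),
                              rpt = empty_set("repeat"),
                              gene = empty_set("gene")) {
  list(snp = snp, cpg_island = cpg, "repeat" = rpt, gene = gene)
}

fake_pair <- function(fwd = c(50L, 70L), rev = c(130L, 150L)) {
  data.frame(pair_id = "pair_01",
             fwd_seq = strrep("A", fwd[2] - fwd[1]),
             rev_seq = strrep("T", rev[2] - rev[1]),
             fwd_start = fwd[1], rev_start = rev[2] - 1L,
             fwd_len = fwd[2] - fwd[1], rev_len = rev[2] - rev[1],
             fwd_win_start = fwd[1], fwd_win_end = fwd[2],
             rev_win_start = rev[1], rev_win_end = rev[2],
             fwd_tm = 60, rev_tm = 60, fwd_gc = 50, rev_gc = 50,
             fwd_self_any = 0, rev_self_any = 0, fwd_self_end = 0,
             rev_self_end = 0, fwd_penalty = 0, rev_penalty = 0,
             amplicon_start = fwd[1], amplicon_end = rev[2],
             product_size = rev[2] - fwd[1], pair_penalty = 0,
             oligo_seq = NA_character_, oligo_win_start = NA_integer_,
             oligo_win_end = NA_integer_, oligo_tm = NA_real_,
             oligo_penalty = NA_real_, stringsAsFactors = FALSE)
}

test_that("genomic lifting is a translation by the range start", {
  pr <- fake_pair()
  gi <- to_genomic(pr, mk_range(r_start = 1000L))
  expect_identical(c(gi$amp_start, gi$amp_end), c(1050L, 1150L))
  expect_identical(c(gi$fwd_start, gi$fwd_end), c(1050L, 1070L))
  gi0 <- to_genomic(pr, mk_range(r_start = 0L, r_end = 300L,
                                 t_start = 100L, t_end = 200L))
  expect_identical(gi0$amp_start, pr$amplicon_start)
  # round trip
  expect_identical(gi$amp_start - 1000L, pr$amplicon_start)
})

test_that("SNP/CpG/repeat counts follow half-open interval intersection", {
  pr <- fake_pair() # genomic: fwd [1050,1070), rev [1130,1150), amp [1050,1150)
  anns <- basic_annotations(
    snp = ann_set("snp", "chr1", c(1060L, 1100L, 1149L, 1150L),
                  c(1061L, 1101L, 1150L, 1151L)),
    cpg = ann_set("cpg_island", "chr1", 1050L, 1150L),
    rpt = ann_set("repeat", "chr1", c(1000L, 1140L), c(1049L, 1160L)))
  seq <- strrep("A", 300)
  a <- annotate_pairs(pr, mk_range(), seq, anns)
  expect_identical(a$n_snps_fwd, 1L)
  expect_identical(a$n_snps_rev, 1L)       # 1149 in; 1150 touches, out
  expect_identical(a$n_snps_amplicon, 3L)
  expect_identical(a$n_cpg_islands, 1L)    # coextensive island counts once
  expect_identical(a$n_repeats, 1L)        # [1000,1049) does not reach 1050
  expect_true(a$repeat_in_primer)          # [1140,1160) overlaps rev primer
  expect_identical(a$target_dist, 1L)      # midpoint 1150 just right of [1050,1150)
})

test_that("annotation counts equal brute-force intersection on random fixtures", {
  set.seed(61)
  for (rep in 1:15) {
    pr <- fake_pair()
    dr <- mk_range()
    n <- sample(5:40, 1)
    s <- sample(1000:1290, n, replace = TRUE)
    anns <- basic_annotations(
      snp = ann_set("snp", "chr1", s, s + 1L),
      rpt = {
        rs <- sample(1000:1250, 5, replace = TRUE)
        ann_set("repeat", "chr1", rs, rs + sample(5:60, 5, replace = TRUE))
      })
    a <- annotate_pairs(pr, dr, strrep("A", 300), anns)
    gi <- to_genomic(pr, dr)
    brute <- function(rec, lo, hi)
      sum(pmax(rec$start, lo) < pmin(rec$end, hi))
    expect_identical(a$n_snps_fwd,
                     brute(anns$snp$records, gi$fwd_start, gi$fwd_end))
    expect_identical(a$n_snps_rev,
                     brute(anns$snp$records, gi$rev_start, gi$rev_end))
    expect_identical(a$n_snps_amplicon,
                     brute(anns$snp$records, gi$amp_start, gi$amp_end))
    expect_identical(a$n_repeats,
                     brute(anns$`repeat`$records, gi$amp_start, gi$amp_end))
  }
})

test_that("counts are anti-monotone under annotation shrinkage", {
  set.seed(62)
  pr <- fake_pair()
  dr <- mk_range()
  s <- sample(1000:1290, 30, replace = TRUE)
  full <- ann_set("snp", "chr1", s, s + 1L)
  a_full <- annotate_pairs(pr, dr, strrep("A", 300),
                           basic_annotations(snp = full))
  for (k in c(20, 10, 3)) {
    sub <- full
    sub$records <- sub$records[sample(nrow(sub$records), k), , drop = FALSE]
    sub$records <- sub$records[order(sub$records$chrom, sub$records$start), ]
    a_sub <- annotate_pairs(pr, dr, strrep("A", 300),
                            basic_annotations(snp = sub))
    expect_lte(a_sub$n_snps_amplicon, a_full$n_snps_amplicon)
    expect_lte(a_sub$n_snps_fwd, a_full$n_snps_fwd)
  }
})

test_that("nearest gene search matches arithmetic and brute force", {
  genes <- ann_set("gene", "chr1", c(0L, 500L), c(100L, 600L),
                   name = c("gA", "gB"), strand = c("+", "-"))
  ng <- nearest_genes("chr1", 250L, 350L, genes)
  expect_identical(ng$upstream_gene, "gA")
  expect_identical(ng$dist_upstream, 150L)
  expect_identical(ng$downstream_gene, "gB")
  expect_identical(ng$dist_downstream, 150L)

  ov <- nearest_genes("chr1", 50L, 350L, genes) # overlaps gA
  expect_identical(ov$upstream_gene, "gA")
  expect_identical(ov$downstream_gene, "gA")
  expect_identical(c(ov$dist_upstream, ov$dist_downstream), c(0L, 0L))

  none <- nearest_genes("chr2", 50L, 350L, genes)
  expect_true(is.na(none$upstream_gene) && is.na(none$downstream_gene))

  set.seed(63)
  for (rep in 1:15) {
    gs <- sort(sample(0:2000, 8))
    g <- ann_set("gene", "chr1", gs, gs + sample(20:100, 8, replace = TRUE),
                 strand = sample(c("+", "-"), 8, replace = TRUE))
    amp <- sort(sample(0:2000, 2))
    got <- nearest_genes("chr1", amp[1], amp[2], g)
    rec <- g$records
    ovl <- pmax(rec$start, amp[1]) < pmin(rec$end, amp[2])
    if (any(ovl)) {
      expect_identical(got$dist_upstream, 0L)
      expect_identical(got$dist_downstream, 0L)
    } else {
      up <- rec[rec$end <= amp[1], ]
      if (nrow(up) > 0) {
        expect_identical(got$dist_upstream, amp[1] - max(up$end))
      } else {
        expect_true(is.na(got$upstream_gene))
      }
      down <- rec[rec$start >= amp[2], ]
      if (nrow(down) > 0) {
        expect_identical(got$dist_downstream, min(down$start) - amp[2])
      } else {
        expect_true(is.na(got$downstream_gene))
      }
    }
  }
})

test_that("annotation results are independent of record order", {
  set.seed(64)
  pr <- fake_pair()
  dr <- mk_range()
  s <- sample(1000:1290, 20, replace = TRUE)
  snp <- ann_set("snp", "chr1", s, s + 1L)
  shuffled <- snp
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  a1 <- annotate_pairs(pr, dr, strrep("A", 300), basic_annotations(snp = snp))
  a2 <- annotate_pairs(pr, dr, strrep("A", 300),
                       basic_annotations(snp = shuffled))
  expect_identical(a1$n_snps_amplicon, a2$n_snps_amplicon)
})
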