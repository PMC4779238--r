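# Independent brute-force oracles. These re-derive expected results from
# first principles (naive enumeration, literature constants re-typed here)
# and deliberately share no code with the package implementation.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", M = "K",
            K = "M", S = "S", W = "W", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# naive per-position, per-strand membership scan; palindromes reported once
oracle_scan <- function(sequence, recognition, cut_offset) {
  sch <- strsplit(sequence, "")[[1]]
  n <- length(sch)
  len <- nchar(recognition)
  match_at <- function(pat_chars, pos) {
    for (k in seq_len(len)) {
      if (!sch[pos + k - 1] %in% oracle_iupac_sets[[pat_chars[k]]]) {
        return(FALSE)
      }
    }
    TRUE
  }
  rc <- oracle_revcomp(recognition)
  palindromic <- identical(recognition, rc)
  pat_fwd <- strsplit(recognition, "")[[1]]
  pat_rc <- strsplit(rc, "")[[1]]
  out <- list()
  for (pos in seq_len(n - len + 1)) {
    if (match_at(pat_fwd, pos)) {
      out[[length(out) + 1]] <- data.frame(
        position = pos - 1L, strand = "+",
        cut_position = pos - 1L + cut_offset)
    }
    if (!palindromic && match_at(pat_rc, pos)) {
      out[[length(out) + 1]] <- data.frame(
        position = pos - 1L, strand = "-",
        cut_position = pos - 1L + len - cut_offset)
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      cut_position = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

# plain NN summation Tm, constants re-typed from the unified parameter set
oracle_tm <- function(s, mono_mM = 50, divalent_mM = 0, dntp_mM = 0,
                      oligo_nM = 50) {
  dh_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  ds_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  dh <- 0; ds <- 0
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  for (i in 1:(n - 1)) {
    key <- paste0(b[i], b[i + 1])
    dh <- dh + dh_tab[[key]]
    ds <- ds + ds_tab[[key]]
  }
  for (t in c(b[1], b[n])) {
    if (t == "G" || t == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  na_eq <- mono_mM + 120 * sqrt(max(0, divalent_mM - dntp_mM))
  ds <- ds + 0.368 * (n - 1) * log(na_eq / 1000)
  dh * 1000 / (ds + 1.987 * log(oligo_nM * 1e-9 / 4)) - 273.15
}

# exhaustive-offset self-complementarity, independent coding
oracle_self_scores <- function(s) {
  x <- strsplit(s, "")[[1]]
  y <- strsplit(oracle_revcomp(s), "")[[1]]
  n <- length(x)
  any_best <- 0; end_best <- 0
  for (k in -(n - 1):(n - 1)) {
    sc <- 0
    covered_3prime <- FALSE
    for (i in 1:n) {
      j <- i - k
      if (j >= 1 && j <= n) {
        sc <- sc + if (x[i] == y[j]) 1 else -1
        if (i == n) covered_3prime <- TRUE
      }
    }
    if (sc > any_best) any_best <- sc
    if (covered_3prime && sc > end_best) end_best <- sc
  }
  c(self_any = any_best, self_end = end_best)
}

# all-pairs half-open overlap subset
oracle_subset <- function(records, ranges) {
  keep <- vapply(seq_len(nrow(records)), function(i) {
    any(vapply(ranges, function(r) {
      records$chrom[i] == r$chrom &&
        max(records$start[i], r$range_start) < min(records$end[i], r$range_end)
    }, logical(1)))
  }, logical(1))
  records[keep, , drop = FALSE]
}

# brute-force candidate windows: every (start, length, strand) window
# re-checked against every hard constraint
oracle_candidates <- function(seq, params) {
  n <- nchar(seq)
  out <- list()
  revcomp_dna <- function(s)
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  for (len in params$size_min:params$size_max) {
    if (len > n) next
    for (s0 in 0:(n - len)) {
      win <- substr(seq, s0 + 1, s0 + len)
      if (grepl("N", win, fixed = TRUE)) next
      if (max(rle(strsplit(win, "")[[1]])$lengths) > params$poly_x_max) next
      tm <- oracle_tm(win, params$mono_mM, params$divalent_mM, params$dntp_mM,
                      params$oligo_nM)
      if (tm < params$tm_min || tm > params$tm_max) next
      gc <- 100 * nchar(gsub("[^GC]", "", win)) / len
      if (gc < params$gc_min || gc > params$gc_max) next
      for (strand in c("forward", "reverse")) {
        pseq <- if (strand == "forward") win else revcomp_dna(win)
        sc <- oracle_self_scores(pseq)
        if (sc[["self_any"]] > params$self_any_max) next
        if (sc[["self_end"]] > params$self_end_max) next
        pen <- params$wt_size * abs(len - params$size_opt) +
          params$wt_tm * abs(tm - params$tm_opt) +
          params$wt_gc * abs(gc - params$gc_opt)
        out[[length(out) + 1]] <- data.frame(
          strand = strand, win_start = s0, win_end = s0 + len,
          sequence = pseq, tm = tm, gc_percent = gc,
          self_any = sc[["self_any"]], self_end = sc[["self_end"]],
          penalty = pen, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# brute-force best pairs under the same documented pairing rule
oracle_best_pairs <- function(cands, params, n_return) {
  fwd <- cands[cands$strand == "forward", , drop = FALSE]
  rev <- cands[cands$strand == "reverse", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      if (fwd$win_end[i] > rev$win_start[j]) next
      product <- rev$win_end[j] - fwd$win_start[i]
      ok <- any(vapply(params$product_size_ranges, function(r)
        product >= r[1] && product <= r[2], logical(1)))
      if (!ok) next
      out[[length(out) + 1]] <- data.frame(
        fwd_win_start = fwd$win_start[i], rev_win_end = rev$win_end[j],
        product_size = product,
        pair_penalty = fwd$penalty[i] + rev$penalty[j] +
          params$pair_wt_tm_diff * abs(fwd$tm[i] - rev$tm[j]),
        fwd_start = fwd$win_start[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$pair_penalty, pairs$fwd_win_start,
                       pairs$product_size, pairs$fwd_start), , drop = FALSE]
  utils::head(pairs, n_return)
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small shared fixture for pipeline-level tests
small_fixture <- function(seed = 7, ...) {
  generate_fixture(fixture_spec(
    n_chroms = 1, chrom_length = 20000, n_cpg_islands = 4,
    island_length = 500, n_snps = 30, n_repeats = 4, n_genes = 3,
    planted_enzyme_sites = list(HpaII = c(1, 0, 2)), seed = seed, ...))
}

write_run_inputs <- function(fix, dir, enzymes = "HpaII") {
  paths <- write_fixture(fix, dir)
  ez <- file.path(dir, "enzymes.txt")
  writeLines(enzymes, ez)
  c(paths, enzymes = ez)
}
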