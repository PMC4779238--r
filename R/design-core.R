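# Step 4: exhaustive candidate primer/pair enumeration under a
# Primer3-compatible parameter set (Boulder-IO dialect), with in-house
# nearest-neighbor thermodynamics and penalty-based ranking. The engine
# implements a documented subset of the Primer3 parameter interface; it does
# not aim at bit-level score parity with the Primer3 binary.

#' Default design parameters
#'
#' Defaults follow the Primer3 (v2.3.x) documented defaults for the
#' implemented subset: primer size 18/20/27 (min/opt/max), Tm 57/60/63 deg C,
#' GC 20/50/80 %, product size 100-300 bp, self-complementarity caps 8 (any)
#' and 3 (3' end) under +1/-1 scoring, max mononucleotide run 5, 50 mM
#' monovalent salt, 1.5 mM divalent, 0.6 mM dNTP, 50 nM oligo concentration.
#' Penalty weights: 1 per bp of size deviation, 1 per deg C of Tm deviation,
#' 0 per GC point (Primer3 default).
#'
#' @param ... Named overrides of any parameter field.
#' @return A list of class `msre_design_params`.
#' @export
design_parameters <- function(...) {
  p <- list(
    size_min = 18L, size_opt = 20L, size_max = 27L,
    tm_min = 57, tm_opt = 60, tm_max = 63,
    gc_min = 20, gc_opt = 50, gc_max = 80,
    product_size_ranges = list(c(100L, 300L)),
    self_any_max = 8, self_end_max = 3,
    poly_x_max = 5L,
    mono_mM = 50, divalent_mM = 1.5, dntp_mM = 0.6, oligo_nM = 50,
    n_return = 5L,
    design_internal_oligo = FALSE,
    oligo_size_min = 18L, oligo_size_opt = 20L, oligo_size_max = 27L,
    oligo_tm_min = 57, oligo_tm_opt = 60, oligo_tm_max = 63,
    wt_size = 1, wt_tm = 1, wt_gc = 0,
    pair_wt_tm_diff = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  p[names(over)] <- over
  validate_params(p)
}

#' @noRd
validate_params <- function(p) {
  if (!(p$size_min <= p$size_opt && p$size_opt <= p$size_max))
    stop("need size_min <= size_opt <= size_max", call. = FALSE)
  if (!(p$tm_min <= p$tm_opt && p$tm_opt <= p$tm_max))
    stop("need tm_min <= tm_opt <= tm_max", call. = FALSE)
  if (!(p$gc_min <= p$gc_opt && p$gc_opt <= p$gc_max))
    stop("need gc_min <= gc_opt <= gc_max", call. = FALSE)
  if (length(p$product_size_ranges) == 0)
    stop("need at least one product size range", call. = FALSE)
  for (r in p$product_size_ranges) {
    if (length(r) != 2 || r[1] > r[2])
      stop("malformed product size range", call. = FALSE)
    if (r[1] < 2 * p$size_min)
      stop("product size range lower bound must be >= 2 * size_min", call. = FALSE)
  }
  structure(p, class = "msre_design_params")
}

# Boulder-IO keys handled by the engine, mapped to parameter fields
BOULDER_KEYS <- c(
  PRIMER_MIN_SIZE = "size_min", PRIMER_OPT_SIZE = "size_opt",
  PRIMER_MAX_SIZE = "size_max",
  PRIMER_MIN_TM = "tm_min", PRIMER_OPT_TM = "tm_opt", PRIMER_MAX_TM = "tm_max",
  PRIMER_MIN_GC = "gc_min", PRIMER_OPT_GC_PERCENT = "gc_opt",
  PRIMER_MAX_GC = "gc_max",
  PRIMER_MAX_SELF_ANY = "self_any_max", PRIMER_MAX_SELF_END = "self_end_max",
  PRIMER_MAX_POLY_X = "poly_x_max",
  PRIMER_SALT_MONOVALENT = "mono_mM", PRIMER_SALT_DIVALENT = "divalent_mM",
  PRIMER_DNTP_CONC = "dntp_mM", PRIMER_DNA_CONC = "oligo_nM",
  PRIMER_NUM_RETURN = "n_return",
  PRIMER_PICK_INTERNAL_OLIGO = "design_internal_oligo",
  PRIMER_INTERNAL_MIN_SIZE = "oligo_size_min",
  PRIMER_INTERNAL_OPT_SIZE = "oligo_size_opt",
  PRIMER_INTERNAL_MAX_SIZE = "oligo_size_max",
  PRIMER_INTERNAL_MIN_TM = "oligo_tm_min",
  PRIMER_INTERNAL_OPT_TM = "oligo_tm_opt",
  PRIMER_INTERNAL_MAX_TM = "oligo_tm_max",
  PRIMER_WT_SIZE_LT = "wt_size", PRIMER_WT_SIZE_GT = "wt_size",
  PRIMER_WT_TM_LT = "wt_tm", PRIMER_WT_TM_GT = "wt_tm",
  PRIMER_WT_GC_PERCENT_LT = "wt_gc", PRIMER_WT_GC_PERCENT_GT = "wt_gc",
  PRIMER_PAIR_WT_DIFF_TM = "pair_wt_tm_diff"
)

#' Parse a Primer3 parameter file (Boulder-IO dialect)
#'
#' One `KEY=VALUE` per line, record terminated by a lone `=` or end of file.
#' Keys outside the implemented subset are ignored with a warning; missing
#' keys take the documented defaults. `PRIMER_PRODUCT_SIZE_RANGE` accepts
#' space-separated `lo-hi` ranges.
#'
#' @param path Path to the parameter file. An empty file yields the full
#'   default set.
#' @return An `msre_design_params` list.
#' @export
parse_parameter_file <- function(path) {
  p <- unclass(design_parameters())
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  unknown <- character(0)
  for (ln in lines) {
    if (ln == "=") break # Boulder-IO record terminator
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1) {
      stop("malformed Boulder-IO line (no '='): ", ln, call. = FALSE)
    }
    key <- substr(ln, 1, eq - 1)
    value <- substr(ln, eq + 1, nchar(ln))
    if (key == "PRIMER_PRODUCT_SIZE_RANGE") {
      parts <- strsplit(trimws(value), "\\s+")[[1]]
      ranges <- lapply(parts, function(x) {
        lohi <- suppressWarnings(as.integer(strsplit(x, "-", fixed = TRUE)[[1]]))
        if (length(lohi) != 2 || anyNA(lohi)) {
          stop("unparseable value for PRIMER_PRODUCT_SIZE_RANGE: ", x,
               call. = FALSE)
        }
        lohi
      })
      p$product_size_ranges <- ranges
    } else if (key %in% names(BOULDER_KEYS)) {
      field <- BOULDER_KEYS[[key]]
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num)) {
        stop("unparseable numeric value for key ", key, ": '", value, "'",
             call. = FALSE)
      }
      p[[field]] <- if (field == "design_internal_oligo") num != 0 else num
    } else {
      unknown <- c(unknown, key)
    }
  }
  if (length(unknown) > 0) {
    warning("ignoring Boulder-IO key(s) outside the implemented subset: ",
            paste(unknown, collapse = ", "))
  }
  int_fields <- c("size_min", "size_opt", "size_max", "poly_x_max", "n_return",
                  "oligo_size_min", "oligo_size_opt", "oligo_size_max")
  p[int_fields] <- lapply(p[int_fields], as.integer)
  validate_params(p)
}

#' Self-complementarity scores of a primer
#'
#' Aligns the sequence against its own reverse complement at every offset
#' and scores each aligned position +1 for a match and -1 for a mismatch
#' (no gaps). `self_any` is the maximum score over all offsets; `self_end`
#' restricts the maximum to offsets in which the primer's 3'-terminal base is
#' aligned, so `self_end <= self_any` always. Scores are floored at 0.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Data.frame with columns `self_any`, `self_end`.
#' @export
#' @examples
#' complementarity_scores("ACGTACGT") # palindrome: self_any 8
complementarity_scores <- function(sequence) {
  sequence <- toupper(sequence)
  res <- vapply(sequence, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    y <- strsplit(reverse_complement(s), "", fixed = TRUE)[[1]]
    n <- length(x)
    best_any <- 0
    best_end <- 0
    for (k in seq(-(n - 1L), n - 1L)) {
      i <- max(1L, k + 1L):min(n, n + k)
      sc <- sum(ifelse(x[i] == y[i - k], 1, -1))
      if (sc > best_any) best_any <- sc
      if (k >= 0 && sc > best_end) best_end <- sc
    }
    c(best_any, best_end)
  }, numeric(2))
  data.frame(self_any = res[1, ], self_end = res[2, ], row.names = NULL)
}

# 0-based half-open windows [start, start+len) that fully contain more than
# poly_x_max consecutive identical bases
#' @noRd
polyx_violations <- function(bases, starts, len, poly_x_max) {
  r <- rle(bases)
  ends <- cumsum(r$lengths)       # 1-based inclusive run ends
  run_start0 <- ends - r$lengths  # 0-based run starts
  run_end0 <- ends                # 0-based half-open run ends
  long <- which(r$lengths > poly_x_max)
  bad <- rep(FALSE, length(starts))
  for (j in long) {
    ov <- pmin(run_end0[j], starts + len) - pmax(run_start0[j], starts)
    bad <- bad | (ov > poly_x_max)
  }
  bad
}

#' Enumerate candidate primers on a target sequence
#'
#' Exhaustively scans every (position, length) window on both strands and
#' keeps candidates satisfying all hard constraints: size, Tm, GC%,
#' self-complementarity caps, maximum mononucleotide run, and no N. The
#' penalty is `wt_size * |len - size_opt| + wt_tm * |tm - tm_opt| +
#' wt_gc * |gc - gc_opt|`.
#'
#' Reverse candidates are the reverse complement of their plus-strand window;
#' `start` is the 0-based position of the primer's 5' end on the plus strand,
#' and `win_start`/`win_end` give the plus-strand window for both strands.
#'
#' @param target_sequence Character scalar (or `msre_target_sequence`).
#' @param params An `msre_design_params`.
#' @return Data.frame of candidates, deterministically ordered by
#'   (win_start, length, strand).
#' @export
candidate_primers <- function(target_sequence, params = design_parameters()) {
  if (inherits(target_sequence, "msre_target_sequence")) {
    target_sequence <- target_sequence$sequence
  }
  n <- nchar(target_sequence)
  empty <- data.frame(strand = character(), start = integer(),
                      length = integer(), win_start = integer(),
                      win_end = integer(), sequence = character(),
                      tm = numeric(), gc_percent = numeric(),
                      self_any = numeric(), self_end = numeric(),
                      penalty = numeric(), stringsAsFactors = FALSE)
  if (n < params$size_min) return(empty)
  profile <- thermo_profile(target_sequence)
  rows <- list()
  for (len in seq(params$size_min, min(params$size_max, n))) {
    starts <- 0:(n - len)
    th <- window_thermo(profile, starts, len, params$mono_mM,
                        params$divalent_mM, params$dntp_mM, params$oligo_nM)
    ok <- !th$has_n &
      th$tm >= params$tm_min & th$tm <= params$tm_max &
      th$gc >= params$gc_min & th$gc <= params$gc_max &
      !polyx_violations(profile$bases, starts, len, params$poly_x_max)
    if (!any(ok)) next
    ws <- starts[ok]
    fwd_seq <- substring(target_sequence, ws + 1L, ws + len)
    rev_seq <- reverse_complement(fwd_seq)
    base <- data.frame(win_start = ws, win_end = ws + len, length = len,
                       tm = th$tm[ok], gc_percent = th$gc[ok],
                       stringsAsFactors = FALSE)
    fwd <- cbind(base, strand = "forward", start = ws, sequence = fwd_seq,
                 stringsAsFactors = FALSE)
    rev <- cbind(base, strand = "reverse", start = ws + len - 1L,
                 sequence = rev_seq, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(fwd, rev)
  }
  if (length(rows) == 0) return(empty)
  cand <- do.call(rbind, rows)
  # self-complementarity on the synthesized primer sequence (cache by
  # sequence: forward/reverse windows often share content)
  uniq <- unique(cand$sequence)
  sc <- complementarity_scores(uniq)
  idx <- match(cand$sequence, uniq)
  cand$self_any <- sc$self_any[idx]
  cand$self_end <- sc$self_end[idx]
  cand <- cand[cand$self_any <= params$self_any_max &
                 cand$self_end <= params$self_end_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand$penalty <- params$wt_size * abs(cand$length - params$size_opt) +
    params$wt_tm * abs(cand$tm - params$tm_opt) +
    params$wt_gc * abs(cand$gc_percent - params$gc_opt)
  cand <- cand[order(cand$win_start, cand$length, cand$strand),
               c("strand", "start", "length", "win_start", "win_end",
                 "sequence", "tm", "gc_percent", "self_any", "self_end",
                 "penalty")]
  rownames(cand) <- NULL
  cand
}

#' Enumerate primer pairs from candidates
#'
#' Pairs every forward candidate with every reverse candidate whose window
#' lies fully to its right (primers may not overlap), keeps pairs whose
#' product size falls in one of the configured ranges, sorts by pair penalty
#' (`forward + reverse + pair_wt_tm_diff * |Tm difference|`) with
#' deterministic ties broken by (amplicon_start, product_size, forward
#' start), and truncates to `n_return`. The amplicon spans the forward
#' primer's 5' end through the reverse primer's 5' end inclusive, so
#' `product_size = amplicon_end - amplicon_start`.
#'
#' @param candidates Data.frame from [candidate_primers()].
#' @param params An `msre_design_params`.
#' @param n_return Maximum pairs returned; defaults to `params$n_return`.
#' @param target_sequence Needed only when `params$design_internal_oligo` is
#'   `TRUE`, to design the internal oligo.
#' @return Data.frame of pairs with flattened `fwd_*`, `rev_*` (and
#'   `oligo_*`) columns plus `amplicon_start`, `amplicon_end`,
#'   `product_size`, `pair_penalty`, `pair_id`.
#' @export
enumerate_pairs <- function(candidates, params = design_parameters(),
                            n_return = params$n_return,
                            target_sequence = NULL) {
  fwd <- candidates[candidates$strand == "forward", , drop = FALSE]
  rev <- candidates[candidates$strand == "reverse", , drop = FALSE]
  empty <- empty_pairs()
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty)
  fi <- rep(seq_len(nrow(fwd)), each = nrow(rev))
  ri <- rep(seq_len(nrow(rev)), times = nrow(fwd))
  amp_start <- fwd$win_start[fi]
  amp_end <- rev$win_end[ri]
  product <- amp_end - amp_start
  in_range <- rep(FALSE, length(product))
  for (r in params$product_size_ranges) {
    in_range <- in_range | (product >= r[1] & product <= r[2])
  }
  keep <- in_range & (fwd$win_end[fi] <= rev$win_start[ri])
  if (!any(keep)) return(empty)
  fi <- fi[keep]; ri <- ri[keep]
  pen <- fwd$penalty[fi] + rev$penalty[ri] +
    params$pair_wt_tm_diff * abs(fwd$tm[fi] - rev$tm[ri])
  pairs <- data.frame(
    fwd_seq = fwd$sequence[fi], rev_seq = rev$sequence[ri],
    fwd_start = fwd$start[fi], rev_start = rev$start[ri],
    fwd_len = fwd$length[fi], rev_len = rev$length[ri],
    fwd_win_start = fwd$win_start[fi], fwd_win_end = fwd$win_end[fi],
    rev_win_start = rev$win_start[ri], rev_win_end = rev$win_end[ri],
    fwd_tm = fwd$tm[fi], rev_tm = rev$tm[ri],
    fwd_gc = fwd$gc_percent[fi], rev_gc = rev$gc_percent[ri],
    fwd_self_any = fwd$self_any[fi], rev_self_any = rev$self_any[ri],
    fwd_self_end = fwd$self_end[fi], rev_self_end = rev$self_end[ri],
    fwd_penalty = fwd$penalty[fi], rev_penalty = rev$penalty[ri],
    amplicon_start = amp_start[keep], amplicon_end = amp_end[keep],
    product_size = product[keep], pair_penalty = pen,
    stringsAsFactors = FALSE)
  ord <- order(pairs$pair_penalty, pairs$amplicon_start, pairs$product_size,
               pairs$fwd_start)
  pairs <- pairs[ord, , drop = FALSE]
  if (nrow(pairs) > n_return) pairs <- pairs[seq_len(n_return), , drop = FALSE]
  pairs$pair_id <- sprintf("pair_%02d", seq_len(nrow(pairs)))
  pairs <- add_oligo_columns(pairs, params, target_sequence)
  rownames(pairs) <- NULL
  pairs
}

#' @noRd
empty_pairs <- function() {
  df <- data.frame(fwd_seq = character(), rev_seq = character(),
                   fwd_start = integer(), rev_start = integer(),
                   fwd_len = integer(), rev_len = integer(),
                   fwd_win_start = integer(), fwd_win_end = integer(),
                   rev_win_start = integer(), rev_win_end = integer(),
                   fwd_tm = numeric(), rev_tm = numeric(),
                   fwd_gc = numeric(), rev_gc = numeric(),
                   fwd_self_any = numeric(), rev_self_any = numeric(),
                   fwd_self_end = numeric(), rev_self_end = numeric(),
                   fwd_penalty = numeric(), rev_penalty = numeric(),
                   amplicon_start = integer(), amplicon_end = integer(),
                   product_size = integer(), pair_penalty = numeric(),
                   pair_id = character(), stringsAsFactors = FALSE)
  add_oligo_columns(df, NULL, NULL)
}

# internal oligo: best candidate (by penalty) strictly between the primers,
# designed with the oligo-specific size/Tm bounds; NA columns when disabled
# or infeasible
#' @noRd
add_oligo_columns <- function(pairs, params, target_sequence) {
  n <- nrow(pairs)
  pairs$oligo_seq <- rep(NA_character_, n)
  pairs$oligo_win_start <- rep(NA_integer_, n)
  pairs$oligo_win_end <- rep(NA_integer_, n)
  pairs$oligo_tm <- rep(NA_real_, n)
  pairs$oligo_penalty <- rep(NA_real_, n)
  if (is.null(params) || !isTRUE(params$design_internal_oligo) ||
      nrow(pairs) == 0) {
    return(pairs)
  }
  if (is.null(target_sequence)) {
    stop("internal oligo design requires the target sequence", call. = FALSE)
  }
  oparams <- params
  oparams$size_min <- params$oligo_size_min
  oparams$size_opt <- params$oligo_size_opt
  oparams$size_max <- params$oligo_size_max
  oparams$tm_min <- params$oligo_tm_min
  oparams$tm_opt <- params$oligo_tm_opt
  oparams$tm_max <- params$oligo_tm_max
  ocand <- candidate_primers(target_sequence, validate_params(unclass(oparams)))
  ocand <- ocand[ocand$strand == "forward", , drop = FALSE]
  if (nrow(ocand) == 0) return(pairs)
  for (i in seq_len(nrow(pairs))) {
    inside <- ocand$win_start >= pairs$fwd_win_end[i] &
      ocand$win_end <= pairs$rev_win_start[i]
    if (!any(inside)) next
    oc <- ocand[inside, , drop = FALSE]
    best <- oc[order(oc$penalty, oc$win_start, oc$length)[1], , drop = FALSE]
    pairs$oligo_seq[i] <- best$sequence
    pairs$oligo_win_start[i] <- best$win_start
    pairs$oligo_win_end[i] <- best$win_end
    pairs$oligo_tm[i] <- best$tm
    pairs$oligo_penalty[i] <- best$penalty
  }
  pairs
}
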