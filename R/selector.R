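# Step 7: rank-based quality matrix parsing, hierarchical quality level
# assignment, MSRE-specific hard filters, and final per-target selection.

#' Parse a quality-matrix file
#'
#' Tab-separated rules, one per line: `column<TAB>operator<TAB>value<TAB>rank`
#' with `#` comments allowed. Operators: `>`, `<`, `>=`, `<=` with a single
#' numeric value, and `-` (inclusive range) with `lo,hi`. `column` must be a
#' numeric column of the summary output schema; `rank` is an integer 1-10.
#'
#' @param path Path to the quality-matrix TSV.
#' @param output_schema Character vector of valid column names; defaults to
#'   the numeric columns of the summary schema.
#' @return Data.frame of rules: `column`, `operator`, `lo`, `hi`, `rank`,
#'   order preserved within ranks.
#' @export
parse_quality_matrix <- function(path, output_schema = quality_rule_columns()) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_rules())
  rules <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) {
      stop("quality-matrix line ", i, ": expected 4 tab-delimited fields",
           call. = FALSE)
    }
    column <- f[1]
    op <- f[2]
    rank <- suppressWarnings(as.integer(f[4]))
    if (!column %in% output_schema) {
      stop("quality-matrix line ", i, ": unknown column '", column,
           "'; valid columns: ", paste(output_schema, collapse = ", "),
           call. = FALSE)
    }
    if (!op %in% c(">", "<", ">=", "<=", "-")) {
      stop("quality-matrix line ", i, ": bad operator '", op, "'",
           call. = FALSE)
    }
    if (is.na(rank) || rank < 1 || rank > 10) {
      stop("quality-matrix line ", i, ": rank must be an integer in 1-10",
           call. = FALSE)
    }
    if (op == "-") {
      v <- suppressWarnings(as.numeric(strsplit(f[3], ",", fixed = TRUE)[[1]]))
      if (length(v) != 2 || anyNA(v) || v[1] > v[2]) {
        stop("quality-matrix line ", i,
             ": '-' operator needs 'lo,hi' with lo <= hi", call. = FALSE)
      }
      lo <- v[1]; hi <- v[2]
    } else {
      v <- suppressWarnings(as.numeric(f[3]))
      if (is.na(v)) {
        stop("quality-matrix line ", i, ": non-numeric value '", f[3], "'",
             call. = FALSE)
      }
      lo <- v; hi <- NA_real_
    }
    data.frame(column = column, operator = op, lo = lo, hi = hi, rank = rank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rules)
  out[order(out$rank), , drop = FALSE]
}

#' @noRd
empty_rules <- function() {
  data.frame(column = character(), operator = character(), lo = numeric(),
             hi = numeric(), rank = integer(), stringsAsFactors = FALSE)
}

# evaluate one rule on a vector of column values
#' @noRd
rule_satisfied <- function(values, rule) {
  switch(rule$operator,
         ">" = values > rule$lo,
         "<" = values < rule$lo,
         ">=" = values >= rule$lo,
         "<=" = values <= rule$lo,
         "-" = values >= rule$lo & values <= rule$hi,
         stop("bad operator"))
}

#' Assign hierarchical quality levels to annotated pairs
#'
#' Rules are grouped by rank. In `"cumulative"` mode (default) a pair's
#' quality level is the smallest rank `r` such that the pair satisfies every
#' rule with rank `<= r`; pairs failing the lowest rank tier get no level
#' (`NA`). In `"independent"` mode the rank tiers are alternatives: the level
#' is the smallest rank whose own rules are all satisfied (a relaxation
#' ladder, rank 1 strictest). With no rules, all pairs keep `NA` levels and
#' selection falls back to pure penalty order.
#'
#' @param annotated_pairs Data.frame from [annotate_pairs()] (any number of
#'   targets).
#' @param rules Data.frame from [parse_quality_matrix()], or `NULL`.
#' @param mode `"cumulative"` or `"independent"`.
#' @return List with `levels` (integer vector per pair), `audit` (data.frame
#'   of every pair x rule evaluation: `pair`, `rule`, `column`, `rank`,
#'   `passed`), and `selected` (logical: pairs at the best achieved level of
#'   their target, all targets' best pairs when no rules are given).
#' @export
assign_quality_levels <- function(annotated_pairs, rules = NULL,
                                  mode = c("cumulative", "independent")) {
  mode <- match.arg(mode)
  n <- nrow(annotated_pairs)
  if (is.null(rules) || nrow(rules) == 0) {
    return(list(levels = rep(NA_integer_, n),
                audit = data.frame(pair = integer(), rule = integer(),
                                   column = character(), rank = integer(),
                                   passed = logical(), stringsAsFactors = FALSE),
                selected = rep(TRUE, n)))
  }
  pass <- matrix(TRUE, nrow = n, ncol = nrow(rules))
  for (j in seq_len(nrow(rules))) {
    vals <- annotated_pairs[[rules$column[j]]]
    pass[, j] <- !is.na(vals) & rule_satisfied(as.numeric(vals), rules[j, ])
  }
  ranks <- sort(unique(rules$rank))
  levels <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (r in ranks) {
      idx <- if (mode == "cumulative") which(rules$rank <= r)
             else which(rules$rank == r)
      if (all(pass[i, idx])) {
        levels[i] <- r
        break
      }
    }
  }
  audit <- data.frame(pair = rep(seq_len(n), times = nrow(rules)),
                      rule = rep(seq_len(nrow(rules)), each = n),
                      column = rep(rules$column, each = n),
                      rank = rep(rules$rank, each = n),
                      passed = as.vector(pass), stringsAsFactors = FALSE)
  selected <- rep(FALSE, n)
  for (tid in unique(annotated_pairs$target_id)) {
    in_t <- annotated_pairs$target_id == tid
    lv <- levels[in_t]
    if (all(is.na(lv))) next
    best <- min(lv, na.rm = TRUE)
    selected[in_t] <- !is.na(lv) & lv == best
  }
  list(levels = levels, audit = audit, selected = selected)
}

#' MSRE assay validation filter
#'
#' A designed pair qualifies as an MSRE assay when (1) the amplicon contains
#' at least one restriction enzyme cut site, (2) neither primer overlaps a
#' SNP, (3) no repeat element overlaps the amplicon, and (4) the original
#' target midpoint lies inside the amplicon extended by `proximity_bp` on
#' each side.
#'
#' @param annotated_pairs Data.frame from [annotate_pairs()].
#' @param proximity_bp Proximity window in bp (default 50).
#' @return Data.frame with `pass` (logical) and `reasons`
#'   (`;`-separated violated criteria, empty string when passing). Reason
#'   codes: `no_cutsite_in_amplicon`, `snp_in_primer`, `repeat_in_assay`,
#'   `target_not_proximal`.
#' @export
msre_validation_filter <- function(annotated_pairs, proximity_bp = 50L) {
  n <- nrow(annotated_pairs)
  fail <- cbind(
    no_cutsite_in_amplicon = annotated_pairs$n_cutsites_amplicon < 1,
    snp_in_primer = annotated_pairs$n_snps_fwd > 0 | annotated_pairs$n_snps_rev > 0,
    repeat_in_assay = annotated_pairs$n_repeats > 0,
    target_not_proximal = abs(annotated_pairs$target_dist) > proximity_bp)
  reasons <- apply(fail, 1, function(f)
    paste(colnames(fail)[f], collapse = ";"))
  data.frame(pass = rowSums(fail) == 0,
             reasons = if (n == 0) character(0) else reasons,
             stringsAsFactors = FALSE)
}
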