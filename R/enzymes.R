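# Type-II (methylation-sensitive) restriction enzymes: caret-notation
# definitions, IUPAC-degenerate site scanning on both strands, per-region cut
# site counting, and genome-wide CpG coverage statistics.

#' Built-in restriction enzyme catalog
#'
#' The catalog ships the ten CpG-motif methylation-sensitive enzymes commonly
#' used for MSRE-PCR, in caret notation (`^` marks the cleavage position
#' within the recognition motif). Degenerate IUPAC codes are supported
#' (e.g. XmiI `GT^MKAC`).
#'
#' @return A data.frame with columns `name`, `recognition`, `cut_offset`,
#'   `is_palindromic`.
#' @export
#' @examples
#' enzyme_catalog()
enzyme_catalog <- function() {
  defs <- c(
    HpaII    = "C^CGG",
    Hin6I    = "G^CGC",
    AciI     = "C^CGC",
    HpyCH4IV = "A^CGT",
    Bsu15I   = "AT^CGAT",
    NarI     = "GG^CGCC",
    Bsp119I  = "TT^CGAA",
    Psp1406I = "AA^CGTT",
    XmiI     = "GT^MKAC",
    Hin1I    = "GR^CGYC"
  )
  do.call(rbind, lapply(names(defs), function(nm) parse_enzyme_def(nm, defs[[nm]])))
}

#' Parse a caret-notation enzyme definition
#'
#' @param name Enzyme name.
#' @param caret Recognition motif with `^` at the cleavage position,
#'   e.g. `"C^CGG"`.
#' @return One-row data.frame with `name`, `recognition`, `cut_offset`,
#'   `is_palindromic`.
#' @export
parse_enzyme_def <- function(name, caret) {
  caret <- toupper(trimws(caret))
  n_caret <- lengths(regmatches(caret, gregexpr("^", caret, fixed = TRUE)))
  if (n_caret != 1) {
    stop("recognition motif must contain exactly one '^': ", caret, call. = FALSE)
  }
  cut_offset <- regexpr("^", caret, fixed = TRUE)[1] - 1L
  recognition <- gsub("^", "", caret, fixed = TRUE)
  if (nchar(recognition) == 0) stop("empty recognition motif", call. = FALSE)
  bad <- setdiff(strsplit(recognition, "")[[1]], names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in recognition motif: ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  data.frame(name = name, recognition = recognition, cut_offset = cut_offset,
             is_palindromic = recognition == reverse_complement(recognition),
             stringsAsFactors = FALSE)
}

#' Read an enzyme list file
#'
#' One enzyme name per line (case-insensitive, `#` comments allowed). Names
#' are resolved against the built-in catalog, optionally extended by a custom
#' catalog TSV with lines `NAME<TAB>RECOGNITION_WITH_CARET`.
#'
#' @param path Path to the enzyme list file.
#' @param catalog Catalog data.frame, by default [enzyme_catalog()].
#' @param custom_catalog Optional path to a custom catalog TSV.
#' @return Data.frame of enzymes in file order (catalog schema).
#' @export
parse_enzyme_list <- function(path, catalog = enzyme_catalog(),
                              custom_catalog = NULL) {
  if (!is.null(custom_catalog)) {
    extra <- utils::read.table(custom_catalog, sep = "\t", header = FALSE,
                               comment.char = "#", stringsAsFactors = FALSE)
    add <- do.call(rbind, Map(parse_enzyme_def, extra[[1]], extra[[2]]))
    catalog <- rbind(catalog, add)
  }
  lines <- trimws(readLines(path))
  names_req <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(names_req) == 0) stop("empty enzyme list: ", path, call. = FALSE)
  idx <- match(tolower(names_req), tolower(catalog$name))
  if (anyNA(idx)) {
    stop("unknown enzyme name(s): ",
         paste(names_req[is.na(idx)], collapse = ", "),
         "; known: ", paste(catalog$name, collapse = ", "), call. = FALSE)
  }
  out <- catalog[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# regex character classes built from the IUPAC membership sets
#' @noRd
iupac_regex <- function(pattern) {
  codes <- strsplit(pattern, "")[[1]]
  paste(vapply(codes, function(cc) {
    set <- IUPAC_SETS[[cc]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# all 0-based match starts of an IUPAC pattern on a concrete sequence,
# overlapping matches included
#' @noRd
iupac_match_starts <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for restriction enzyme cut sites
#'
#' Finds all matches of the enzyme's (IUPAC-degenerate) recognition motif on
#' the plus strand, plus all matches of its reverse complement reported as
#' minus-strand sites. For palindromic enzymes each physical site is reported
#' exactly once, as a plus-strand site. Overlapping matches are all reported.
#'
#' @param sequence DNA string over A/C/G/T (N allowed; N never matches).
#' @param enzyme One-row data.frame from the enzyme catalog.
#' @return Data.frame with columns `enzyme`, `position` (0-based match
#'   start), `strand`, `cut_position` (0-based gap index of cleavage on the
#'   plus sequence), sorted by position.
#' @export
#' @examples
#' hpa <- enzyme_catalog()[1, ]
#' scan_sites("TTCCGGAA", hpa)
scan_sites <- function(sequence, enzyme) {
  stopifnot(nrow(enzyme) == 1)
  len <- nchar(enzyme$recognition)
  pos_plus <- iupac_match_starts(sequence, enzyme$recognition)
  res <- data.frame(enzyme = character(), position = integer(),
                    strand = character(), cut_position = integer(),
                    stringsAsFactors = FALSE)
  if (length(pos_plus) > 0) {
    res <- data.frame(enzyme = enzyme$name, position = pos_plus, strand = "+",
                      cut_position = pos_plus + enzyme$cut_offset,
                      stringsAsFactors = FALSE)
  }
  if (!enzyme$is_palindromic) {
    pos_minus <- iupac_match_starts(sequence, reverse_complement(enzyme$recognition))
    if (length(pos_minus) > 0) {
      res <- rbind(res, data.frame(
        enzyme = enzyme$name, position = pos_minus, strand = "-",
        cut_position = pos_minus + len - enzyme$cut_offset,
        stringsAsFactors = FALSE))
    }
  }
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# scan with several enzymes, deduplicating identical (enzyme, position,
# strand) triples
#' @noRd
scan_sites_multi <- function(sequence, enzymes) {
  if (is.null(enzymes) || nrow(enzymes) == 0) {
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), cut_position = integer(),
                      len = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(enzymes)), function(i) {
    s <- scan_sites(sequence, enzymes[i, , drop = FALSE])
    if (nrow(s) > 0) s$len <- nchar(enzymes$recognition[i])
    else s$len <- integer(0)
    s
  }))
  out <- out[!duplicated(out[, c("enzyme", "position", "strand")]), , drop = FALSE]
  out <- out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count cut sites in the regions of a primer pair
#'
#' A site is counted for a region when its recognition-motif match overlaps
#' that region's interval on the target sequence (a primer overlapping any
#' part of a recognition site is disrupted by digestion). Identical
#' (enzyme, position, strand) sites are never double-counted.
#'
#' @param pair One-row data.frame from [enumerate_pairs()] (sequence-space
#'   coordinates: `fwd_win_start/end`, `rev_win_start/end`, optional
#'   `oligo_win_start/end`, `amplicon_start/end`).
#' @param target_sequence The design sequence the pair was designed on.
#' @param enzymes Enzyme catalog rows, or `NULL` for genomic-PCR mode (all
#'   counts zero, scan skipped).
#' @return List with counts `n_fwd`, `n_rev`, `n_oligo`, `n_amplicon`, a
#'   `per_enzyme` data.frame and the amplicon-relative site table `sites`.
#' @export
count_cut_sites <- function(pair, target_sequence, enzymes) {
  zero <- list(n_fwd = 0L, n_rev = 0L, n_oligo = 0L, n_amplicon = 0L,
               per_enzyme = data.frame(enzyme = character(),
                                       n_fwd = integer(), n_rev = integer(),
                                       n_oligo = integer(),
                                       n_amplicon = integer(),
                                       stringsAsFactors = FALSE),
               sites = data.frame(enzyme = character(), position = integer(),
                                  strand = character(),
                                  rel_amplicon = integer(),
                                  stringsAsFactors = FALSE))
  if (is.null(enzymes) || nrow(enzymes) == 0) return(zero)
  sites <- scan_sites_multi(target_sequence, enzymes)
  if (nrow(sites) == 0) return(zero)
  s0 <- sites$position
  s1 <- sites$position + sites$len
  in_region <- function(a, b) {
    if (is.na(a) || is.na(b)) rep(FALSE, nrow(sites)) else overlaps(s0, s1, a, b)
  }
  oligo_start <- if ("oligo_win_start" %in% names(pair)) pair$oligo_win_start else NA
  oligo_end <- if ("oligo_win_end" %in% names(pair)) pair$oligo_win_end else NA
  hit <- data.frame(
    fwd = in_region(pair$fwd_win_start, pair$fwd_win_end),
    rev = in_region(pair$rev_win_start, pair$rev_win_end),
    oligo = in_region(oligo_start, oligo_end),
    amplicon = in_region(pair$amplicon_start, pair$amplicon_end))
  per <- do.call(rbind, lapply(split(seq_len(nrow(sites)), sites$enzyme), function(i) {
    data.frame(enzyme = sites$enzyme[i[1]],
               n_fwd = sum(hit$fwd[i]), n_rev = sum(hit$rev[i]),
               n_oligo = sum(hit$oligo[i]), n_amplicon = sum(hit$amplicon[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  amp_sites <- sites[hit$amplicon, , drop = FALSE]
  list(n_fwd = sum(hit$fwd), n_rev = sum(hit$rev), n_oligo = sum(hit$oligo),
       n_amplicon = sum(hit$amplicon), per_enzyme = per,
       sites = data.frame(enzyme = amp_sites$enzyme,
                          position = amp_sites$position,
                          strand = amp_sites$strand,
                          rel_amplicon = amp_sites$position - pair$amplicon_start,
                          stringsAsFactors = FALSE))
}

#' CpG coverage statistics per enzyme
#'
#' For each enzyme, reports (a) the percentage of CpG dinucleotides in the
#' genome that lie within at least one recognition-site match of that enzyme,
#' (b) the mean number of recognition sites per kb inside CpG island
#' intervals and (c) outside them.
#'
#' @param genome An `msre_genome`.
#' @param enzymes Enzyme catalog rows.
#' @param cpg_islands An `msre_annotation` of kind `cpg_island`.
#' @return Data.frame with one row per enzyme: `enzyme`, `pct_cpg_covered`,
#'   `sites_per_kb_islands`, `sites_per_kb_outside`.
#' @export
cpg_coverage_stats <- function(genome, enzymes, cpg_islands) {
  isl <- cpg_islands$records
  out <- lapply(seq_len(nrow(enzymes)), function(i) {
    enz <- enzymes[i, , drop = FALSE]
    len <- nchar(enz$recognition)
    covered <- 0L
    total_cpg <- 0L
    n_in <- 0L
    n_out <- 0L
    for (chrom in names(genome$sequences)) {
      s <- genome$sequences[[chrom]]
      cpg <- iupac_match_starts(s, "CG")
      total_cpg <- total_cpg + length(cpg)
      sites <- scan_sites(s, enz)
      ir <- isl[isl$chrom == chrom, , drop = FALSE]
      if (nrow(sites) > 0) {
        if (length(cpg) > 0) {
          # CpG interval [p, p+2) overlapping any site interval [q, q+len)
          hits <- vapply(cpg, function(p)
            any(overlaps(p, p + 2L, sites$position, sites$position + len)),
            logical(1))
          covered <- covered + sum(hits)
        }
        if (nrow(ir) > 0) {
          inside <- vapply(sites$position, function(p)
            any(p >= ir$start & p < ir$end), logical(1))
          n_in <- n_in + sum(inside)
          n_out <- n_out + sum(!inside)
        } else {
          n_out <- n_out + nrow(sites)
        }
      }
    }
    bp_in <- sum(pmin(isl$end, genome$lengths[isl$chrom]) - pmax(isl$start, 0))
    bp_out <- sum(genome$lengths) - bp_in
    pct <- if (total_cpg == 0) {
      warning("genome contains no CpG dinucleotides; coverage reported as 0")
      0
    } else 100 * covered / total_cpg
    data.frame(enzyme = enz$name,
               pct_cpg_covered = pct,
               sites_per_kb_islands = if (bp_in > 0) 1000 * n_in / bp_in else NA_real_,
               sites_per_kb_outside = if (bp_out > 0) 1000 * n_out / bp_out else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
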