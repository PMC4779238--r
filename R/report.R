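# Outputs: summary table (TSV + HTML), per-target UCSC custom track in GTF,
# and UCSC genome-browser / In-Silico-PCR hyperlink strings. URLs are emitted
# as strings only; nothing is fetched.

UCSC_BROWSER_BASE <- "https://genome.ucsc.edu/cgi-bin/hgTracks"
UCSC_INSILICO_BASE <- "https://genome.ucsc.edu/cgi-bin/hgPcr"

#' Frozen column order of the summary table
#'
#' These exact strings are also the vocabulary for quality-matrix rules
#' (see [quality_rule_columns()] for the numeric subset).
#'
#' @return Character vector of column names.
#' @export
summary_columns <- function() {
  c("target_id", "pair_id", "fwd_seq", "rev_seq", "oligo_seq",
    "fwd_tm", "rev_tm", "fwd_gc", "rev_gc",
    "fwd_penalty", "rev_penalty", "pair_penalty",
    "chrom", "amplicon_coord", "amplicon_start", "amplicon_end",
    "product_size",
    "n_cutsites_fwd", "n_cutsites_rev", "n_cutsites_oligo",
    "n_cutsites_amplicon",
    "n_snps_fwd", "n_snps_rev", "n_snps_oligo", "n_snps_amplicon",
    "n_cpg_islands", "n_repeats", "repeat_in_primer",
    "upstream_gene", "upstream_gene_strand", "dist_upstream",
    "downstream_gene", "downstream_gene_strand", "dist_downstream",
    "target_dist", "msre_pass", "msre_fail_reasons", "quality_level",
    "browser_url", "insilico_url")
}

#' Columns usable in quality-matrix rules
#'
#' The numeric/logical columns of the summary schema.
#'
#' @return Character vector of column names.
#' @export
quality_rule_columns <- function() {
  c("fwd_tm", "rev_tm", "fwd_gc", "rev_gc", "fwd_penalty", "rev_penalty",
    "pair_penalty", "amplicon_start", "amplicon_end", "product_size",
    "n_cutsites_fwd", "n_cutsites_rev", "n_cutsites_oligo",
    "n_cutsites_amplicon", "n_snps_fwd", "n_snps_rev", "n_snps_oligo",
    "n_snps_amplicon", "n_cpg_islands", "n_repeats", "repeat_in_primer",
    "dist_upstream", "dist_downstream", "target_dist", "quality_level")
}

#' UCSC genome browser URL for an interval
#'
#' The position string uses the browser's 1-based inclusive display
#' convention (`chrom:start+1-end` for a 0-based half-open interval) and is
#' URL-encoded.
#'
#' @param chrom,start,end Interval, 0-based half-open.
#' @param assembly Assembly label, e.g. `"hg19"`.
#' @return URL string.
#' @export
#' @examples
#' browser_url("chr10", 129467190, 129768042, "hg19")
browser_url <- function(chrom, start, end, assembly = "hg19") {
  position <- sprintf("%s:%d-%d", chrom, start + 1, end)
  sprintf("%s?db=%s&position=%s", UCSC_BROWSER_BASE, assembly,
          utils::URLencode(position, reserved = TRUE))
}

#' UCSC In-Silico PCR URL for a primer pair
#'
#' @param fwd_seq,rev_seq Primer sequences (case is normalized to upper).
#' @param assembly Assembly label.
#' @return URL string.
#' @export
insilico_pcr_url <- function(fwd_seq, rev_seq, assembly = "hg19") {
  sprintf("%s?db=%s&wp_target=genome&wp_f=%s&wp_r=%s&Submit=submit",
          UCSC_INSILICO_BASE, assembly,
          utils::URLencode(toupper(fwd_seq), reserved = TRUE),
          utils::URLencode(toupper(rev_seq), reserved = TRUE))
}

#' Assemble summary rows from annotated pairs
#'
#' @param annotated Data.frame from [annotate_pairs()], optionally with
#'   `msre_pass`, `msre_fail_reasons` and `quality_level` columns (filled
#'   with uniform defaults when absent, so MSRE and genomic mode share one
#'   schema).
#' @param assembly Assembly label for the hyperlinks.
#' @return Data.frame in [summary_columns()] order.
#' @export
build_summary <- function(annotated, assembly = "hg19") {
  a <- annotated
  n <- nrow(a)
  if (!"msre_pass" %in% names(a)) a$msre_pass <- rep(NA, n)
  if (!"msre_fail_reasons" %in% names(a)) a$msre_fail_reasons <- rep("", n)
  if (!"quality_level" %in% names(a)) a$quality_level <- rep(NA_integer_, n)
  rows <- data.frame(
    target_id = a$target_id, pair_id = a$pair_id,
    fwd_seq = a$fwd_seq, rev_seq = a$rev_seq, oligo_seq = a$oligo_seq,
    fwd_tm = round(a$fwd_tm, 2), rev_tm = round(a$rev_tm, 2),
    fwd_gc = round(a$fwd_gc, 2), rev_gc = round(a$rev_gc, 2),
    fwd_penalty = round(a$fwd_penalty, 4), rev_penalty = round(a$rev_penalty, 4),
    pair_penalty = round(a$pair_penalty, 4),
    chrom = a$chrom,
    amplicon_coord = sprintf("%s:%d-%d", a$chrom, a$g_amp_start, a$g_amp_end),
    amplicon_start = a$g_amp_start, amplicon_end = a$g_amp_end,
    product_size = a$product_size,
    n_cutsites_fwd = a$n_cutsites_fwd, n_cutsites_rev = a$n_cutsites_rev,
    n_cutsites_oligo = a$n_cutsites_oligo,
    n_cutsites_amplicon = a$n_cutsites_amplicon,
    n_snps_fwd = a$n_snps_fwd, n_snps_rev = a$n_snps_rev,
    n_snps_oligo = a$n_snps_oligo, n_snps_amplicon = a$n_snps_amplicon,
    n_cpg_islands = a$n_cpg_islands, n_repeats = a$n_repeats,
    repeat_in_primer = a$repeat_in_primer,
    upstream_gene = a$upstream_gene,
    upstream_gene_strand = a$upstream_gene_strand,
    dist_upstream = a$dist_upstream,
    downstream_gene = a$downstream_gene,
    downstream_gene_strand = a$downstream_gene_strand,
    dist_downstream = a$dist_downstream,
    target_dist = a$target_dist,
    msre_pass = a$msre_pass, msre_fail_reasons = a$msre_fail_reasons,
    quality_level = a$quality_level,
    browser_url = if (n == 0) character(0) else
      mapply(browser_url, a$chrom, a$g_amp_start, a$g_amp_end,
             MoreArgs = list(assembly = assembly), USE.NAMES = FALSE),
    insilico_url = if (n == 0) character(0) else
      mapply(insilico_pcr_url, a$fwd_seq, a$rev_seq,
             MoreArgs = list(assembly = assembly), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rows[, summary_columns(), drop = FALSE]
}

#' Write the summary table as TSV and HTML
#'
#' The TSV is the canonical machine artifact: frozen column order, UTF-8, one
#' header line, no quoting. The HTML file renders the same rows with the
#' browser and In-Silico-PCR links as hyperlinks. A zero-row table still
#' produces a header-only TSV.
#'
#' @param rows Data.frame from [build_summary()].
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Named character vector with the `tsv` and `html` paths, invisibly.
#' @export
write_summary <- function(rows, out_dir, name = "primer_summary") {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  tsv <- file.path(out_dir, paste0(name, ".tsv"))
  html <- file.path(out_dir, paste0(name, ".html"))
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  writeLines(summary_html(rows), html, useBytes = TRUE)
  invisible(c(tsv = tsv, html = html))
}

# static, script-free HTML rendering of the summary rows
#' @noRd
summary_html <- function(rows) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cols <- summary_columns()
  head_row <- paste0("<tr>", paste0("<th>", esc(cols), "</th>", collapse = ""),
                     "</tr>")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    cells <- vapply(cols, function(cn) {
      v <- rows[[cn]][i]
      txt <- if (is.na(v)) "" else as.character(v)
      if (cn %in% c("browser_url", "insilico_url") && nzchar(txt)) {
        label <- if (cn == "browser_url") "browser" else "in-silico PCR"
        sprintf("<td><a href=\"%s\">%s</a></td>", esc(txt), label)
      } else {
        sprintf("<td>%s</td>", esc(txt))
      }
    }, character(1))
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Primer pair summary</title></head><body>",
    "<table border=\"1\">", head_row, body, "</table></body></html>")
}

#' Write a per-target UCSC custom track in GTF
#'
#' Emits one track header line plus, per pair, three features (amplicon,
#' forward_primer, reverse_primer). GTF coordinates are 1-based inclusive
#' (start = BED start + 1, end = BED end); the score column carries the pair
#' penalty and the attributes carry `target_id` and `pair_id`.
#'
#' @param annotated Annotated pairs of one target (genomic coordinates
#'   present).
#' @param path Output path (conventionally `<target_id>.gtf`).
#' @return `path`, invisibly.
#' @export
write_gtf_track <- function(annotated, path) {
  stopifnot(length(unique(annotated$target_id)) <= 1)
  lines <- character(0)
  tid <- if (nrow(annotated) > 0) annotated$target_id[1] else "empty"
  lines <- c(lines, sprintf(
    "track name=\"msreprimer_%s\" description=\"primer pairs for %s\"",
    tid, tid))
  gtf_line <- function(chrom, start0, end0, feature, score, strand, tid, pid) {
    sprintf("%s\tmsreprimer\t%s\t%d\t%d\t%.4f\t%s\t.\ttarget_id \"%s\"; pair_id \"%s\";",
            chrom, feature, start0 + 1L, end0, score, strand, tid, pid)
  }
  for (i in seq_len(nrow(annotated))) {
    a <- annotated[i, ]
    lines <- c(lines,
               gtf_line(a$chrom, a$g_amp_start, a$g_amp_end, "amplicon",
                        a$pair_penalty, "+", a$target_id, a$pair_id),
               gtf_line(a$chrom, a$g_fwd_start, a$g_fwd_end, "forward_primer",
                        a$fwd_penalty, "+", a$target_id, a$pair_id),
               gtf_line(a$chrom, a$g_rev_start, a$g_rev_end, "reverse_primer",
                        a$rev_penalty, "-", a$target_id, a$pair_id))
  }
  writeLines(lines, path)
  invisible(path)
}
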