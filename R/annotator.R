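# Step 6: lift primer pairs to genomic coordinates and annotate with SNPs,
# CpG islands, repeats and nearest up/downstream genes.

#' Lift a pair's sequence-space intervals to genomic coordinates
#'
#' Genomic position = design-range start + sequence-space position, for the
#' amplicon, both primers and the internal oligo (if present).
#'
#' @param pair One-row pairs data.frame (sequence-space coordinates).
#' @param design_range An `msre_design_range`.
#' @return Named list of genomic intervals (`chrom`, `amp_start`, `amp_end`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `oligo_start`,
#'   `oligo_end`).
#' @export
to_genomic <- function(pair, design_range) {
  off <- design_range$range_start
  list(chrom = design_range$chrom,
       amp_start = off + pair$amplicon_start, amp_end = off + pair$amplicon_end,
       fwd_start = off + pair$fwd_win_start, fwd_end = off + pair$fwd_win_end,
       rev_start = off + pair$rev_win_start, rev_end = off + pair$rev_win_end,
       oligo_start = off + pair$oligo_win_start,
       oligo_end = off + pair$oligo_win_end)
}

# count annotation records overlapping [start, end) on chrom
#' @noRd
count_overlapping <- function(records, chrom, start, end) {
  if (nrow(records) == 0 || is.na(start)) return(0L)
  sum(records$chrom == chrom & overlaps(records$start, records$end, start, end))
}

#' Nearest genes up- and downstream of an amplicon
#'
#' Upstream gene = greatest end at or left of the amplicon start (distance
#' `amplicon_start - gene_end`); downstream gene = least start at or right of
#' the amplicon end (distance `gene_start - amplicon_end`). A gene
#' overlapping the amplicon is reported on both sides with distance 0.
#' Up/downstream are genomic left/right; the gene's own strand is reported
#' alongside.
#'
#' @param chrom,amp_start,amp_end Genomic amplicon interval (0-based
#'   half-open).
#' @param gene_set `msre_annotation` of kind gene.
#' @return List: `upstream_gene`, `upstream_strand`, `dist_upstream`,
#'   `downstream_gene`, `downstream_strand`, `dist_downstream` (NA fields
#'   when no gene qualifies on that side).
#' @export
nearest_genes <- function(chrom, amp_start, amp_end, gene_set) {
  g <- gene_set$records
  g <- g[g$chrom == chrom, , drop = FALSE]
  res <- list(upstream_gene = NA_character_, upstream_strand = NA_character_,
              dist_upstream = NA_integer_,
              downstream_gene = NA_character_, downstream_strand = NA_character_,
              dist_downstream = NA_integer_)
  if (nrow(g) == 0) return(res)
  ov <- overlaps(g$start, g$end, amp_start, amp_end)
  if (any(ov)) {
    # deterministic choice among overlapping genes: leftmost, then name
    sel <- which(ov)[order(g$start[ov], g$name[ov])][1]
    res$upstream_gene <- res$downstream_gene <- g$name[sel]
    res$upstream_strand <- res$downstream_strand <- g$strand[sel]
    res$dist_upstream <- res$dist_downstream <- 0L
    return(res)
  }
  up <- which(g$end <= amp_start)
  if (length(up) > 0) {
    sel <- up[order(-g$end[up], -g$start[up], g$name[up])][1]
    res$upstream_gene <- g$name[sel]
    res$upstream_strand <- g$strand[sel]
    res$dist_upstream <- amp_start - g$end[sel]
  }
  down <- which(g$start >= amp_end)
  if (length(down) > 0) {
    sel <- down[order(g$start[down], g$end[down], g$name[down])][1]
    res$downstream_gene <- g$name[sel]
    res$downstream_strand <- g$strand[sel]
    res$dist_downstream <- g$start[sel] - amp_end
  }
  res
}

#' Annotate primer pairs with genomic features
#'
#' Lifts each pair of one target to genomic coordinates and counts SNPs per
#' primer / oligo / amplicon, CpG islands and repeats over the amplicon,
#' whether any repeat overlaps a primer, nearest genes with distances, cut
#' sites per region, and the signed distance of the original target midpoint
#' from the amplicon (0 when the midpoint lies inside; negative when left of
#' the amplicon).
#'
#' @param pairs Pairs data.frame from [enumerate_pairs()] for one target.
#' @param design_range The target's `msre_design_range`.
#' @param target_sequence The design sequence (for cut-site scanning).
#' @param annotations Named list of `msre_annotation` objects (`snp`,
#'   `cpg_island`, `repeat`, `gene`), ideally pre-subset to the design
#'   ranges.
#' @param enzymes Enzyme catalog rows or `NULL` (genomic-PCR mode: all cut
#'   counts 0).
#' @return Data.frame: the input pairs plus `target_id`, `chrom`, genomic
#'   interval columns and all annotation count columns.
#' @export
annotate_pairs <- function(pairs, design_range, target_sequence, annotations,
                           enzymes = NULL) {
  if (inherits(target_sequence, "msre_target_sequence")) {
    target_sequence <- target_sequence$sequence
  }
  if (nrow(pairs) == 0) return(empty_annotated())
  snp <- annotations$snp$records
  cpg <- annotations$cpg_island$records
  rpt <- annotations$`repeat`$records
  target_mid <- (design_range$target_start + design_range$target_end) %/% 2L
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, , drop = FALSE]
    gi <- to_genomic(pr, design_range)
    cuts <- count_cut_sites(pr, target_sequence, enzymes)
    genes <- nearest_genes(gi$chrom, gi$amp_start, gi$amp_end, annotations$gene)
    rep_amp <- count_overlapping(rpt, gi$chrom, gi$amp_start, gi$amp_end)
    rep_fwd <- count_overlapping(rpt, gi$chrom, gi$fwd_start, gi$fwd_end)
    rep_rev <- count_overlapping(rpt, gi$chrom, gi$rev_start, gi$rev_end)
    target_dist <- if (target_mid >= gi$amp_start && target_mid < gi$amp_end) {
      0L
    } else if (target_mid < gi$amp_start) {
      target_mid - gi$amp_start # negative: midpoint left of amplicon
    } else {
      target_mid - (gi$amp_end - 1L)
    }
    cbind(pr,
          data.frame(
            target_id = design_range$target_id, chrom = gi$chrom,
            g_amp_start = gi$amp_start, g_amp_end = gi$amp_end,
            g_fwd_start = gi$fwd_start, g_fwd_end = gi$fwd_end,
            g_rev_start = gi$rev_start, g_rev_end = gi$rev_end,
            n_cutsites_fwd = cuts$n_fwd, n_cutsites_rev = cuts$n_rev,
            n_cutsites_oligo = cuts$n_oligo,
            n_cutsites_amplicon = cuts$n_amplicon,
            n_snps_fwd = count_overlapping(snp, gi$chrom, gi$fwd_start, gi$fwd_end),
            n_snps_rev = count_overlapping(snp, gi$chrom, gi$rev_start, gi$rev_end),
            n_snps_oligo = count_overlapping(snp, gi$chrom, gi$oligo_start,
                                             gi$oligo_end),
            n_snps_amplicon = count_overlapping(snp, gi$chrom, gi$amp_start,
                                                gi$amp_end),
            n_cpg_islands = count_overlapping(cpg, gi$chrom, gi$amp_start,
                                              gi$amp_end),
            n_repeats = rep_amp,
            repeat_in_primer = (rep_fwd + rep_rev) > 0,
            upstream_gene = genes$upstream_gene,
            upstream_gene_strand = genes$upstream_strand,
            dist_upstream = genes$dist_upstream,
            downstream_gene = genes$downstream_gene,
            downstream_gene_strand = genes$downstream_strand,
            dist_downstream = genes$dist_downstream,
            target_dist = target_dist,
            stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
empty_annotated <- function() {
  cbind(empty_pairs(),
        data.frame(target_id = character(), chrom = character(),
                   g_amp_start = integer(), g_amp_end = integer(),
                   g_fwd_start = integer(), g_fwd_end = integer(),
                   g_rev_start = integer(), g_rev_end = integer(),
                   n_cutsites_fwd = integer(), n_cutsites_rev = integer(),
                   n_cutsites_oligo = integer(),
                   n_cutsites_amplicon = integer(),
                   n_snps_fwd = integer(), n_snps_rev = integer(),
                   n_snps_oligo = integer(), n_snps_amplicon = integer(),
                   n_cpg_islands = integer(), n_repeats = integer(),
                   repeat_in_primer = logical(),
                   upstream_gene = character(),
                   upstream_gene_strand = character(),
                   dist_upstream = integer(),
                   downstream_gene = character(),
                   downstream_gene_strand = character(),
                   dist_downstream = integer(),
                   target_dist = integer(), stringsAsFactors = FALSE))
}
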