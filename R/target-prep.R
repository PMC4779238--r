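# Steps 2-3 of the workflow: extend targets by optional flanks, extract the
# design sequence, and subset annotation tracks to the design ranges.

#' Extend a target region by flanking bases
#'
#' The design range is `[max(0, start - flank_up), min(chrom_length,
#' end + flank_down))`; clamping at chromosome bounds is silent.
#'
#' @param target One-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `target_id`.
#' @param flank_up,flank_down Non-negative flank sizes in bp.
#' @param chrom_length Chromosome length for clamping.
#' @return A list of class `msre_design_range` with the target fields plus
#'   `range_start`, `range_end`, `target_offset`.
#' @export
extend_region <- function(target, flank_up = 0L, flank_down = 0L, chrom_length) {
  if (flank_up < 0 || flank_down < 0) stop("flanks must be >= 0", call. = FALSE)
  range_start <- max(0L, target$start - as.integer(flank_up))
  range_end <- min(as.integer(chrom_length), target$end + as.integer(flank_down))
  structure(list(chrom = target$chrom, target_id = target$target_id,
                 target_start = target$start, target_end = target$end,
                 range_start = range_start, range_end = range_end,
                 target_offset = target$start - range_start),
            class = "msre_design_range")
}

#' Extract the design sequence for a design range
#'
#' @param genome An `msre_genome`.
#' @param design_range An `msre_design_range` from [extend_region()].
#' @return A list of class `msre_target_sequence`: `design_range`,
#'   `sequence` (length `range_end - range_start`) and `target_offset`
#'   (0-based start of the original target within the sequence).
#' @export
extract_sequence <- function(genome, design_range) {
  ch <- design_range$chrom
  if (!ch %in% names(genome$sequences)) {
    stop("chromosome not in genome: ", ch, call. = FALSE)
  }
  seq <- substr0(genome$sequences[[ch]], design_range$range_start,
                 design_range$range_end)
  structure(list(design_range = design_range, sequence = seq,
                 target_offset = design_range$target_offset),
            class = "msre_target_sequence")
}

#' Subset an annotation set to records overlapping design ranges
#'
#' Keeps exactly the records that overlap at least one design range by at
#' least 1 bp (half-open overlap: `max(starts) < min(ends)`). Idempotent.
#'
#' @param annotation_set An `msre_annotation`.
#' @param design_ranges A list of `msre_design_range` objects (or a single
#'   one).
#' @return An `msre_annotation` with the overlapping records, original sort
#'   order preserved.
#' @export
subset_annotations <- function(annotation_set, design_ranges) {
  if (inherits(design_ranges, "msre_design_range")) {
    design_ranges <- list(design_ranges)
  }
  rec <- annotation_set$records
  if (nrow(rec) == 0 || length(design_ranges) == 0) {
    return(new_annotation(annotation_set$kind, rec[integer(0), , drop = FALSE]))
  }
  keep <- rep(FALSE, nrow(rec))
  for (dr in design_ranges) {
    keep <- keep | (rec$chrom == dr$chrom &
                      overlaps(rec$start, rec$end, dr$range_start, dr$range_end))
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_annotation(annotation_set$kind, out)
}
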