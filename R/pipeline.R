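# End-to-end orchestration of the seven-step workflow: read inputs, extend
# and extract targets, design candidate pairs, predict cut sites, annotate,
# select, and write all report outputs. Targets are processed independently
# (optionally in parallel); results are assembled in input target order, so
# output bytes do not depend on the worker count.

#' Build and validate a run configuration
#'
#' @param genome Path to the reference FASTA.
#' @param targets Path to the BED4 target file.
#' @param snp,cpg,repeats,genes Paths to the four annotation BED tracks.
#' @param params Optional path to a Primer3 parameter file (Boulder-IO);
#'   defaults apply when `NULL`.
#' @param enzymes Optional path to the enzyme list (one name per line);
#'   required in `"msre"` mode.
#' @param quality_matrix Optional path to the quality-matrix TSV.
#' @param mode `"msre"` or `"genomic"`.
#' @param flank_up,flank_down Flank sizes in bp.
#' @param n_return Pairs to report per target (overrides the parameter file
#'   when not `NULL`).
#' @param proximity_bp Target proximity window for the MSRE filter.
#' @param quality_mode Quality-level semantics, `"cumulative"` or
#'   `"independent"`.
#' @param msre_filter Apply the MSRE validation filter columns (default: only
#'   in msre mode).
#' @param workers Number of parallel workers for per-target design.
#' @param out_dir Output directory.
#' @param assembly Assembly label used in hyperlinks.
#' @param fail_fast Abort the run on the first per-target error instead of
#'   logging and continuing.
#' @return List of class `msre_run_config`.
#' @export
run_config <- function(genome, targets, snp, cpg, repeats, genes,
                       params = NULL, enzymes = NULL, quality_matrix = NULL,
                       mode = c("msre", "genomic"),
                       flank_up = 0L, flank_down = 0L, n_return = NULL,
                       proximity_bp = 50L,
                       quality_mode = c("cumulative", "independent"),
                       msre_filter = NULL, workers = 1L, out_dir,
                       assembly = "hg19", fail_fast = FALSE) {
  mode <- match.arg(mode)
  quality_mode <- match.arg(quality_mode)
  if (mode == "msre" && is.null(enzymes)) {
    stop("msre mode requires an enzyme list file", call. = FALSE)
  }
  paths <- c(genome = genome, targets = targets, snp = snp, cpg = cpg,
             repeats = repeats, genes = genes)
  opt <- c(params = params, enzymes = enzymes, quality_matrix = quality_matrix)
  missing <- c(paths, opt)[!file.exists(c(paths, opt))]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(genome = genome, targets = targets, snp = snp, cpg = cpg,
                 repeats = repeats, genes = genes, params = params,
                 enzymes = enzymes, quality_matrix = quality_matrix,
                 mode = mode, flank_up = as.integer(flank_up),
                 flank_down = as.integer(flank_down), n_return = n_return,
                 proximity_bp = as.integer(proximity_bp),
                 quality_mode = quality_mode,
                 msre_filter = if (is.null(msre_filter)) mode == "msre"
                               else isTRUE(msre_filter),
                 workers = as.integer(workers), out_dir = out_dir,
                 assembly = assembly, fail_fast = isTRUE(fail_fast)),
            class = "msre_run_config")
}

# steps 2-6 for one target; pure function of its inputs
#' @noRd
design_one_target <- function(target, genome, annotations, params, enzymes,
                              flank_up, flank_down, n_return) {
  dr <- extend_region(target, flank_up, flank_down,
                      genome$lengths[[target$chrom]])
  ts <- extract_sequence(genome, dr)
  cand <- candidate_primers(ts$sequence, params)
  pairs <- enumerate_pairs(cand, params, n_return = n_return,
                           target_sequence = ts$sequence)
  annotate_pairs(pairs, dr, ts$sequence, annotations, enzymes)
}

#' Run the primer design pipeline
#'
#' Executes the per-target workflow for every target, assigns quality levels,
#' applies the MSRE validation filter (msre mode), and writes the summary
#' TSV/HTML, one GTF custom track per target, and a run log under
#' `config$out_dir`. A per-target hard error aborts that target with a logged
#' reason; the run continues (unless `fail_fast`) and the failure is reported
#' in the returned object.
#'
#' @param config An [run_config()].
#' @return Invisibly, a list: `summary` (selected rows, as written),
#'   `all_pairs` (every designed pair incl. unselected), `failures`
#'   (data.frame target_id/error), `paths` (output files), `log` (character).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "msre_run_config"))
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  say("[load] reading genome %s", config$genome)
  genome <- read_fasta(config$genome)
  targets <- read_target_bed(config$targets, genome)
  annotations <- list(
    snp = read_annotation_bed(config$snp, "snp"),
    cpg_island = read_annotation_bed(config$cpg, "cpg_island"),
    "repeat" = read_annotation_bed(config$repeats, "repeat"),
    gene = read_annotation_bed(config$genes, "gene"))
  params <- if (is.null(config$params)) design_parameters()
            else parse_parameter_file(config$params)
  n_return <- if (is.null(config$n_return)) params$n_return
              else as.integer(config$n_return)
  enzymes <- if (config$mode == "msre") parse_enzyme_list(config$enzymes)
             else NULL
  rules <- if (!is.null(config$quality_matrix))
    parse_quality_matrix(config$quality_matrix) else NULL
  say("[load] %d targets, %d SNPs, %d islands, %d repeats, %d genes%s",
      nrow(targets), nrow(annotations$snp$records),
      nrow(annotations$cpg_island$records),
      nrow(annotations$`repeat`$records), nrow(annotations$gene$records),
      if (is.null(enzymes)) "" else
        sprintf(", %d enzymes", nrow(enzymes)))

  # subset annotation tracks to the union of design ranges once, for speed
  ranges <- lapply(seq_len(nrow(targets)), function(i)
    extend_region(targets[i, ], config$flank_up, config$flank_down,
                  genome$lengths[[targets$chrom[i]]]))
  annotations <- lapply(annotations, subset_annotations, design_ranges = ranges)

  worker <- function(i) {
    target <- targets[i, ]
    tryCatch({
      t1 <- Sys.time()
      res <- design_one_target(target, genome, annotations, params, enzymes,
                               config$flank_up, config$flank_down, n_return)
      list(ok = TRUE, target_id = target$target_id, result = res,
           seconds = as.numeric(difftime(Sys.time(), t1, units = "secs")))
    }, error = function(e) {
      list(ok = FALSE, target_id = target$target_id,
           error = conditionMessage(e))
    })
  }
  idx <- seq_len(nrow(targets))
  results <- if (config$workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, worker, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, worker)
  }

  failures <- data.frame(target_id = character(), error = character(),
                         stringsAsFactors = FALSE)
  annotated <- list()
  for (r in results) {
    if (isTRUE(r$ok)) {
      say("[design] %s: %d pair(s) in %.2fs", r$target_id, nrow(r$result),
          r$seconds)
      annotated[[length(annotated) + 1L]] <- r$result
    } else {
      say("[design] %s: FAILED (%s)", r$target_id, r$error)
      failures <- rbind(failures, data.frame(target_id = r$target_id,
                                             error = r$error,
                                             stringsAsFactors = FALSE))
      if (config$fail_fast) {
        stop("target ", r$target_id, " failed: ", r$error, call. = FALSE)
      }
    }
  }
  all_pairs <- if (length(annotated) > 0) do.call(rbind, annotated)
               else empty_annotated()

  # MSRE validation filter columns (uniform schema: NA in genomic mode)
  if (config$msre_filter && nrow(all_pairs) > 0) {
    flt <- msre_validation_filter(all_pairs, config$proximity_bp)
    all_pairs$msre_pass <- flt$pass
    all_pairs$msre_fail_reasons <- flt$reasons
  }
  sel <- assign_quality_levels(all_pairs, rules, mode = config$quality_mode)
  all_pairs$quality_level <- sel$levels
  say("[select] %d/%d pair(s) selected by quality matrix",
      sum(sel$selected), nrow(all_pairs))

  chosen <- all_pairs[sel$selected, , drop = FALSE]
  # final ordering: input target order, then penalty within target
  chosen <- chosen[order(match(chosen$target_id, targets$target_id),
                         chosen$pair_penalty, chosen$pair_id), , drop = FALSE]
  rows <- build_summary(chosen, assembly = config$assembly)
  paths <- write_summary(rows, config$out_dir)
  gtf_dir <- file.path(config$out_dir, "tracks")
  dir.create(gtf_dir, recursive = TRUE, showWarnings = FALSE)
  for (tid in unique(chosen$target_id)) {
    p <- file.path(gtf_dir, paste0(tid, ".gtf"))
    write_gtf_track(chosen[chosen$target_id == tid, , drop = FALSE], p)
    paths <- c(paths, stats::setNames(p, paste0("gtf_", tid)))
  }
  say("[done] %d summary row(s), %d failed target(s), %.2fs total",
      nrow(rows), nrow(failures),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  log_path <- file.path(config$out_dir, "run.log")
  writeLines(log, log_path)
  paths <- c(paths, log = log_path)
  invisible(list(summary = rows, all_pairs = all_pairs, failures = failures,
                 paths = paths, log = log))
}
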