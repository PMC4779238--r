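# Reading/writing the standard input formats: FASTA reference, BED4 targets,
# BED-like annotation tracks.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the {A,C,G,T,N} alphabet.
#' Record order is preserved.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return An object of class `msre_genome`: a list with `sequences` (named
#'   character vector) and `lengths` (named integer vector).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  check_dna(seqs, allow = c("A", "C", "G", "T", "N"), what = "reference sequence")
  new_genome(seqs)
}

#' @noRd
new_genome <- function(seqs) {
  structure(list(sequences = seqs,
                 lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "msre_genome")
}

#' @export
print.msre_genome <- function(x, ...) {
  cat(sprintf("msre_genome: %d chromosome(s), %s bp total\n",
              length(x$sequences), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome An `msre_genome`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$sequences)) {
    writeLines(paste0(">", nm), con)
    s <- genome$sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read target regions from a 4-column BED file
#'
#' Each non-comment line must have four tab-delimited columns: chromosome,
#' start, end (0-based half-open) and a unique target ID. Regions are
#' validated against the genome bounds; input order is preserved.
#'
#' @param path Path to the BED4 file. Lines starting with `#` are ignored.
#' @param genome An `msre_genome` used for bounds checking.
#' @return A data.frame with columns `chrom`, `start`, `end`, `target_id`.
#' @export
read_target_bed <- function(path, genome) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no target records in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    lineno <- keep[i]
    if (length(f) < 4) {
      stop(sprintf("line %d: expected 4 tab-delimited columns, got %d",
                   lineno, length(f)), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-numeric coordinates", lineno), call. = FALSE)
    }
    if (start >= end) {
      stop(sprintf("line %d: start (%d) must be < end (%d)", lineno, start, end),
           call. = FALSE)
    }
    if (!f[1] %in% names(genome$lengths)) {
      stop(sprintf("line %d: unknown chromosome '%s'", lineno, f[1]),
           call. = FALSE)
    }
    if (start < 0 || end > genome$lengths[[f[1]]]) {
      stop(sprintf("line %d: region [%d,%d) outside chromosome '%s' (length %d)",
                   lineno, start, end, f[1], genome$lengths[[f[1]]]),
           call. = FALSE)
    }
    data.frame(chrom = f[1], start = start, end = end, target_id = f[4],
               stringsAsFactors = FALSE)
  })
  targets <- do.call(rbind, out)
  dup <- targets$target_id[duplicated(targets$target_id)]
  if (length(dup) > 0) {
    stop("duplicate target ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  targets
}

#' Read a BED-like annotation track
#'
#' Accepts BED3+ files; column 4 (name) is optional except for informative
#' tracks, and gene tracks must carry a strand column (BED6). Records are
#' returned sorted by (chrom, start).
#'
#' @param path Path to the BED file.
#' @param kind One of `"snp"`, `"cpg_island"`, `"repeat"`, `"gene"`.
#' @return An `msre_annotation`: list with `kind` and `records` (data.frame
#'   `chrom`, `start`, `end`, `name`, `strand`).
#' @export
read_annotation_bed <- function(path, kind = c("snp", "cpg_island", "repeat", "gene")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) return(new_annotation(kind, empty_records()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop(sprintf("line %d: annotation BED needs >= 3 columns",
                 keep[which(ncols < 3)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.integer(vapply(fields, `[`, character(1), 2))
  end <- as.integer(vapply(fields, `[`, character(1), 3))
  if (anyNA(start) || anyNA(end) || any(start >= end)) {
    stop("malformed coordinates in ", path, call. = FALSE)
  }
  name <- ifelse(ncols >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                    character(1)),
                 paste0(kind, "_", seq_along(fields)))
  strand <- rep(NA_character_, length(fields))
  if (kind == "gene") {
    if (any(ncols < 6)) {
      stop("gene annotation requires a strand column (BED6)", call. = FALSE)
    }
    strand <- vapply(fields, `[`, character(1), 6)
    bad <- !strand %in% c("+", "-")
    if (any(bad)) {
      stop(sprintf("line %d: malformed strand '%s' for gene record",
                   keep[which(bad)[1]], strand[which(bad)[1]]), call. = FALSE)
    }
  }
  rec <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    strand = strand, stringsAsFactors = FALSE)
  rec <- rec[order(rec$chrom, rec$start, rec$end, rec$name), , drop = FALSE]
  rownames(rec) <- NULL
  new_annotation(kind, rec)
}

#' @noRd
empty_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(), stringsAsFactors = FALSE)
}

#' @noRd
new_annotation <- function(kind, records) {
  structure(list(kind = kind, records = records), class = "msre_annotation")
}

#' @export
print.msre_annotation <- function(x, ...) {
  cat(sprintf("msre_annotation (%s): %d record(s)\n", x$kind, nrow(x$records)))
  invisible(x)
}

#' Write annotation records (or a target table) as BED
#'
#' @param x An `msre_annotation` or a data.frame with chrom/start/end plus a
#'   name-like fourth column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rec <- if (inherits(x, "msre_annotation")) x$records else x
  cols <- c("chrom", "start", "end")
  extra <- intersect(c("name", "target_id"), names(rec))
  if (length(extra) > 0) cols <- c(cols, extra[1])
  out <- rec[, cols, drop = FALSE]
  if ("strand" %in% names(rec) && any(!is.na(rec$strand))) {
    out$score <- 0L
    out$strand <- rec$strand
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
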