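# Low-level DNA string helpers shared across the package.
# All coordinates in this package are 0-based half-open (BED convention);
# conversion to 1-based happens only when emitting GTF/UCSC text.

# IUPAC degenerate code -> base membership sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# symbolic complement of IUPAC codes (complement of the membership set)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", M = "K", K = "M", S = "S", W = "W",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of DNA sequences
#'
#' Works on plain character vectors. IUPAC degenerate codes are complemented
#' symbolically (e.g. M = A/C maps to K = G/T), so degenerate restriction
#' motifs reverse-complement correctly.
#'
#' @param x Character vector of DNA sequences (IUPAC alphabet, upper case).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement(c("ACGT", "GTMKAC"))
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYMKSWBDHVN", "TGCAYRKMSWVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @noRd
check_dna <- function(x, allow = c("A", "C", "G", "T"), what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(allow, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("invalid %s: characters outside {%s} in %s",
                 what, paste(allow, collapse = ","),
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' @noRd
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0, NA_real_, 100 * gc / n)
}

#' @noRd
max_mono_run <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    if (length(ch) == 0) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# substring by 0-based half-open coordinates
#' @noRd
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# random DNA string, base frequencies in A,C,G,T order
#' @noRd
random_dna <- function(n, freq = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq),
        collapse = "")
}

# half-open interval overlap test, vectorized
#' @noRd
overlaps <- function(start1, end1, start2, end2) {
  pmax(start1, start2) < pmin(end1, end2)
}

# run code with a private RNG stream, restoring the caller's .Random.seed
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
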