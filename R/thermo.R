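# Nearest-neighbor duplex thermodynamics for primer melting temperature.
#
# Parameter set: unified NN table of Allawi & SantaLucia (1997) /
# SantaLucia (1998), with duplex initiation terms per terminal base pair.
# Salt correction: entropic, dS + 0.368 * (N-1) * ln[Na+] (SantaLucia 1998);
# divalent cations are folded into an equivalent monovalent concentration as
# Na_eq = Na + 120 * sqrt(max(0, [Mg2+] - [dNTP])) (all mM; von Ahsen 2001,
# as used by Primer3). Effective annealing concentration is CT/4 for
# non-self-complementary duplexes.

# dH in kcal/mol, dS in cal/(mol K); names are plus-strand dinucleotides
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation with terminal G.C / A.T pair
INIT_GC <- c(dh = 0.1, ds = -2.8)
INIT_AT <- c(dh = 2.3, ds = 4.1)
GAS_CONSTANT <- 1.987 # cal/(mol K)

#' @noRd
monovalent_equivalent_mM <- function(mono_mM, divalent_mM, dntp_mM) {
  mono_mM + 120 * sqrt(max(0, divalent_mM - dntp_mM))
}

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature of each primer sequence with the
#' unified nearest-neighbor parameter set (Allawi & SantaLucia 1997;
#' SantaLucia 1998) and an entropic salt correction. Divalent cations are
#' converted to an equivalent monovalent concentration. The effective
#' annealing concentration is one quarter of the oligo concentration
#' (non-self-complementary assumption, as in Primer3).
#'
#' @param sequence Character vector of DNA sequences over A/C/G/T, each of
#'   length >= 2. Sequences containing N (or any other letter) are an error.
#' @param mono_mM Monovalent cation concentration (mM).
#' @param divalent_mM Divalent cation concentration (mM).
#' @param dntp_mM dNTP concentration (mM).
#' @param oligo_nM Oligo concentration (nM).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT", mono_mM = 50, oligo_nM = 250)
melting_temperature <- function(sequence, mono_mM = 50, divalent_mM = 0,
                                dntp_mM = 0, oligo_nM = 50) {
  sequence <- toupper(sequence)
  check_dna(sequence, what = "primer sequence (Tm)")
  if (any(nchar(sequence) < 2)) stop("Tm needs length >= 2", call. = FALSE)
  na_eq <- monovalent_equivalent_mM(mono_mM, divalent_mM, dntp_mM)
  ct <- oligo_nM * 1e-9 / 4
  vapply(sequence, function(s) {
    n <- nchar(s)
    dinucs <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(NN_DH[dinucs])
    ds <- sum(NN_DS[dinucs])
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      init <- if (term %in% c("G", "C")) INIT_GC else INIT_AT
      dh <- dh + init[["dh"]]
      ds <- ds + init[["ds"]]
    }
    ds <- ds + 0.368 * (n - 1) * log(na_eq / 1000)
    dh * 1000 / (ds + GAS_CONSTANT * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Window-sum machinery for scanning all candidate windows of a design
# sequence: precompute per-position NN increments once, then read window
# thermodynamics off cumulative sums. Must agree exactly with
# melting_temperature() on every window (regression-tested).
#' @noRd
thermo_profile <- function(sequence) {
  n <- nchar(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (n < 2) {
    return(list(n = n, bases = bases, cum_dh = 0, cum_ds = 0,
                cum_gc = cumsum(c(0, bases %in% c("G", "C"))),
                cum_n = cumsum(c(0, bases == "N"))))
  }
  dinucs <- paste0(bases[-n], bases[-1])
  dh <- unname(NN_DH[dinucs])
  ds <- unname(NN_DS[dinucs])
  dh[is.na(dh)] <- 0 # windows containing N are discarded by the N mask
  ds[is.na(ds)] <- 0
  list(n = n, bases = bases,
       cum_dh = c(0, cumsum(dh)), cum_ds = c(0, cumsum(ds)),
       cum_gc = cumsum(c(0, bases %in% c("G", "C"))),
       cum_n = cumsum(c(0, bases == "N")))
}

# Tm and GC% for all windows [start, start+len) (0-based starts)
#' @noRd
window_thermo <- function(profile, starts, len, mono_mM, divalent_mM, dntp_mM,
                          oligo_nM) {
  na_eq <- monovalent_equivalent_mM(mono_mM, divalent_mM, dntp_mM)
  ct <- oligo_nM * 1e-9 / 4
  dh <- profile$cum_dh[starts + len] - profile$cum_dh[starts + 1]
  ds <- profile$cum_ds[starts + len] - profile$cum_ds[starts + 1]
  first <- profile$bases[starts + 1]
  last <- profile$bases[starts + len]
  for (term in list(first, last)) {
    gc_term <- term %in% c("G", "C")
    dh <- dh + ifelse(gc_term, INIT_GC[["dh"]], INIT_AT[["dh"]])
    ds <- ds + ifelse(gc_term, INIT_GC[["ds"]], INIT_AT[["ds"]])
  }
  ds <- ds + 0.368 * (len - 1) * log(na_eq / 1000)
  tm <- dh * 1000 / (ds + GAS_CONSTANT * log(ct)) - 273.15
  gc <- 100 * (profile$cum_gc[starts + len + 1] - profile$cum_gc[starts + 1]) / len
  has_n <- (profile$cum_n[starts + len + 1] - profile$cum_n[starts + 1]) > 0
  list(tm = tm, gc = gc, has_n = has_n)
}
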