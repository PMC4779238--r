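# qPCR assay qualification: calibration-curve fitting from a dilution
# series, efficiency from the slope, theoretical 1 ng detection from the
# intercept, R-squared, and MIQE-style pass/fail criteria, plus a dilution
# series simulator for testing and power analysis.

#' Fit a qPCR calibration curve
#'
#' Ordinary least squares of Cq on log10(input amount in ng). The derived
#' efficiency is `(10^(-1/slope) - 1) * 100` and the theoretical 1 ng
#' detection is the intercept (Cq at log10(ng) = 0).
#'
#' @param input_ng Numeric vector of template amounts per reaction (ng, > 0),
#'   or a data.frame with columns `input_ng` and `cq`.
#' @param cq Numeric vector of quantification cycles (ignored when
#'   `input_ng` is a data.frame).
#' @return List of class `msre_calibration`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`, `theoretical_1ng_ct`, `n`.
#' @export
#' @examples
#' amounts <- c(10, 2.5, 0.625, 0.156)
#' fit_calibration(amounts, 30 - log2(amounts))
fit_calibration <- function(input_ng, cq = NULL) {
  if (is.data.frame(input_ng)) {
    cq <- input_ng$cq
    input_ng <- input_ng$input_ng
  }
  if (length(input_ng) != length(cq)) {
    stop("input_ng and cq must have equal length", call. = FALSE)
  }
  if (any(input_ng <= 0)) stop("input amounts must be > 0", call. = FALSE)
  x <- log10(input_ng)
  if (length(unique(x)) < 2) {
    stop("need >= 2 points with distinct input amounts", call. = FALSE)
  }
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency_percent = efficiency_from_slope(slope),
                 theoretical_1ng_ct = intercept, n = length(cq)),
            class = "msre_calibration")
}

#' @export
print.msre_calibration <- function(x, ...) {
  cat(sprintf(paste0("qPCR calibration (n=%d): slope %.4f, intercept %.2f, ",
                     "R^2 %.4f, efficiency %.2f%%, theoretical 1 ng Cq %.2f\n"),
              x$n, x$slope, x$intercept, x$r_squared, x$efficiency_percent,
              x$theoretical_1ng_ct))
  invisible(x)
}

#' qPCR efficiency from a calibration slope
#'
#' `E = (10^(-1/slope) - 1) * 100`; a slope of `-1/log10(2) ~= -3.32`
#' corresponds to 100 % efficiency (perfect doubling per cycle).
#'
#' @param slope Calibration slope (Cq per log10 ng); must be negative.
#' @return Efficiency in percent.
#' @export
#' @examples
#' efficiency_from_slope(-3.32)
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) {
    stop("non-amplifying fit: slope must be < 0", call. = FALSE)
  }
  (10^(-1 / slope) - 1) * 100
}

#' Calibration slope implied by a qPCR efficiency
#'
#' Algebraic inverse of [efficiency_from_slope()].
#'
#' @param efficiency_percent Efficiency in percent (> 0).
#' @return Slope (Cq per log10 ng).
#' @export
slope_from_efficiency <- function(efficiency_percent) {
  if (any(efficiency_percent <= 0)) stop("efficiency must be > 0", call. = FALSE)
  -1 / log10(1 + efficiency_percent / 100)
}

#' Theoretical 1 ng detection
#'
#' The expected Cq when 1 ng of template is applied: the calibration line's
#' y-intercept (log10(1) = 0).
#'
#' @param fit An `msre_calibration`.
#' @return Cq value.
#' @export
theoretical_1ng <- function(fit) {
  stopifnot(inherits(fit, "msre_calibration"))
  fit$intercept
}

#' Assay qualification criteria
#'
#' Default thresholds (efficiency 90-110 %, R^2 >= 0.99) follow common MIQE
#' practice; they are an explicit, overridable configuration, not values
#' fixed by any single study.
#'
#' @param efficiency_range Length-2 numeric, allowed efficiency in percent.
#' @param min_r_squared Minimum R^2.
#' @param max_ct_1ng Optional upper bound on the theoretical 1 ng Cq.
#' @return List of class `msre_qualification_criteria`.
#' @export
qualification_criteria <- function(efficiency_range = c(90, 110),
                                   min_r_squared = 0.99,
                                   max_ct_1ng = NULL) {
  if (efficiency_range[1] >= efficiency_range[2]) {
    stop("efficiency_range must be (lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(efficiency_range = efficiency_range,
                 min_r_squared = min_r_squared, max_ct_1ng = max_ct_1ng),
            class = "msre_qualification_criteria")
}

#' Qualify an assay from its calibration fit
#'
#' @param fit An `msre_calibration`.
#' @param criteria An [qualification_criteria()] object.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated criteria: `"efficiency"`, `"r_squared"`, `"ct_1ng"`).
#' @export
qualify_assay <- function(fit, criteria = qualification_criteria()) {
  reasons <- character(0)
  if (fit$efficiency_percent < criteria$efficiency_range[1] ||
      fit$efficiency_percent > criteria$efficiency_range[2]) {
    reasons <- c(reasons, "efficiency")
  }
  if (fit$r_squared < criteria$min_r_squared) reasons <- c(reasons, "r_squared")
  if (!is.null(criteria$max_ct_1ng) &&
      fit$theoretical_1ng_ct > criteria$max_ct_1ng) {
    reasons <- c(reasons, "ct_1ng")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Simulate a qPCR dilution series
#'
#' Generates `cq = ct_1ng - log10(amount) / log10(1 + efficiency/100) +
#' Normal(0, cq_noise_sd)`, deterministically for a given seed.
#'
#' @param efficiency_percent Generating efficiency (> 0).
#' @param ct_1ng Cq at 1 ng input.
#' @param amounts Template amounts (ng); defaults to the 4-point
#'   dilution-factor-4 series 10, 2.5, 0.625, 0.156 ng.
#' @param cq_noise_sd Gaussian Cq noise standard deviation.
#' @param seed Optional integer seed (local RNG stream; the caller's RNG
#'   state is untouched).
#' @return Data.frame with `input_ng` and `cq`.
#' @export
simulate_dilution_series <- function(efficiency_percent, ct_1ng,
                                     amounts = c(10, 2.5, 0.625, 0.156),
                                     cq_noise_sd = 0, seed = NULL) {
  if (efficiency_percent <= 0) stop("efficiency must be > 0", call. = FALSE)
  if (any(amounts <= 0)) stop("amounts must be > 0", call. = FALSE)
  gen <- function() {
    noise <- if (cq_noise_sd > 0) {
      stats::rnorm(length(amounts), 0, cq_noise_sd)
    } else {
      rep(0, length(amounts))
    }
    data.frame(input_ng = amounts,
               cq = ct_1ng - log10(amounts) / log10(1 + efficiency_percent / 100) +
                 noise)
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Evaluate a batch of assays from long-format Cq data
#'
#' @param data Data.frame with columns `assay_id`, `input_ng`, `cq` (the CSV
#'   interchange format).
#' @param criteria [qualification_criteria()] for pass/fail.
#' @return Data.frame, one row per assay: slope, intercept, R^2, efficiency,
#'   theoretical 1 ng Cq, `qualified`, `reasons`.
#' @export
evaluate_assays <- function(data, criteria = qualification_criteria()) {
  stopifnot(all(c("assay_id", "input_ng", "cq") %in% names(data)))
  out <- lapply(split(data, data$assay_id), function(d) {
    fit <- fit_calibration(d$input_ng, d$cq)
    q <- qualify_assay(fit, criteria)
    data.frame(assay_id = d$assay_id[1], slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$r_squared,
               efficiency_percent = fit$efficiency_percent,
               theoretical_1ng_ct = fit$theoretical_1ng_ct,
               qualified = q$pass,
               reasons = paste(q$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
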