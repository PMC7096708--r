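# Linear standard curves within an assay-specific linear range.
#
# Each assay calibrates signal against product concentration only up to a
# ceiling below which the response is linear (50 uM for free 4MU, 0.5 % w/v
# for scattering, 250 uM for the ferricyanide read, 30 uM for the coupled
# oxidase assay); standards above the ceiling are excluded from the fit.

#' Default linear-range ceilings per assay
#'
#' @return Named list of `linear_max` values (in the assay's product unit):
#'   `four_mu` 50 uM, `clearance` 0.5 % w/v, `ferricyanide` 250 uM,
#'   `chito` 30 uM.
#' @export
default_linear_max <- function() {
  list(four_mu = 50, clearance = 0.5, ferricyanide = 250, chito = 30)
}

#' Fit a linear standard curve within the linear range
#'
#' Ordinary least squares of signal on concentration, restricted to
#' standards with `concentration <= linear_max` (boundary inclusive).
#'
#' @param points Data frame with columns `concentration` and `signal`.
#' @param linear_max Concentration ceiling of the linear range; points above
#'   it are excluded from the fit (default `Inf`, all points retained).
#' @param conc_unit Concentration unit label carried on the curve.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `linear_max`, `n_used`, `n_excluded`,
#'   `conc_unit`.
#' @export
fit_standard_curve <- function(points, linear_max = Inf,
                               conc_unit = c("uM", "mM", "percent_wv")) {
  conc_unit <- match.arg(conc_unit)
  stopifnot(is.data.frame(points),
            all(c("concentration", "signal") %in% names(points)))
  if (!is.numeric(linear_max) || length(linear_max) != 1 ||
      is.na(linear_max) || linear_max <= 0) {
    stop("`linear_max` must be a single positive value", call. = FALSE)
  }
  conc <- as.numeric(points$concentration)
  sig <- as.numeric(points$signal)
  if (any(!is.finite(conc)) || any(!is.finite(sig))) {
    stop("standards must be finite", call. = FALSE)
  }
  keep <- conc <= linear_max
  if (sum(keep) < 3) {
    stop("need at least 3 standards with concentration <= linear_max (have ",
         sum(keep), ")", call. = FALSE)
  }
  if (stats::var(conc[keep]) == 0) {
    stop("in-range standards have zero concentration variance", call. = FALSE)
  }
  fit <- stats::lm(sig[keep] ~ conc[keep])
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         # suppressed: lm warns on exact (noise-free) calibration data
         r_squared = suppressWarnings(summary(fit)$r.squared),
         linear_max = linear_max,
         n_used = sum(keep),
         n_excluded = sum(!keep),
         conc_unit = conc_unit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> signal = %.6g * conc + %.6g  (R^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear range <= %g %s; %d standards used, %d excluded\n",
              x$linear_max, x$conc_unit, x$n_used, x$n_excluded))
  invisible(x)
}

#' Convert a signal to a concentration via a standard curve
#'
#' @param sc A [fit_standard_curve()] result.
#' @param signal Signal value(s).
#' @return Concentration(s) `(signal - intercept) / slope`, in
#'   `sc$conc_unit`.
#' @export
signal_to_concentration <- function(sc, signal) {
  stopifnot(inherits(sc, "standard_curve"))
  if (sc$slope == 0) stop("standard curve slope is zero", call. = FALSE)
  (signal - sc$intercept) / sc$slope
}

#' Convert a signal rate to a concentration rate
#'
#' The intercept cancels when differentiating with respect to time, so only
#' the slope is used: `rate / slope`.
#'
#' @param sc A [fit_standard_curve()] result.
#' @param rate Rate(s) in signal units per second.
#' @return Rate(s) in `sc$conc_unit` per second.
#' @export
rate_to_concentration <- function(sc, rate) {
  stopifnot(inherits(sc, "standard_curve"))
  if (sc$slope == 0) stop("standard curve slope is zero", call. = FALSE)
  rate / sc$slope
}
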