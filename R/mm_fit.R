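# Michaelis-Menten estimation across a substrate concentration series.
#
# Initial rates v(S) from the progress-curve stage are fit by nonlinear
# least squares to v = Vmax * S / (Km + S). kcat = Vmax / [E] (with the
# enzyme concentration expressed in the same unit as the rate), and the
# catalytic efficiency kcat/Km carries a delta-method SD that accounts for
# the (Vmax, Km) covariance of the fit:
#
#   Var(r)/r^2 = Var(Vmax)/Vmax^2 + Var(Km)/Km^2 - 2 Cov(Vmax,Km)/(Vmax Km)

#' Rate-versus-concentration series
#'
#' @param substrate_conc Substrate concentrations (>= 0).
#' @param rate Initial rates, concentration per second. When
#'   `normalized = TRUE` the rates are already divided by the enzyme
#'   concentration (units 1/s) and `Vmax` of the fit is `kcat` directly.
#' @param rate_se Optional per-rate standard errors (carried through for
#'   reporting; the fit itself is unweighted).
#' @param enzyme_conc Enzyme concentration, nM (ignored when
#'   `normalized = TRUE`).
#' @param conc_unit Substrate concentration unit.
#' @param product_unit Unit of the rate's concentration axis (defaults to
#'   `conc_unit`); used to express the enzyme concentration for
#'   kcat = Vmax / [E].
#' @param normalized Rates are per-enzyme turnover rates (1/s).
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(substrate_conc, rate, rate_se = NULL,
                        enzyme_conc = NA_real_,
                        conc_unit = c("uM", "mM", "percent_wv"),
                        product_unit = NULL, normalized = FALSE) {
  conc_unit <- match.arg(conc_unit)
  if (is.null(product_unit)) product_unit <- conc_unit
  product_unit <- match.arg(product_unit, .chitkin_units)
  substrate_conc <- as.numeric(substrate_conc)
  rate <- as.numeric(rate)
  if (length(substrate_conc) != length(rate)) {
    stop("`substrate_conc` and `rate` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(substrate_conc)) || any(substrate_conc < 0)) {
    stop("`substrate_conc` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(rate))) stop("`rate` must be finite", call. = FALSE)
  if (!is.null(rate_se) && length(rate_se) != length(rate)) {
    stop("`rate_se` must match `rate` in length", call. = FALSE)
  }
  structure(
    list(data = tibble::tibble(
           substrate_conc = substrate_conc, rate = rate,
           rate_se = if (is.null(rate_se)) NA_real_ else as.numeric(rate_se)),
         enzyme_conc = enzyme_conc, conc_unit = conc_unit,
         product_unit = product_unit, normalized = normalized),
    class = "rate_series"
  )
}

#' Fit a Michaelis-Menten curve to a rate series
#'
#' Unweighted nonlinear least squares of `v = Vmax * S / (Km + S)` with
#' positivity bounds on both parameters (Levenberg-Marquardt, analytic
#' Jacobian, deterministic multi-start on Km). Requires at least 4 distinct
#' substrate concentrations. When the highest concentration is far below
#' the fitted Km the two parameters are not separately identifiable; the
#' fit is then flagged `"km_unidentifiable"` and only the ratio `Vmax/Km`
#' (the low-substrate slope) should be trusted.
#'
#' @param series A [rate_series()].
#' @return An object of class `mm_fit`: `Vmax`, `Km`, their SEs,
#'   `covariance` (2x2, order Vmax then Km), `kcat` and `kcat_se`
#'   (`Vmax / [E]`), `efficiency` and `efficiency_sd` (kcat/Km with the
#'   delta-method SD), `conc_unit`, `flags`, `n`, fitted values and
#'   residuals.
#' @export
fit_michaelis_menten <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  S <- series$data$substrate_conc
  v <- series$data$rate
  if (length(unique(S)) < 4) {
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  }
  Vmax0 <- max(v) * 1.2
  if (Vmax0 <= 0) Vmax0 <- max(abs(v), 1e-12)
  half_idx <- which.min(abs(v - Vmax0 / 2))
  Km0 <- max(S[half_idx], min(S[S > 0]), 1e-12)

  residual_fn <- function(p) p[1] * S / (p[2] + S) - v
  jac_fn <- function(p) cbind(S / (p[2] + S), -p[1] * S / (p[2] + S)^2)

  best <- NULL
  for (scale in c(0.2, 1, 5)) {
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(Vmax0, Km0 * scale), lower = c(1e-300, 1e-300),
        fn = residual_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = 1e-12, ptol = 1e-10))),
      error = function(e) NULL
    )
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(res = res, sse = sse)
  }
  if (is.null(best)) stop("Michaelis-Menten fit failed", call. = FALSE)
  res <- best$res
  flags <- character(0)
  if (!lm_converged(res)) flags <- c(flags, "nonconvergence")
  Vmax <- res$par[1]
  Km <- res$par[2]
  fitted <- Vmax * S / (Km + S)
  residuals <- v - fitted
  sse <- sum(residuals^2)
  n <- length(v)
  sigma2 <- sse / max(n - 2, 1)
  J <- jac_fn(res$par)
  cv <- ls_covariance(J, sigma2)
  covm <- cv$cov
  if (cv$rank_deficient) flags <- c(flags, "singular_covariance")
  dimnames(covm) <- list(c("Vmax", "Km"), c("Vmax", "Km"))
  if (max(S) < Km / 5) flags <- c(flags, "km_unidentifiable")

  e_scale <- if (series$normalized) 1 else
    enzyme_nM_to_conc(series$enzyme_conc, series$product_unit)
  kcat <- Vmax / e_scale
  se_Vmax <- sqrt(max(covm["Vmax", "Vmax"], 0))
  se_Km <- sqrt(max(covm["Km", "Km"], 0))
  kcat_se <- se_Vmax / e_scale

  fit <- structure(
    list(Vmax = Vmax, Km = Km, se_Vmax = se_Vmax, se_Km = se_Km,
         covariance = covm, kcat = kcat, kcat_se = kcat_se,
         enzyme_conc = series$enzyme_conc, conc_unit = series$conc_unit,
         product_unit = series$product_unit,
         normalized = series$normalized,
         flags = flags, n = n, sse = sse,
         fitted = fitted, residuals = residuals, series = series),
    class = "mm_fit"
  )
  eff <- efficiency_with_sd(fit)
  fit$efficiency <- eff[["efficiency"]]
  fit$efficiency_sd <- eff[["sd"]]
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>\n")
  cat(sprintf("  Vmax = %.6g +/- %.3g %s/s; Km = %.6g +/- %.3g %s\n",
              x$Vmax, x$se_Vmax, x$product_unit, x$Km, x$se_Km,
              x$conc_unit))
  cat(sprintf("  kcat = %.6g +/- %.3g /s; kcat/Km = %.6g +/- %.3g per %s s\n",
              x$kcat, x$kcat_se, x$efficiency, x$efficiency_sd,
              x$conc_unit))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Catalytic efficiency kcat/Km with covariance-propagated SD
#'
#' Delta-method propagation of the (Vmax, Km) fit covariance into the ratio
#' `r = kcat / Km`:
#' `Var(r) = r^2 * (Var(Vmax)/Vmax^2 + Var(Km)/Km^2
#'                  - 2 Cov(Vmax, Km)/(Vmax * Km))`,
#' with `Var(kcat) = Var(Vmax) / [E]^2`. Perfectly correlated equal
#' relative errors cancel exactly (SD = 0).
#'
#' @param fit An [fit_michaelis_menten()] result (or any list with `kcat`,
#'   `Vmax`, `Km`, and a 2x2 `covariance` over (Vmax, Km)).
#' @return Named numeric vector `c(efficiency = , sd = )`.
#' @export
efficiency_with_sd <- function(fit) {
  if (!is.numeric(fit$Km) || fit$Km <= 0) {
    stop("Km must be positive", call. = FALSE)
  }
  r <- fit$kcat / fit$Km
  C <- fit$covariance
  if (any(!is.finite(C))) {
    return(c(efficiency = r, sd = NA_real_))
  }
  rel_var <- C["Vmax", "Vmax"] / fit$Vmax^2 + C["Km", "Km"] / fit$Km^2 -
    2 * C["Vmax", "Km"] / (fit$Vmax * fit$Km)
  c(efficiency = r, sd = abs(r) * sqrt(max(rel_var, 0)))
}

#' Fold change between two measured values
#'
#' `ratio = mutant / wild-type`, reported to 2 significant figures, with a
#' two-sided z test on the difference using the two standard errors:
#' `z = (m - w) / sqrt(se_m^2 + se_w^2)`. If either SE is missing or
#' non-positive the p-value is omitted.
#'
#' @param mutant_value,wt_value Point estimates; `wt_value` must be
#'   non-zero.
#' @param mutant_se,wt_se Standard errors (optional).
#' @return A list: `ratio` (2 significant figures), `ratio_raw`, `p_value`.
#' @export
fold_change <- function(mutant_value, mutant_se = NA_real_,
                        wt_value, wt_se = NA_real_) {
  if (!is.finite(wt_value) || wt_value == 0) {
    stop("`wt_value` must be finite and non-zero", call. = FALSE)
  }
  raw <- mutant_value / wt_value
  ses_ok <- is.finite(mutant_se) && is.finite(wt_se) &&
    mutant_se > 0 && wt_se > 0
  p <- if (ses_ok) {
    z <- (mutant_value - wt_value) / sqrt(mutant_se^2 + wt_se^2)
    2 * stats::pnorm(-abs(z))
  } else {
    NA_real_
  }
  list(ratio = signif(raw, 2), ratio_raw = raw, p_value = p)
}
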