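# Relaxation-model fitting of progress curves.
#
# The working model for a plate-reader progress curve is a sum of
# exponential approaches to equilibrium plus an optional linear term and a
# background:
#
#   signal(t) = sum_i A_i * (1 - exp(-k1_i * t)) + m * t + B
#
# A is the asymptotic signal amplitude from clearance of substrate, k1 the
# relaxation rate constant and B the background. A single component usually
# suffices; when the residuals show systematic structure the model is
# extended with a second component or a linear term (the latter captures
# the pseudo-zeroth-order regime where substrate is in large excess and the
# velocity is effectively constant over the observation window). Negative
# amplitudes are permitted so loss-of-signal assays share the same code
# path. The initial rate is the model derivative at t = 0:
# v0 = sum_i A_i * k1_i + m.

#' A single well's progress curve
#'
#' @param times Times, s; strictly increasing, finite.
#' @param signals Signals, assay units; same length as `times`, finite.
#' @param substrate_conc Initial substrate concentration of the well.
#' @param enzyme_conc Enzyme concentration, nM.
#' @param construct Construct label.
#' @param role Well role (`sample`, `standard`, `pos_control`,
#'   `neg_control`, `enzyme_free_control`).
#' @param well Well ID.
#' @param conc_unit Concentration unit of `substrate_conc`.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(times, signals, substrate_conc = NA_real_,
                           enzyme_conc = NA_real_,
                           construct = NA_character_, role = "sample",
                           well = NA_character_, conc_unit = NA_character_) {
  times <- as.numeric(times)
  signals <- as.numeric(signals)
  if (length(times) < 1 || length(times) != length(signals)) {
    stop("`times` and `signals` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(signals))) {
    stop("`times` and `signals` must be finite", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(times = times, signals = signals, substrate_conc = substrate_conc,
         enzyme_conc = enzyme_conc, construct = construct, role = role,
         well = well, conc_unit = conc_unit),
    class = "progress_curve"
  )
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf(
    "<progress_curve> %s%d points, t = %g..%g s, signal %.4g..%.4g\n",
    if (!is.na(x$well)) paste0(x$well, ": ") else "",
    length(x$times), min(x$times), max(x$times),
    min(x$signals), max(x$signals)))
  invisible(x)
}

# Evaluate the relaxation model and its partial derivatives.
relax_model <- function(times, A, k, m, B) {
  y <- rep(B, length(times)) + m * times
  for (i in seq_along(A)) y <- y + A[i] * (1 - exp(-k[i] * times))
  y
}

# Jacobian of the model wrt c(A, k, [m], B); columns in parameter order.
relax_jacobian <- function(times, A, k, m, B, include_linear) {
  nc <- length(A)
  cols <- vector("list", 2 * nc + include_linear + 1)
  for (i in seq_len(nc)) {
    e <- exp(-k[i] * times)
    cols[[i]] <- 1 - e              # d/dA_i
    cols[[nc + i]] <- A[i] * times * e  # d/dk_i
  }
  j <- 2 * nc
  if (include_linear) cols[[j + 1]] <- times
  cols[[j + include_linear + 1]] <- rep(1, length(times))
  do.call(cbind, cols)
}

# Unpack the flat parameter vector used by the optimizer.
relax_unpack <- function(p, nc, include_linear) {
  list(A = if (nc > 0) p[seq_len(nc)] else numeric(0),
       k = if (nc > 0) p[nc + seq_len(nc)] else numeric(0),
       m = if (include_linear) p[2 * nc + 1] else 0,
       B = p[length(p)])
}

# Levenberg-Marquardt convergence check. minpack's own stopping codes are
# accepted, and so is an iteration-capped run whose SSE trace had already
# plateaued: ill-conditioned but benign ridges (a nearly linear curve fit
# by A(1 - e^{-kt}) has k -> 0 with A k fixed) keep LM walking along a
# flat valley without meeting ftol/ptol even though the fit is done.
lm_converged <- function(res, plateau_tol = 1e-6) {
  if (res$info %in% 1:4) return(TRUE)
  tr <- res$rsstrace
  if (length(tr) >= 5) {
    last <- tr[length(tr)]
    prev <- tr[length(tr) - 4]
    return(is.finite(last) && last > 0 && (prev - last) <= plateau_tol * last)
  }
  FALSE
}

# Parameter covariance s^2 (J'J)^-1 via the SVD, with near-null directions
# of J dropped (pseudo-inverse). Extended relaxation models can be locally
# degenerate (e.g. two components with nearly equal rates); the SVD keeps
# the well-determined combinations — in particular v0 = sum(A k) + m —
# finite while flagging the rank deficiency.
ls_covariance <- function(J, sigma2, tol = 1e-10) {
  sv <- svd(J)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) {
    return(list(cov = matrix(NA_real_, ncol(J), ncol(J)),
                rank_deficient = TRUE))
  }
  V <- sv$v[, keep, drop = FALSE]
  covm <- sigma2 * V %*% (t(V) / sv$d[keep]^2)
  list(cov = covm, rank_deficient = !all(keep))
}

# Small-sample-corrected AIC for a least-squares fit; p counts the model
# parameters plus the error variance.
aicc_ls <- function(sse, n, n_par) {
  p <- n_par + 1
  aic <- n * log(sse / n) + 2 * p
  if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
}

#' Fit a relaxation model to a progress curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, analytic Jacobian) of
#' `signal(t) = sum_i A_i (1 - exp(-k1_i t)) + m t + B` with `k1_i > 0`.
#' Starting values follow a fixed rule (`B0` = first signal, `A0` = last
#' minus first, `k1_0 = 2 / t_half` with `t_half` the time to reach the
#' mid-signal), with a small multi-start over `k1_0 x {0.2, 1, 5}`; the
#' lowest-SSE solution wins, so the fit is deterministic given the data.
#' Negative amplitudes are allowed (loss-of-signal curves).
#'
#' @param curve A [progress_curve()] with at least 5 points.
#' @param n_components Number of exponential components (>= 0; if 0,
#'   `include_linear` must be `TRUE`).
#' @param include_linear Include a linear term `m * t`.
#' @return An object of class `relaxation_fit`: `components` (tibble of
#'   `A`, `k1`, and their SEs), `linear_slope`, `B`, `covariance` (over all
#'   free parameters, order A..., k1..., m, B), `residuals`, `fitted`,
#'   `v0_signal` (model derivative at t = 0) and `v0_se`, `sse`, `sigma`,
#'   `aicc`, `converged`, and `flags` (`"nonconvergence"` after exhausting
#'   restarts; `"rate_indeterminate"` when v0 is indistinguishable from 0;
#'   `"singular_covariance"` when the information matrix cannot be
#'   inverted).
#' @export
fit_relaxation <- function(curve, n_components = 1, include_linear = FALSE) {
  stopifnot(inherits(curve, "progress_curve"))
  n <- length(curve$times)
  if (n < 5) stop("need at least 5 time points", call. = FALSE)
  if (n_components < 0) stop("`n_components` must be >= 0", call. = FALSE)
  if (n_components == 0 && !include_linear) {
    stop("need at least one exponential component or a linear term",
         call. = FALSE)
  }
  t <- curve$times
  y <- curve$signals
  nc <- as.integer(n_components)

  # initialization rule
  B0 <- y[1]
  A0 <- y[n] - y[1]
  mid <- (y[1] + y[n]) / 2
  cross <- if (abs(A0) > 0) which((y - mid) * sign(A0) >= 0)[1] else NA
  t_half <- if (!is.na(cross) && t[cross] > 0) t[cross] else
    stats::median(t[t > 0])
  k0 <- 2 / t_half

  linear_only <- nc == 0
  n_par <- 2 * nc + include_linear + 1

  residual_fn <- function(p) {
    q <- relax_unpack(p, nc, include_linear)
    relax_model(t, q$A, q$k, q$m, q$B) - y
  }
  jac_fn <- function(p) {
    q <- relax_unpack(p, nc, include_linear)
    relax_jacobian(t, q$A, q$k, q$m, q$B, include_linear)
  }

  starts <- if (linear_only) list(numeric(0)) else
    lapply(c(0.2, 1, 5), function(s) s * k0)
  best <- NULL
  for (ks in starts) {
    if (linear_only) {
      p0 <- c(if (include_linear) A0 / max(t) else NULL, B0)
    } else {
      A_init <- rep(A0 / nc, nc)
      k_init <- ks * 10^-(seq_len(nc) - 1)
      p0 <- c(A_init, k_init,
              if (include_linear) 0 else NULL, B0)
    }
    lower <- rep(-Inf, n_par)
    if (nc > 0) lower[nc + seq_len(nc)] <- 1e-12
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, lower = lower, fn = residual_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, maxfev = 100000, ftol = 1e-12, ptol = 1e-10))),
      error = function(e) NULL
    )
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(res = res, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("relaxation fit failed for all starts", call. = FALSE)
  }
  res <- best$res
  flags <- character(0)
  if (!lm_converged(res)) flags <- c(flags, "nonconvergence")
  p_hat <- res$par
  q <- relax_unpack(p_hat, nc, include_linear)
  fitted <- relax_model(t, q$A, q$k, q$m, q$B)
  residuals <- y - fitted
  sse <- sum(residuals^2)
  dof <- max(n - n_par, 1)
  sigma2 <- sse / dof
  J <- relax_jacobian(t, q$A, q$k, q$m, q$B, include_linear)
  cv <- ls_covariance(J, sigma2)
  covm <- cv$cov
  if (cv$rank_deficient) flags <- c(flags, "singular_covariance")
  par_names <- c(if (nc > 0) paste0("A", seq_len(nc)),
                 if (nc > 0) paste0("k1_", seq_len(nc)),
                 if (include_linear) "m", "B")
  dimnames(covm) <- list(par_names, par_names)

  v0 <- sum(q$A * q$k) + q$m
  grad_v0 <- c(if (nc > 0) q$k, if (nc > 0) q$A,
               if (include_linear) 1, 0)
  v0_se <- if (all(is.finite(covm))) {
    v <- drop(crossprod(grad_v0, covm %*% grad_v0))
    if (v >= 0) sqrt(v) else NA_real_
  } else NA_real_
  if (!is.finite(v0_se) || abs(v0) <= 3 * v0_se) {
    flags <- c(flags, "rate_indeterminate")
  }
  comp_se <- function(nm) {
    if (all(is.finite(diag(covm)))) sqrt(pmax(diag(covm)[nm], 0)) else
      rep(NA_real_, length(nm))
  }
  components <- if (nc > 0) {
    tibble::tibble(A = q$A, k1 = q$k,
                   A_se = comp_se(paste0("A", seq_len(nc))),
                   k1_se = comp_se(paste0("k1_", seq_len(nc))))
  } else {
    tibble::tibble(A = numeric(0), k1 = numeric(0),
                   A_se = numeric(0), k1_se = numeric(0))
  }
  structure(
    list(components = components,
         linear_slope = q$m,
         include_linear = include_linear,
         B = q$B,
         covariance = covm,
         residuals = residuals,
         fitted = fitted,
         v0_signal = v0,
         v0_se = v0_se,
         sse = sse,
         sigma = sqrt(sigma2),
         aicc = aicc_ls(max(sse, 1e-300), n, n_par),
         n = n,
         n_par = n_par,
         converged = lm_converged(res),
         flags = flags,
         curve = curve),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> %d component(s)%s, n = %d\n",
              nrow(x$components),
              if (x$include_linear) " + linear term" else "", x$n))
  if (nrow(x$components) > 0) {
    for (i in seq_len(nrow(x$components))) {
      cat(sprintf("  A%d = %.6g +/- %.3g, k1_%d = %.6g +/- %.3g /s\n",
                  i, x$components$A[i], x$components$A_se[i],
                  i, x$components$k1[i], x$components$k1_se[i]))
    }
  }
  if (x$include_linear) cat(sprintf("  m = %.6g /s\n", x$linear_slope))
  cat(sprintf("  B = %.6g; v0 = %.6g +/- %.3g signal/s\n",
              x$B, x$v0_signal, x$v0_se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a relaxation fit
#'
#' @param object A `relaxation_fit`.
#' @param times Times at which to evaluate (default: the fitted times).
#' @param ... Unused.
#' @return Predicted signals.
#' @export
predict.relaxation_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$curve$times
  relax_model(times, object$components$A, object$components$k1,
              object$linear_slope, object$B)
}

# ---- Wald-Wolfowitz runs test on residual signs ----

# Exact lower-tail P(R <= r_obs) for the number of runs in a random
# arrangement of n1 plus-signs and n2 minus-signs.
runs_exact_lower_p <- function(r_obs, n1, n2) {
  n <- n1 + n2
  total <- choose(n, n1)
  pr <- function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / total
    } else {
      k <- (r - 1) / 2
      (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
         choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / total
    }
  }
  sum(vapply(2:max(2, r_obs), pr, 0)[seq_len(max(0, r_obs - 1))])
}

# Lower-tail runs-test p-value: exact for n <= 30, otherwise normal
# approximation with continuity correction.
runs_test_lower_p <- function(signs) {
  n1 <- sum(signs > 0)
  n2 <- sum(signs < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(0) # all one sign: extreme lack of fit
  r <- 1 + sum(diff(signs) != 0)
  if (n <= 30) {
    runs_exact_lower_p(r, n1, n2)
  } else {
    mu <- 2 * n1 * n2 / n + 1
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    stats::pnorm((r - mu + 0.5) / sqrt(v))
  }
}

#' Diagnose systematic structure in fit residuals
#'
#' Wald-Wolfowitz runs test on the signs of the residuals: too few runs
#' (long stretches of same-signed residuals) indicate systematic lack of
#' fit. The test is one-sided (lower tail), exact for up to 30 signed
#' residuals and normal-approximated above that. Fewer than 8 signed
#' residuals is inconclusive and reported as unstructured.
#'
#' @param fit A [fit_relaxation()] result.
#' @param p_threshold Significance threshold; residuals are called
#'   structured when `p < p_threshold` (default 0.01).
#' @param fit_larger Optional larger-model fit; when supplied, the AICc
#'   difference `fit_larger$aicc - fit$aicc` is reported.
#' @return A list: `structured` (logical), `statistic` (observed number of
#'   runs), `p_value`, `threshold`, `n_pos`, `n_neg`, `inconclusive`,
#'   `delta_aicc`.
#' @export
assess_residual_structure <- function(fit, p_threshold = 0.01,
                                      fit_larger = NULL) {
  stopifnot(inherits(fit, "relaxation_fit"))
  r <- fit$residuals
  signs <- sign(r)[sign(r) != 0]
  n <- length(signs)
  delta_aicc <- if (!is.null(fit_larger)) fit_larger$aicc - fit$aicc else
    NA_real_
  if (n < 8) {
    return(list(structured = FALSE, statistic = NA_real_,
                p_value = NA_real_, threshold = p_threshold,
                n_pos = sum(signs > 0), n_neg = sum(signs < 0),
                inconclusive = TRUE, delta_aicc = delta_aicc))
  }
  p <- runs_test_lower_p(signs)
  runs <- 1 + sum(diff(signs) != 0)
  list(structured = p < p_threshold, statistic = runs, p_value = p,
       threshold = p_threshold, n_pos = sum(signs > 0),
       n_neg = sum(signs < 0), inconclusive = FALSE,
       delta_aicc = delta_aicc)
}

# Heuristic for auto_fit: prefer a linear extension when the late part of
# the curve is still rising at a steady rate with little curvature
# (pseudo-zeroth-order regime: substrate in excess, velocity ~ constant).
prefer_linear_extension <- function(curve) {
  n <- length(curve$times)
  tail_idx <- seq.int(max(1, ceiling(2 * n / 3)), n)
  if (length(tail_idx) < 5) return(FALSE)
  t <- curve$times[tail_idx]
  y <- curve$signals[tail_idx]
  tc <- t - mean(t)
  fit <- tryCatch(stats::lm(y ~ tc + I(tc^2)), error = function(e) NULL)
  if (is.null(fit)) return(FALSE)
  sm <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sm) < 3) return(FALSE)
  slope_t <- abs(sm[2, "t value"])
  quad_t <- abs(sm[3, "t value"])
  is.finite(slope_t) && slope_t > 3 && (!is.finite(quad_t) || quad_t < 2)
}

#' Fit a relaxation model with automatic extension
#'
#' Fits a single-component relaxation model first. While the residuals show
#' significant structure (see [assess_residual_structure()]) and the model
#' can still grow, the model is extended and refit: a linear term is tried
#' first when the curve's tail is still rising steadily with low curvature
#' (pseudo-zeroth-order regime), otherwise an exponential component is
#' added. Returns the first fit whose residuals are unstructured; if none
#' is found, the best-AICc fit (smallest model within 2 AICc units of the
#' minimum) is returned carrying a `"structured_residuals"` flag.
#'
#' @param curve A [progress_curve()].
#' @param max_components Maximum number of exponential components.
#' @param p_threshold Runs-test significance threshold for "structured".
#' @return A `relaxation_fit` with the residual diagnostic attached as
#'   `$diagnostic`.
#' @export
auto_fit <- function(curve, max_components = 2, p_threshold = 0.01) {
  stopifnot(inherits(curve, "progress_curve"))
  try_fit <- function(nc, lin) {
    tryCatch(fit_relaxation(curve, n_components = nc, include_linear = lin),
             error = function(e) NULL)
  }
  tried <- list()
  key <- function(nc, lin) paste0(nc, "_", lin)
  fits <- list()
  nc <- 1L
  lin <- FALSE
  fit <- try_fit(nc, lin)
  if (is.null(fit)) stop("initial relaxation fit failed", call. = FALSE)
  tried[[key(nc, lin)]] <- TRUE
  fits[[length(fits) + 1]] <- fit
  prefer_lin <- prefer_linear_extension(curve)
  repeat {
    d <- assess_residual_structure(fit, p_threshold = p_threshold)
    if (!d$structured) {
      fit$diagnostic <- d
      return(fit)
    }
    cands <- list()
    if (prefer_lin && !lin) cands <- c(cands, list(c(nc, TRUE)))
    if (nc < max_components) cands <- c(cands, list(c(nc + 1, lin)))
    if (!lin) cands <- c(cands, list(c(nc, TRUE)))
    cands <- Filter(function(cd) is.null(tried[[key(cd[1], cd[2])]]), cands)
    if (length(cands) == 0) break
    cd <- cands[[1]]
    nc <- as.integer(cd[1])
    lin <- as.logical(cd[2])
    tried[[key(nc, lin)]] <- TRUE
    new_fit <- try_fit(nc, lin)
    if (is.null(new_fit)) next
    fit <- new_fit
    fits[[length(fits) + 1]] <- fit
  }
  # No unstructured model found: return the best-AICc fit, flagged, with a
  # parsimony tie-break — the smallest model within 2 AICc units of the
  # minimum. Overparameterized extensions on long reads can shave AICc
  # marginally while degrading the t = 0 derivative (v0) by splitting the
  # initial slope between degenerate terms.
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  npars <- vapply(fits, function(f) f$n_par, 0)
  near <- which(aiccs <= min(aiccs) + 2)
  best <- fits[[near[which.min(npars[near])]]]
  best$flags <- union(best$flags, "structured_residuals")
  best$diagnostic <- assess_residual_structure(best,
                                               p_threshold = p_threshold)
  best
}

#' Subtract a control curve from a sample curve
#'
#' Pointwise subtraction on a shared time grid (used for the coupled-assay
#' chitinase-free control, whose drifting background would otherwise bias
#' the relaxation fit). If the grids differ by less than half a sampling
#' interval the control is interpolated onto the sample grid; larger
#' mismatches are an error.
#'
#' @param curve Sample [progress_curve()].
#' @param control Control [progress_curve()].
#' @return A `progress_curve` with the control signal removed; metadata of
#'   `curve` preserved.
#' @export
subtract_control <- function(curve, control) {
  stopifnot(inherits(curve, "progress_curve"),
            inherits(control, "progress_curve"))
  half_step <- stats::median(diff(curve$times)) / 2
  if (length(control$times) == length(curve$times) &&
      max(abs(control$times - curve$times)) <= half_step) {
    ctrl_sig <- control$signals
  } else {
    if (min(curve$times) < min(control$times) - half_step ||
        max(curve$times) > max(control$times) + half_step) {
      stop("control time grid does not cover the sample grid", call. = FALSE)
    }
    ctrl_sig <- stats::approx(control$times, control$signals,
                              xout = curve$times, rule = 2)$y
  }
  out <- curve
  out$signals <- curve$signals - ctrl_sig
  out
}

#' Subtract a curve's initial state
#'
#' `signal(t) - signal(t0)`; the first point becomes exactly 0. Used for
#' the insoluble-substrate clearance assay, where each well starts at a
#' different scattering level set by its substrate load. Idempotent.
#'
#' @param curve A [progress_curve()].
#' @return A `progress_curve` re-zeroed at its first point.
#' @export
subtract_initial <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  out <- curve
  out$signals <- curve$signals - curve$signals[1]
  out
}

#' Endpoint rate from an absorbance read window
#'
#' For the ferricyanide endpoint assay the difference between the maximum
#' and minimum absorbance over the read window, scaled by the chitinase
#' incubation time (not the read window), is a robust measure of total
#' reducing-sugar generation:
#' `rate = (max(signal) - min(signal)) / incubation_time`.
#'
#' @param curve A [progress_curve()] with at least 2 points.
#' @param incubation_time Chitinase incubation time, s (e.g. up to 18 h =
#'   64800 s). Strictly positive.
#' @return Rate in signal units per second (non-negative).
#' @export
endpoint_rate <- function(curve, incubation_time) {
  stopifnot(inherits(curve, "progress_curve"))
  if (!is.numeric(incubation_time) || length(incubation_time) != 1 ||
      !is.finite(incubation_time) || incubation_time <= 0) {
    stop("`incubation_time` must be a single positive duration in seconds",
         call. = FALSE)
  }
  if (length(curve$signals) < 2) {
    stop("need at least 2 points for an endpoint rate", call. = FALSE)
  }
  (max(curve$signals) - min(curve$signals)) / incubation_time
}
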