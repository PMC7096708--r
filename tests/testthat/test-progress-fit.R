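# Relaxation-model fitting: exact recovery, degenerate inputs, residual
# diagnostics, automatic model extension, control/initial subtraction and
# the endpoint-rate estimator.

test_that("noiseless single-exponential parameters recover to 1e-6", {
  times <- seq(0, 3600, by = 60)
  cv <- progress_curve(times, 100 * (1 - exp(-0.01 * times)) + 5)
  fit <- fit_relaxation(cv)
  expect_equal(fit$components$A, 100, tolerance = 1e-6)
  expect_equal(fit$components$k1, 0.01, tolerance = 1e-6)
  expect_equal(fit$B, 5, tolerance = 1e-6)
  expect_equal(fit$v0_signal, 100 * 0.01, tolerance = 1e-6)
  # asymptote identity: prediction at large t -> A + B
  expect_equal(predict(fit, 1e7), 105, tolerance = 1e-6)
  expect_length(fit$flags, 0)
})

test_that("a constant curve is flagged rate-indeterminate", {
  cv <- progress_curve(seq(0, 600, 60), rep(5, 11))
  fit <- fit_relaxation(cv)
  expect_true("rate_indeterminate" %in% fit$flags)
  expect_lt(abs(fit$v0_signal), 1e-8)
})

test_that("negative amplitudes fit loss-of-signal curves unchanged", {
  times <- seq(0, 3600, by = 60)
  cv <- progress_curve(times, -80 * (1 - exp(-0.002 * times)) + 1.2)
  fit <- fit_relaxation(cv)
  expect_equal(fit$components$A, -80, tolerance = 1e-6)
  expect_equal(fit$components$k1, 0.002, tolerance = 1e-6)
})

test_that("noisy fits agree with the grid-search oracle and the truth", {
  for (seed in c(2, 9, 31)) {
    sim <- sim_exp_curve(seed)
    fit <- fit_relaxation(sim$curve)
    oracle <- oracle_exp_fit(sim$curve$times, sim$curve$signals)
    expect_equal(fit$components$k1, oracle$k1, tolerance = 1e-4)
    expect_equal(fit$components$A, oracle$A, tolerance = 1e-4)
    expect_lt(abs(fit$components$A - sim$truth["A"]),
              3 * fit$components$A_se)
    expect_lt(abs(fit$components$k1 - sim$truth["k1"]),
              3 * fit$components$k1_se)
  }
})

test_that("runs-test diagnostic flags blocked residuals, not alternating", {
  mk_fit <- function(res) {
    f <- fit_relaxation(progress_curve(seq_along(res), seq_along(res) * 0 +
                                         res + 100))
    f$residuals <- res
    f
  }
  alt <- mk_fit(rep(c(0.5, -0.5), 8))
  expect_false(assess_residual_structure(alt)$structured)
  # 3 runs in 12 signs is suggestive but, by the exact conditional null,
  # not significant at 0.01 (P(R <= 3 | n1 = 8, n2 = 4) = 2/495 + 10/495)
  weak <- mk_fit(c(rep(0.5, 4), rep(-0.5, 4), rep(0.5, 4)))
  dw <- assess_residual_structure(weak)
  expect_equal(dw$statistic, 3)
  expect_equal(dw$p_value, 12 / 495, tolerance = 1e-12)
  expect_false(dw$structured)
  # 3 runs in 18 signs is decisive lack of fit
  blocked <- mk_fit(c(rep(0.5, 6), rep(-0.5, 6), rep(0.5, 6)))
  d <- assess_residual_structure(blocked)
  expect_true(d$structured)
  expect_equal(d$statistic, 3)
  short <- mk_fit(c(1, 1, 1, -1, -1))
  expect_true(assess_residual_structure(short)$inconclusive)
  expect_false(assess_residual_structure(short)$structured)
})

test_that("exact runs-test tail probabilities match full enumeration", {
  for (r_obs in c(2, 3, 4, 5, 7)) {
    expect_equal(chitkin:::runs_exact_lower_p(r_obs, 5, 5),
                 oracle_runs_lower_p(r_obs, 5, 5), tolerance = 1e-12)
  }
  expect_equal(chitkin:::runs_exact_lower_p(4, 7, 3),
               oracle_runs_lower_p(4, 7, 3), tolerance = 1e-12)
})

test_that("model-matched noiseless fits show no residual structure", {
  times <- seq(0, 3600, by = 60)
  cv <- progress_curve(times, 100 * (1 - exp(-0.01 * times)) + 5)
  expect_false(assess_residual_structure(fit_relaxation(cv))$structured)
})

test_that("auto_fit keeps the single-component model for pure exponentials", {
  sim <- sim_exp_curve(4)
  fit <- auto_fit(sim$curve)
  expect_equal(nrow(fit$components), 1)
  expect_false(fit$include_linear)
})

test_that("auto_fit adds a linear term for exponential-plus-drift input", {
  times <- seq(0, 3600, by = 30)
  truth_m <- 0.02
  clean <- 60 * (1 - exp(-0.004 * times)) + truth_m * times + 10
  noisy <- withr::with_seed(8, clean + rnorm(length(times), 0, 0.6))
  fit <- auto_fit(progress_curve(times, noisy))
  expect_true(fit$include_linear)
  m_se <- sqrt(diag(fit$covariance)["m"])
  expect_lt(abs(fit$linear_slope - truth_m), 3 * m_se)
})

test_that("auto_fit resolves two well-separated exponential components", {
  times <- seq(0, 7200, by = 30)
  clean <- 50 * (1 - exp(-0.02 * times)) + 80 * (1 - exp(-0.001 * times)) + 3
  noisy <- withr::with_seed(12, clean + rnorm(length(times), 0, 0.5))
  fit <- auto_fit(progress_curve(times, noisy))
  expect_equal(nrow(fit$components), 2)
  ks <- sort(fit$components$k1)
  expect_equal(ks[1], 0.001, tolerance = 0.1)
  expect_equal(ks[2], 0.02, tolerance = 0.1)
})

test_that("control subtraction cancels shared drift and offsets", {
  spec <- simulation_spec(kcat = 1, Km = 100, enzyme_conc = 10,
                          substrate_concs = 5, gain = 100, background = 20,
                          background_drift = 0.05, noise_sd = 0.4,
                          duration = 3600, interval = 30, seed = 21L,
                          assay_mode = "coupled_gain", conc_unit = "uM")
  spec_free <- spec
  spec_free$background_drift <- 0
  smp <- integrated_mm_curve(spec, 5, stream = 1L)
  ctl <- integrated_mm_curve(spec, 5, stream = 2L, enzyme_conc = 0)
  sub <- subtract_control(smp, ctl)
  fit_sub <- fit_relaxation(sub)
  smp_free <- integrated_mm_curve(spec_free, 5, stream = 1L)
  fit_free <- fit_relaxation(smp_free)
  se <- sqrt(fit_sub$components$k1_se^2 + fit_free$components$k1_se^2)
  expect_lt(abs(fit_sub$components$k1 - fit_free$components$k1), se)

  # curve minus itself is exactly zero
  zero <- subtract_control(smp, smp)
  expect_equal(zero$signals, rep(0, length(smp$times)))

  # offset-only control shifts B and leaves A, k1 untouched
  offset <- progress_curve(smp_free$times, rep(7, length(smp_free$times)))
  fit_off <- fit_relaxation(subtract_control(smp_free, offset))
  expect_equal(fit_off$components$A, fit_free$components$A,
               tolerance = 1e-8)
  expect_equal(fit_off$components$k1, fit_free$components$k1,
               tolerance = 1e-8)
  expect_equal(fit_off$B, fit_free$B - 7, tolerance = 1e-8)

  # incompatible grids are an error
  shifted <- progress_curve(smp$times + 2000, smp$signals)
  expect_error(subtract_control(shifted, ctl), "grid")
})

test_that("initial-state subtraction zeroes the first point, idempotently", {
  sim <- sim_exp_curve(3, A = -40, B = 0.9) # loss-of-scattering shape
  z <- subtract_initial(sim$curve)
  expect_equal(z$signals[1], 0)
  expect_identical(subtract_initial(z), z)
  fit <- fit_relaxation(z)
  expect_lt(abs(abs(fit$components$A) - 40), 3 * fit$components$A_se)
})

test_that("re-zeroing a noiseless curve changes B only", {
  times <- seq(0, 3600, by = 60)
  cv <- progress_curve(times, 100 * (1 - exp(-0.01 * times)) + 5)
  f0 <- fit_relaxation(cv)
  f1 <- fit_relaxation(subtract_initial(cv))
  expect_equal(f1$components$A, f0$components$A, tolerance = 1e-6)
  expect_equal(f1$components$k1, f0$components$k1, tolerance = 1e-6)
  expect_equal(f1$B, 0, tolerance = 1e-6)
})

test_that("endpoint rate is the signal range over the incubation time", {
  times <- seq(0, 14400, by = 600)
  falling <- progress_curve(times, 1.0 - 0.6 * (1 - exp(-3e-4 * times)))
  expect_equal(endpoint_rate(falling, 18 * 3600),
               (max(falling$signals) - min(falling$signals)) / 64800)
  expect_equal(endpoint_rate(progress_curve(times, rep(1, length(times))),
                             3600), 0)
  expect_error(endpoint_rate(falling, 0), "positive")
})

test_that("fitted v0 matches the analytic MM velocity at low substrate", {
  spec <- simulation_spec(kcat = 1.5, Km = 33, enzyme_conc = 10,
                          substrate_concs = 3.3, gain = 100,
                          background = 50, duration = 1800, interval = 30,
                          conc_unit = "uM")
  Vmax <- 1.5 * 0.01
  for (S0 in c(0.33, 1, 3.3)) { # all <= Km/10
    fit <- auto_fit(integrated_mm_curve(spec, S0))
    v0_analytic <- Vmax * S0 / (33 + S0)
    expect_lt(abs(fit$v0_signal / 100 - v0_analytic) / v0_analytic, 0.05)
  }
})

test_that("short or malformed curves are rejected", {
  expect_error(progress_curve(c(0, 1, 1, 2), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(progress_curve(1:3, c(1, 2, NA)), "finite")
  expect_error(fit_relaxation(progress_curve(1:4, 1:4)), "at least 5")
  expect_error(fit_relaxation(progress_curve(1:10, 1:10), n_components = 0),
               "at least one")
})
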