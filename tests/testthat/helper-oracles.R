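# Independent oracles for cross-checking the package's fitters. These
# deliberately avoid Levenberg-Marquardt: profile grid searches exploit
# the conditional linearity of each model, and the runs-test oracle
# enumerates sign arrangements outright.

# Single-exponential relaxation fit by profile grid search + golden-section
# polish: for fixed k the model A(1 - e^{-kt}) + B is linear in (A, B).
oracle_exp_fit <- function(times, signals, n_grid = 400) {
  prof_sse <- function(lk) {
    X <- cbind(1 - exp(-exp(lk) * times), 1)
    sum(stats::lm.fit(X, signals)$residuals^2)
  }
  t_pos <- times[times > 0]
  lo <- log(0.01 / max(times))
  hi <- log(50 / min(t_pos))
  grid <- seq(lo, hi, length.out = n_grid)
  sses <- vapply(grid, prof_sse, 0)
  i <- which.min(sses)
  opt <- stats::optimize(prof_sse,
                         interval = c(grid[max(1, i - 1)],
                                      grid[min(n_grid, i + 1)]),
                         tol = 1e-11)
  k <- exp(opt$minimum)
  X <- cbind(1 - exp(-k * times), 1)
  beta <- stats::lm.fit(X, signals)$coefficients
  list(A = unname(beta[1]), k1 = k, B = unname(beta[2]),
       sse = opt$objective)
}

# Michaelis-Menten fit by profile grid search over Km: for fixed Km the
# model Vmax * S / (Km + S) is linear (through the origin) in Vmax.
oracle_mm_fit <- function(S, v, n_grid = 400) {
  prof <- function(lKm) {
    x <- S / (exp(lKm) + S)
    Vmax <- sum(v * x) / sum(x * x)
    sum((v - Vmax * x)^2)
  }
  lo <- log(min(S[S > 0]) / 100)
  hi <- log(max(S) * 100)
  grid <- seq(lo, hi, length.out = n_grid)
  sses <- vapply(grid, prof, 0)
  i <- which.min(sses)
  opt <- stats::optimize(prof,
                         interval = c(grid[max(1, i - 1)],
                                      grid[min(n_grid, i + 1)]),
                         tol = 1e-11)
  Km <- exp(opt$minimum)
  x <- S / (Km + S)
  list(Vmax = sum(v * x) / sum(x * x), Km = Km, sse = opt$objective)
}

# Exact lower-tail runs-test p-value by full enumeration of all
# arrangements of n1 plus and n2 minus signs (feasible for small n).
oracle_runs_lower_p <- function(r_obs, n1, n2) {
  n <- n1 + n2
  pos_sets <- utils::combn(n, n1)
  count <- 0
  for (j in seq_len(ncol(pos_sets))) {
    s <- rep(-1, n)
    s[pos_sets[, j]] <- 1
    runs <- 1 + sum(diff(s) != 0)
    if (runs <= r_obs) count <- count + 1
  }
  count / ncol(pos_sets)
}

# Monte-Carlo propagation of the (Vmax, Km) covariance into kcat/Km.
oracle_mc_ratio_sd <- function(Vmax, Km, covm, e_scale, n = 1e6,
                               seed = 1) {
  withr::with_seed(seed, {
    L <- chol(covm)
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    Vm <- Vmax + z[, 1]
    K <- Km + z[, 2]
    stats::sd((Vm / e_scale) / K)
  })
}

# Simulate one noisy single-exponential curve (used by several fitter
# tests); returns the curve and the generating truth.
sim_exp_curve <- function(seed, A = 100, k1 = 0.01, B = 5,
                          noise_frac = 0.01, duration = 3600,
                          interval = 60) {
  times <- seq(0, duration, by = interval)
  clean <- A * (1 - exp(-k1 * times)) + B
  noisy <- withr::with_seed(seed,
    clean + stats::rnorm(length(times), 0, noise_frac * abs(A)))
  list(curve = progress_curve(times, noisy),
       truth = c(A = A, k1 = k1, B = B))
}
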