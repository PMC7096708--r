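# Synthetic plate-reader data from known Michaelis-Menten ground truth.
#
# Substrate depletion follows the integrated Michaelis-Menten equation
#   Km * ln(S0/S) + (S0 - S) = Vmax * t
# solved in closed form with the Lambert W function, then mapped to one of
# four plate-reader signal shapes (gain-of-fluorescence, loss-of-scattering,
# loss-of-absorbance endpoint, coupled gain with a drifting enzyme-free
# background). Gaussian noise is added last.

#' Specification for a simulated kinetic experiment
#'
#' Bundles the kinetic ground truth (`kcat`, `Km`), the experimental design
#' (enzyme and substrate concentrations, time grid) and the signal model
#' (gain, background, drift, noise) for one assay type.
#'
#' @param kcat Turnover number, 1/s. Strictly positive.
#' @param Km Michaelis constant, in `conc_unit`. Strictly positive.
#' @param enzyme_conc Enzyme concentration, nM. Strictly positive.
#' @param substrate_concs Initial substrate concentrations S0, in `conc_unit`.
#'   Non-empty, all non-negative.
#' @param gain Signal units per unit of product concentration. Strictly
#'   positive.
#' @param background Constant background signal.
#' @param background_drift Linear background drift, signal units per second
#'   (models the slowly rising chitinase-free signal of the coupled assay).
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise on
#'   the signal. Non-negative.
#' @param duration Total observation time, s. Strictly positive.
#' @param interval Sampling interval, s. Strictly positive.
#' @param seed Integer seed; an identical spec with an identical seed yields
#'   bit-identical output.
#' @param assay_mode Signal shape: `"gain_fluor"` (fluorophore release),
#'   `"loss_scatter"` (OD680 falls as solid substrate clears),
#'   `"loss_abs_endpoint"` (absorbance falls in proportion to accumulated
#'   reducing sugar), or `"coupled_gain"` (enzyme-coupled fluorescence with
#'   drifting background).
#' @param conc_unit Concentration unit for `Km` and `substrate_concs`.
#' @return An object of class `sim_spec`.
#' @export
simulation_spec <- function(kcat, Km, enzyme_conc, substrate_concs, gain,
                            background = 0, background_drift = 0,
                            noise_sd = 0, duration = 3600, interval = 60,
                            seed = 1L,
                            assay_mode = c("gain_fluor", "loss_scatter",
                                           "loss_abs_endpoint", "coupled_gain"),
                            conc_unit = c("uM", "mM", "percent_wv")) {
  assay_mode <- match.arg(assay_mode)
  conc_unit <- match.arg(conc_unit)
  pos <- c(kcat = kcat, Km = Km, enzyme_conc = enzyme_conc, gain = gain,
           duration = duration, interval = interval)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    stop("spec fields must be finite and strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be finite and non-negative", call. = FALSE)
  }
  if (!all(is.finite(c(background, background_drift)))) {
    stop("`background` and `background_drift` must be finite", call. = FALSE)
  }
  if (length(substrate_concs) == 0 || any(!is.finite(substrate_concs)) ||
      any(substrate_concs < 0)) {
    stop("`substrate_concs` must be non-empty, finite and non-negative",
         call. = FALSE)
  }
  structure(
    list(kcat = kcat, Km = Km, enzyme_conc = enzyme_conc,
         substrate_concs = as.numeric(substrate_concs), gain = gain,
         background = background, background_drift = background_drift,
         noise_sd = noise_sd, duration = duration, interval = interval,
         seed = as.integer(seed), assay_mode = assay_mode,
         conc_unit = conc_unit),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec> ", x$assay_mode, "\n", sep = "")
  cat(sprintf("  kcat = %g /s, Km = %g %s, [E] = %g nM\n",
              x$kcat, x$Km, x$conc_unit, x$enzyme_conc))
  cat(sprintf("  S0: %s %s\n",
              paste(signif(x$substrate_concs, 4), collapse = ", "),
              x$conc_unit))
  cat(sprintf("  gain = %g, background = %g, drift = %g /s, noise sd = %g\n",
              x$gain, x$background, x$background_drift, x$noise_sd))
  cat(sprintf("  t = 0..%g s every %g s, seed = %d\n",
              x$duration, x$interval, x$seed))
  invisible(x)
}

# Vmax in substrate-concentration units per second implied by the spec.
vmax_of_spec <- function(spec) {
  spec$kcat * enzyme_nM_to_conc(spec$enzyme_conc, spec$conc_unit)
}

# Solve w + log(w) = y for w > 0, i.e. w = W(exp(y)) with the Lambert W
# principal branch taken on a log-scale argument. The log-scale form stays
# finite when exp(y) would overflow (S0 >> Km makes y of order S0/Km).
# Newton iteration on f(w) = w + log(w) - y; f is strictly increasing.
lambert_w_exp <- function(y) {
  stopifnot(all(is.finite(y)))
  out <- numeric(length(y))
  # for y <= -36, W(e^y) = e^y to full double precision (correction O(e^2y))
  small <- y <= -36
  out[small] <- exp(y[small])
  if (!any(!small)) return(out)
  yy <- y[!small]
  w <- ifelse(yy > 1, yy - log(pmax(yy, 1)), exp(pmin(yy, 1)))
  w <- pmax(w, .Machine$double.xmin)
  y <- yy
  for (i in seq_len(200)) {
    f <- w + log(w) - y
    step <- f * w / (w + 1)
    w_new <- w - step
    bad <- !is.finite(w_new) | w_new <= 0
    w_new[bad] <- w[bad] / 2
    done <- abs(step) <= 1e-15 * pmax(abs(w), .Machine$double.xmin)
    w <- w_new
    if (all(done)) break
  }
  out[!small] <- w
  out
}

#' Substrate remaining under the integrated Michaelis-Menten equation
#'
#' Closed-form solution of `Km * ln(S0/S) + (S0 - S) = Vmax * t` via the
#' Lambert W function: `S(t) = Km * W((S0/Km) * exp((S0 - Vmax t)/Km))`,
#' evaluated on a log-scale argument so it remains stable for `S0 >> Km`.
#'
#' @param S0 Initial substrate concentration (single non-negative value).
#' @param Vmax Maximal rate, concentration/s.
#' @param Km Michaelis constant, same concentration unit as `S0`.
#' @param times Times at which to evaluate, s.
#' @return Substrate concentrations `S(t)`, same unit as `S0`.
#' @export
mm_substrate_remaining <- function(S0, Vmax, Km, times) {
  stopifnot(length(S0) == 1, is.finite(S0), S0 >= 0,
            is.finite(Vmax), Vmax >= 0, is.finite(Km), Km > 0,
            all(is.finite(times)), all(times >= 0))
  if (S0 == 0 || Vmax == 0) {
    return(rep(S0, length(times)))
  }
  y <- log(S0 / Km) + (S0 - Vmax * times) / Km
  pmin(Km * lambert_w_exp(y), S0)
}

# Derive a well/stream-specific RNG seed from the spec seed. Kept < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) + 1000003 * as.double(stream)) %% 2147483647)
}

#' Simulate one progress curve from the integrated Michaelis-Menten model
#'
#' Product accumulation `P(t) = S0 - S(t)` is computed in closed form (see
#' [mm_substrate_remaining()]) and mapped to a plate-reader signal according
#' to the spec's `assay_mode`:
#' \describe{
#'   \item{gain_fluor}{`gain * P + background`}
#'   \item{loss_scatter, loss_abs_endpoint}{`background + gain * (S0 - P)`
#'     (signal falls as substrate is consumed)}
#'   \item{coupled_gain}{`gain * P + background + background_drift * t`}
#' }
#' Gaussian noise of sd `noise_sd` is added last.
#'
#' @param spec A [simulation_spec()].
#' @param S0 Initial substrate concentration; `S0 = 0` yields a flat
#'   background curve.
#' @param stream Integer RNG sub-stream, so multiple curves drawn from one
#'   spec get independent (but reproducible) noise.
#' @param enzyme_conc Optional override of the spec's enzyme concentration,
#'   nM; `0` gives an enzyme-free curve (background and drift only).
#' @return A [progress_curve()].
#' @export
integrated_mm_curve <- function(spec, S0, stream = 0L, enzyme_conc = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (length(S0) != 1 || !is.finite(S0) || S0 < 0) {
    stop("`S0` must be a single finite non-negative concentration",
         call. = FALSE)
  }
  E <- if (is.null(enzyme_conc)) spec$enzyme_conc else enzyme_conc
  if (!is.finite(E) || E < 0) stop("`enzyme_conc` must be finite and >= 0",
                                   call. = FALSE)
  times <- seq(0, spec$duration, by = spec$interval)
  Vmax <- spec$kcat * enzyme_nM_to_conc(E, spec$conc_unit) * (E > 0)
  P <- S0 - mm_substrate_remaining(S0, Vmax, spec$Km, times)
  signal <- switch(spec$assay_mode,
    gain_fluor = spec$gain * P + spec$background,
    loss_scatter = ,
    loss_abs_endpoint = spec$background + spec$gain * (S0 - P),
    coupled_gain = spec$gain * P + spec$background +
      spec$background_drift * times
  )
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(
      derive_seed(spec$seed, stream),
      stats::rnorm(length(times), 0, spec$noise_sd)
    )
    signal <- signal + noise
  }
  progress_curve(times, signal, substrate_conc = S0, enzyme_conc = E,
                 conc_unit = spec$conc_unit)
}

#' Simulate calibration standards
#'
#' Standards follow the same linear signal model as the simulated curves:
#' `signal = gain * conc + background + noise`.
#'
#' @param spec A [simulation_spec()] (provides gain, background, noise, seed).
#' @param concs Standard concentrations, non-negative.
#' @param stream Integer RNG sub-stream.
#' @return A tibble with columns `concentration` and `signal`.
#' @export
make_standards <- function(spec, concs, stream = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (any(!is.finite(concs)) || any(concs < 0)) {
    stop("standard concentrations must be finite and non-negative",
         call. = FALSE)
  }
  signal <- spec$gain * concs + spec$background
  if (spec$noise_sd > 0) {
    signal <- signal + withr::with_seed(
      derive_seed(spec$seed, stream),
      stats::rnorm(length(concs), 0, spec$noise_sd)
    )
  }
  tibble::tibble(concentration = as.numeric(concs), signal = signal)
}

#' Serial dilution series
#'
#' @param top Highest concentration.
#' @param n Number of points.
#' @param factor Dilution factor between successive points (default halving).
#' @return Numeric vector of length `n`, descending.
#' @export
serial_dilution <- function(top, n, factor = 2) {
  stopifnot(top > 0, n >= 1, factor > 1)
  top / factor^(seq_len(n) - 1)
}

#' Plate layout table
#'
#' @param well Well IDs (e.g. "A1".."H12"); must be unique.
#' @param role One of `sample`, `standard`, `pos_control`, `neg_control`,
#'   `enzyme_free_control` per well.
#' @param construct Construct label per well (NA allowed for standards).
#' @param substrate_conc Initial substrate (or standard) concentration.
#' @param enzyme_conc Enzyme concentration, nM (0 for enzyme-free wells).
#' @param conc_unit Concentration unit, recycled.
#' @return A tibble of class `plate_layout`.
#' @export
plate_layout <- function(well, role, construct = NA_character_,
                         substrate_conc = NA_real_, enzyme_conc = NA_real_,
                         conc_unit = "uM") {
  roles <- c("sample", "standard", "pos_control", "neg_control",
             "enzyme_free_control")
  if (anyDuplicated(well)) {
    stop("duplicate well assignment: ",
         paste(unique(well[duplicated(well)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(role %in% roles)) {
    stop("`role` must be one of: ", paste(roles, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    well = as.character(well), role = as.character(role),
    construct = rep_len(as.character(construct), length(well)),
    substrate_conc = rep_len(as.numeric(substrate_conc), length(well)),
    enzyme_conc = rep_len(as.numeric(enzyme_conc), length(well)),
    conc_unit = rep_len(as.character(conc_unit), length(well))
  )
  class(out) <- c("plate_layout", class(out))
  out
}

#' Simulate a whole plate
#'
#' Generates one progress curve per layout well. Sample and positive-control
#' wells use the spec of their construct; negative-control wells are
#' simulated with zero enzyme; enzyme-free control wells carry only the
#' (possibly drifting) background; standard wells read a constant
#' `gain * conc + background` level at every time point.
#'
#' @param specs Named list of [simulation_spec()] objects, one per construct
#'   appearing in the layout (a single unnamed spec is applied to all).
#' @param layout A [plate_layout()].
#' @return A list of class `plate_data` with elements `timeseries` (long
#'   tibble: `well`, `time_s`, `signal`), `layout`, `standards` (per-well
#'   standard reads), and `ground_truth` (tibble of construct, kcat, Km).
#' @export
make_plate <- function(specs, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  if (inherits(specs, "sim_spec")) specs <- list(.default = specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "sim_spec")))
  get_spec <- function(construct) {
    if (!is.null(names(specs)) && !is.na(construct) &&
        construct %in% names(specs)) {
      specs[[construct]]
    } else if (".default" %in% names(specs)) {
      specs[[".default"]]
    } else if (length(specs) == 1) {
      specs[[1]]
    } else {
      stop("no simulation spec for construct '", construct, "'",
           call. = FALSE)
    }
  }
  ts <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    spec <- get_spec(row$construct)
    times <- seq(0, spec$duration, by = spec$interval)
    curve <- switch(row$role,
      sample = ,
      pos_control = integrated_mm_curve(
        spec, row$substrate_conc, stream = i,
        enzyme_conc = if (is.na(row$enzyme_conc)) NULL else row$enzyme_conc),
      neg_control = ,
      enzyme_free_control = integrated_mm_curve(
        spec, row$substrate_conc, stream = i, enzyme_conc = 0),
      standard = {
        sig <- rep(spec$gain * row$substrate_conc + spec$background,
                   length(times))
        if (spec$noise_sd > 0) {
          sig <- sig + withr::with_seed(
            derive_seed(spec$seed, i),
            stats::rnorm(length(times), 0, spec$noise_sd))
        }
        progress_curve(times, sig, substrate_conc = row$substrate_conc,
                       conc_unit = spec$conc_unit)
      }
    )
    ts[[i]] <- tibble::tibble(well = row$well, time_s = curve$times,
                              signal = curve$signals)
  }
  constructs <- unique(stats::na.omit(layout$construct))
  gt <- tibble::tibble(
    construct = constructs,
    kcat = vapply(constructs, function(cc) get_spec(cc)$kcat, 0,
                  USE.NAMES = FALSE),
    Km = vapply(constructs, function(cc) get_spec(cc)$Km, 0,
                USE.NAMES = FALSE),
    conc_unit = vapply(constructs, function(cc) get_spec(cc)$conc_unit, "",
                       USE.NAMES = FALSE)
  )
  structure(
    list(timeseries = dplyr::bind_rows(ts), layout = layout,
         ground_truth = gt),
    class = "plate_data"
  )
}

#' @export
print.plate_data <- function(x, ...) {
  cat(sprintf("<plate_data> %d wells, %d time points/well (median)\n",
              nrow(x$layout),
              stats::median(table(x$timeseries$well))))
  print(table(x$layout$role))
  invisible(x)
}
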