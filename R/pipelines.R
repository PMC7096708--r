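# End-to-end assay pipelines: standards -> progress curves -> initial rates
# -> Michaelis-Menten parameters, one orchestration per assay chemistry,
# plus on-plate normalization for the directed-evolution screen.

#' Assay pipeline configuration
#'
#' Encodes the per-assay processing policy:
#' \describe{
#'   \item{four_mu}{continuous gain-of-fluorescence from 4MU release;
#'     standards linear to 50 uM; relaxation fit, v0 -> uM/s.}
#'   \item{clearance}{loss of OD680 scattering as insoluble chitin clears;
#'     calibration linear to 0.5 % w/v; curves re-zeroed at their initial
#'     state before fitting (negative amplitudes).}
#'   \item{ferricyanide}{endpoint loss of A420; calibration linear to
#'     250 uM; rate = (max - min) / chitinase incubation time.}
#'   \item{chito}{continuous coupled oxidase/peroxidase fluorescence;
#'     calibration linear to 30 uM; matched chitinase-free control
#'     subtracted before fitting.}
#' }
#'
#' @param assay One of `"four_mu"`, `"clearance"`, `"ferricyanide"`,
#'   `"chito"`.
#' @param linear_max Standard-curve linear-range ceiling (default per
#'   assay, see [default_linear_max()]).
#' @param substrate_unit Unit of the substrate concentration axis (Km
#'   unit): uM/mM for oligomers, % w/v for bulk chitin.
#' @param product_unit Unit of the calibrated product axis (defaults to
#'   `substrate_unit`).
#' @param direction `"gain"` or `"loss"` of signal with product formation.
#' @param endpoint Endpoint assay (ferricyanide only).
#' @param control_policy `"none"` or `"enzyme_free_subtract"` (chito only).
#' @param enzyme_conc Default enzyme concentration, nM, used when the
#'   layout does not carry one.
#' @param incubation_time Chitinase incubation time, s (endpoint assays).
#' @param max_components Cap on exponential components in [auto_fit()].
#' @param p_threshold Runs-test threshold for residual structure.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(assay = c("four_mu", "clearance", "ferricyanide",
                                   "chito"),
                         linear_max = NULL, substrate_unit = NULL,
                         product_unit = NULL, direction = NULL,
                         endpoint = NULL, control_policy = NULL,
                         enzyme_conc = NULL, incubation_time = NULL,
                         max_components = 2, p_threshold = 0.01) {
  assay <- match.arg(assay)
  defaults <- list(
    four_mu = list(linear_max = 50, substrate_unit = "uM",
                   product_unit = "uM", direction = "gain",
                   endpoint = FALSE, control_policy = "none",
                   enzyme_conc = 10, incubation_time = NA_real_),
    clearance = list(linear_max = 0.5, substrate_unit = "percent_wv",
                     product_unit = "percent_wv", direction = "loss",
                     endpoint = FALSE, control_policy = "none",
                     enzyme_conc = 100, incubation_time = NA_real_),
    ferricyanide = list(linear_max = 250, substrate_unit = "percent_wv",
                        product_unit = "uM", direction = "loss",
                        endpoint = TRUE, control_policy = "none",
                        enzyme_conc = 10, incubation_time = 18 * 3600),
    chito = list(linear_max = 30, substrate_unit = "percent_wv",
                 product_unit = "uM", direction = "gain",
                 endpoint = FALSE,
                 control_policy = "enzyme_free_subtract",
                 enzyme_conc = 2, incubation_time = NA_real_)
  )[[assay]]
  cfg <- list(
    assay = assay,
    linear_max = linear_max %||% defaults$linear_max,
    substrate_unit = substrate_unit %||% defaults$substrate_unit,
    product_unit = product_unit %||% defaults$product_unit,
    direction = direction %||% defaults$direction,
    endpoint = endpoint %||% defaults$endpoint,
    control_policy = control_policy %||% defaults$control_policy,
    enzyme_conc = enzyme_conc %||% defaults$enzyme_conc,
    incubation_time = incubation_time %||% defaults$incubation_time,
    max_components = max_components,
    p_threshold = p_threshold
  )
  if (cfg$endpoint && assay != "ferricyanide") {
    stop("`endpoint = TRUE` is only valid for the ferricyanide assay",
         call. = FALSE)
  }
  if (cfg$control_policy == "enzyme_free_subtract" && assay != "chito") {
    stop("enzyme-free control subtraction is only valid for the chito assay",
         call. = FALSE)
  }
  if (!cfg$control_policy %in% c("none", "enzyme_free_subtract")) {
    stop("unknown control_policy", call. = FALSE)
  }
  structure(cfg, class = "assay_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a plate's long time series into per-well progress curves joined to
# layout metadata.
plate_curves <- function(timeseries, layout) {
  stopifnot(all(c("well", "time_s", "signal") %in% names(timeseries)))
  unknown <- setdiff(unique(timeseries$well), layout$well)
  if (length(unknown)) {
    stop("time series contains wells absent from the layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  curves <- list()
  for (w in unique(timeseries$well)) {
    sub <- timeseries[timeseries$well == w, ]
    sub <- sub[order(sub$time_s), ]
    meta <- layout[layout$well == w, ]
    curves[[w]] <- progress_curve(
      sub$time_s, sub$signal,
      substrate_conc = meta$substrate_conc,
      enzyme_conc = meta$enzyme_conc,
      construct = meta$construct, role = meta$role, well = w,
      conc_unit = meta$conc_unit)
  }
  curves
}

# Standards table (concentration, signal) from wells with role == standard:
# each standard well contributes its mean signal.
standards_from_plate <- function(curves, layout) {
  std_wells <- layout$well[layout$role == "standard"]
  if (length(std_wells) == 0) return(NULL)
  tibble::tibble(
    concentration = vapply(std_wells, function(w)
      layout$substrate_conc[layout$well == w], 0),
    signal = vapply(std_wells, function(w) mean(curves[[w]]$signals), 0)
  )
}

#' Run a full assay pipeline on a plate
#'
#' Fits the standard curve from the plate's standard wells (or uses a
#' pre-fit one), processes every sample well into an initial rate according
#' to the assay policy, converts rates to product concentration per second
#' via the standard-curve slope, normalizes each rate by its well's enzyme
#' concentration (so mixed-enzyme plates are handled uniformly and `Vmax`
#' of the Michaelis-Menten fit is `kcat` directly), and fits one
#' Michaelis-Menten curve per construct on the pooled (un-averaged) rates.
#'
#' @param plate A [make_plate()] result, or a list with elements
#'   `timeseries` (long tibble `well`, `time_s`, `signal`) and `layout`
#'   (a [plate_layout()]).
#' @param config An [assay_config()].
#' @param standard_curve Optional pre-fit [fit_standard_curve()] result;
#'   otherwise standards are taken from the plate.
#' @param reference Optional reference construct name; fold changes of
#'   kcat, Km and kcat/Km relative to it are added to the table.
#' @return An object of class `assay_result`: `table` (per-construct
#'   tibble with kcat +/- SD, Km +/- SD, kcat/Km +/- SD, units, flags and,
#'   if requested, fold changes), `fits` (named list of `mm_fit`),
#'   `rates` (per-well tibble of rates and flags), `standard_curve`,
#'   `config`.
#' @export
run_assay <- function(plate, config, standard_curve = NULL,
                      reference = NULL) {
  stopifnot(inherits(config, "assay_config"))
  layout <- plate$layout
  curves <- plate_curves(plate$timeseries, layout)

  sc <- standard_curve
  if (is.null(sc)) {
    std <- standards_from_plate(curves, layout)
    if (is.null(std)) {
      stop("no standards on the plate and no `standard_curve` supplied",
           call. = FALSE)
    }
    sc <- fit_standard_curve(std, linear_max = config$linear_max,
                             conc_unit = config$product_unit)
  }

  sample_wells <- layout$well[layout$role == "sample"]
  if (length(sample_wells) == 0) stop("no sample wells", call. = FALSE)

  control_curves <- NULL
  if (config$control_policy == "enzyme_free_subtract") {
    ctl_wells <- layout$well[layout$role == "enzyme_free_control"]
    if (length(ctl_wells) == 0) {
      stop("chito pipeline requires enzyme-free control wells",
           call. = FALSE)
    }
    control_curves <- curves[ctl_wells]
    ctl_concs <- vapply(control_curves, function(cv) cv$substrate_conc, 0)
  }

  rows <- vector("list", length(sample_wells))
  for (i in seq_along(sample_wells)) {
    w <- sample_wells[i]
    cv <- curves[[w]]
    flags <- character(0)
    if (config$endpoint) {
      rate_signal <- endpoint_rate(cv, config$incubation_time)
      rate_se_signal <- NA_real_
    } else {
      if (config$assay == "clearance") cv <- subtract_initial(cv)
      if (!is.null(control_curves)) {
        j <- which.min(abs(ctl_concs - cv$substrate_conc))
        cv <- subtract_control(cv, control_curves[[j]])
      }
      fit <- auto_fit(cv, max_components = config$max_components,
                      p_threshold = config$p_threshold)
      flags <- fit$flags
      rate_signal <- if (config$direction == "loss") -fit$v0_signal else
        fit$v0_signal
      rate_se_signal <- fit$v0_se
    }
    rate_conc <- rate_to_concentration(sc, rate_signal)
    E_nM <- curves[[w]]$enzyme_conc
    if (is.na(E_nM)) E_nM <- config$enzyme_conc
    e_conv <- enzyme_nM_to_conc(E_nM, config$product_unit)
    rows[[i]] <- tibble::tibble(
      well = w, construct = curves[[w]]$construct,
      substrate_conc = curves[[w]]$substrate_conc,
      enzyme_conc = E_nM,
      rate_signal = rate_signal,
      rate = rate_conc,
      rate_se = rate_se_signal / abs(sc$slope),
      turnover = rate_conc / e_conv,
      flagged = any(flags %in% c("nonconvergence", "rate_indeterminate")),
      flags = paste(flags, collapse = ";")
    )
  }
  rates <- dplyr::bind_rows(rows)

  fits <- list()
  tab_rows <- list()
  for (cc in unique(rates$construct)) {
    sub <- rates[rates$construct == cc, ]
    ok <- sub[!sub$flagged, ]
    if (nrow(ok) < 4 || length(unique(ok$substrate_conc)) < 4) {
      tab_rows[[cc]] <- tibble::tibble(
        construct = cc, assay = config$assay,
        kcat = NA_real_, kcat_sd = NA_real_,
        Km = NA_real_, Km_sd = NA_real_,
        Km_unit = config$substrate_unit,
        efficiency = NA_real_, efficiency_sd = NA_real_,
        n_rates = nrow(ok), flags = "insufficient_rates")
      next
    }
    series <- rate_series(ok$substrate_conc, ok$turnover,
                          rate_se = ok$rate_se,
                          conc_unit = config$substrate_unit,
                          product_unit = config$product_unit,
                          normalized = TRUE)
    fit <- fit_michaelis_menten(series)
    fits[[cc]] <- fit
    tab_rows[[cc]] <- tibble::tibble(
      construct = cc, assay = config$assay,
      kcat = fit$kcat, kcat_sd = fit$kcat_se,
      Km = fit$Km, Km_sd = fit$se_Km,
      Km_unit = config$substrate_unit,
      efficiency = fit$efficiency, efficiency_sd = fit$efficiency_sd,
      n_rates = fit$n, flags = paste(fit$flags, collapse = ";"))
  }
  table <- dplyr::bind_rows(tab_rows)
  if (!is.null(reference)) {
    table <- add_fold_changes(table, reference)
  }
  structure(
    list(table = table, fits = fits, rates = rates, standard_curve = sc,
         config = config),
    class = "assay_result"
  )
}

# Fold-change columns (kcat, Km, efficiency vs a named reference construct).
add_fold_changes <- function(table, reference) {
  if (!reference %in% table$construct) {
    stop("unknown reference construct '", reference, "'", call. = FALSE)
  }
  ref <- table[table$construct == reference, ]
  fc <- function(v, vse, w, wse) {
    if (!is.finite(v) || !is.finite(w) || w == 0) {
      return(list(ratio = NA_real_, p_value = NA_real_))
    }
    fold_change(v, vse, w, wse)
  }
  n <- nrow(table)
  table$kcat_fold <- NA_real_
  table$kcat_fold_p <- NA_real_
  table$Km_fold <- NA_real_
  table$Km_fold_p <- NA_real_
  for (i in seq_len(n)) {
    if (table$construct[i] == reference) next
    a <- fc(table$kcat[i], table$kcat_sd[i], ref$kcat, ref$kcat_sd)
    b <- fc(table$Km[i], table$Km_sd[i], ref$Km, ref$Km_sd)
    table$kcat_fold[i] <- a$ratio
    table$kcat_fold_p[i] <- a$p_value
    table$Km_fold[i] <- b$ratio
    table$Km_fold_p[i] <- b$p_value
  }
  table
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %s pipeline, %d construct(s), %d rate(s)\n",
              x$config$assay, nrow(x$table), nrow(x$rates)))
  print(x$table)
  invisible(x)
}

#' Per-well activities for a screening plate
#'
#' Fits each non-standard well's progress curve and reports the initial
#' rate in signal units per second. No calibration is needed: the screen
#' score is scale- and offset-free after [normalize_screen()]. Wells whose
#' relaxation fit is rate-indeterminate (typically dead mutants: flat
#' noise, where the exponential's t = 0 derivative extrapolates wildly)
#' fall back to the linear-only member of the model family, whose slope is
#' well-behaved near zero activity.
#'
#' @param plate A plate (see [run_assay()]).
#' @param max_components Cap on exponential components per fit.
#' @return Tibble: `well`, `construct`, `role`, `activity` (signal/s),
#'   `flagged`.
#' @export
well_activities <- function(plate, max_components = 2) {
  layout <- plate$layout
  keep <- layout$role != "standard"
  curves <- plate_curves(
    plate$timeseries[plate$timeseries$well %in% layout$well[keep], ],
    layout)
  rows <- lapply(layout$well[keep], function(w) {
    fit <- auto_fit(curves[[w]], max_components = max_components)
    if ("rate_indeterminate" %in% fit$flags) {
      fit <- fit_relaxation(curves[[w]], n_components = 0,
                            include_linear = TRUE)
    }
    tibble::tibble(well = w,
                   construct = curves[[w]]$construct,
                   role = curves[[w]]$role,
                   activity = fit$v0_signal,
                   flagged = length(fit$flags) > 0)
  })
  dplyr::bind_rows(rows)
}

#' Normalize screen activities to on-plate controls
#'
#' Linear rescaling so that the mean catalytically-dead negative control
#' maps to 0 and the mean wild-type positive control maps to 1:
#' `score = (activity - mean(neg)) / (mean(pos) - mean(neg))`.
#' Normalization is strictly per-plate, since screening wells report the
#' combination of specific activity, expression and secretion, all of
#' which drift between plates.
#'
#' @param activities Tibble with columns `well` and `activity` (e.g. from
#'   [well_activities()]); a `construct` column is carried through.
#' @param pos_wells,neg_wells Well IDs of the positive (wild-type) and
#'   negative (dead) control wells; at least one of each.
#' @return Tibble: `well`, `construct` (if present), `normalized_activity`.
#' @export
normalize_screen <- function(activities, pos_wells, neg_wells) {
  stopifnot(is.data.frame(activities),
            all(c("well", "activity") %in% names(activities)))
  if (length(pos_wells) < 1 || length(neg_wells) < 1) {
    stop("need at least one positive and one negative control well",
         call. = FALSE)
  }
  missing <- setdiff(c(pos_wells, neg_wells), activities$well)
  if (length(missing)) {
    stop("control wells absent from activities: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos_mean <- mean(activities$activity[activities$well %in% pos_wells])
  neg_mean <- mean(activities$activity[activities$well %in% neg_wells])
  if (pos_mean == neg_mean) {
    stop("degenerate plate: positive and negative control means are equal",
         call. = FALSE)
  }
  out <- tibble::tibble(
    well = activities$well,
    normalized_activity = (activities$activity - neg_mean) /
      (pos_mean - neg_mean))
  if ("construct" %in% names(activities)) {
    out$construct <- activities$construct
    out <- out[, c("well", "construct", "normalized_activity")]
  }
  out
}
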