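# Canonical simulated experiments. Each assay scenario fixes the operating
# conditions of the corresponding bench protocol — enzyme concentration,
# substrate dilution series, read interval and duration — so that recovery
# tests and worked examples all run under one set of study conditions.
#
#   four_mu      10 nM enzyme, 4MU-chitobioside halving series 480..3.75 uM,
#                30 s reads for 30 min, gain-of-fluorescence.
#   clearance    100 nM enzyme, colloidal chitin 2..0.015625 % w/v, 20 min
#                reads for 72 h, loss of OD680 scattering.
#   ferricyanide 10 nM enzyme, chitin 0.4..0.003125 % w/v, 18 h incubation,
#                endpoint loss of A420.
#   chito        2 nM enzyme, chitin 2..0.015625 % w/v, 1 min reads for
#                16 h, coupled gain-of-fluorescence with a drifting
#                chitinase-free background.
#
# "noise_frac" scales the additive Gaussian noise to a fraction of the
# enzyme-dependent signal amplitude of the S0 = Km curve at the end of the
# read (so 0.05 is "5% noise" in curve-amplitude terms).

scenario_params <- function(assay) {
  switch(assay,
    four_mu = list(
      kcat = 1.5, Km = 33, conc_unit = "uM", enzyme_conc = 10,
      substrate_concs = serial_dilution(480, 8),
      gain = 100, background = 50, background_drift = 0,
      duration = 1800, interval = 30, assay_mode = "gain_fluor",
      standard_concs = c(1, 2, 5, 10, 20, 35, 50, 80, 100),
      linear_max = 50, incubation_time = NA_real_),
    clearance = list(
      kcat = 0.0014, Km = 0.09, conc_unit = "percent_wv",
      enzyme_conc = 100,
      substrate_concs = serial_dilution(2, 8),
      gain = 1, background = 0.05, background_drift = 0,
      duration = 259200, interval = 1200, assay_mode = "loss_scatter",
      standard_concs = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 1, 2),
      linear_max = 0.5, incubation_time = NA_real_),
    ferricyanide = list(
      kcat = 0.454, Km = 0.046, conc_unit = "percent_wv",
      enzyme_conc = 10,
      substrate_concs = serial_dilution(0.4, 8),
      gain = 100, background = 1.2, background_drift = 0,
      duration = 64800, interval = 600, assay_mode = "loss_abs_endpoint",
      standard_concs = c(0.0005, 0.001, 0.002, 0.004, 0.006, 0.008, 0.012),
      linear_max = 0.012, incubation_time = 64800),
    chito = list(
      kcat = 1.0, Km = 0.032, conc_unit = "percent_wv", enzyme_conc = 2,
      substrate_concs = serial_dilution(2, 8),
      gain = 3e4, background = 100, background_drift = 0.002,
      duration = 57600, interval = 60, assay_mode = "coupled_gain",
      standard_concs = c(0.0005, 0.001, 0.002, 0.004, 0.008, 0.012, 0.016),
      linear_max = 0.016, incubation_time = NA_real_),
    stop("unknown assay scenario: ", assay, call. = FALSE)
  )
}

# Enzyme-dependent signal amplitude of the S0 = Km curve at the end of the
# read, used to anchor the noise level.
scenario_amplitude <- function(p, kcat, Km) {
  Vmax <- kcat * enzyme_nM_to_conc(p$enzyme_conc, p$conc_unit)
  S_end <- mm_substrate_remaining(Km, Vmax, Km, p$duration)
  p$gain * (Km - S_end)
}

#' Simulate a canonical assay plate
#'
#' Builds a full synthetic plate for one of the four assay scenarios:
#' calibration standards, `n_replicates` sample wells per substrate
#' concentration per construct, and (for the chito scenario) one matched
#' enzyme-free control well per substrate concentration.
#'
#' @param assay One of `"four_mu"`, `"clearance"`, `"ferricyanide"`,
#'   `"chito"`.
#' @param constructs Named list of ground truths; each element is a list
#'   with `kcat` (1/s) and `Km` (scenario unit). Default: one `WT`
#'   construct at the scenario's reference values (four_mu: kcat 1.5/s,
#'   Km 33 uM; chito: kcat 1.0/s, Km 0.032 % w/v; clearance: 0.0014/s,
#'   0.09 % w/v; ferricyanide: 0.454/s, 0.046 % w/v).
#' @param seed Integer seed (reproducible plates).
#' @param noise_frac Noise sd as a fraction of the enzyme-dependent signal
#'   amplitude of the S0 = Km curve (default 0.05).
#' @param n_replicates Sample wells per (construct, concentration)
#'   (default 3).
#' @return A `plate_data` (see [make_plate()]) whose `config` element is a
#'   matching [assay_config()].
#' @export
simulate_assay_plate <- function(assay = c("four_mu", "clearance",
                                           "ferricyanide", "chito"),
                                 constructs = NULL, seed = 1L,
                                 noise_frac = 0.05, n_replicates = 3) {
  assay <- match.arg(assay)
  p <- scenario_params(assay)
  if (is.null(constructs)) {
    constructs <- list(WT = list(kcat = p$kcat, Km = p$Km))
  }
  specs <- list()
  for (nm in names(constructs)) {
    tr <- constructs[[nm]]
    amp <- scenario_amplitude(p, tr$kcat, tr$Km)
    specs[[nm]] <- simulation_spec(
      kcat = tr$kcat, Km = tr$Km, enzyme_conc = p$enzyme_conc,
      substrate_concs = p$substrate_concs, gain = p$gain,
      background = p$background, background_drift = p$background_drift,
      noise_sd = noise_frac * abs(amp), duration = p$duration,
      interval = p$interval, seed = seed, assay_mode = p$assay_mode,
      conc_unit = p$conc_unit)
  }
  first <- names(constructs)[1]

  wells <- character(0); roles <- character(0); cons <- character(0)
  concs <- numeric(0); enz <- numeric(0)
  idx <- 0
  nw <- function() { idx <<- idx + 1; sprintf("W%03d", idx) }
  for (sc in p$standard_concs) {
    wells <- c(wells, nw()); roles <- c(roles, "standard")
    cons <- c(cons, first); concs <- c(concs, sc); enz <- c(enz, 0)
  }
  for (nm in names(constructs)) {
    for (s0 in p$substrate_concs) {
      for (r in seq_len(n_replicates)) {
        wells <- c(wells, nw()); roles <- c(roles, "sample")
        cons <- c(cons, nm); concs <- c(concs, s0)
        enz <- c(enz, p$enzyme_conc)
      }
    }
  }
  if (assay == "chito") {
    for (s0 in p$substrate_concs) {
      wells <- c(wells, nw()); roles <- c(roles, "enzyme_free_control")
      cons <- c(cons, first); concs <- c(concs, s0); enz <- c(enz, 0)
    }
  }
  layout <- plate_layout(wells, roles, construct = cons,
                         substrate_conc = concs, enzyme_conc = enz,
                         conc_unit = p$conc_unit)
  plate <- make_plate(specs, layout)
  plate$config <- assay_config(
    assay,
    linear_max = p$linear_max,
    substrate_unit = p$conc_unit,
    product_unit = p$conc_unit,
    enzyme_conc = p$enzyme_conc,
    incubation_time = p$incubation_time)
  plate
}

#' Simulate a directed-evolution screening plate
#'
#' One 4MU-chitobioside progress curve per well at a single substrate
#' concentration: dead negative-control wells (no enzyme activity),
#' wild-type positive-control wells, and mutant wells whose specific
#' activity is a stated multiple of wild-type (equal expression).
#'
#' @param multipliers Named numeric vector of kcat multiples of wild-type
#'   for the mutant wells (e.g. `c(mut5x = 5, dud = 0.1)`); one well each.
#' @param n_pos,n_neg Numbers of wild-type and dead control wells.
#' @param S0 Screening substrate concentration, uM (default 10.8, half of
#'   the 21.6 uM stock after 1:1 mixing with the expression media).
#' @param seed Integer seed.
#' @param noise_frac Noise sd as a fraction of the wild-type screen
#'   curve's enzyme-dependent amplitude.
#' @param enzyme_conc Secreted enzyme concentration in the screening
#'   well, nM. The default (2 nM) keeps even a ~5x hit in the
#'   initial-rate regime over the read: screen scores are rate ratios,
#'   and a well that exhausts its substrate mid-read has no valid
#'   initial rate to rank.
#' @param interval Read interval, s (default 10 s, a standard kinetic
#'   screening read).
#' @param duration Total read time, s.
#' @return A `plate_data`; control wells are identifiable by role.
#' @export
simulate_screen_plate <- function(multipliers = c(mut5x = 5), n_pos = 4,
                                  n_neg = 4, S0 = 10.8, seed = 1L,
                                  noise_frac = 0.05, enzyme_conc = 2,
                                  interval = 10, duration = 1800) {
  p <- scenario_params("four_mu")
  wt_vmax <- p$kcat * enzyme_nM_to_conc(enzyme_conc, p$conc_unit)
  wt_amp <- p$gain * (S0 - mm_substrate_remaining(S0, wt_vmax, p$Km,
                                                  duration))
  mk_spec <- function(kcat_mult) {
    simulation_spec(
      kcat = p$kcat * kcat_mult, Km = p$Km, enzyme_conc = enzyme_conc,
      substrate_concs = S0, gain = p$gain, background = p$background,
      noise_sd = noise_frac * abs(wt_amp),
      duration = duration, interval = interval, seed = seed,
      assay_mode = "gain_fluor", conc_unit = p$conc_unit)
  }
  specs <- list(WT = mk_spec(1))
  for (nm in names(multipliers)) specs[[nm]] <- mk_spec(multipliers[[nm]])

  wells <- character(0); roles <- character(0); cons <- character(0)
  idx <- 0
  nw <- function() { idx <<- idx + 1; sprintf("S%03d", idx) }
  for (i in seq_len(n_neg)) {
    wells <- c(wells, nw()); roles <- c(roles, "neg_control")
    cons <- c(cons, "dead")
  }
  for (i in seq_len(n_pos)) {
    wells <- c(wells, nw()); roles <- c(roles, "pos_control")
    cons <- c(cons, "WT")
  }
  for (nm in names(multipliers)) {
    wells <- c(wells, nw()); roles <- c(roles, "sample")
    cons <- c(cons, nm)
  }
  specs$dead <- mk_spec(1) # dead wells are simulated with zero enzyme
  layout <- plate_layout(wells, roles, construct = cons,
                         substrate_conc = S0,
                         enzyme_conc = ifelse(roles == "neg_control", 0,
                                              enzyme_conc),
                         conc_unit = p$conc_unit)
  make_plate(specs, layout)
}
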