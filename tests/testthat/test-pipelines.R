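# End-to-end pipeline behaviour: configuration policy, recovery on the
# endpoint and clearance assays, invariances, and screen normalization.
# (The four_mu and chito recovery runs at the reference ground truths live
# in test-acceptance.R.)

test_that("assay configs enforce the per-assay processing policy", {
  cfg <- assay_config("four_mu")
  expect_equal(cfg$linear_max, 50)
  expect_false(cfg$endpoint)
  expect_equal(assay_config("clearance")$direction, "loss")
  expect_equal(assay_config("ferricyanide")$incubation_time, 64800)
  expect_equal(assay_config("chito")$control_policy, "enzyme_free_subtract")
  expect_error(assay_config("four_mu", endpoint = TRUE), "ferricyanide")
  expect_error(assay_config("clearance",
                            control_policy = "enzyme_free_subtract"),
               "chito")
})

test_that("doubling the simulated gain leaves recovered parameters alone", {
  run_with_gain <- function(gain_mult) {
    plate <- simulate_assay_plate("four_mu", seed = 5)
    # rescale every signal and the standards together, as a detector
    # gain change would
    plate$timeseries$signal <- plate$timeseries$signal * gain_mult
    run_assay(plate, plate$config)
  }
  r1 <- run_with_gain(1)
  r2 <- run_with_gain(2)
  # the calibration absorbs the gain exactly: every well's converted rate
  # is invariant
  expect_equal(r2$rates$rate, r1$rates$rate, tolerance = 1e-6)
  expect_equal(r2$standard_curve$slope, 2 * r1$standard_curve$slope,
               tolerance = 1e-9)
  # the MM table may differ slightly: LM iteration paths are not
  # scale-free, so a marginal well's convergence flag (and hence its
  # inclusion) can flip
  expect_equal(r2$table$kcat, r1$table$kcat, tolerance = 0.10)
  expect_equal(r2$table$Km, r1$table$Km, tolerance = 0.10)
})

test_that("a zero-enzyme plate is all flagged and yields no MM fit", {
  plate <- simulate_assay_plate("four_mu", seed = 9, n_replicates = 2)
  plate$layout$enzyme_conc[plate$layout$role == "sample"] <- 0
  dead <- make_plate(
    list(WT = simulation_spec(
      kcat = 1.5, Km = 33, enzyme_conc = 10,
      substrate_concs = serial_dilution(480, 8), gain = 100,
      background = 50, noise_sd = 3, duration = 1800, interval = 30,
      seed = 9L, conc_unit = "uM")),
    plate$layout)
  res <- run_assay(dead, plate$config)
  expect_true(all(res$rates$flagged))
  expect_equal(res$table$flags, "insufficient_rates")
  expect_true(is.na(res$table$kcat))
})

test_that("chito pipeline demands enzyme-free controls", {
  plate <- simulate_assay_plate("chito", seed = 2, n_replicates = 1)
  keep <- plate$layout$role != "enzyme_free_control"
  plate$layout <- plate$layout[keep, ]
  class(plate$layout) <- c("plate_layout", "tbl_df", "tbl", "data.frame")
  plate$timeseries <- plate$timeseries[
    plate$timeseries$well %in% plate$layout$well, ]
  expect_error(run_assay(plate, plate$config), "enzyme-free control")
})

test_that("drift-bearing chito plates match drift-free plates within 1 SE", {
  plate_drift <- simulate_assay_plate("chito", seed = 8)
  res_drift <- run_assay(plate_drift, plate_drift$config)
  # same kinetics and noise seed, drift disabled
  p <- chitkin:::scenario_params("chito")
  amp <- chitkin:::scenario_amplitude(p, 1.0, 0.032)
  spec_free <- simulation_spec(
    kcat = 1.0, Km = 0.032, enzyme_conc = 2,
    substrate_concs = p$substrate_concs, gain = p$gain,
    background = p$background, background_drift = 0,
    noise_sd = 0.05 * amp, duration = p$duration, interval = p$interval,
    seed = 8L, assay_mode = "coupled_gain", conc_unit = "percent_wv")
  plate_free <- make_plate(list(WT = spec_free), plate_drift$layout)
  res_free <- run_assay(plate_free, plate_drift$config)
  se <- sqrt(res_drift$table$kcat_sd^2 + res_free$table$kcat_sd^2)
  expect_lt(abs(res_drift$table$kcat - res_free$table$kcat), se)
})

test_that("ferricyanide endpoint pipeline recovers the MM parameters", {
  # 5 mAU per-read instrument noise (typical A420 plate-reader figure)
  plate <- simulate_assay_plate("ferricyanide", seed = 1,
                                noise_frac = 0.017)
  res <- run_assay(plate, plate$config)
  expect_lt(abs(res$table$kcat - 0.454) / 0.454, 0.10)
  expect_lt(abs(res$table$Km - 0.046) / 0.046, 0.15)
})

test_that("endpoint max-min rates carry a noise floor that deflates Km", {
  # (max - min) can never fall below the noise range, so low-substrate
  # rates are inflated and the fitted Km shrinks as noise grows: a known
  # limitation of the endpoint estimator, asserted directionally.
  km_at <- function(nf) {
    plate <- simulate_assay_plate("ferricyanide", seed = 4, noise_frac = nf)
    run_assay(plate, plate$config)$table$Km
  }
  expect_lt(km_at(0.05), km_at(0.005))
})

test_that("clearance pipeline recovers parameters from scattering loss", {
  plate <- simulate_assay_plate("clearance", seed = 1, noise_frac = 0.01)
  res <- run_assay(plate, plate$config)
  expect_lt(abs(res$table$kcat - 0.0014) / 0.0014, 0.20)
  expect_lt(abs(res$table$Km - 0.09) / 0.09, 0.20)
})

test_that("screen scores map controls to 0 and 1 by construction", {
  act <- tibble::tibble(well = c("A1", "A2", "B1", "B2", "C1"),
                        activity = c(0.1, 0.3, 1.9, 2.1, 1.2))
  sc <- normalize_screen(act, pos_wells = c("B1", "B2"),
                         neg_wells = c("A1", "A2"))
  expect_equal(sc$normalized_activity[sc$well == "C1"],
               (1.2 - 0.2) / (2.0 - 0.2))
  expect_equal(mean(sc$normalized_activity[1:2]), 0)
  expect_equal(mean(sc$normalized_activity[3:4]), 1)
  expect_error(normalize_screen(act, "B1", "B1"), "degenerate")
  expect_error(normalize_screen(act, "Z9", "A1"), "absent")
})

test_that("pipeline errors on missing standards", {
  plate <- simulate_assay_plate("four_mu", seed = 3, n_replicates = 1)
  keep <- plate$layout$role != "standard"
  plate$layout <- plate$layout[keep, ]
  class(plate$layout) <- c("plate_layout", "tbl_df", "tbl", "data.frame")
  plate$timeseries <- plate$timeseries[
    plate$timeseries$well %in% plate$layout$well, ]
  expect_error(run_assay(plate, plate$config), "standard")
  # but a pre-fit standard curve substitutes
  sc <- fit_standard_curve(
    data.frame(concentration = c(0, 10, 20, 40),
               signal = 100 * c(0, 10, 20, 40) + 50), linear_max = 50)
  res <- run_assay(plate, plate$config, standard_curve = sc)
  expect_false(is.na(res$table$kcat))
})
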