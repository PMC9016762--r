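# The synthetic plate-experiment generator: determinism, design arithmetic,
# noiseless closure and QC behavior.

test_that("same seed reproduces curves and experiments exactly", {
  s <- default_strains()$lab_ref
  p <- default_perturbations()$furfural_2gL
  w1 <- simulate_growth_curve(s, p, noise_sd = 0.05, seed = 99)
  w2 <- simulate_growth_curve(s, p, noise_sd = 0.05, seed = 99)
  expect_identical(w1$values, w2$values)
  sim1 <- simulate_experiment(strains = default_strains()[1:2],
                              perturbations = default_perturbations()[1:4],
                              seed = 17)
  sim2 <- simulate_experiment(strains = default_strains()[1:2],
                              perturbations = default_perturbations()[1:4],
                              seed = 17)
  expect_identical(sim1$endpoints, sim2$endpoints)
  expect_identical(sim1$timeseries$P1_A3$values, sim2$timeseries$P1_A3$values)
  sim3 <- simulate_experiment(strains = default_strains()[1:2],
                              perturbations = default_perturbations()[1:4],
                              seed = 18)
  expect_false(identical(sim1$endpoints$ethanol, sim3$endpoints$ethanol))
})

test_that("default design is 3 plates x 87 wells with 29 conditions", {
  expect_length(default_perturbations(), 29)
  sim <- simulate_experiment(noise = NULL, seed = 1)
  expect_equal(nrow(sim$layout), 3 * 29 * 3)
  expect_equal(length(unique(sub("_.*", "", sim$layout$well_id))), 3)
  expect_equal(sum(sim$layout$is_control), 3 * 3)
  expect_equal(nrow(sim$ground_truth), nrow(sim$layout))
})

test_that("noiseless curves are recovered by the fitting pipeline", {
  p_ctrl <- default_perturbations()$glucose_20gL
  p_hard <- default_perturbations()$furfural_3gL
  for (s in default_strains()) {
    for (p in list(p_ctrl, p_hard)) {
      w <- simulate_growth_curve(s, p, noise_sd = 0)
      truth <- attr(w, "truth")
      fit <- compute_lag(apply_qc(fit_growth_curve(w, blank = 26.3)))
      expect_true(fit$grew)
      expect_equal(fit$mu_max, truth$mu, tolerance = 0.05)
      expect_lt(abs(fit$lag - truth$lag_tangent), 0.5)
    }
  }
})

test_that("growth-abolishing condition fails QC even under noise", {
  s <- default_strains()$lab_ref
  p <- default_perturbations()$furfural_4gL
  w0 <- simulate_growth_curve(s, p, noise_sd = 0, seed = 1)
  f0 <- apply_qc(fit_growth_curve(w0, blank = 26.3))
  expect_false(f0$grew)
  expect_equal(f0$mu_max, 0)
  wn <- simulate_growth_curve(s, p, noise_sd = 0.02, seed = 2)
  fn <- apply_qc(fit_growth_curve(wn, blank = 26.3))
  expect_false(fn$grew)
  expect_true(is.na(compute_lag(fn)$lag))
})

test_that("noiseless endpoints invert to the effective ground-truth yields", {
  strains <- default_strains()
  perts <- default_perturbations()
  for (s in strains) {
    for (pname in c("glucose_20gL", "acetic_4gL", "xylose_20gL")) {
      p <- perts[[pname]]
      ep <- simulate_endpoints(s, p, conc_sd = 0, od_sd = 0)
      truth <- attr(ep, "truth")
      consumed <- consumed_sugars(ep)
      expect_equal(consumed, truth$consumed, tolerance = 1e-12)
      expect_equal(ethanol_yield(ep$ethanol, consumed),
                   truth$ethanol_yield, tolerance = 1e-12)
      cal <- calibration_model(cdw_slopes = sim_cdw_slopes(strains))
      cdw_f <- cdw_from_od(ep$od600_48h, s$name, cal)
      cdw_i <- cdw_from_od(0.02, s$name, cal)
      expect_equal(biomass_yield(cdw_f, cdw_i, consumed),
                   truth$biomass_yield, tolerance = 1e-12)
    }
  }
  # zero consumption propagates to missing yields
  ep0 <- simulate_endpoints(default_strains()$lab_ref,
                            default_perturbations()$furfural_4gL)
  expect_equal(attr(ep0, "truth")$consumed, 0)
  expect_warning(y0 <- ethanol_yield(ep0$ethanol, 0), "undefined")
  expect_true(is.na(y0))
})

test_that("single replicate leaves the SEM missing downstream", {
  sim <- simulate_experiment(strains = default_strains()[1],
                             perturbations = default_perturbations()[1:5],
                             n_replicates = 1, noise = NULL, seed = 3)
  cal <- calibration_model(cdw_slopes = sim_cdw_slopes(sim$strains))
  bundle <- suppressWarnings(run_pipeline(sim$timeseries, sim$layout,
                                          sim$endpoints, cal = cal))
  expect_true(all(is.na(bundle$robustness$sem)))
})

test_that("invalid generator inputs are rejected", {
  s <- default_strains()$lab_ref
  p <- default_perturbations()$glucose_20gL
  expect_error(simulate_growth_curve(s, p, noise_sd = -0.1), ">= 0")
  expect_error(perturbation_spec("x", mu_mult = -1), ">= 0")
  expect_error(perturbation_spec("x", consumed_frac = 1.2), "\\[0, 1\\]")
  expect_error(strain_spec("x", mu_max = 0.3, lag = 2, ethanol_yield = 1.2,
                           biomass_yield = 0.1, cdw_slope = 0.5,
                           capacity_gv = 100))
})
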