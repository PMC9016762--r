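# Consumed sugars, yields, CDW calibration and function-table assembly.

ep_row <- function(glc_i = 20, glc_f = 2, xyl_i = 0, xyl_f = 0,
                   ethanol = 8, od = 2, well = "A1") {
  data.frame(well_id = well, glucose_initial = glc_i, glucose_final = glc_f,
             mannose_initial = 0, mannose_final = 0,
             xylose_initial = xyl_i, xylose_final = xyl_f,
             galactose_initial = 0, galactose_final = 0,
             arabinose_initial = 0, arabinose_final = 0,
             ethanol = ethanol, od600_48h = od, stringsAsFactors = FALSE)
}

test_that("consumed sugars sum per-sugar differences, zeroing negatives", {
  expect_equal(consumed_sugars(ep_row(20, 2, 10, 10)), 18)
  row5 <- ep_row(1, 0)
  for (s in c("mannose", "xylose", "galactose", "arabinose")) {
    row5[[paste0(s, "_initial")]] <- 1
    row5[[paste0(s, "_final")]] <- 0
  }
  expect_equal(consumed_sugars(row5), 5)
  expect_warning(v <- consumed_sugars(ep_row(20, 2, 10, 11)), "set to 0")
  expect_equal(v, 18)
  no_substrate <- ep_row(0, 0, 0, 0)
  expect_error(consumed_sugars(no_substrate), "no substrate")
})

test_that("yields follow their defining ratios and handle zero consumption", {
  expect_equal(ethanol_yield(8, 20), 0.40)
  expect_equal(ethanol_yield(0, 20), 0)
  expect_warning(na_y <- ethanol_yield(8, 0), "undefined")
  expect_true(is.na(na_y))
  expect_equal(biomass_yield(1.02, 0.02, 10), 0.10)
  expect_equal(biomass_yield(0.5, 0.5, 10), 0)
  expect_warning(floored <- biomass_yield(0.3, 0.5, 10), "floored")
  expect_equal(floored, 0)
  expect_warning(na_b <- biomass_yield(1, 0, 0), "undefined")
  expect_true(is.na(na_b))
})

test_that("CDW uses the per-strain slope", {
  cal <- calibration_model(cdw_slopes = c(S1 = 0.5, S2 = 0.6))
  expect_equal(cdw_from_od(2.0, "S1", cal), 1.0)
  expect_equal(cdw_from_od(0, "S1", cal), 0)
  expect_false(cdw_from_od(2, "S1", cal) == cdw_from_od(2, "S2", cal))
  expect_error(cdw_from_od(2, "S9", cal), "no CDW slope")
})

test_that("assembly gives five records per well with correct lag handling", {
  layout <- tiny_layout(n_strains = 1, n_cond = 2, n_rep = 3)
  cal <- calibration_model(cdw_slopes = c(S1 = 0.5))
  fits <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    data.frame(well_id = layout$well_id[i], strain = layout$strain[i],
               condition_id = layout$condition_id[i],
               replicate = layout$replicate[i],
               is_control = layout$is_control[i],
               mu_max = 0.3, lag = 2.5, r_squared = 0.999, y0 = 0,
               inflection_time = 8, inflection_value = 2, grew = TRUE,
               stringsAsFactors = FALSE)
  }))
  eps <- do.call(rbind, lapply(layout$well_id, function(w) ep_row(well = w)))
  eps <- validate_endpoints(eps)
  ft <- assemble_function_table(fits, eps, layout, cal)
  expect_equal(nrow(ft), 5 * 6)
  expect_setequal(unique(ft$fun),
                  c("mu_max", "lag", "cdw", "biomass_yield", "ethanol_yield"))
  # ethanol yield 8 / 18, cdw 2 * 0.5
  expect_equal(unique(ft$value[ft$fun == "ethanol_yield"]), 8 / 18)
  expect_equal(unique(ft$value[ft$fun == "cdw"]), 1.0)
  # inoculum subtracted in the biomass yield: (1.0 - 0.02*0.5)/18
  expect_equal(unique(ft$value[ft$fun == "biomass_yield"]),
               (1.0 - 0.02 * 0.5) / 18)
  expect_equal(unique(ft$value[ft$fun == "biomass_yield"]),
               1.0 / 18, tolerance = 0.02)
  # a QC-failed well: mu_max record 0, lag record missing
  fits2 <- fits
  fits2$mu_max[1] <- 0
  fits2$lag[1] <- NA
  fits2$grew[1] <- FALSE
  ft2 <- assemble_function_table(fits2, eps, layout, cal)
  w1 <- layout$well_id[1]
  r1 <- ft2[ft2$condition_id == fits2$condition_id[1] &
              ft2$replicate == fits2$replicate[1], ]
  expect_equal(r1$value[r1$fun == "mu_max"], 0)
  expect_true(is.na(r1$value[r1$fun == "lag"]))
  expect_equal(attr(ft2, "n_missing")[["lag"]], 1)
  # record-count identity: 5 x wells, with missing lag still a record
  expect_equal(nrow(ft2), 5 * 6)
})

test_that("wells without endpoints keep growth functions only, with warning", {
  layout <- tiny_layout(n_strains = 1, n_cond = 1, n_rep = 2, control = FALSE)
  cal <- calibration_model(cdw_slopes = c(S1 = 0.5))
  fits <- data.frame(well_id = layout$well_id, strain = "S1",
                     condition_id = "cond1", replicate = 1:2,
                     is_control = FALSE, mu_max = 0.3, lag = 2,
                     r_squared = 0.999, y0 = 0, inflection_time = 8,
                     inflection_value = 2, grew = TRUE,
                     stringsAsFactors = FALSE)
  eps <- validate_endpoints(ep_row(well = layout$well_id[1]))
  expect_warning(ft <- assemble_function_table(fits, eps, layout, cal),
                 "no endpoint row")
  expect_equal(sum(ft$replicate == 2), 2)  # mu_max + lag only
  expect_equal(sum(ft$replicate == 1), 5)
})

test_that("empty inputs give an empty table; registry is extensible", {
  empty <- assemble_function_table(NULL, NULL, tiny_layout(),
                                   calibration_model())
  expect_s3_class(empty, "function_table")
  expect_equal(nrow(empty), 0)
  register_function("biosensor_gfp", "AU")
  expect_true("biosensor_gfp" %in% names(known_functions()))
  expect_equal(known_functions()[["mu_max"]], "1/h")
})
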