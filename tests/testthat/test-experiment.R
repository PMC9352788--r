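test_that("dilution formulas reproduce the reference bivalent series", {
  conc <- biv_conc
  expect_equal(nrow(conc), 14L)
  # high-precision evaluation of l_1 with the schedule constants
  expect_equal(conc$l[1], 4.85268572505824e-4, tolerance = 1e-10)
  expect_equal(conc$m[1], 0.0709507798960139, tolerance = 1e-10)
  # l increases, m decreases, everything positive
  expect_true(all(diff(conc$l) > 0))
  expect_true(all(diff(conc$m) < 0))
  expect_true(all(conc$l > 0 & conc$m > 0))
  # both reference titrations pass the molar ratio 0.3 used for weighting
  expect_gt(conc$molar_ratio[14], 0.3)
  expect_gt(tri_conc$molar_ratio[14], 0.3)
})

test_that("dilution-free limit and scale consistency of the concentrations", {
  tiny <- titration_schedule(V0 = 1.442, injection_volumes = 1e-9,
                             c_L = 0.7, c_M = 0.071)
  conc <- total_concentrations(tiny)
  expect_equal(conc$l[1], 0, tolerance = 1e-9)
  expect_equal(conc$m[1], 0.071, tolerance = 1e-8)
  # doubling both concentrations doubles l and m elementwise
  doubled <- titration_schedule(V0 = 1.442,
                                injection_volumes = biv$schedule$injection_volumes,
                                c_L = 2 * 0.7, c_M = 2 * 0.071)
  conc2 <- total_concentrations(doubled)
  expect_identical(conc2$l, 2 * biv_conc$l)
  expect_identical(conc2$m, 2 * biv_conc$m)
})

test_that("invalid schedules are rejected with informative errors", {
  expect_error(titration_schedule(V0 = -1, injection_volumes = 0.01,
                                  c_L = 1, c_M = 1), "V0")
  expect_error(titration_schedule(V0 = 1.442, injection_volumes = c(0.01, -0.01),
                                  c_L = 1, c_M = 1), "positive")
  expect_error(titration_schedule(V0 = 0.05, injection_volumes = rep(0.01, 11),
                                  c_L = 1, c_M = 1), "2 \\* V0")
  expect_error(heat_series(c(1, NA)), "finite")
  expect_error(power_trace(c(0, 1, 1), c(0, 0, 0), 0), "increasing")
})

test_that("experiments round-trip through the JSON + CSV interface", {
  cfg <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  h <- heat_series(seq(-60, -5, length.out = 14), excluded = 1L)
  write_experiment(biv$schedule, h, cfg, csv)
  back <- read_experiment(cfg, csv)
  expect_equal(back$schedule$V0, biv$schedule$V0)
  expect_equal(back$schedule$injection_volumes, biv$schedule$injection_volumes)
  expect_equal(back$heats$q, h$q)
  expect_equal(back$heats$excluded, 1L)

  # malformed inputs are rejected at the field level
  writeLines('{"V0_ml": 1.442}', cfg)
  expect_error(read_experiment(cfg, csv), "c_L_mmol_per_l")
  jsonlite::write_json(list(V0_ml = 1.442, c_L_mmol_per_l = 0.7,
                            c_M_mmol_per_l = 0.071,
                            injection_volumes_ml = c(0.001, -0.01)),
                       cfg, auto_unbox = TRUE)
  expect_error(read_experiment(cfg, csv), "positive")
})

test_that("power traces read back as traces when injection times are present", {
  cfg <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  jsonlite::write_json(list(V0_ml = 1.442, c_L_mmol_per_l = 0.7,
                            c_M_mmol_per_l = 0.071, valency = 2,
                            injection_volumes_ml = c(0.001, 0.01),
                            injection_times_s = c(0, 120)),
                       cfg, auto_unbox = TRUE)
  write.csv(data.frame(time_s = 0:239, power_ucal_per_s = 0),
            csv, row.names = FALSE)
  back <- read_experiment(cfg, csv)
  expect_s3_class(back$trace, "power_trace")
  expect_length(back$trace$injection_times, 2L)
})
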