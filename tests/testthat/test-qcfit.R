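test_that("Gaussian weights: peak, symmetry, one-sigma value, exclusions", {
  spec <- weight_spec(mu = 0.3, sigma = 0.1758, excluded = 1L)
  expect_equal(gaussian_weights(0.3, weight_spec()), 1)
  d <- 0.123
  expect_equal(gaussian_weights(0.3 + d, weight_spec()),
               gaussian_weights(0.3 - d, weight_spec()))
  expect_equal(gaussian_weights(0.3 + 0.1758, weight_spec()), exp(-0.5))
  w <- gaussian_weights(c(0.3, 0.3), spec)
  expect_equal(w, c(0, 1))
  # disabled weighting is all ones (bar exclusions)
  expect_equal(gaussian_weights(c(5, 9), weight_spec(enabled = FALSE)), c(1, 1))
})

test_that("Q_c objective vanishes at the truth and ignores disabled weighting", {
  h <- simulate_heats(simulation_spec(biv$schedule, biv$qc))
  expect_lt(qc_objective(biv$qc, h, biv_conc), 1e-10)
  hq <- heat_series(h$q * 1.07)
  expect_equal(qc_objective(biv$qc, hq, biv_conc,
                            weights = weight_spec(enabled = FALSE)),
               qc_objective(biv$qc, hq, biv_conc, weights = rep(1, 14)))
})

test_that("objective depends on the micro rates only through their ratios", {
  h <- simulate_heats(simulation_spec(biv$schedule, biv$qc))
  hq <- heat_series(h$q * 1.05)
  base <- qc_objective(biv$qc, hq, biv_conc)
  for (cc in c(0.01, 3.7, 250)) {
    scaled <- qc_params(micro_rates(cc * biv$qc$rates$k_on,
                                    cc * biv$qc$rates$k_off),
                        biv$qc$n, biv$qc$dH)
    expect_equal(qc_objective(scaled, hq, biv_conc), base, tolerance = 1e-8)
  }
})

test_that("with s = 1 the Q_c model reduces to the Wiseman model", {
  truth <- wiseman_params(K_a = 120, n = 0.4, dH = -60)
  h <- simulate_heats(simulation_spec(biv$schedule, truth,
                                      noise_width = 0.02, seed = 4))
  wfit <- fit_wiseman(h, biv_conc)
  # identical objectives when K_1 = k_on/k_off equals K_a
  p1 <- qc_params(micro_rates(wfit$params$K_a, 1), wfit$params$n,
                  wfit$params$dH)
  expect_equal(qc_objective(p1, h, biv_conc),
               wiseman_objective(wfit$params, h, biv_conc), tolerance = 1e-10)
  # refining (n, dH) at fixed K_1 reaches the Wiseman minimum
  qfit <- fit_qc(h, biv_conc, init_rates = micro_rates(wfit$params$K_a, 1),
                 search = search_config(seed = 1, max_draws = 1),
                 wiseman_norm = wfit$norm, init_dH = wfit$params$dH)
  expect_lt(qfit$norm, wfit$norm * (1 + 1e-6))
})

test_that("random search breaks on the first winning candidate and is reproducible", {
  h <- simulate_heats(simulation_spec(biv$schedule, biv$qc,
                                      noise_width = 0.01, seed = 2))
  # a huge threshold makes any candidate win: exactly one draw
  f <- fit_qc(h, biv_conc, s = 2,
              search = search_config(seed = 3, max_draws = 50,
                                     break_norm = 1e6),
              refine = "none")
  expect_identical(f$draws, 1L)
  expect_true(f$converged)
  # same seed, same everything
  g1 <- fit_qc(h, biv_conc, s = 2,
               search = search_config(seed = 10, max_draws = 8),
               refine = "none")
  g2 <- fit_qc(h, biv_conc, s = 2,
               search = search_config(seed = 10, max_draws = 8),
               refine = "none")
  expect_identical(g1$params, g2$params)
  expect_identical(g1$norm, g2$norm)
  # refinement never worsens the selected candidate
  g3 <- fit_qc(h, biv_conc, s = 2,
               search = search_config(seed = 10, max_draws = 8),
               refine = "ndh")
  expect_lte(g3$norm, g1$norm)
})

test_that("the search does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123)
  h <- simulate_heats(simulation_spec(biv$schedule, biv$qc))
  invisible(fit_qc(h, biv_conc, s = 2,
                   search = search_config(seed = 99, max_draws = 3),
                   refine = "none"))
  expect_identical(runif(3), before)
})
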