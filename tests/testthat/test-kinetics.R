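test_that("decay curves count survivors past each bin edge", {
  ev <- dissociation_data(data.frame(tether_id = 1:4,
                                     time_s = c(10, 20, 30, 40),
                                     censored = FALSE, replicate_id = 1L),
                          t_end = 40, frame_interval = 5)
  cur <- build_decay_curve(ev, n_bins = 4, t_end = 40)
  expect_equal(cur$t, c(0, 10, 20, 30))
  expect_equal(cur$frac, c(1, 0.75, 0.5, 0.25))

  ## All censored: flat at 1 and flagged.
  evc <- dissociation_data(data.frame(tether_id = 1:3, time_s = 40,
                                      censored = TRUE, replicate_id = 1L),
                           t_end = 40, frame_interval = 5)
  expect_warning(curc <- build_decay_curve(evc, n_bins = 4), "unconstrained")
  expect_true(all(curc$frac == 1))
  expect_true(attr(curc, "all_censored"))
  expect_error(fit_off_rate(curc), "unconstrained")
})

test_that("large-sample decay curves track the closed-form survival", {
  ev <- sample_dissociation_times(
    kinetics_sim_params(0.01, 5000, t_end = 300, frame_interval = 1,
                        seed = 41))
  cur <- build_decay_curve(ev, n_bins = 50, t_end = 300)
  expect_lt(max(abs(cur$frac - exp(-0.01 * cur$t))), 0.03)
  expect_true(all(diff(cur$frac) <= 0))
})

test_that("noiseless single-exponential curves are recovered exactly", {
  t <- seq(0, 490, by = 10)
  f1 <- fit_off_rate(make_curve(t, exp(-0.01 * t)))
  expect_lt(abs(f1$k - 0.01), 1e-6)
  expect_lt(abs(f1$y0), 1e-6)

  f2 <- fit_off_rate(make_curve(t, 0.1 + 0.9 * exp(-0.05 * t)))
  expect_lt(abs(f2$k - 0.05), 1e-4)
  expect_lt(abs(f2$y0 - 0.1), 1e-4)
  expect_lt(abs(f2$A - 0.9), 1e-4)
  expect_true(f2$converged)
})

test_that("replicate fits recover the generating off-rate", {
  reps <- lapply(1:3, function(s) sample_dissociation_times(
    kinetics_sim_params(0.02, 500, t_end = 150, frame_interval = 5,
                        seed = 50 + s)))
  rr <- replicate_off_rates(reps, n_bins = 50)
  expect_lt(abs(rr$k_mean - 0.02), 3 * max(rr$k_sd, 1e-4))
  ## Bin-robustness diagnostic: halving bin width moves k by < 5%.
  for (f in rr$fits) expect_lt(f$bin_robustness, 0.05)
})

test_that("centrifugal force reproduces the calibrated working point", {
  ## 1291 rpm with the calibrated bead and rotor: ~15 pN.
  expect_lt(abs(centrifugal_force(1291) - 15) / 15, 0.03)
  expect_identical(centrifugal_force(0), 0)
  ## Direct evaluation at 2000 rpm (frozen from the formula).
  expect_equal(centrifugal_force(2000), 36.01748, tolerance = 1e-5)
  ## Scaling: linear in mass and radius, quadratic in rpm.
  expect_equal(centrifugal_force(1291, m_eff = 2 * 6.9e-12),
               2 * centrifugal_force(1291), tolerance = 1e-12)
  expect_equal(centrifugal_force(1291, r = 0.238),
               2 * centrifugal_force(1291), tolerance = 1e-12)
  expect_equal(centrifugal_force(2582), 4 * centrifugal_force(1291),
               tolerance = 1e-12)
  expect_error(centrifugal_force(NA), "finite")
})

test_that("stacking free energy follows RT log-ratio with propagated error", {
  rt <- 1.987e-3 * 298.15
  expect_identical(stacking_free_energy(0.01, 0.01)$delta_g, 0)

  ## Ratio e^-1: delta_G = -RT.
  en <- stacking_free_energy(0.01 * exp(-1), 0.01)
  expect_equal(en$delta_g, -rt, tolerance = 1e-10)
  expect_equal(en$delta_g, -0.5925, tolerance = 1e-3)

  ## Ratio 0.0289: the strongest purine-pyrimidine stack, ~ -2.1 kcal/mol.
  en2 <- stacking_free_energy(0.01 * 0.0289, 0.01)
  expect_equal(en2$delta_g, rt * log(0.0289), tolerance = 1e-12)
  expect_lt(abs(en2$delta_g - (-2.1)), 0.1)

  ## Antisymmetry is exact, sign tracks the rate ordering.
  a <- stacking_free_energy(3e-4, 0.01)$delta_g
  b <- stacking_free_energy(0.01, 3e-4)$delta_g
  expect_identical(a, -b)
  expect_lt(a, 0)
  expect_gt(b, 0)

  expect_error(stacking_free_energy(0, 0.01), "off-rates")
  expect_error(stacking_free_energy(0.01, -1), "off-rates")

  ## First-order propagation agrees with Monte-Carlo error of the estimator.
  set.seed(8)
  k1 <- 0.003; k2 <- 0.01; s1 <- 2e-4; s2 <- 6e-4
  sig <- stacking_free_energy(k1, k2, s1, s2)$sigma_delta_g
  draws <- rt * (log(stats::rnorm(20000, k1, s1)) -
                   log(stats::rnorm(20000, k2, s2)))
  expect_lt(abs(stats::sd(draws) - sig) / sig, 0.1)
})

test_that("pooling partitions tethers into reproducible near-equal groups", {
  ev <- sample_dissociation_times(
    kinetics_sim_params(0.01, 300, t_end = 400, seed = 61))
  g <- pool_replicates(ev, 3, seed = 5)
  expect_identical(vapply(g, nrow, integer(1)), rep(100L, 3))
  g2 <- pool_replicates(ev, 3, seed = 5)
  expect_identical(lapply(g, function(d) d$tether_id),
                   lapply(g2, function(d) d$tether_id))
  ## Union of the groups is the input multiset.
  expect_identical(sort(unlist(lapply(g, `[[`, "tether_id"))), ev$tether_id)
  expect_error(pool_replicates(ev, 0), "n_groups")
})
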