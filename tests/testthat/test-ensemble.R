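const_series <- function(rho, theta = 40, n = 100, temperature = 300) {
  rho_theta(data.frame(frame = seq_len(n), time_ps = (seq_len(n) - 1) * 25,
                       rho_nm = rho, theta_deg = theta, flag = FALSE),
            temperature = temperature)
}

sim_series <- function(delta_g, seed, temperature = 300, n_frames = 2000,
                       ...) {
  tr <- generate_interface_trajectory(
    stack_sim_params(delta_g, temperature = temperature, n_frames = n_frames,
                     seed = seed, ...))
  project_trajectory(tr, align = FALSE)
}

test_that("rho summaries are exact on constant series", {
  s <- const_series(0.5)
  out <- rho_series_summary(list(s))
  expect_equal(out$median_rho_nm, 0.5)
  expect_equal(out$iqr_rho_nm, 0)
  expect_identical(out$n_excursions, 0L)
  expect_equal(out$excursion_fraction, 0)
  expect_error(rho_series_summary(list()), "at least one")
})

test_that("weaker stacks suffer at least as many excursions (rank test)", {
  wins <- 0
  for (s in 1:5) {
    weak <- rho_series_summary(list(sim_series(-0.5, seed = s)))
    strong <- rho_series_summary(list(sim_series(-3, seed = s)))
    wins <- wins + (weak$n_excursions >= strong$n_excursions)
  }
  expect_gte(wins, 4)
})

test_that("excursion fraction rises along the temperature ladder", {
  temps <- seq(300, 400, 20)
  series <- lapply(temps, function(T) sim_series(-1.5, seed = 2,
                                                 temperature = T))
  out <- rho_series_summary(series)
  expect_identical(out$temperature_K, temps)
  expect_gt(stats::cor(out$temperature_K, out$excursion_fraction,
                       method = "spearman"), 0)
})

test_that("polar densities conserve mass and match sampling law", {
  ## Single repeated point: all mass in one bin.
  pd <- polar_density(const_series(0.5, 40))
  expect_equal(sum(pd$counts), 1, tolerance = 1e-12)
  expect_identical(sum(pd$counts > 0), 1L)

  ## Uniform theta at fixed rho: chi-square uniformity not rejected.
  set.seed(33)
  n <- 5000
  s <- rho_theta(data.frame(frame = 1:n, time_ps = 0,
                            rho_nm = 0.5,
                            theta_deg = stats::runif(n, 0, 180),
                            flag = FALSE))
  pd2 <- polar_density(s, rho_breaks = c(0, 1),
                       theta_breaks = seq(0, 180, 10))
  expect_equal(sum(pd2$counts), 1, tolerance = 1e-12)
  p <- stats::chisq.test(as.vector(pd2$counts) * n)$p.value
  expect_gt(p, 0.01)

  ## Flagged frames are excluded and reported.
  sf <- s; sf$flag[1:100] <- TRUE
  pd3 <- polar_density(rho_theta(sf))
  expect_identical(pd3$n_flagged, 100L)
})

test_that("stacked fraction is exact on constructed mixtures", {
  expect_equal(stacked_fraction(const_series(0.5)), 1)
  expect_equal(stacked_fraction(const_series(2.0)), 0)
  mix <- const_series(rep(c(0.5, 1.5), each = 50))
  expect_equal(stacked_fraction(mix), 0.5)
})

test_that("mixture clustering identifies constructed cloud structure", {
  set.seed(44)
  ## One tight cloud: one component.
  one <- rho_theta(data.frame(
    frame = 1:1000, time_ps = 0,
    rho_nm = stats::rnorm(1000, 0.5, 0.03),
    theta_deg = stats::rnorm(1000, 40, 8), flag = FALSE))
  c1 <- cluster_interface_states(one, seed = 2)
  expect_identical(c1$n_components, 1L)

  ## Two clouds separated by 0.5 nm in rho: two components, means recovered.
  two <- rho_theta(data.frame(
    frame = 1:1000, time_ps = 0,
    rho_nm = c(stats::rnorm(500, 0.3, 0.03), stats::rnorm(500, 0.8, 0.03)),
    theta_deg = stats::rnorm(1000, 40, 6), flag = FALSE))
  c2 <- cluster_interface_states(two, seed = 2)
  expect_identical(c2$n_components, 2L)
  m <- c2$means[order(c2$means$rho_nm), ]
  expect_lt(abs(m$rho_nm[1] - 0.3), 0.05)
  expect_lt(abs(m$rho_nm[2] - 0.8), 0.05)
  expect_lt(abs(m$theta_deg[1] - 40), 5)
  expect_lt(abs(m$theta_deg[2] - 40), 5)
  expect_equal(sum(c2$weights), 1, tolerance = 1e-9)

  ## Centroid frames sit deep inside their cluster (10th percentile of the
  ## members' Mahalanobis distances to the cluster mean).
  xy <- cbind(two$rho_nm, two$theta_deg)
  for (g in seq_len(c2$n_components)) {
    mu <- unlist(c2$means[g, ]); sig <- c2$covariances[, , g]
    d_all <- stats::mahalanobis(xy, mu, sig)
    members <- which(d_all <= sort(d_all)[500])   # roughly this cluster
    d_centroid <- stats::mahalanobis(
      xy[c2$centroid_frames[g], , drop = FALSE], mu, sig)
    expect_lte(d_centroid, stats::quantile(d_all[members], 0.1))
  }

  expect_error(cluster_interface_states(const_series(0.5, n = 20)),
               "at least 50")
})
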