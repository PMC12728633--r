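test_that("ring centers are exact means and transform linearly", {
  hex <- make_hexagon(center = c(0, 0, 0), r = 1)
  expect_equal(unname(ring_center(hex, "A")), c(0, 0, 0), tolerance = 1e-12)

  v <- c(1.5, -2, 0.25)
  expect_equal(ring_center(sweep(hex, 2, -v), "C"),
               ring_center(hex, "C") + v, tolerance = 1e-12)

  ## Centers of the ideal step match the generator's analytic centers.
  st <- ideal_stacked_step("G", "C")
  expect_equal(unname(ring_center(st$coords$base_5p, "G")),
               unname(st$centers["base_5p", ]), tolerance = 1e-9)
  expect_equal(unname(ring_center(st$coords$base_3p, "C")),
               unname(st$centers["base_3p", ]), tolerance = 1e-9)

  expect_error(ring_center(hex[1:5, ], "A"), "missing ring atom")
})

test_that("WC-face vectors lie in the ring plane and rotate equivariantly", {
  hex <- make_hexagon(center = c(2, 1, -3), r = 1.2, phi0 = 25)
  for (b in c("A", "G", "C", "T")) {
    v <- wc_face_vector(hex, b)
    expect_lt(abs(v[3]), 1e-9)              # plane normal is z here
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
  set.seed(3)
  R <- random_rotation()
  v0 <- wc_face_vector(hex, "A")
  v1 <- wc_face_vector(hex %*% R, "A")
  expect_equal(unname(v1), unname(drop(v0 %*% R)), tolerance = 1e-10)

  ## Degenerate face (midpoint coincides with the ring centre) errors.
  bad <- rbind(N1 = c(0, 1, 0), C2 = c(1, 0, 0), N3 = c(0, -1, 0),
               C4 = c(0, 0, 1), C5 = c(0, 0, -1), C6 = c(-1, 0, 0))
  expect_error(wc_face_vector(bad, "A"), "degenerate")
})

test_that("anchor-based alignment recovers rigid transforms", {
  st <- ideal_stacked_step("A", "A")
  frame <- rbind(st$coords$base_5p, st$coords$base_3p)
  anchor_idx <- 1:6

  ## Identity.
  out <- align_frame(frame, frame, anchor_idx)
  expect_lt(max(abs(out - frame)), 1e-12)

  ## Exact recovery of a rotation + translation.
  set.seed(9)
  for (i in 1:5) {
    R <- random_rotation(); tvec <- stats::rnorm(3)
    moved <- frame %*% R + matrix(tvec, nrow(frame), 3, byrow = TRUE)
    back <- align_frame(moved, frame, anchor_idx)
    expect_lt(sqrt(mean((back[anchor_idx, ] - frame[anchor_idx, ])^2)), 1e-6)
    expect_lt(max(abs(back - frame)), 1e-6)
  }

  ## Gaussian anchor noise: least squares can only shrink the residual, so
  ## each aligned RMSD is bounded by its own unaligned RMSD, and the mean
  ## aligned RMSD stays below the raw-noise expectation sigma * sqrt(3).
  sigma <- 0.01
  rmsds <- numeric(10)
  for (i in 1:10) {
    noisy <- frame
    noisy[anchor_idx, ] <- noisy[anchor_idx, ] +
      matrix(stats::rnorm(18, 0, sigma), 6, 3)
    raw <- sqrt(mean(rowSums((noisy[anchor_idx, ] - frame[anchor_idx, ])^2)))
    back <- align_frame(noisy, frame, anchor_idx)
    rmsds[i] <- sqrt(mean(rowSums((back[anchor_idx, ] - frame[anchor_idx, ])^2)))
    expect_lte(rmsds[i], raw + 1e-12)
  }
  expect_lte(mean(rmsds), sigma * sqrt(3))

  ## Collinear anchors are rejected.
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(align_frame(rbind(line, frame), rbind(line, frame), 1:5),
               "collinear")
})

test_that("rho-theta projection reproduces constructed geometries", {
  hex5 <- make_hexagon(r = 0.139, phi0 = 180)

  ## Identical superposed rings: rho = 0, theta = 0.
  pr0 <- project_rho_theta(hex5, hex5, "A", "A")
  expect_equal(pr0$rho, 0, tolerance = 1e-12)
  expect_equal(pr0$theta, 0, tolerance = 1e-6)

  ## Pure z displacement: rho equals the offset, theta stays 0.
  hex3 <- hex5; hex3[, 3] <- hex3[, 3] + 0.5
  pr1 <- project_rho_theta(hex5, hex3, "A", "A")
  expect_equal(pr1$rho, 0.5, tolerance = 1e-12)
  expect_equal(pr1$theta, 0, tolerance = 1e-6)

  ## Additional 36-degree rotation about z: theta = 36.
  Rz <- matrix(c(cos(0.2 * pi), sin(0.2 * pi), 0,
                 -sin(0.2 * pi), cos(0.2 * pi), 0, 0, 0, 1), 3, 3)
  hex3r <- hex3 %*% Rz
  rownames(hex3r) <- rownames(hex3)
  pr2 <- project_rho_theta(hex5, hex3r, "A", "A")
  expect_equal(pr2$theta, 36, tolerance = 1e-6)

  ## Theta is symmetric in the two residues; rho trivially so.
  pr3 <- project_rho_theta(hex3r, hex5, "A", "A")
  expect_equal(pr2$theta, pr3$theta, tolerance = 1e-9)
  expect_equal(pr2$rho, pr3$rho, tolerance = 1e-12)

  ## A face vector pointing along z degenerates under xy projection.
  vert <- make_hexagon(r = 0.139)[, c(3, 2, 1)]   # WC face along z
  colnames(vert) <- c("x", "y", "z")
  pr4 <- project_rho_theta(vert, hex5, "A", "A")
  expect_true(pr4$flag)
  expect_true(is.na(pr4$theta))
})

test_that("the aligned pipeline is invariant under global rigid transforms", {
  tr <- generate_interface_trajectory(stack_sim_params(-1.5, n_frames = 200,
                                                       seed = 13))
  ref <- tr$coords[, , 1]
  base <- project_trajectory(tr, reference = ref)
  set.seed(14)
  for (i in 1:3) {
    moved <- transform_trajectory(tr, random_rotation(), stats::rnorm(3, 0, 5))
    got <- project_trajectory(moved, reference = ref)
    expect_lt(max(abs(got$rho_nm - base$rho_nm)), 1e-6)
    expect_lt(max(abs(got$theta_deg - base$theta_deg), na.rm = TRUE), 1e-6)
  }
})
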