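make_test_movie <- function(n_tethers, seed, width = 480, height = 360,
                            noise = 2, t_end = 10, ...) {
  ev <- sample_dissociation_times(
    kinetics_sim_params(0.01, n_tethers, t_end = t_end, frame_interval = 5,
                        seed = seed))
  render_bead_movie(ev, movie_sim_params(width = width, height = height,
                                         noise_sigma = noise,
                                         seed = seed + 500L, ...))
}

test_that("detection recovers well-separated beads near ground truth", {
  mv <- make_test_movie(50, seed = 31)
  b <- detect_beads(mv$frames[, , 1])
  tr <- mv$truth
  hit <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((b$x - tr$x[i])^2 + (b$y - tr$y[i])^2)), numeric(1))
  expect_gte(sum(hit <= 2), 48)
  ## No spurious detections away from any true object.
  spurious <- vapply(seq_len(nrow(b)), function(i)
    min(sqrt((tr$x - b$x[i])^2 + (tr$y - b$y[i])^2)), numeric(1))
  expect_true(all(spurious <= 3))
})

test_that("blank frames and single beads behave as constructed", {
  set.seed(42)
  blank <- matrix(stats::rnorm(200 * 200, 100, 4), 200, 200)
  expect_identical(nrow(detect_beads(blank)), 0L)

  mv <- make_test_movie(1, seed = 33, width = 96, height = 96)
  b <- detect_beads(mv$frames[, , 1])
  expect_identical(nrow(b), 1L)
  expect_lt(sqrt((b$x - mv$truth$x)^2 + (b$y - mv$truth$y)^2), 1.5)
})

test_that("screening applies the exclusion rules deterministically", {
  ## Two beads one radius apart: both excluded as a cluster.
  pair <- bead_set(data.frame(bead_id = 1:2, x = c(50, 56), y = c(50, 50),
                              radius = 6, score = 0.95, status = "candidate"))
  out <- screen_beads(pair)
  expect_identical(out$status, rep("excluded:cluster", 2))

  ## Empty candidate set stays empty.
  empty <- bead_set(data.frame(bead_id = integer(0), x = numeric(0),
                               y = numeric(0), radius = numeric(0),
                               score = numeric(0), status = character(0)))
  expect_identical(nrow(screen_beads(empty)), 0L)

  ## Permuting candidate order does not change the accepted set.
  set.seed(7)
  cand <- bead_set(data.frame(
    bead_id = 1:20,
    x = stats::runif(20, 20, 300), y = stats::runif(20, 20, 300),
    radius = sample(c(3, 6, 25), 20, replace = TRUE),
    score = stats::runif(20, 0.5, 1), status = "candidate"))
  a1 <- screen_beads(cand)
  perm <- sample(20)
  a2 <- screen_beads(bead_set(cand[perm, ]))
  key <- function(b) sort(paste(b$x, b$y)[b$status == "accepted"])
  expect_identical(key(a1), key(a2))
})

test_that("injected debris is excluded for low circularity", {
  mv <- make_test_movie(10, seed = 35, n_debris = 4, t_end = 50)
  b <- screen_beads(detect_beads(mv$frames[, , 1]))
  tr <- mv$truth
  debris <- tr[tr$kind == "debris", ]
  for (i in seq_len(nrow(debris))) {
    near <- which(sqrt((b$x - debris$x[i])^2 + (b$y - debris$y[i])^2) <= 8)
    expect_true(all(b$status[near] == "excluded:low_circularity"))
  }
  teth <- tr[tr$kind == "tether", ]
  acc <- b[b$status == "accepted", ]
  hit <- vapply(seq_len(nrow(teth)), function(i)
    min(sqrt((acc$x - teth$x[i])^2 + (acc$y - teth$y[i])^2)), numeric(1))
  expect_gte(sum(hit <= 2), 9)
})

test_that("variance traces have the closed-form noise level", {
  ## Pure Gaussian noise: E[var] = sigma^2.
  set.seed(11)
  sigma <- 3
  arr <- array(stats::rnorm(80 * 80 * 200, 0, sigma), c(80, 80, 200))
  st <- image_stack(arr, frame_interval = 1)
  tr <- variance_trace(st, list(x = 40, y = 40, radius = 6, bead_id = 1L))
  n_px <- sum(outer((34:46 - 40)^2, (34:46 - 40)^2, "+") <= 7^2)
  se <- sqrt(2 * sigma^4 / (n_px - 1) / 200)
  expect_lt(abs(mean(tr$variance) - sigma^2), 3 * se)

  ## Constant image: exactly zero variance.
  st0 <- image_stack(array(5, c(40, 40, 10)), frame_interval = 1)
  tr0 <- variance_trace(st0, list(x = 20, y = 20, radius = 5, bead_id = 1L))
  expect_true(all(tr0$variance == 0))

  ## Disk partially outside the frame is an error.
  expect_error(variance_trace(st0, list(x = 2, y = 20, radius = 5,
                                        bead_id = 2L)),
               "outside the frame")
})

test_that("event calling handles step, flat, and multi-step traces", {
  ## Clean step 100 -> 5 at frame 201 (time 200 s).
  v <- c(rep(100, 200), rep(5, 100))
  call <- call_dissociation(make_trace(v), time_zero = 0)
  expect_identical(call$outcome, "dissociated")
  expect_equal(call$time_s, 200)

  ## Constant bound-level trace: censored.
  expect_identical(call_dissociation(make_trace(rep(80, 200)))$outcome,
                   "censored")

  ## Two distinct downward steps: excluded as multiple tethers.
  v2 <- c(rep(100, 120), rep(50, 120), rep(5, 120))
  expect_identical(call_dissociation(make_trace(v2))$outcome,
                   "excluded_multistep")

  ## Event time is reported relative to time zero.
  call2 <- call_dissociation(make_trace(v), time_zero = 50)
  expect_equal(call2$time_s, 150)
})

test_that("event calls are invariant to a constant intensity offset", {
  mv <- make_test_movie(8, seed = 37, width = 220, height = 180, t_end = 250)
  res1 <- track_movie(mv)
  mv2 <- mv
  mv2$frames <- mv2$frames + 500
  res2 <- track_movie(mv2)
  expect_identical(res1$events$outcome, res2$events$outcome)
  expect_identical(res1$events$time_s, res2$events$time_s)
})
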