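## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Rotation by `deg` degrees about the z axis (3x3).
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## 2-D linear convolution via FFT, returning the "same"-size map aligned so
## that entry [i, j] is the kernel-weighted sum centred on pixel (i, j).
## Kernel dimensions must be odd.
conv2_same <- function(img, kern) {
  di <- dim(img); dk <- dim(kern)
  if (any(dk %% 2 != 1L)) stopf("kernel dimensions must be odd")
  dp <- c(stats::nextn(di[1] + dk[1] - 1L, c(2, 3, 5)),
          stats::nextn(di[2] + dk[2] - 1L, c(2, 3, 5)))
  A <- matrix(0, dp[1], dp[2]); A[seq_len(di[1]), seq_len(di[2])] <- img
  B <- matrix(0, dp[1], dp[2]); B[seq_len(dk[1]), seq_len(dk[2])] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) / 2L
  full[off[1] + seq_len(di[1]), off[2] + seq_len(di[2])]
}

## Least-squares rigid superposition (Kabsch).  Returns the rotation R and
## translation t such that  moving %*% R + t  best matches `fixed`.
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L, ncol(fixed) == 3L)
  mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
  M <- sweep(moving, 2, mu_m); F <- sweep(fixed, 2, mu_f)
  s <- svd(crossprod(M, F))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- mu_f - drop(mu_m %*% R)
  list(R = R, t = t_vec)
}

apply_rigid <- function(coords, R, t) sweep(coords %*% R, 2, -t)

## Seed scoping: run `expr` under a seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}
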