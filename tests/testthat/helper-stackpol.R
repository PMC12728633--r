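## Shared fixture builders (everything generated in code, no stored data).

## Regular hexagon with ring-atom names, circumradius `r`, centered at
## `center`, lying in the xy-plane, N1 at azimuth `phi0` (degrees).
make_hexagon <- function(center = c(0, 0, 0), r = 1, phi0 = 0) {
  ang <- (phi0 + 60 * (0:5)) * pi / 180
  xyz <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), center[3])
  dimnames(xyz) <- list(c("N1", "C2", "N3", "C4", "C5", "C6"),
                        c("x", "y", "z"))
  xyz
}

## Random proper rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Apply a rigid transform to every frame of a trajectory.
transform_trajectory <- function(traj, R, t) {
  for (f in seq_len(traj$n_frames))
    traj$coords[, , f] <- traj$coords[, , f] %*% R +
      matrix(t, nrow(traj$atoms), 3, byrow = TRUE)
  traj
}

## Bare decay_curve object from an analytic survival function.
make_curve <- function(t, frac) {
  structure(data.frame(t = t, frac = frac),
            class = c("decay_curve", "data.frame"),
            n_total = NA_integer_, n_censored = NA_integer_,
            t_end = max(t), n_bins = length(t), all_censored = FALSE,
            events = NULL)
}

## Variance-trace object from a plain numeric vector (dt = 1 s).
make_trace <- function(v, bead_id = 1L, dt = 1) {
  structure(data.frame(frame = seq_along(v), time_s = (seq_along(v) - 1) * dt,
                       variance = v),
            class = c("variance_trace", "data.frame"), bead_id = bead_id)
}
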