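## Bead identification and dissociation-event calling.
##
## Detection is a Hough-style matched filter: the frame is normalized-
## cross-correlated with anti-aliased disk templates over a radius range,
## the per-pixel best response across radii is kept, and local maxima above
## a score threshold become candidate beads. The NCC score doubles as the
## circularity measure used by screening (elongated debris correlates
## poorly with a disk). Pixel coordinates are 0-based, x right / y down.

disk_template <- function(r) {
  n <- 2L * ceiling(r) + 7L               # odd square support with margin
  c0 <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - c0)^2, (0:(n - 1) - c0)^2, "+"))
  matrix(pmin(1, pmax(0, r + 0.5 - d)), n, n)
}

## Normalized cross-correlation of `img` with template `tmpl` (odd square),
## computed over the template's full square support at every pixel.
ncc_map <- function(img, tmpl) {
  n <- nrow(tmpl)
  npix <- n * n
  t0 <- tmpl - mean(tmpl)
  t_norm <- sqrt(sum(t0^2))
  ones <- matrix(1, n, n)
  s1 <- conv2_same(img, ones)               # local sum
  s2 <- conv2_same(img^2, ones)             # local sum of squares
  ## Correlation = convolution with the flipped template.
  num <- conv2_same(img, t0[n:1, n:1])
  var_loc <- pmax(s2 - s1^2 / npix, 0)
  den <- sqrt(var_loc) * t_norm
  out <- num / pmax(den, 1e-9)
  out[den < 1e-9] <- 0
  out
}

#' Detect circular bead candidates in a frame
#'
#' Matched-filter (Hough-style) detection of circular features over a radius
#' range. Returns scored candidates; no screening is applied yet.
#'
#' @param frame 2-D numeric matrix (grayscale image).
#' @param radii candidate radii in pixels (vector).
#' @param polarity `"dark"` (default) for dark-on-light beads, `"bright"`
#'   for the inverse appearance.
#' @param score_threshold minimum matched-filter NCC score for a candidate.
#' @param min_distance non-maximum-suppression distance (px); default
#'   `max(radii) + 1`, so that the sidelobes of the larger templates cannot
#'   produce satellite detections around one bead.
#' @return A `bead_set` data.frame: `bead_id`, `x`, `y` (0-based px),
#'   `radius`, `score`, `status` (all `"candidate"`).
#' @export
detect_beads <- function(frame, radii = 4:9,
                         polarity = c("dark", "bright"),
                         score_threshold = 0.35, min_distance = NULL) {
  polarity <- match.arg(polarity)
  if (!is.matrix(frame) || any(dim(frame) < 8))
    stopf("`frame` must be a numeric matrix of at least 8 x 8 pixels")
  sgn <- if (polarity == "dark") -1 else 1
  best <- matrix(-Inf, nrow(frame), ncol(frame))
  best_r <- matrix(NA_real_, nrow(frame), ncol(frame))
  for (r in radii) {
    s <- sgn * ncc_map(frame, disk_template(r))
    upd <- s > best
    best[upd] <- s[upd]
    best_r[upd] <- r
  }
  min_distance <- min_distance %||% (max(radii) + 1)
  ## Keep maxima away from the border (template support must fit).
  marg <- ceiling(max(radii)) + 3L
  h <- nrow(frame); w <- ncol(frame)
  cand <- which(best > score_threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    keep <- cand[, 1] > marg & cand[, 1] <= h - marg &
      cand[, 2] > marg & cand[, 2] <= w - marg
    cand <- cand[keep, , drop = FALSE]
  }
  ## Greedy non-maximum suppression, strongest first.
  sel <- matrix(numeric(0), 0, 2); scores <- numeric(0); rads <- numeric(0)
  if (nrow(cand)) {
    ord <- order(best[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(sel) == 0L ||
          min((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2) > min_distance^2) {
        sel <- rbind(sel, p)
        scores <- c(scores, best[p[1], p[2]])
        rads <- c(rads, best_r[p[1], p[2]])
      }
    }
  }
  bead_set(data.frame(
    bead_id = seq_len(nrow(sel)),
    x = if (nrow(sel)) sel[, 2] - 1 else numeric(0),
    y = if (nrow(sel)) sel[, 1] - 1 else numeric(0),
    radius = rads, score = scores,
    status = rep("candidate", nrow(sel)),
    stringsAsFactors = FALSE))
}

#' Construct a bead set
#' @param df data.frame with columns bead_id, x, y, radius, score, status.
#' @return A `bead_set` object.
#' @export
bead_set <- function(df) {
  need <- c("bead_id", "x", "y", "radius", "score", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  structure(df[, need], class = c("bead_set", "data.frame"))
}

#' Screen bead candidates
#'
#' Applies the exclusion rules used before kinetic analysis: touching or
#' closely clustered objects, low-circularity objects (debris, noncircular
#' particles), and out-of-range radii. Deterministic and independent of
#' candidate order; every excluded bead carries a reason.
#'
#' @param candidates a `bead_set` from [detect_beads()].
#' @param min_separation minimum pairwise center distance (px); any pair
#'   closer than this has both members excluded as `cluster`.
#' @param circularity_threshold minimum matched-filter score.
#' @param radius_range allowed radius range (px).
#' @return The `bead_set` with `status` set to `accepted` or
#'   `excluded:<reason>`.
#' @export
screen_beads <- function(candidates, min_separation = 15,
                         circularity_threshold = 0.8,
                         radius_range = c(2, 20)) {
  stopifnot(inherits(candidates, "bead_set"))
  b <- candidates
  n <- nrow(b)
  status <- rep("accepted", n)
  ## Non-circular objects first (debris often fires several elongated
  ## detections; those must not masquerade as a bead cluster) ...
  status[b$score < circularity_threshold] <- "excluded:low_circularity"
  status[status == "accepted" &
           (b$radius < radius_range[1] | b$radius > radius_range[2])] <-
    "excluded:radius"
  ## ... then the cluster rule among the remaining circular candidates.
  ok <- which(status == "accepted")
  if (length(ok) > 1) {
    d <- as.matrix(stats::dist(cbind(b$x[ok], b$y[ok])))
    diag(d) <- Inf
    status[ok[apply(d < min_separation, 1, any)]] <- "excluded:cluster"
  }
  b$status <- status
  bead_set(b)
}

#' Per-frame intensity-variance trace at a fixed bead location
#'
#' Computes the unbiased variance of pixel intensity within the disk of the
#' bead's radius centered at its first-frame position, for every frame. The
#' location is fixed (no re-tracking): tether sway and the bound/unbound
#' contrast change are both absorbed into the variance signal.
#'
#' @param stack an `image_stack`.
#' @param bead one-row portion of a `bead_set` (or list with `x`, `y`,
#'   `radius`, `bead_id`).
#' @param radius_pad extra pixels added to the bead radius for the analysis
#'   disk.
#' @return A `variance_trace` data.frame: `frame`, `time_s`, `variance`,
#'   with attribute `bead_id`.
#' @export
variance_trace <- function(stack, bead, radius_pad = 1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  r <- bead$radius + radius_pad
  cx <- bead$x; cy <- bead$y
  if (cx - r < 0 || cy - r < 0 || cx + r > d[2] - 1 || cy + r > d[1] - 1)
    stopf("analysis disk for bead %s extends outside the frame",
          format(bead$bead_id))
  xs <- floor(cx - r):ceiling(cx + r)
  ys <- floor(cy - r):ceiling(cy + r)
  msk <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  sub <- stack$frames[ys + 1L, xs + 1L, , drop = FALSE]
  m <- matrix(sub, nrow = length(ys) * length(xs), ncol = d[3])[as.vector(msk), ,
                                                               drop = FALSE]
  npx <- nrow(m)
  v <- (colSums(m^2) - npx * colMeans(m)^2) / (npx - 1)
  structure(data.frame(frame = seq_len(d[3]),
                       time_s = frame_times(stack),
                       variance = pmax(v, 0)),
            class = c("variance_trace", "data.frame"),
            bead_id = bead$bead_id)
}

## Count distinct downward level shifts in a trace: sliding-median step
## statistic, thresholded, merged into separated step locations.
count_down_steps <- function(x, window, min_step) {
  n <- length(x)
  if (n < 2 * window + 1) return(0L)
  stat <- rep(0, n)
  for (t in (window + 1):(n - window + 1)) {
    stat[t] <- stats::median(x[(t - window):(t - 1)]) -
      stats::median(x[t:(t + window - 1)])
  }
  above <- which(stat > min_step)
  if (!length(above)) return(0L)
  ## Merge hits closer than `window` frames into one step.
  sum(diff(c(-window - 1L, above)) > window)
}

#' Call a dissociation event from a variance trace
#'
#' The bound level `B` is the maximum of the median-smoothed trace (robust
#' to dissociations during the first frames, when an initial-window median
#' would already be contaminated by the unbound level) and the unbound
#' level `U` the median of a trailing window. The event is
#' the first frame at which the median-smoothed trace crosses below
#' `B - drop_frac * (B - U)` and stays below it for `persistence` frames.
#' Traces with no resolvable drop are censored; traces with more than one
#' distinct downward level shift are excluded as multi-step (likely
#' multiple tethers).
#'
#' @param trace a `variance_trace`.
#' @param time_zero clamp start (s); frames before it are ignored and the
#'   reported event time is relative to it.
#' @param drop_frac fraction of the bound-unbound contrast that must be
#'   lost, default 0.5.
#' @param persistence frames the smoothed trace must stay below threshold.
#' @param init_window minimum trace length guard (frames).
#' @param tail_window frames used for the trailing (unbound-level) median.
#' @param smooth_k running-median width (odd).
#' @param step_frac step-detector threshold as a fraction of `B - U`.
#' @param step_window sliding-median half-window of the step detector.
#' @return An `event_call`: list with `bead_id`, `outcome` (`dissociated`,
#'   `censored`, or `excluded_multistep`), and `time_s` (relative to time
#'   zero; `NA` unless dissociated).
#' @export
call_dissociation <- function(trace, time_zero = 0, drop_frac = 0.5,
                              persistence = 5, init_window = 10,
                              tail_window = 10, smooth_k = 3,
                              step_frac = 0.35, step_window = 8) {
  stopifnot(inherits(trace, "variance_trace"))
  keep <- trace$time_s >= time_zero
  if (!any(keep)) stopf("trace does not cover time_zero")
  tr <- trace[keep, ]
  v <- tr$variance
  n <- length(v)
  if (n < init_window + tail_window)
    stopf("trace shorter than the analysis windows")
  s <- stats::runmed(v, smooth_k)
  B <- max(s)
  U <- stats::median(s[(n - tail_window + 1):n])
  noise <- stats::mad(diff(v)) / sqrt(2)
  out <- function(outcome, t = NA_real_)
    structure(list(bead_id = attr(trace, "bead_id"), outcome = outcome,
                   time_s = t), class = "event_call")
  if (!is.finite(B) || (B - U) <= max(3 * noise, 1e-12 * max(B, 1)))
    return(out("censored"))
  thr <- B - drop_frac * (B - U)
  below <- s < thr
  cross <- NA_integer_
  for (t in which(below)) {
    stretch <- t:min(n, t + persistence - 1L)
    if (all(below[stretch])) { cross <- t; break }
  }
  if (is.na(cross)) return(out("censored"))
  n_steps <- count_down_steps(v, step_window, step_frac * (B - U))
  if (n_steps > 1L) return(out("excluded_multistep"))
  out("dissociated", tr$time_s[cross] - time_zero)
}

#' @export
print.event_call <- function(x, ...) {
  cat(sprintf("event_call bead %s: %s%s\n", format(x$bead_id), x$outcome,
              if (!is.na(x$time_s)) sprintf(" at %g s", x$time_s) else ""))
  invisible(x)
}

#' Track a movie end to end
#'
#' Detect beads on the first frame, screen them, build fixed-location
#' variance traces, and call per-bead dissociation events.
#'
#' @param stack an `image_stack`.
#' @param detection list of arguments for [detect_beads()].
#' @param screening list of arguments for [screen_beads()].
#' @param calling list of arguments for [call_dissociation()].
#' @param time_zero clamp start (s); defaults to the stack's `time_zero`.
#' @return List with `beads` (screened `bead_set`), `events` (data.frame:
#'   bead_id, x, y, radius, outcome, time_s, reason) and `qc` (named counts
#'   per screening/calling category).
#' @export
track_movie <- function(stack, detection = list(), screening = list(),
                        calling = list(), time_zero = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  time_zero <- time_zero %||% stack$time_zero
  beads <- do.call(detect_beads, c(list(stack$frames[, , 1]), detection))
  beads <- do.call(screen_beads, c(list(beads), screening))
  acc <- beads[beads$status == "accepted", ]
  events <- data.frame(bead_id = integer(0), x = numeric(0), y = numeric(0),
                       radius = numeric(0), outcome = character(0),
                       time_s = numeric(0), reason = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(acc))) {
    bead <- acc[i, ]
    call <- tryCatch({
      tr <- variance_trace(stack, bead)
      do.call(call_dissociation, c(list(tr, time_zero = time_zero), calling))
    }, error = function(e) {
      structure(list(bead_id = bead$bead_id, outcome = "excluded_border",
                     time_s = NA_real_), class = "event_call")
    })
    events <- rbind(events, data.frame(
      bead_id = bead$bead_id, x = bead$x, y = bead$y, radius = bead$radius,
      outcome = call$outcome, time_s = call$time_s,
      reason = if (startsWith(call$outcome, "excluded")) call$outcome else "",
      stringsAsFactors = FALSE))
  }
  qc <- c(table(beads$status), table(events$outcome))
  list(beads = beads, events = events, qc = qc)
}
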