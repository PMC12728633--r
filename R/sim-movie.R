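#' Parameters for the synthetic bead-movie generator
#'
#' Fixture generator for the tracking arm: circular microsphere images on a
#' uniform background with Gaussian camera noise, plus deliberately invalid
#' objects (touching bead pairs, irregular debris) that the screening rules
#' must reject. The physically meaningful quantities live in the dissociation
#' dataset;
#' everything here is imaging plumbing with configurable appearance.
#'
#' @param width,height frame size (pixels).
#' @param bead_radius bead radius (pixels, >= 2).
#' @param bead_contrast intensity difference bead minus background; negative
#'   values give the default dark-on-light appearance.
#' @param background background intensity level.
#' @param noise_sigma Gaussian camera noise sd (intensity units, >= 0).
#' @param n_clustered number of deliberately touching bead pairs.
#' @param n_debris number of irregular (elongated) debris objects.
#' @param seed integer RNG seed.
#' @return An object of class `movie_sim_params`.
#' @export
movie_sim_params <- function(width = 192, height = 128, bead_radius = 6,
                             bead_contrast = -90, background = 180,
                             noise_sigma = 4, n_clustered = 0L,
                             n_debris = 0L, seed = 1L) {
  if (bead_radius < 2) stopf("`bead_radius` must be >= 2 px")
  if (noise_sigma < 0) stopf("`noise_sigma` must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 bead_radius = bead_radius, bead_contrast = bead_contrast,
                 background = background, noise_sigma = noise_sigma,
                 n_clustered = as.integer(n_clustered),
                 n_debris = as.integer(n_debris), seed = as.integer(seed)),
            class = "movie_sim_params")
}

## Pixel coordinates are 0-based throughout: the center of matrix entry
## [i, j] is (x = j - 1, y = i - 1), x right / y down.

## Anti-aliased disk: per-pixel coverage ramp of width 1 px at the rim.
add_disk <- function(img, cx, cy, r, amplitude) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
  y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(1, pmax(0, r + 0.5 - d))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * cov
  img
}

## Elongated "debris": anti-aliased ellipse at a random orientation.
add_ellipse <- function(img, cx, cy, a, b, phi, amplitude) {
  h <- nrow(img); w <- ncol(img)
  r <- max(a, b)
  x0 <- max(0L, floor(cx - r - 2)); x1 <- min(w - 1L, ceiling(cx + r + 2))
  y0 <- max(0L, floor(cy - r - 2)); y1 <- min(h - 1L, ceiling(cy + r + 2))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  ## Signed distance approximation through the normalized radius.
  rr <- sqrt((xr / a)^2 + (yr / b)^2)
  cov <- pmin(1, pmax(0, (1 - rr) * min(a, b) + 0.5))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * cov
  img
}

place_objects <- function(n, w, h, margin, min_sep, existing, max_tries = 5000L) {
  pts <- existing
  out <- matrix(NA_real_, n, 2)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("could not place %d objects without overlap after %d tries",
            n, max_tries)
    cand <- c(stats::runif(1, margin, (w - 1) - margin),
              stats::runif(1, margin, (h - 1) - margin))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep) {
      placed <- placed + 1L
      out[placed, ] <- cand
      pts <- rbind(pts, cand)
    }
  }
  out
}

#' Render a synthetic bead movie from a dissociation dataset
#'
#' Each tether becomes a circular feature at a random non-overlapping
#' position; the feature reverts to background (plus noise) from its
#' dissociation frame onward. Clustered pairs and debris persist for the
#' whole movie. Ground truth (positions, radii, true event frames) is
#' attached as sidecar metadata, never embedded in the images.
#'
#' @param dataset a `dissociation_data` object with times on the frame grid.
#' @param params a [movie_sim_params()] object.
#' @return An `image_stack`: list with `frames` (height x width x n_frames
#'   array), `frame_interval`, `time_zero`, and `truth` (sidecar
#'   data.frame: object_id, kind, x, y, radius, event_frame, tether_id).
#' @export
render_bead_movie <- function(dataset, params) {
  stopifnot(inherits(dataset, "dissociation_data"),
            inherits(params, "movie_sim_params"))
  p <- params
  dt <- attr(dataset, "frame_interval")
  t_end <- attr(dataset, "t_end")
  if (!is.finite(t_end)) stopf("movie rendering needs a finite t_end")
  n_frames <- as.integer(round(t_end / dt)) + 1L  # frames at 0, dt, ..., t_end
  n_teth <- nrow(dataset)

  with_seed(p$seed, {
    margin <- p$bead_radius + 3
    min_sep <- 2.5 * p$bead_radius + 2
    pos <- place_objects(n_teth + p$n_clustered + p$n_debris,
                         p$width, p$height, margin, min_sep,
                         matrix(numeric(0), 0, 2))
    teth_pos <- pos[seq_len(n_teth), , drop = FALSE]
    clus_pos <- pos[n_teth + seq_len(p$n_clustered), , drop = FALSE]
    debris_pos <- pos[n_teth + p$n_clustered + seq_len(p$n_debris), ,
                      drop = FALSE]
    clus_phi <- stats::runif(max(p$n_clustered, 0L), 0, 2 * pi)
    debris_phi <- stats::runif(max(p$n_debris, 0L), 0, pi)

    ## First absent frame index per tether (NA = never disappears).
    event_frame <- ifelse(dataset$censored, NA_integer_,
                          as.integer(round(dataset$time_s / dt)) + 1L)

    base <- matrix(p$background, p$height, p$width)
    for (i in seq_len(p$n_clustered)) {
      off <- 1.1 * p$bead_radius * c(cos(clus_phi[i]), sin(clus_phi[i]))
      base <- add_disk(base, clus_pos[i, 1] - off[1], clus_pos[i, 2] - off[2],
                       p$bead_radius, p$bead_contrast)
      base <- add_disk(base, clus_pos[i, 1] + off[1], clus_pos[i, 2] + off[2],
                       p$bead_radius, p$bead_contrast)
    }
    for (i in seq_len(p$n_debris))
      base <- add_ellipse(base, debris_pos[i, 1], debris_pos[i, 2],
                          1.8 * p$bead_radius, 0.55 * p$bead_radius,
                          debris_phi[i], p$bead_contrast)

    frames <- array(0, dim = c(p$height, p$width, n_frames))
    for (f in seq_len(n_frames)) {
      img <- base
      alive <- is.na(event_frame) | f < event_frame
      for (i in which(alive))
        img <- add_disk(img, teth_pos[i, 1], teth_pos[i, 2],
                        p$bead_radius, p$bead_contrast)
      if (p$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(p$height * p$width, 0, p$noise_sigma),
                            p$height, p$width)
      frames[, , f] <- img
    }

    truth <- data.frame(
      object_id = seq_len(n_teth + 2L * p$n_clustered + p$n_debris),
      kind = c(rep("tether", n_teth),
               rep("cluster", 2L * p$n_clustered),
               rep("debris", p$n_debris)),
      x = c(teth_pos[, 1],
            as.vector(t(cbind(
              clus_pos[, 1] - 1.1 * p$bead_radius * cos(clus_phi),
              clus_pos[, 1] + 1.1 * p$bead_radius * cos(clus_phi)))),
            debris_pos[, 1]),
      y = c(teth_pos[, 2],
            as.vector(t(cbind(
              clus_pos[, 2] - 1.1 * p$bead_radius * sin(clus_phi),
              clus_pos[, 2] + 1.1 * p$bead_radius * sin(clus_phi)))),
            debris_pos[, 2]),
      radius = p$bead_radius,
      event_frame = c(event_frame, rep(NA_integer_, 2L * p$n_clustered),
                      rep(NA_integer_, p$n_debris)),
      tether_id = c(dataset$tether_id,
                    rep(NA_integer_, 2L * p$n_clustered + p$n_debris)),
      stringsAsFactors = FALSE)

    image_stack(frames, frame_interval = dt, time_zero = 0, truth = truth,
                params = p)
  })
}

#' Construct an image stack
#'
#' @param frames height x width x n_frames numeric array.
#' @param frame_interval time between saved frames (s).
#' @param time_zero clamp start (s) on the frame time axis.
#' @param truth optional ground-truth sidecar data.frame.
#' @param params optional generator parameters.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval, time_zero = 0, truth = NULL,
                        params = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  structure(list(frames = frames, frame_interval = frame_interval,
                 time_zero = time_zero, truth = truth, params = params),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, dt = %g s\n",
              d[3], d[1], d[2], x$frame_interval))
  invisible(x)
}

#' Frame timestamps of an image stack (s)
#' @param stack an `image_stack`.
#' @return Numeric vector, frame f at time (f-1) * frame_interval.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - 1L) * stack$frame_interval
}
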