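## Summaries of (rho, theta) series: temperature ladders, polar densities,
## stacked-state occupancy, and stacked-basin bimodality.

usable <- function(series) series[!series$flag & is.finite(series$rho_nm), ]

## Maximal runs of consecutive frames with rho above the cutoff.
excursion_runs <- function(rho, cutoff) {
  r <- rle(rho > cutoff)
  sum(r$values)
}

#' Temperature-ladder summary of rho series
#'
#' Per temperature: median rho, interquartile range, number of excursions
#' (maximal runs of consecutive frames with rho above the cutoff) and the
#' fraction of time spent above the cutoff. Rows are ordered by
#' temperature.
#'
#' @param series_list list of `rho_theta` objects (one per temperature;
#'   temperatures are taken from their attributes unless `temperatures` is
#'   given).
#' @param cutoff unstacking cutoff on rho (nm), default 0.75.
#' @param temperatures optional numeric vector overriding the series
#'   temperature labels.
#' @return data.frame: temperature_K, n_frames, median_rho_nm, iqr_rho_nm,
#'   n_excursions, excursion_fraction.
#' @export
rho_series_summary <- function(series_list, cutoff = 0.75,
                               temperatures = NULL) {
  if (inherits(series_list, "rho_theta")) series_list <- list(series_list)
  if (!length(series_list)) stopf("need at least one series")
  temperatures <- temperatures %||%
    vapply(series_list, function(s) attr(s, "temperature") %||% NA_real_,
           numeric(1))
  rows <- lapply(seq_along(series_list), function(i) {
    s <- usable(series_list[[i]])
    if (!nrow(s)) stopf("series %d has no usable frames", i)
    data.frame(temperature_K = temperatures[i],
               n_frames = nrow(s),
               median_rho_nm = stats::median(s$rho_nm),
               iqr_rho_nm = stats::IQR(s$rho_nm),
               n_excursions = excursion_runs(s$rho_nm, cutoff),
               excursion_fraction = mean(s$rho_nm > cutoff))
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature_K), , drop = FALSE]
}

#' Two-dimensional polar density of a rho-theta series
#'
#' Normalized 2-D histogram over (rho, theta). Flagged frames are excluded
#' and their count reported.
#'
#' @param series a `rho_theta` object.
#' @param rho_breaks,theta_breaks bin edges; defaults cover the observed
#'   rho range with 30 bins and \[0, 180\] degrees with 18 bins.
#' @return A `polar_density`: list with `counts` (rho x theta matrix
#'   summing to 1), `rho_breaks`, `theta_breaks`, `n_flagged`,
#'   `temperature`.
#' @export
polar_density <- function(series, rho_breaks = NULL, theta_breaks = NULL) {
  stopifnot(inherits(series, "rho_theta"))
  s <- usable(series)
  if (!nrow(s)) stopf("no usable frames")
  rho_breaks <- rho_breaks %||%
    seq(0, max(s$rho_nm) * 1.001 + 1e-9, length.out = 31)
  theta_breaks <- theta_breaks %||% seq(0, 180, length.out = 19)
  ri <- cut(s$rho_nm, rho_breaks, include.lowest = TRUE)
  ti <- cut(pmin(pmax(s$theta_deg, 0), 180), theta_breaks,
            include.lowest = TRUE)
  counts <- table(ri, ti)
  structure(list(counts = unclass(counts) / sum(counts),
                 rho_breaks = rho_breaks, theta_breaks = theta_breaks,
                 n_flagged = nrow(series) - nrow(s),
                 temperature = attr(series, "temperature")),
            class = "polar_density")
}

#' Fraction of frames in the stacked state
#'
#' Fraction of non-flagged frames with rho at or below the cutoff; the
#' stacked state lives near the ~0.5 nm stable stacking distance, so the
#' default cutoff of 0.75 nm separates it from unstacking excursions.
#'
#' @param series a `rho_theta` object.
#' @param rho_cutoff cutoff (nm), default 0.75.
#' @return Scalar fraction in \[0, 1\].
#' @export
stacked_fraction <- function(series, rho_cutoff = 0.75) {
  stopifnot(inherits(series, "rho_theta"))
  s <- usable(series)
  if (!nrow(s)) stopf("no usable frames")
  mean(s$rho_nm <= rho_cutoff)
}

#' Gaussian-mixture bimodality analysis of the stacked basin
#'
#' Fits 1- and 2-component Gaussian mixtures to the series in the
#' (rho, theta) plane and selects the component count by BIC with a
#' configurable margin. Because theta is defined through the dot product it
#' is already folded onto \[0, 180\] degrees, so no angular wraparound can
#' occur in this plane; fitting there (rather than in a Cartesian
#' rho*cos/sin embedding) keeps a single fluctuating stacked state -- a
#' product of Gaussians in rho and theta -- genuinely one component instead
#' of a curved arc. Fitting is restricted to frames with `rho <= rho_max`,
#' i.e. to the stacked basin: the diffuse unstacked excursion cloud would
#' otherwise absorb a component. Each cluster is reported with its
#' (rho, theta) mean, weight, covariance summary, and a centroid frame: the
#' member frame nearest the cluster mean in the cluster's Mahalanobis
#' metric.
#'
#' @param series a `rho_theta` object with at least 50 usable frames.
#' @param max_components maximum mixture size (default 2).
#' @param rho_max stacked-basin ceiling (nm), default 0.9; `Inf` disables
#'   the restriction.
#' @param ic_margin BIC margin required to accept the larger model,
#'   default 10.
#' @param seed RNG seed (mixture initialization is deterministic given it).
#' @importFrom mclust Mclust mclustBIC
#' @return A `cluster_report`: list with `n_components`, `means`
#'   (data.frame of per-cluster rho_nm, theta_deg), `weights`,
#'   `covariances` (2 x 2 x G array), `centroid_frames` (frame indices
#'   into the original series), `score_diff` (BIC(2) - BIC(1), larger
#'   favors 2), `n_used`.
#' @export
cluster_interface_states <- function(series, max_components = 2,
                                     rho_max = 0.9, ic_margin = 10,
                                     seed = 1L) {
  stopifnot(inherits(series, "rho_theta"))
  s <- usable(series)
  s <- s[s$rho_nm <= rho_max, ]
  if (nrow(s) < 50) stopf("need at least 50 usable frames for clustering")
  xy <- cbind(rho_nm = s$rho_nm, theta_deg = s$theta_deg)
  fit <- with_seed(seed, tryCatch(
    Mclust(xy, G = seq_len(max_components), modelNames = "VVV",
           verbose = FALSE),
    error = function(e) NULL))
  fallback <- function(reason) {
    warning(sprintf("mixture fit degenerate (%s); falling back to 1 component",
                    reason))
    mu <- colMeans(xy)
    sig <- stats::cov(xy)
    d2 <- stats::mahalanobis(xy, mu, sig)
    structure(list(n_components = 1L,
                   means = data.frame(rho_nm = mu[1], theta_deg = mu[2]),
                   weights = 1,
                   covariances = array(sig, c(2, 2, 1)),
                   centroid_frames = s$frame[which.min(d2)],
                   score_diff = NA_real_, n_used = nrow(s)),
              class = "cluster_report")
  }
  if (is.null(fit)) return(fallback("fit failed"))
  bic <- fit$BIC[, "VVV"]
  if (any(!is.finite(bic))) return(fallback("non-finite BIC"))
  n_comp <- if (length(bic) >= 2 && bic[2] - bic[1] >= ic_margin) 2L else 1L
  ## Refit at the selected size for clean parameters/classification.
  sel <- with_seed(seed, Mclust(xy, G = n_comp, modelNames = "VVV",
                                verbose = FALSE))
  if (is.null(sel)) return(fallback("refit failed"))
  mu <- sel$parameters$mean                      # 2 x G (rho, theta)
  sig <- sel$parameters$variance$sigma           # 2 x 2 x G
  wts <- sel$parameters$pro
  cls <- sel$classification
  centroids <- integer(n_comp)
  for (g in seq_len(n_comp)) {
    member <- which(cls == g)
    d2 <- stats::mahalanobis(xy[member, , drop = FALSE], mu[, g], sig[, , g])
    centroids[g] <- s$frame[member[which.min(d2)]]
  }
  structure(list(
    n_components = n_comp,
    means = data.frame(rho_nm = mu[1, ], theta_deg = mu[2, ]),
    weights = wts, covariances = sig, centroid_frames = centroids,
    score_diff = if (length(bic) >= 2) unname(bic[2] - bic[1]) else NA_real_,
    n_used = nrow(s)),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d component(s) over %d frames\n",
              x$n_components, x$n_used))
  for (g in seq_len(x$n_components))
    cat(sprintf("  %d: rho %.3f nm, theta %.1f deg, weight %.2f, centroid frame %d\n",
                g, x$means$rho_nm[g], x$means$theta_deg[g], x$weights[g],
                x$centroid_frames[g]))
  invisible(x)
}
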