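#' Parameters for the synthetic dissociation-time generator
#'
#' Describes a force-clamp experiment in which tethers dissociate as a
#' first-order process with rate `k_off`, a fraction `baseline_frac` of
#' tethers never dissociates (surface-stuck beads and other non-specific
#' attachments that populate the baseline term of the survival fit), and
#' observation stops at `t_end`. Times are recorded on the acquisition
#' frame grid (`frame_interval`; the instrument saves at 0.2 fps, i.e.
#' every 5 s, by default).
#'
#' @param k_off true off-rate (1/s), > 0.
#' @param n_tethers number of tethers to simulate (>= 1).
#' @param t_end observation window (s); may be `Inf` for an uncensored run.
#' @param frame_interval acquisition grid spacing (s).
#' @param baseline_frac fraction in \[0, 1\] of tethers that never dissociate.
#' @param seed integer RNG seed.
#' @return An object of class `kinetics_sim_params`.
#' @export
kinetics_sim_params <- function(k_off, n_tethers, t_end = Inf,
                                frame_interval = 5, baseline_frac = 0,
                                seed = 1L) {
  if (!is.numeric(k_off) || length(k_off) != 1L || !is.finite(k_off) || k_off <= 0)
    stopf("`k_off` must be a single finite number > 0")
  check_scalar(n_tethers, "n_tethers", positive = TRUE)
  if (n_tethers < 1 || n_tethers != round(n_tethers))
    stopf("`n_tethers` must be a positive integer")
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end <= 0)
    stopf("`t_end` must be > 0 (Inf allowed)")
  check_scalar(frame_interval, "frame_interval", positive = TRUE)
  check_scalar(baseline_frac, "baseline_frac")
  if (baseline_frac < 0 || baseline_frac > 1)
    stopf("`baseline_frac` must lie in [0, 1]")
  structure(list(k_off = k_off, n_tethers = as.integer(n_tethers),
                 t_end = t_end, frame_interval = frame_interval,
                 baseline_frac = baseline_frac, seed = as.integer(seed)),
            class = "kinetics_sim_params")
}

#' Simulate per-tether dissociation times under a force clamp
#'
#' Non-baseline tethers draw an exponential(`k_off`) lifetime; lifetimes are
#' snapped up to the next acquisition frame (the event is only observable at
#' the first saved frame after it happened). Tethers whose snapped time
#' exceeds `t_end`, and all baseline tethers, are censored at `t_end`.
#'
#' @param params a [kinetics_sim_params()] object.
#' @return A `dissociation_data` data.frame with columns `tether_id`,
#'   `time_s`, `censored` (logical), `replicate_id`, and attributes
#'   `t_end`, `frame_interval`, `time_zero`.
#' @export
sample_dissociation_times <- function(params) {
  stopifnot(inherits(params, "kinetics_sim_params"))
  p <- params
  with_seed(p$seed, {
    baseline <- stats::runif(p$n_tethers) < p$baseline_frac
    raw <- stats::rexp(p$n_tethers, rate = p$k_off)
    snapped <- ceiling(raw / p$frame_interval) * p$frame_interval
    censored <- baseline | snapped > p$t_end
    time_s <- ifelse(censored, p$t_end, snapped)
    dissociation_data(
      data.frame(tether_id = seq_len(p$n_tethers),
                 time_s = time_s,
                 censored = censored,
                 replicate_id = 1L),
      t_end = p$t_end, frame_interval = p$frame_interval)
  })
}

#' Construct a dissociation dataset
#'
#' @param df data.frame with columns `tether_id`, `time_s`, `censored`,
#'   `replicate_id`.
#' @param t_end observation window (s).
#' @param frame_interval acquisition grid (s).
#' @param time_zero clamp start time (s); event times are relative to it.
#' @return A `dissociation_data` object.
#' @export
dissociation_data <- function(df, t_end = Inf, frame_interval = NA_real_,
                              time_zero = 0) {
  need <- c("tether_id", "time_s", "censored", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.na(df$time_s) & df$time_s < 0)) stopf("negative event times")
  df$censored <- as.logical(df$censored)
  structure(df[, need], class = c("dissociation_data", "data.frame"),
            t_end = t_end, frame_interval = frame_interval,
            time_zero = time_zero)
}

#' @export
print.dissociation_data <- function(x, ...) {
  cat(sprintf("dissociation_data: %d tethers, %d censored, t_end = %s s\n",
              nrow(x), sum(x$censored), format(attr(x, "t_end"))))
  invisible(x)
}
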