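#' Parameters for the synthetic nicked-interface trajectory generator
#'
#' The generator emulates a restrained nicked-duplex simulation: the two
#' nucleotides flanking the nick alternate between a stacked state
#' (fluctuating about the idealized B-form step) and an unstacked state
#' (inflated inter-ring distance, randomized twist), as a discrete-time
#' two-state Markov chain whose per-frame unstacking probability is
#' `attempt_freq * exp(delta_g / RT)`. Weaker (less negative) stacking free
#' energies and higher temperatures therefore both increase excursion
#' frequency; the attempt frequency is a free scale, so only orderings
#' across `delta_g`/`temperature` are meaningful, not absolute rates.
#'
#' @param delta_g stacking free energy (kcal/mol, <= 0 for a stabilizing
#'   stack).
#' @param temperature simulation temperature (K).
#' @param n_frames number of saved frames; alternatively give `duration_ns`.
#' @param frame_dt saving interval (ps), default 25.
#' @param duration_ns optional production length (ns); when supplied,
#'   `n_frames = duration_ns * 1000 / frame_dt` (250 ns at 25 ps gives
#'   10,000 frames).
#' @param base_5p,base_3p interface base letters (5' and 3' side of the
#'   stack).
#' @param rho_stacked_mean stacked-state inter-ring-center distance (nm);
#'   `NULL` (default) uses the ideal-step value (~0.48 nm).
#' @param rho_stacked_sd Gaussian sd of the stacked-state rho (nm).
#' @param theta_diffusion per-frame variance of the twist-angle random walk
#'   (degrees^2/frame).
#' @param theta_reversion mean-reversion rate of the twist angle per frame
#'   (0 = pure diffusion); keeps stacked substates localized in theta.
#' @param unstacked_rho_scale rho inflation of the unstacked state (nm);
#'   0 makes the unstacked state geometrically identical to the stacked one
#'   (degenerate-testing convention).
#' @param bimodal logical; if `TRUE` the stacked state alternates between
#'   two substates with distinct (rho, theta) offsets (a second stacked
#'   geometry such as a base sitting over the five-membered ring).
#' @param bimodal_rho_offset,bimodal_theta_offset offsets (nm, degrees) of
#'   the second stacked substate.
#' @param bimodal_switch_prob per-frame substate switching probability.
#' @param attempt_freq dimensionless unstacking attempt scale.
#' @param restack_prob per-frame restacking probability.
#' @param seed integer RNG seed.
#' @return An object of class `stack_sim_params`.
#' @export
stack_sim_params <- function(delta_g, temperature = 300, n_frames = 10000,
                             frame_dt = 25, duration_ns = NULL,
                             base_5p = "G", base_3p = "C",
                             rho_stacked_mean = NULL, rho_stacked_sd = 0.03,
                             theta_diffusion = 25, theta_reversion = 0.05,
                             unstacked_rho_scale = 0.8,
                             bimodal = FALSE, bimodal_rho_offset = -0.12,
                             bimodal_theta_offset = 55,
                             bimodal_switch_prob = 0.01,
                             attempt_freq = 1.0, restack_prob = 0.25,
                             seed = 1L) {
  if (!is.numeric(delta_g) || length(delta_g) != 1L || !is.finite(delta_g))
    stopf("`delta_g` must be a single finite number (kcal/mol)")
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(frame_dt, "frame_dt", positive = TRUE)
  if (!is.null(duration_ns)) {
    check_scalar(duration_ns, "duration_ns", positive = TRUE)
    n_frames <- round(duration_ns * 1000 / frame_dt)
  }
  if (!is.numeric(n_frames) || length(n_frames) != 1L || !is.finite(n_frames) ||
      n_frames < 1 || n_frames != round(n_frames))
    stopf("`n_frames` must be a positive integer")
  if (!is.null(rho_stacked_mean))
    check_scalar(rho_stacked_mean, "rho_stacked_mean", positive = TRUE)
  check_base(base_5p); check_base(base_3p)
  structure(list(delta_g = delta_g, temperature = temperature,
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 base_5p = base_5p, base_3p = base_3p,
                 rho_stacked_mean = rho_stacked_mean,
                 rho_stacked_sd = rho_stacked_sd,
                 theta_diffusion = theta_diffusion,
                 theta_reversion = theta_reversion,
                 unstacked_rho_scale = unstacked_rho_scale,
                 bimodal = isTRUE(bimodal),
                 bimodal_rho_offset = bimodal_rho_offset,
                 bimodal_theta_offset = bimodal_theta_offset,
                 bimodal_switch_prob = bimodal_switch_prob,
                 attempt_freq = attempt_freq, restack_prob = restack_prob,
                 seed = as.integer(seed)),
            class = "stack_sim_params")
}

## Stationary per-frame unstacking probability implied by the parameters.
unstack_prob <- function(params) {
  min(1, params$attempt_freq *
        exp(params$delta_g / (R_KCAL * params$temperature)))
}

#' Generate a synthetic nicked-interface trajectory
#'
#' Emits per-frame coordinates (nm) of the six-membered rings of the two
#' interface nucleotides plus two fixed terminal-anchor rings (emulating
#' position restraints on the terminal nucleotides of the duplex). The
#' per-frame hidden state (`stacked`, `stacked2`, `unstacked`) is attached
#' as ground-truth sidecar metadata.
#'
#' @param params a [stack_sim_params()] object.
#' @return An object of class `interface_trajectory`: list with `coords`
#'   (n_atoms x 3 x n_frames array, nm), `atoms` (data.frame: eleno, elety,
#'   resid, resname, chain, anchor), `n_frames`, `frame_dt` (ps),
#'   `temperature` (K), `states` (character per frame), `interface`
#'   (residue/base bookkeeping), and `params`.
#' @export
generate_interface_trajectory <- function(params) {
  stopifnot(inherits(params, "stack_sim_params"))
  p <- params
  n <- p$n_frames
  step <- ideal_stacked_step(p$base_5p, p$base_3p)
  c5 <- step$centers["base_5p", ]; c3 <- step$centers["base_3p", ]
  sep <- c3 - c5
  rho_ideal <- sqrt(sum(sep^2))
  u_sep <- sep / rho_ideal
  rho_base <- p$rho_stacked_mean %||% rho_ideal
  offsets <- sweep(step$coords$base_3p, 2, c3)   # planar: z column is 0

  ## Anchor rings: terminal nucleotides of a 12-bp duplex with the nick
  ## between residues 6 and 7 (interface = residues 6 and 7).
  anchor_lo <- helical_ring("A", -5, step$params$rise, step$params$twist,
                            step$params$radial_disp, step$params$ring_radius)
  anchor_hi <- helical_ring("T", 6, step$params$rise, step$params$twist,
                            step$params$radial_disp, step$params$ring_radius)

  p_un <- unstack_prob(p)
  with_seed(p$seed, {
    ## Two-state chain (1 = stacked, 0 = unstacked), started stacked.
    u1 <- stats::runif(n); state <- integer(n); s <- 1L
    for (i in seq_len(n)) {
      s <- if (s == 1L) {
        if (u1[i] < p_un) 0L else 1L
      } else {
        if (u1[i] < p$restack_prob) 1L else 0L
      }
      state[i] <- s
    }
    ## Stacked substate chain for the bimodal flag (1 or 2).
    if (p$bimodal) {
      u2 <- stats::runif(n); sub <- integer(n); ss <- 1L
      for (i in seq_len(n)) {
        if (u2[i] < p$bimodal_switch_prob) ss <- 3L - ss
        sub[i] <- ss
      }
    } else sub <- rep(1L, n)

    ## Twist angle: AR(1) (Ornstein-Uhlenbeck) fluctuation plus substate
    ## offset; unstacked frames are redrawn uniformly on (-180, 180].
    eps <- stats::rnorm(n, 0, sqrt(p$theta_diffusion))
    x <- as.numeric(stats::filter(eps, 1 - p$theta_reversion,
                                  method = "recursive"))
    psi <- x + ifelse(sub == 2L, p$bimodal_theta_offset, 0)
    psi_un <- stats::runif(n, -180, 180)
    rho_noise <- stats::rnorm(n, 0, p$rho_stacked_sd)
    rho_infl <- p$unstacked_rho_scale * (1 + abs(stats::rnorm(n, 0, 0.3)))
    stacked <- state == 1L
    rho <- rho_base + rho_noise +
      ifelse(stacked & sub == 2L, p$bimodal_rho_offset, 0) +
      ifelse(stacked, 0, rho_infl)
    rho <- pmax(rho, 0.05)
    if (p$unstacked_rho_scale > 0) psi[!stacked] <- psi_un[!stacked]
  })

  ## Assemble coordinates.
  c3t <- outer(rho, u_sep)                       # n x 3 moving 3' centre
  c3t <- sweep(c3t, 2, c5, "+")
  cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
  coords <- array(NA_real_, dim = c(24L, 3L, n))
  fixed_block <- rbind(anchor_lo, step$coords$base_5p)
  for (k in 1:12) for (j in 1:3) coords[k, j, ] <- fixed_block[k, j]
  for (k in 1:6) {
    ox <- offsets[k, 1]; oy <- offsets[k, 2]
    coords[12L + k, 1, ] <- c3t[, 1] + ox * cp - oy * sp
    coords[12L + k, 2, ] <- c3t[, 2] + ox * sp + oy * cp
    coords[12L + k, 3, ] <- c3t[, 3]
  }
  for (k in 1:6) for (j in 1:3) coords[18L + k, j, ] <- anchor_hi[k, j]

  atoms <- data.frame(
    eleno = 1:24,
    elety = rep(RING_ATOMS, 4),
    resid = rep(c(1L, 6L, 7L, 12L), each = 6),
    resname = rep(paste0("D", c("A", p$base_5p, p$base_3p, "T")), each = 6),
    chain = "A",
    anchor = rep(c(TRUE, FALSE, FALSE, TRUE), each = 6),
    stringsAsFactors = FALSE)

  structure(list(coords = coords, atoms = atoms, n_frames = n,
                 frame_dt = p$frame_dt, temperature = p$temperature,
                 states = c("unstacked", "stacked", "stacked2")[
                   ifelse(state == 1L, ifelse(sub == 2L, 3L, 2L), 1L) + 0L],
                 interface = list(res_5p = 6L, res_3p = 7L,
                                  base_5p = p$base_5p, base_3p = p$base_3p,
                                  anchor_resids = c(1L, 12L)),
                 params = p),
            class = "interface_trajectory")
}

#' @export
print.interface_trajectory <- function(x, ...) {
  cat(sprintf(
    "interface_trajectory: %d frames x %d atoms, %s|%s, %g K, dt %g ps\n",
    x$n_frames, nrow(x$atoms), x$interface$base_5p, x$interface$base_3p,
    x$temperature, x$frame_dt))
  invisible(x)
}
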