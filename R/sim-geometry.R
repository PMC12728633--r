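## Idealized B-form stacked-step construction.
##
## Each base contributes its six-membered ring (atoms N1, C2, N3, C4, C5, C6)
## as a planar regular hexagon of radius `ring_radius`, lying perpendicular
## to the helix axis (z). Successive bases along a strand are related by the
## fiber B-form step: rise 0.34 nm and twist 36 degrees. Ring centers sit at
## a common radial displacement `radial_disp` from the axis, and each ring is
## oriented so that its Watson-Crick-face bisector (through the midpoint of
## C2/C6 for purines, C2/C4 for pyrimidines) points at the axis, i.e. toward
## the pairing partner. The radial displacement is the calibration knob that
## sets the inter-ring-center distance of the stacked state; the default
## 0.55 nm places it at ~0.48 nm, the stable stacking distance regime.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6")

check_base <- function(base) {
  if (!is.character(base) || length(base) != 1L ||
      !(base %in% c(PURINES, PYRIMIDINES)))
    stopf("unknown base letter: %s (expected A, C, G or T)",
          paste(format(base), collapse = ","))
  base
}

is_purine <- function(base) base %in% PURINES

## Six-membered-ring coordinates (nm) for one base at helical step `index`
## (0 = reference level, +1 = one step up the strand).
helical_ring <- function(base, index, rise = 0.34, twist = 36,
                         radial_disp = 0.55, ring_radius = 0.139) {
  phi <- index * twist                      # azimuth of the ring centre (deg)
  centre <- c(radial_disp * cos(deg2rad(phi)),
              radial_disp * sin(deg2rad(phi)),
              index * rise)
  ## Azimuth of the WC-face direction: from centre toward the axis.
  wc_az <- phi + 180
  ## N1 sits on the WC azimuth for purines; N3 (two ring positions on) for
  ## pyrimidines, so N1 is rotated back by 120 degrees.
  n1_az <- if (is_purine(base)) wc_az else wc_az - 120
  ang <- deg2rad(n1_az + 60 * (0:5))
  xyz <- cbind(centre[1] + ring_radius * cos(ang),
               centre[2] + ring_radius * sin(ang),
               centre[3])
  dimnames(xyz) <- list(RING_ATOMS, c("x", "y", "z"))
  xyz
}

#' Idealized B-form coordinates for two stacked bases across a nick
#'
#' Builds deterministic six-membered-ring coordinates for the 5' base and
#' the 3' base of a stack using fiber B-form helical parameters. The 5'
#' base sits at the reference level, the 3' base one step (rise + twist) up
#' the helix. Units are nm.
#'
#' @param base_5p,base_3p base letters in `A`, `C`, `G`, `T`.
#' @param rise helical rise per step (nm), default 0.34.
#' @param twist helical twist per step (degrees), default 36.
#' @param radial_disp radial displacement of the ring centers from the helix
#'   axis (nm); calibrates the stacked inter-center distance.
#' @param ring_radius hexagon circumradius (nm), default 0.139 (aromatic
#'   C-C/C-N bond length).
#' @return An object of class `stacked_step`: list with `coords` (named list
#'   of two 6x3 matrices, rows N1..C6), `centers` (2x3), the base letters
#'   and the construction parameters.
#' @examples
#' step <- ideal_stacked_step("A", "A")
#' sqrt(sum((step$centers[1, ] - step$centers[2, ])^2))  # ~0.48 nm
#' @export
ideal_stacked_step <- function(base_5p, base_3p, rise = 0.34, twist = 36,
                               radial_disp = 0.55, ring_radius = 0.139) {
  b5 <- check_base(base_5p); b3 <- check_base(base_3p)
  r5 <- helical_ring(b5, 0, rise, twist, radial_disp, ring_radius)
  r3 <- helical_ring(b3, 1, rise, twist, radial_disp, ring_radius)
  structure(list(
    base_5p = b5, base_3p = b3,
    coords = list(base_5p = r5, base_3p = r3),
    centers = rbind(base_5p = colMeans(r5), base_3p = colMeans(r3)),
    params = list(rise = rise, twist = twist, radial_disp = radial_disp,
                  ring_radius = ring_radius,
                  source = "idealized fiber B-form, regular-hexagon base rings")),
    class = "stacked_step")
}

#' @export
print.stacked_step <- function(x, ...) {
  rho <- sqrt(sum((x$centers[1, ] - x$centers[2, ])^2))
  cat(sprintf("stacked_step %s|%s: rise %.2f nm, twist %g deg, rho = %.3f nm\n",
              x$base_5p, x$base_3p, x$params$rise, x$params$twist, rho))
  invisible(x)
}
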