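#' Interface specification for the (rho, theta) projection
#'
#' Identifies the two nucleotides flanking the nick (the 5' base and the 3'
#' base of the stack, `X|Y` notation) and the anchor residues used to align
#' each frame into the reference laboratory frame whose z axis carries the
#' helix axis.
#'
#' @param res_5p,res_3p residue numbers of the 5' and 3' interface
#'   nucleotides (distinct).
#' @param base_5p,base_3p their base letters.
#' @param anchor_resids residue numbers of the restrained terminal
#'   nucleotides whose atoms drive the alignment.
#' @param chain chain identifier.
#' @return An object of class `interface_spec`.
#' @export
interface_spec <- function(res_5p, res_3p, base_5p, base_3p,
                           anchor_resids, chain = "A") {
  if (res_5p == res_3p) stopf("the two interface residues must be distinct")
  check_base(base_5p); check_base(base_3p)
  structure(list(res_5p = as.integer(res_5p), res_3p = as.integer(res_3p),
                 base_5p = base_5p, base_3p = base_3p,
                 anchor_resids = as.integer(anchor_resids), chain = chain),
            class = "interface_spec")
}

#' Geometric center of a base's six-membered ring
#'
#' Unweighted mean of the positions of atoms N1, C2, N3, C4, C5, C6 (for
#' purines these names address the six-membered ring of the fused system;
#' the same six names are used for every base).
#'
#' @param atoms matrix of atom coordinates with rownames containing the
#'   ring atom names (rows x 3 columns).
#' @param base base letter (used only for validation/reporting).
#' @return Numeric length-3 center.
#' @export
ring_center <- function(atoms, base = NULL) {
  if (!is.null(base)) check_base(base)
  missing_atoms <- setdiff(RING_ATOMS, rownames(atoms))
  if (length(missing_atoms))
    stopf("missing ring atom(s): %s", paste(missing_atoms, collapse = ", "))
  colMeans(atoms[RING_ATOMS, , drop = FALSE])
}

#' Watson-Crick-face bisector vector of a base
#'
#' Unit vector from the ring center through the midpoint of the two ring
#' carbons flanking the Watson-Crick face: C2 and C6 for purines (A, G),
#' C2 and C4 for pyrimidines (C, T). This carbon-pair reading of the WC
#' face is isolated here so it can be swapped wholesale if desired.
#'
#' @param atoms coordinate matrix with ring-atom rownames.
#' @param base base letter.
#' @return Unit length-3 vector.
#' @export
wc_face_vector <- function(atoms, base) {
  check_base(base)
  ctr <- ring_center(atoms, base)
  carbons <- if (is_purine(base)) c("C2", "C6") else c("C2", "C4")
  mid <- colMeans(atoms[carbons, , drop = FALSE])
  v <- mid - ctr
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stopf("degenerate Watson-Crick face vector")
  v / nv
}

#' Rigidly align a frame onto a reference using anchor atoms
#'
#' Least-squares (Kabsch) superposition computed on the anchor atoms only
#' and applied to the whole frame. The reference orientation is expected to
#' carry the duplex helix axis along z so that the xy-plane projection of
#' theta is well defined.
#'
#' @param frame n x 3 coordinate matrix to transform.
#' @param reference n_ref x 3 reference coordinates (same atom order as
#'   `frame[anchor_idx, ]`... see `anchor_idx`).
#' @param anchor_idx indices of the anchor atoms within `frame`; the
#'   reference must contain these same atoms in the same order (either as
#'   its only rows, or addressed by the same indices when `reference` has
#'   the full frame's rows).
#' @return The transformed frame (n x 3), with the rigid transform attached
#'   as attributes `rotation` and `translation`.
#' @export
align_frame <- function(frame, reference, anchor_idx) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  ref_anchor <- if (nrow(reference) == length(anchor_idx)) reference
                else reference[anchor_idx, , drop = FALSE]
  mov_anchor <- frame[anchor_idx, , drop = FALSE]
  if (nrow(mov_anchor) < 3) stopf("need at least 3 anchor atoms")
  ## Collinearity check: rank of the centred anchor cloud must be >= 2.
  sv <- svd(sweep(mov_anchor, 2, colMeans(mov_anchor)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("anchor atoms are collinear; alignment is underdetermined")
  tr <- kabsch(mov_anchor, ref_anchor)
  out <- apply_rigid(frame, tr$R, tr$t)
  attr(out, "rotation") <- tr$R
  attr(out, "translation") <- tr$t
  out
}

#' Project one aligned frame onto the (rho, theta) coordinate system
#'
#' `rho` is the Euclidean distance between the six-membered-ring centers of
#' the two interface nucleotides. `theta` is the angle between their
#' Watson-Crick-face bisector vectors after zeroing the z components and
#' renormalizing, reported in degrees on \[0, 180\] via the dot product.
#' Frames whose projected vectors nearly vanish are flagged degenerate
#' rather than dropped, preserving frame counts.
#'
#' @param atoms_5p,atoms_3p coordinate matrices (ring-atom rownames) of the
#'   5' and 3' nucleotides in the aligned frame.
#' @param base_5p,base_3p base letters.
#' @param eps degeneracy threshold on the projected vector norm.
#' @return List with `rho`, `theta` (degrees), `flag` (TRUE when the
#'   projection is degenerate).
#' @export
project_rho_theta <- function(atoms_5p, atoms_3p, base_5p, base_3p,
                              eps = 1e-6) {
  c5 <- ring_center(atoms_5p, base_5p)
  c3 <- ring_center(atoms_3p, base_3p)
  rho <- sqrt(sum((c5 - c3)^2))
  v5 <- wc_face_vector(atoms_5p, base_5p)
  v3 <- wc_face_vector(atoms_3p, base_3p)
  v5[3] <- 0; v3[3] <- 0
  n5 <- sqrt(sum(v5^2)); n3 <- sqrt(sum(v3^2))
  if (n5 < eps || n3 < eps)
    return(list(rho = rho, theta = NA_real_, flag = TRUE))
  ct <- sum(v5 * v3) / (n5 * n3)
  list(rho = rho, theta = rad2deg(acos(pmin(1, pmax(-1, ct)))), flag = FALSE)
}

#' Project a whole trajectory onto (rho, theta)
#'
#' Aligns every frame onto the reference via the anchor atoms, then applies
#' [project_rho_theta()] per frame. For generator output the interface and
#' anchors are taken from the trajectory itself; for externally read
#' trajectories supply an [interface_spec()].
#'
#' @param traj an `interface_trajectory`.
#' @param spec an `interface_spec`; defaults to the trajectory's own
#'   bookkeeping.
#' @param reference reference coordinates (n_atoms x 3); defaults to the
#'   first frame.
#' @param align logical, set `FALSE` to skip alignment (already-aligned
#'   input).
#' @return A `rho_theta` data.frame: `frame`, `time_ps`, `rho_nm`,
#'   `theta_deg`, `flag`; attribute `temperature`.
#' @export
project_trajectory <- function(traj, spec = NULL, reference = NULL,
                               align = TRUE) {
  stopifnot(inherits(traj, "interface_trajectory"))
  spec <- spec %||% interface_spec(traj$interface$res_5p,
                                   traj$interface$res_3p,
                                   traj$interface$base_5p,
                                   traj$interface$base_3p,
                                   traj$interface$anchor_resids)
  at <- traj$atoms
  idx5 <- which(at$resid == spec$res_5p)
  idx3 <- which(at$resid == spec$res_3p)
  anchor_idx <- which(at$resid %in% spec$anchor_resids)
  if (!length(idx5) || !length(idx3)) stopf("interface residues not found")
  if (length(anchor_idx) < 3) stopf("need at least 3 anchor atoms")
  reference <- reference %||% traj$coords[, , 1]
  n <- traj$n_frames
  rho <- theta <- numeric(n); flag <- logical(n)
  rn5 <- at$elety[idx5]; rn3 <- at$elety[idx3]
  for (f in seq_len(n)) {
    fr <- traj$coords[, , f]
    if (align) fr <- align_frame(fr, reference, anchor_idx)
    a5 <- fr[idx5, , drop = FALSE]; rownames(a5) <- rn5
    a3 <- fr[idx3, , drop = FALSE]; rownames(a3) <- rn3
    pr <- project_rho_theta(a5, a3, spec$base_5p, spec$base_3p)
    rho[f] <- pr$rho; theta[f] <- pr$theta; flag[f] <- pr$flag
  }
  rho_theta(data.frame(frame = seq_len(n),
                       time_ps = (seq_len(n) - 1) * traj$frame_dt,
                       rho_nm = rho, theta_deg = theta, flag = flag),
            temperature = traj$temperature)
}

#' Construct a rho-theta series
#'
#' @param df data.frame with columns `frame`, `time_ps`, `rho_nm`,
#'   `theta_deg`, `flag`.
#' @param temperature temperature label (K).
#' @return A `rho_theta` object.
#' @export
rho_theta <- function(df, temperature = NA_real_) {
  need <- c("frame", "time_ps", "rho_nm", "theta_deg", "flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$rho_nm < 0, na.rm = TRUE)) stopf("rho must be >= 0")
  structure(df[, need], class = c("rho_theta", "data.frame"),
            temperature = temperature)
}
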