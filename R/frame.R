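## Local wall coordinate system and cardiac angle maps.

#' Cylindrical local wall frame
#'
#' Builds a per-voxel right-handed orthonormal triad (longitudinal,
#' circumferential, radial) from a cylindrical approximation of the
#' ventricular wall: the user supplies the long axis (default: third
#' array dimension) and the per-slice centroid defaults to the grid
#' centre. This is the documented fallback for real data whose
#' mesh-based local frame is unavailable; the phantom generator supplies
#' the true frame directly.
#'
#' @param dim integer vector, 3-D grid dimensions.
#' @param center xy centre of the annulus in voxel coordinates (defaults
#'   to the grid centre).
#' @param long_axis index of the array dimension along the long axis
#'   (default 3).
#' @return a `wall_frame` object: matrices `long`, `circ`, `radial`
#'   (n_voxel x 3, row order = column-major voxel order) and `valid`
#'   (logical; voxels on the axis have no defined frame).
#' @export
cylindrical_wall_frame <- function(dim, center = NULL, long_axis = 3L) {
  stopifnot(length(dim) == 3L, long_axis %in% 1:3)
  if (is.null(center)) center <- (dim[-long_axis] + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  planar <- setdiff(1:3, long_axis)
  L <- matrix(0, nrow(idx), 3); L[, long_axis] <- 1
  R <- matrix(0, nrow(idx), 3)
  R[, planar[1]] <- idx[, planar[1]] - center[1]
  R[, planar[2]] <- idx[, planar[2]] - center[2]
  nrm <- sqrt(rowSums(R^2))
  valid <- nrm > 1e-9
  R <- normalize_rows(R)
  C <- vec_cross(R, L)   # right-handed in the order (long, circ, radial)
  structure(list(long = L, circ = C, radial = R, valid = valid, dim = dim),
            class = "wall_frame")
}

#' Helix, transverse and sheetlet angle maps
#'
#' Angle conventions (degrees, all in `[-90, 90]`):
#' \itemize{
#'   \item helix: angle between the projection of the primary
#'     eigenvector onto the circumferential-longitudinal plane and the
#'     short-axis (circumferential) direction; 0 when the primary
#'     eigenvector is circumferential, +/-90 when longitudinal.
#'   \item transverse: angle between the projection of the primary
#'     eigenvector onto the short-axis plane and the circumferential
#'     direction.
#'   \item sheetlet: angle between the projection of the tertiary
#'     eigenvector onto the longitudinal-radial plane and the radial
#'     direction, measured toward the long axis; 0 when the tertiary
#'     eigenvector is radial.
#' }
#' Eigenvector signs are fixed before computation (primary flipped so
#' its circumferential component is non-negative, tertiary so its radial
#' component is non-negative), so all angles are invariant to
#' eigenvector sign flips. Voxels with a degenerate frame yield `NA`.
#'
#' @param v1,v3 primary and tertiary eigenvectors, n x 3 matrices (or
#'   length-3 vectors for a single voxel).
#' @param frame a `wall_frame` (or any list with `long`, `circ`,
#'   `radial`, `valid` matrices conformable with `v1`).
#' @return data frame with columns `helix`, `transverse`, `sheetlet`
#'   (degrees).
#' @export
compute_angles <- function(v1, v3, frame) {
  if (is.null(dim(v1))) v1 <- matrix(v1, 1)
  if (is.null(dim(v3))) v3 <- matrix(v3, 1)
  n <- nrow(v1)
  vC <- rowSums(v1 * frame$circ); vL <- rowSums(v1 * frame$long)
  vR <- rowSums(v1 * frame$radial)
  flip <- vC < 0
  vC[flip] <- -vC[flip]; vL[flip] <- -vL[flip]; vR[flip] <- -vR[flip]
  helix <- atan2(vL, vC) * 180 / pi
  transverse <- atan2(vR, vC) * 180 / pi
  wR <- rowSums(v3 * frame$radial); wL <- rowSums(v3 * frame$long)
  flip3 <- wR < 0
  wR[flip3] <- -wR[flip3]; wL[flip3] <- -wL[flip3]
  sheetlet <- atan2(wL, wR) * 180 / pi
  bad <- !(frame$valid %||% rep(TRUE, n)) |
    (abs(vC) < 1e-12 & abs(vL) < 1e-12 & abs(vR) < 1e-12)
  helix[bad] <- NA_real_; transverse[bad] <- NA_real_
  sheetlet[bad] <- NA_real_
  data.frame(helix = helix, transverse = transverse, sheetlet = sheetlet)
}
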