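#' Rigid-body superposition and RMSD
#'
#' Least-squares superposition uses the Kabsch algorithm with the SVD sign
#' correction, so the fitted transform is always a proper rotation
#' (det = +1): mirror images are never matched by reflection. In the
#' degenerate case of a rank-deficient cross-covariance the singular vectors
#' are taken in ascending singular-value index order as returned by the SVD,
#' which makes the result deterministic.
#'
#' @name superposition
NULL

# Rotation R (3x3) such that centred `mobile` %*% R best matches centred
# `target` (row-vector convention).
kabsch_rotation <- function(mobile, target) {
  P <- as_coord_matrix(mobile); Q <- as_coord_matrix(target)
  stopifnot(nrow(P) == nrow(Q))
  H <- crossprod(P, Q)                      # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Fit `mobile` (n x 3) onto `target` using atoms `fit_idx`; returns the
# transformed full coordinate set.
superpose_coords <- function(mobile, target, fit_idx = NULL) {
  M <- as_coord_matrix(mobile); Tg <- as_coord_matrix(target)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(M))
  if (length(fit_idx) < 3L) stop_fd("need at least 3 fit atoms")
  Pm <- M[fit_idx, , drop = FALSE]
  Pt <- Tg[fit_idx, , drop = FALSE]
  cm <- colMeans(Pm); ct <- colMeans(Pt)
  Pc <- sweep(Pm, 2, cm)
  if (qr(Pc)$rank < 2L) stop_fd("fit atoms are collinear; superposition is ill-defined")
  R <- kabsch_rotation(Pc, sweep(Pt, 2, ct))
  sweep(sweep(M, 2, cm) %*% R, 2, ct, `+`)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Each frame is rigid-body least-squares fitted (proper rotation only) onto
#' the reference coordinates using the fit selection. Fitting an
#' already-fitted trajectory is idempotent to numerical precision.
#'
#' @param traj a [trajectory()].
#' @param reference a `structure_model` or n x 3 coordinate matrix with the
#'   same atom count as the trajectory.
#' @param fit_selection a `selection` (or atom index vector) used for the fit.
#' @return the fitted trajectory.
#' @export
superpose_trajectory <- function(traj, reference, fit_selection = NULL) {
  ref <- if (inherits(reference, "structure_model")) coords(reference)
         else as_coord_matrix(reference)
  if (nrow(ref) != n_atoms(traj$structure))
    stop_fd("reference has %d atoms, trajectory has %d", nrow(ref), n_atoms(traj$structure))
  idx <- if (is.null(fit_selection)) seq_len(nrow(ref))
         else if (inherits(fit_selection, "selection")) fit_selection$indices
         else as.integer(fit_selection)
  out <- traj$xyz
  for (f in seq_len(n_frames(traj))) {
    out[f, ] <- as_xyz_vector(superpose_coords(frame_coords(traj, f), ref, idx))
  }
  trajectory(traj$structure, out, times = traj$times, replica = traj$replica)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b n x 3 matrices or length-3N vectors (Angstrom).
#' @param selection optional `selection` (or index vector) over which the
#'   deviation is computed; with `fit = TRUE` the same atoms are also the fit
#'   set.
#' @param fit superpose `a` onto `b` first (proper rotation).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, fit = FALSE) {
  A <- as_coord_matrix(a); B <- as_coord_matrix(b)
  if (!all(dim(A) == dim(B))) stop_fd("coordinate shape mismatch: %d x 3 vs %d x 3", nrow(A), nrow(B))
  idx <- if (is.null(selection)) seq_len(nrow(A))
         else if (inherits(selection, "selection")) selection$indices
         else as.integer(selection)
  if (fit) A <- superpose_coords(A, B, idx)
  d <- A[idx, , drop = FALSE] - B[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
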