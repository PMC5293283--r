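#' Essential dynamics: covariance PCA of coordinate fluctuations
#'
#' Principal component analysis of the 3N Calpha coordinate covariance over
#' the (already superposed) frames recovers the collective modes that carry
#' most of the fluctuation variance — the "essential" subspace. Replicas are
#' concatenated after fitting each to the common reference; per-replica
#' analyses are obtained by passing a single trajectory.
#'
#' Conventions: mass-unweighted coordinates; population covariance
#' (divide by F); modes sorted by descending eigenvalue; eigenvector sign is
#' made deterministic by forcing the largest-magnitude component of each
#' mode positive; eigenvalues below numerical zero are clamped to 0.
#'
#' @param trajs a [trajectory()] or list of replica trajectories, superposed
#'   to a common reference on the analysis selection.
#' @param selection a `selection` (or atom index vector).
#' @param n_modes how many mode projections to precompute.
#' @return class `ed_result`: `mean` (3N mean structure), `values`
#'   (eigenvalues, Angstrom^2), `vectors` (3N x 3N orthonormal columns),
#'   `projections` (F x n_modes over the pooled frames),
#'   `variance_fraction`, `frame_replica`, `labels`.
#' @export
fit_pca <- function(trajs, selection = NULL, n_modes = 10) {
  trajs <- as_trajectory_list(trajs)
  idx <- selection_indices(selection, trajs[[1]])
  cols <- xyz_columns(idx)
  X <- do.call(rbind, lapply(trajs, function(t) t$xyz[, cols, drop = FALSE]))
  F <- nrow(X)
  if (F <= 1L) stop_fd("PCA needs more than one frame")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / F
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # deterministic sign: largest-magnitude component of each mode positive
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  n_modes <- min(n_modes, ncol(vecs))
  proj <- Xc %*% vecs[, seq_len(n_modes), drop = FALSE]
  structure(list(mean = mu, values = vals, vectors = vecs,
                 projections = proj,
                 variance_fraction = vals / sum(vals),
                 frame_replica = rep(vapply(trajs, function(t) t$replica, ""),
                                     vapply(trajs, n_frames, 0L)),
                 labels = residue_labels(trajs[[1]]$structure, idx)),
            class = "ed_result")
}

#' @export
print.ed_result <- function(x, ...) {
  cat(sprintf("ed_result: %d coordinates, %d frames; top-2 variance %.1f%%\n",
              length(x$mean), nrow(x$projections),
              100 * sum(x$variance_fraction[1:2])))
  invisible(x)
}

#' Project a trajectory onto essential modes
#'
#' Projection of frame x on mode k is `(x - mean) . v_k`. Projecting the
#' ensemble that defined the PCA reproduces its per-mode variances
#' (eigenvalues); projecting another system's frames onto a common essential
#' subspace is how conformational ensembles are compared.
#'
#' @param traj a [trajectory()] (superposed consistently with the PCA input).
#' @param ed an `ed_result`.
#' @param selection same selection used for the PCA.
#' @param modes mode indices.
#' @return F x length(modes) projection matrix.
#' @export
project_trajectory <- function(traj, ed, selection = NULL, modes = 1:2) {
  stopifnot(inherits(ed, "ed_result"))
  idx <- selection_indices(selection, traj)
  cols <- xyz_columns(idx)
  if (length(cols) != length(ed$mean))
    stop_fd("selection size does not match the PCA dimensionality")
  if (any(modes < 1L | modes > ncol(ed$vectors)))
    stop_fd("mode index out of range (1..%d)", ncol(ed$vectors))
  Xc <- sweep(traj$xyz[, cols, drop = FALSE], 2, ed$mean)
  Xc %*% ed$vectors[, modes, drop = FALSE]
}

#' Cosine content of a mode projection
#'
#' The cosine content of the projection p(t) on mode rank k compares it to a
#' half-period cosine, using the discrete form
#' \deqn{c_k = \frac{2}{F} \frac{\left(\sum_t p_t \cos(k\pi t/T)\right)^2}{\sum_t p_t^2}}
#' on a midpoint time grid. A value near 1 means the mode projection is
#' indistinguishable from the leading mode of a random diffusion — the
#' classic symptom of unconverged sampling; values near 0 indicate
#' structured, repeatedly sampled motion.
#'
#' @param projection numeric per-frame projection series.
#' @param k cosine rank (use the mode's rank).
#' @return fraction in `[0, 1]`; an all-zero projection returns 0 with a
#'   warning.
#' @export
cosine_content <- function(projection, k = 1) {
  p <- as.numeric(projection)
  F <- length(p)
  stopifnot(F > 1L, k >= 1L)
  denom <- sum(p^2)
  if (denom == 0) {
    warn_fd("all-zero projection; cosine content defined as 0")
    return(0)
  }
  tmid <- (seq_len(F) - 0.5) / F
  num <- sum(p * cos(k * pi * tmid))^2
  c_k <- (2 / F) * num / denom
  min(max(c_k, 0), 1)
}

#' Normalised overlap of two essential subspaces
#'
#' Root-mean-square inner product (RMSIP) of two orthonormal mode sets of
#' equal size m:
#' \deqn{\mathrm{RMSIP} = \sqrt{\frac{1}{m}\sum_{i,j} (a_i \cdot b_j)^2}.}
#' 1 for identical subspaces, 0 for mutually orthogonal ones.
#'
#' @param vectors_a,vectors_b 3N x m matrices of orthonormal columns.
#' @return overlap in `[0, 1]`.
#' @export
subspace_overlap <- function(vectors_a, vectors_b) {
  A <- as.matrix(vectors_a); B <- as.matrix(vectors_b)
  if (!all(dim(A) == dim(B))) stop_fd("subspace dimension mismatch")
  sqrt(sum((crossprod(A, B))^2) / ncol(A))
}

#' Split-half sampling diagnostics
#'
#' For each replica: the RMSIP between the top-m essential subspaces of the
#' first and second halves of the trajectory, and the cosine content of the
#' first `n_modes` mode projections. Both diagnose how exhaustively the
#' essential subspace has been sampled.
#'
#' @param trajs a [trajectory()] or list of replicas (superposed).
#' @param selection a `selection`.
#' @param m subspace size for the split-half overlap.
#' @param n_modes number of modes for cosine content.
#' @return class `sampling_diagnostics`: data.frame `per_replica` with
#'   columns replica, split_half_overlap, cosine_content_1..n.
#' @export
sampling_diagnostics <- function(trajs, selection = NULL, m = 2, n_modes = 2) {
  trajs <- as_trajectory_list(trajs)
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    F <- n_frames(tr)
    if (F < 4L) stop_fd("split-half diagnostics need >= 4 frames")
    h1 <- trajectory(tr$structure, tr$xyz[seq_len(F %/% 2), , drop = FALSE])
    h2 <- trajectory(tr$structure, tr$xyz[(F %/% 2 + 1L):F, , drop = FALSE])
    e1 <- fit_pca(h1, selection, n_modes = m)
    e2 <- fit_pca(h2, selection, n_modes = m)
    ov <- subspace_overlap(e1$vectors[, seq_len(m), drop = FALSE],
                           e2$vectors[, seq_len(m), drop = FALSE])
    ed <- fit_pca(tr, selection, n_modes = n_modes)
    cc <- vapply(seq_len(n_modes), function(k) cosine_content(ed$projections[, k], k), 0)
    c(split_half_overlap = ov, stats::setNames(cc, paste0("cosine_content_", seq_len(n_modes))))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$replica <- vapply(trajs, function(t) t$replica, "")
  structure(list(per_replica = out[, c(ncol(out), seq_len(ncol(out) - 1L))]),
            class = "sampling_diagnostics")
}

#' @export
print.sampling_diagnostics <- function(x, ...) {
  print(x$per_replica)
  invisible(x)
}
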