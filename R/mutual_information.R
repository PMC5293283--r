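#' k-nearest-neighbour mutual information (KSG estimator)
#'
#' Kraskov-Stoegbauer-Grassberger estimator, variant 1, with Chebyshev
#' (max-norm) distances and natural-log units (nats). This is the standard
#' non-parametric MI estimator for continuous samples; with `k = 6`
#' neighbours it balances bias and variance at the sample sizes typical of
#' per-residue MD fluctuation series. Small negative estimates (finite-sample
#' noise around independence) are clamped to zero.
#'
#' Exactly duplicated sample points make the k-th neighbour distance zero,
#' where the estimator is undefined; `on_ties` chooses between adding a
#' negligible deterministic-free jitter (default, magnitude
#' `1e-9 * sd(data)`, drawn from the caller's RNG stream) and failing.
#'
#' @param x,y sample matrices, F rows each (vectors are treated as F x 1).
#' @param k neighbour count (default 6).
#' @param on_ties `"jitter"` or `"error"`.
#' @param clamp clamp negative estimates to 0 (default TRUE).
#' @return mutual information in nats.
#' @export
knn_mutual_information <- function(x, y, k = 6, on_ties = c("jitter", "error"),
                                   clamp = TRUE) {
  on_ties <- match.arg(on_ties)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_fd("x and y must have the same number of samples")
  F <- nrow(x)
  if (F <= k + 1L) stop_fd("need more than k + 1 = %d samples, got %d", k + 1L, F)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_fd("samples must be finite")
  xy <- cbind(x, y)
  mi <- ksg_mi_cpp(xy, ncol(x), ncol(y), as.integer(k))
  if (is.na(mi)) {
    if (on_ties == "error") stop_fd("duplicate sample points: k-th neighbour distance is 0")
    s <- sd(as.numeric(xy)); if (!is.finite(s) || s == 0) s <- 1
    xy <- xy + matrix(rnorm(length(xy), sd = 1e-9 * s), nrow = F)
    mi <- ksg_mi_cpp(xy, ncol(x), ncol(y), as.integer(k))
    if (is.na(mi)) stop_fd("duplicate sample points persist after jitter")
  }
  if (clamp) mi <- max(mi, 0)
  mi
}

#' Generalized correlation matrix from mutual information
#'
#' For every pair of selected atoms, the mutual information between their
#' 3-D displacement series (after superposition, so fluctuations rather than
#' absolute positions are compared) is mapped to a correlation-like
#' coefficient
#' \deqn{r_{MI} = \sqrt{1 - e^{-2 I / 3}} \in [0, 1],}
#' the dimensionality-3 form appropriate for displacement vectors. Unlike a
#' Pearson cross-correlation, this detects coupled motion regardless of the
#' relative orientation of the motions and includes nonlinear contributions;
#' for jointly Gaussian displacements with isotropic cross-correlation rho,
#' \eqn{r_{MI} = |rho|}. Per-replica matrices are averaged.
#'
#' The estimator cost is O(F^2) per pair; `stride` subsamples frames to cap
#' the work (the default caps the per-replica frame count at
#' `max_frames`, logged via message).
#'
#' @param trajs a [trajectory()] or list of replica trajectories (superposed).
#' @param selection a `selection` (or atom index vector).
#' @param k neighbour count (default 6).
#' @param stride frame subsampling stride; `NULL` picks the smallest stride
#'   keeping at most `max_frames` frames.
#' @param max_frames frame cap used when `stride` is `NULL`.
#' @param on_ties see [knn_mutual_information()].
#' @return class `lmi_matrix`: `mat` (symmetric, unit diagonal, entries in
#'   `[0, 1]`), `labels`, `k`, `stride`, `n_frames`.
#' @export
generalized_correlation_matrix <- function(trajs, selection = NULL, k = 6,
                                           stride = NULL, max_frames = 2000,
                                           on_ties = c("jitter", "error")) {
  on_ties <- match.arg(on_ties)
  trajs <- as_trajectory_list(trajs)
  idx <- selection_indices(selection, trajs[[1]])
  cols <- xyz_columns(idx)
  n <- length(idx)
  mats <- list(); used <- 0L
  for (tr in trajs) {
    F <- n_frames(tr)
    st <- stride %||% max(1L, ceiling(F / max_frames))
    rows <- seq(1L, F, by = st)
    if (length(rows) <= k + 1L)
      stop_fd("replica has too few frames (%d at stride %d) for k = %d", length(rows), st, k)
    if (st > 1L)
      message(sprintf("generalized_correlation_matrix: stride %d -> %d frames", st, length(rows)))
    X <- tr$xyz[rows, cols, drop = FALSE]
    X <- sweep(X, 2, colMeans(X))              # displacements about the mean
    mi <- ksg_mi_pairs_cpp(X, n, as.integer(k))
    if (anyNA(mi[upper.tri(mi)])) {
      if (on_ties == "error") stop_fd("duplicate frames: k-th neighbour distance is 0")
      s <- sd(as.numeric(X)); if (!is.finite(s) || s == 0) s <- 1
      X <- X + matrix(rnorm(length(X), sd = 1e-9 * s), nrow = nrow(X))
      mi <- ksg_mi_pairs_cpp(X, n, as.integer(k))
    }
    mats[[length(mats) + 1L]] <- mi
    used <- used + length(rows)
  }
  mi <- Reduce(`+`, mats) / length(mats)
  mi <- pmax(mi, 0)
  r <- sqrt(1 - exp(-2 * mi / 3))
  r <- pmin(r, 1)
  diag(r) <- 1
  labs <- residue_labels(trajs[[1]]$structure, idx)
  dimnames(r) <- list(labs, labs)
  structure(list(mat = r, labels = labs, k = k,
                 stride = stride %||% NA_integer_, n_frames = used),
            class = "lmi_matrix")
}

#' @export
print.lmi_matrix <- function(x, ...) {
  off <- x$mat[upper.tri(x$mat)]
  cat(sprintf("lmi_matrix: %d atoms, k = %d, %d frames; off-diagonal r_MI mean %.3f max %.3f\n",
              nrow(x$mat), x$k, x$n_frames, mean(off), max(off)))
  invisible(x)
}

#' Write a generalized-correlation matrix to disk
#' @param x an `lmi_matrix`.
#' @param file TSV path.
#' @param long_file optional long-format CSV path.
#' @export
write_lmi_matrix <- function(x, file, long_file = NULL) {
  stopifnot(inherits(x, "lmi_matrix"))
  utils::write.table(x$mat, file, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(long_file)) {
    iu <- which(upper.tri(x$mat), arr.ind = TRUE)
    utils::write.csv(data.frame(i = x$labels[iu[, 1]], j = x$labels[iu[, 2]],
                                r_mi = x$mat[iu]),
                     long_file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
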