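#' Distance-fluctuation coordination matrix
#'
#' For every pair of selected atoms (conventionally Calpha), the
#' distance fluctuation is the time-averaged mean-square fluctuation of the
#' inter-atomic distance,
#' \deqn{DF_{ij} = \langle (r_{ij} - \langle r_{ij} \rangle)^2 \rangle,}
#' where the brackets are time averages over a trajectory. Low values mark
#' mechanically coordinated residue pairs: a pair belonging to one rigid unit
#' has DF exactly zero regardless of how that unit translates or rotates,
#' which is what makes the statistic a useful coordination/allostery probe.
#' The time average uses the population convention (divide by F), matching
#' the bracket notation; with multiple replicas the per-replica matrices are
#' averaged arithmetically rather than the frames concatenated, so that
#' static offsets between replicas cannot inflate the fluctuation
#' (`aggregate = "concatenate"` switches to pooled frames).
#'
#' Memory use is O(N^2) via streaming accumulation over frames, in two
#' passes (mean distances first, then squared deviations) so large absolute
#' distances do not erode the precision of the small fluctuations around
#' them.
#'
#' @param trajs a [trajectory()] or list of replica trajectories.
#' @param selection a `selection` (or atom index vector); each trajectory
#'   needs at least 2 frames.
#' @param aggregate `"mean"` (default, per-replica matrices averaged) or
#'   `"concatenate"` (single matrix over pooled frames).
#' @return an object of class `df_matrix`: list with `mat` (N x N, Angstrom^2,
#'   symmetric, zero diagonal), `labels` (chain:resno), `n_frames`,
#'   `replicas`.
#' @export
df_matrix <- function(trajs, selection = NULL, aggregate = c("mean", "concatenate")) {
  aggregate <- match.arg(aggregate)
  trajs <- as_trajectory_list(trajs)
  idx <- selection_indices(selection, trajs[[1]])
  cols <- xyz_columns(idx)
  ntot <- 0L
  frame_dist <- function(tr, f)
    as.matrix(dist(matrix(tr$xyz[f, cols], ncol = 3L, byrow = TRUE)))
  replica_df <- function(tr_list) {
    # pass 1: mean distance per pair; pass 2: mean squared deviation
    F <- sum(vapply(tr_list, n_frames, 0L))
    m <- 0
    for (tr in tr_list) for (f in seq_len(n_frames(tr)))
      m <- m + frame_dist(tr, f)
    m <- m / F
    v <- 0
    for (tr in tr_list) for (f in seq_len(n_frames(tr)))
      v <- v + (frame_dist(tr, f) - m)^2
    v / F
  }
  for (tr in trajs) {
    if (n_frames(tr) < 2L) stop_fd("distance fluctuations need >= 2 frames per replica")
    ntot <- ntot + n_frames(tr)
  }
  mat <- if (aggregate == "mean")
    Reduce(`+`, lapply(trajs, function(tr) replica_df(list(tr)))) / length(trajs)
  else replica_df(trajs)
  mat <- pmax((mat + t(mat)) / 2, 0)   # symmetrise; clip tiny negative round-off
  diag(mat) <- 0
  labs <- residue_labels(trajs[[1]]$structure, idx)
  dimnames(mat) <- list(labs, labs)
  structure(list(mat = mat, labels = labs, n_frames = ntot,
                 replicas = vapply(trajs, function(t) t$replica, "")),
            class = "df_matrix")
}

#' @export
print.df_matrix <- function(x, ...) {
  cat(sprintf("df_matrix: %d x %d pairs, %d frames, %d replica(s); DF range [%.3g, %.3g] A^2\n",
              nrow(x$mat), ncol(x$mat), x$n_frames, length(x$replicas),
              min(x$mat), max(x$mat)))
  invisible(x)
}

#' Difference between two distance-fluctuation matrices
#' @param a,b `df_matrix` objects over the same selection labels.
#' @return matrix `a$mat - b$mat`.
#' @export
df_difference <- function(a, b) {
  stopifnot(inherits(a, "df_matrix"), inherits(b, "df_matrix"))
  if (!identical(a$labels, b$labels))
    stop_fd("df matrices are over different selections")
  a$mat - b$mat
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF per atom is the root of the time-averaged squared displacement from
#' the atom's mean position. Trajectories must already be superposed to a
#' common reference on the analysis selection; a heuristic check warns when
#' the input still carries global motion (re-fitting a sample frame reduces
#' its RMSD to the mean structure noticeably). With several replicas the
#' profile is the per-atom mean across replicas and the spread is the
#' between-replica standard deviation.
#'
#' @param trajs a [trajectory()] or list of replica trajectories (superposed).
#' @param selection a `selection` (or atom index vector).
#' @return class `rmsf_profile`: `rmsf` (Angstrom), `sd` (across replicas),
#'   `labels`.
#' @export
rmsf_profile <- function(trajs, selection = NULL) {
  trajs <- as_trajectory_list(trajs)
  idx <- selection_indices(selection, trajs[[1]])
  cols <- xyz_columns(idx)
  per <- vapply(trajs, function(tr) {
    X <- tr$xyz[, cols, drop = FALSE]
    if (nrow(X) < 2L) stop_fd("RMSF needs >= 2 frames per replica")
    check_superposed(tr, idx)
    mu <- colMeans(X)
    dev2 <- sweep(X, 2, mu)^2
    msf3 <- colMeans(dev2)                       # per coordinate
    sqrt(colSums(matrix(msf3, nrow = 3L)))       # per atom: sum over x,y,z
  }, numeric(length(idx)))
  per <- matrix(per, nrow = length(idx))
  structure(list(rmsf = rowMeans(per),
                 sd = if (ncol(per) > 1L) apply(per, 1, sd) else rep(0, nrow(per)),
                 labels = residue_labels(trajs[[1]]$structure, idx)),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile: %d atoms, mean RMSF %.3f A (max %.3f)\n",
              length(x$rmsf), mean(x$rmsf), max(x$rmsf)))
  invisible(x)
}

# warn when a trajectory looks unfitted: re-fitting a probe frame to the
# mean structure shrinks its RMSD well below what the 6 rigid-body degrees
# of freedom would absorb by chance (~ a factor sqrt(1 - 2/n) for n atoms)
check_superposed <- function(tr, idx) {
  F <- n_frames(tr)
  cols <- xyz_columns(idx)
  mu <- matrix(colMeans(tr$xyz[, cols, drop = FALSE]), ncol = 3L, byrow = TRUE)
  probe <- matrix(tr$xyz[F, cols], ncol = 3L, byrow = TRUE)
  r0 <- rmsd(probe, mu)
  if (r0 < 1e-8 || nrow(probe) < 4L) return(invisible(TRUE))
  r1 <- rmsd(probe, mu, fit = TRUE)
  if (r1 < 0.5 * sqrt(1 - 2 / nrow(probe)) * r0)
    warn_fd("trajectory does not appear to be superposed (fit reduces probe RMSD %.3f -> %.3f A)",
            r0, r1)
  invisible(TRUE)
}

selection_indices <- function(selection, traj_or_structure) {
  n <- if (inherits(traj_or_structure, "trajectory"))
    n_atoms(traj_or_structure$structure) else n_atoms(traj_or_structure)
  if (is.null(selection)) return(seq_len(n))
  idx <- if (inherits(selection, "selection")) selection$indices else as.integer(selection)
  if (!length(idx) || any(idx < 1L | idx > n)) stop_fd("selection indices out of range")
  idx
}

#' Write a distance-fluctuation matrix to disk
#'
#' Dense TSV with residue labels as row/column names, plus an optional
#' long-format CSV (`i`, `j`, `df`).
#'
#' @param x a `df_matrix`.
#' @param file TSV path.
#' @param long_file optional CSV path for the long format.
#' @export
write_df_matrix <- function(x, file, long_file = NULL) {
  stopifnot(inherits(x, "df_matrix"))
  utils::write.table(x$mat, file, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(long_file)) {
    iu <- which(upper.tri(x$mat), arr.ind = TRUE)
    utils::write.csv(data.frame(i = x$labels[iu[, 1]], j = x$labels[iu[, 2]],
                                df = x$mat[iu]),
                     long_file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
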