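#' GROMOS-style conformational clustering
#'
#' Greedy neighbour-count clustering of trajectory frames on pairwise RMSD,
#' after Daura's method: compute the RMSD between all frame pairs; count,
#' for each frame, the neighbours within the cutoff; the frame with the most
#' neighbours seeds a cluster together with all its neighbours; remove those
#' frames and repeat on the remainder until the pool is empty. The result is
#' a disjoint, exhaustive partition; every member lies within the cutoff of
#' its cluster centre at assignment time, and cluster sizes are
#' non-increasing in discovery order. Ties in the neighbour count are broken
#' by the lowest frame index, which makes the partition deterministic.
#'
#' Pairwise RMSD is computed with per-pair superposition on `fit_selection`
#' (defaulting to the analysis selection itself — local fitting, the natural
#' choice for side-chain-region rotamer analysis; pass a different selection
#' for global fitting). The all-pairs matrix is O(F^2): `stride` subsamples
#' frames, and frame counts above `max_frames` are refused rather than
#' silently truncated.
#'
#' @param traj a [trajectory()].
#' @param selection `selection` of atoms whose RMSD defines the clustering.
#' @param cutoff RMSD cutoff in Angstrom (0.2 nm = 2 Angstrom is the
#'   conventional choice for side-chain rotamer regions; 3 Angstrom a looser
#'   preset).
#' @param fit_selection atoms used for the per-pair superposition (default:
#'   `selection`).
#' @param fit superpose each pair before the RMSD (default TRUE).
#' @param stride frame subsampling stride.
#' @param max_frames guard for the O(F^2) matrix.
#' @return class `cluster_result`: `assignment` (cluster id per analysed
#'   frame), `clusters` data.frame (id, center_frame, size, population_pct),
#'   `frames` (analysed frame indices), `cutoff_nm`.
#' @export
gromos_cluster <- function(traj, selection = NULL, cutoff = 2.0,
                           fit_selection = NULL, fit = TRUE,
                           stride = 1L, max_frames = 6000L) {
  idx <- selection_indices(selection, traj)
  fidx <- if (is.null(fit_selection)) idx else selection_indices(fit_selection, traj)
  frames <- seq(1L, n_frames(traj), by = stride)
  F <- length(frames)
  if (F < 1L) stop_fd("no frames to cluster")
  if (F > max_frames)
    stop_fd("%d frames exceed max_frames = %d; use stride", F, max_frames)
  M <- pairwise_rmsd_cpp(traj$xyz[frames, xyz_columns(idx), drop = FALSE],
                         traj$xyz[frames, xyz_columns(fidx), drop = FALSE],
                         isTRUE(fit))
  part <- gromos_partition(M, cutoff)
  sizes <- vapply(part, function(p) length(p$members), 0L)
  clusters <- data.frame(id = seq_along(part),
                         center_frame = frames[vapply(part, function(p) p$center, 0L)],
                         size = sizes,
                         population_pct = 100 * sizes / F)
  assignment <- integer(F)
  for (k in seq_along(part)) assignment[part[[k]]$members] <- k
  structure(list(assignment = assignment, clusters = clusters,
                 frames = frames, cutoff_nm = cutoff / 10),
            class = "cluster_result")
}

# greedy partition of a symmetric distance matrix; returns list of
# list(center = index, members = indices) in discovery order
gromos_partition <- function(M, cutoff) {
  remaining <- seq_len(nrow(M))
  out <- list()
  while (length(remaining)) {
    sub <- M[remaining, remaining, drop = FALSE]
    neigh <- rowSums(sub <= cutoff) - 1L        # exclude self
    c_loc <- which.max(neigh)                   # which.max: lowest index wins ties
    members_loc <- which(sub[c_loc, ] <= cutoff)
    out[[length(out) + 1L]] <- list(center = remaining[c_loc],
                                    members = remaining[members_loc])
    remaining <- remaining[-members_loc]
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d frames -> %d clusters (cutoff %.2f nm)\n",
              length(x$assignment), nrow(x$clusters), x$cutoff_nm))
  print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Write clustering outputs
#'
#' Frame assignments as CSV, cluster summary as JSON, and optionally the
#' central structures as a multi-model PDB.
#'
#' @param x a `cluster_result`.
#' @param traj the clustered [trajectory()] (for central structures).
#' @param assignments_csv,summary_json,centers_pdb output paths (NULL skips).
#' @export
write_cluster_result <- function(x, traj = NULL, assignments_csv = NULL,
                                 summary_json = NULL, centers_pdb = NULL) {
  stopifnot(inherits(x, "cluster_result"))
  if (!is.null(assignments_csv))
    utils::write.csv(data.frame(frame = x$frames, cluster = x$assignment),
                     assignments_csv, row.names = FALSE)
  if (!is.null(summary_json))
    jsonlite::write_json(list(cutoff_nm = x$cutoff_nm,
                              clusters = x$clusters),
                         summary_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(centers_pdb)) {
    stopifnot(inherits(traj, "trajectory"))
    ctr <- trajectory(traj$structure,
                      traj$xyz[x$clusters$center_frame, , drop = FALSE])
    write_trajectory(ctr, centers_pdb)
  }
  invisible(x)
}
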