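#' Scalar and geometric trajectory descriptors
#'
#' Per-frame descriptors of global and local conformation: radius of
#' gyration, tagged pair distances (e.g. a carbonyl oxygen to a metal-site
#' ion, or metal-metal spacings), domain principal axes and inter-domain
#' torsion angles, aromatic ring stacking geometry, and hydrogen-bond /
#' salt-bridge occupancy. All are invariant under rigid motion of the whole
#' system applied per frame.
#'
#' @name geometry_descriptors
NULL

descriptor_series <- function(name, values, unit, replica = "") {
  stopifnot(all(is.finite(values)))
  structure(list(name = name, values = as.numeric(values), unit = unit,
                 replica = replica),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("descriptor '%s' [%s]: %d frames, mean %.3f, range [%.3f, %.3f]\n",
              x$name, x$unit, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Radius of gyration per frame
#'
#' Unweighted Rg: root-mean-square distance of the selected atoms to their
#' centroid, per frame.
#'
#' @param traj a [trajectory()].
#' @param selection a `selection` (or index vector).
#' @return a `descriptor_series` in Angstrom.
#' @export
radius_of_gyration <- function(traj, selection = NULL) {
  idx <- selection_indices(selection, traj)
  cols <- xyz_columns(idx)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- matrix(traj$xyz[f, cols], ncol = 3L, byrow = TRUE)
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, 0)
  descriptor_series("radius_of_gyration", vals, "A", traj$replica)
}

#' Distance between two tagged atoms per frame
#'
#' Works for any atom record including HETATM metal particles, so it covers
#' carbonyl-to-ion and ion-to-ion distance series.
#'
#' @param traj a [trajectory()].
#' @param atom_a,atom_b atom labels `"chain:resno:name"` (see
#'   [resolve_atom()]) or single atom indices.
#' @return a `descriptor_series` in Angstrom.
#' @export
pair_distance_series <- function(traj, atom_a, atom_b) {
  ia <- if (is.character(atom_a)) resolve_atom(traj$structure, atom_a) else as.integer(atom_a)
  ib <- if (is.character(atom_b)) resolve_atom(traj$structure, atom_b) else as.integer(atom_b)
  ca <- xyz_columns(ia); cb <- xyz_columns(ib)
  d <- sqrt(rowSums((traj$xyz[, ca, drop = FALSE] - traj$xyz[, cb, drop = FALSE])^2))
  nm <- if (is.character(atom_a)) sprintf("dist %s - %s", atom_a, atom_b) else "pair_distance"
  descriptor_series(nm, d, "A", traj$replica)
}

#' Principal axes of a point set
#'
#' Eigenvectors of the gyration tensor (covariance of positions about the
#' centroid), in descending eigenvalue order, with the deterministic sign
#' rule that each axis's largest-magnitude component is positive. Degenerate
#' (tied) eigenvalues keep the stable order returned by the symmetric eigen
#' solver, so the output is deterministic for a given input.
#'
#' @param coords n x 3 coordinates (n >= 3, non-collinear).
#' @return list with `centroid`, `axes` (3 x 3, columns = axes, descending
#'   extent), `extents` (eigenvalues, Angstrom^2).
#' @export
principal_axes <- function(coords) {
  m <- as_coord_matrix(coords)
  if (nrow(m) < 3L) stop_fd("principal axes need at least 3 atoms")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  if (qr(mc)$rank < 2L) stop_fd("atoms are collinear; principal axes are ill-defined")
  g <- crossprod(mc) / nrow(mc)
  e <- eigen(g, symmetric = TRUE)
  ax <- e$vectors
  for (k in 1:3) {
    i <- which.max(abs(ax[, k]))
    if (ax[i, k] < 0) ax[, k] <- -ax[, k]
  }
  list(centroid = ctr, axes = ax, extents = e$values)
}

#' Inter-domain torsion angle series
#'
#' The mutual orientation of two domains is tracked as the dihedral angle of
#' the four points (tip_a, centroid_a, centroid_b, tip_b), where each tip is
#' the domain centroid displaced by the domain's first principal axis. The
#' axis sign is kept continuous across frames (flipped whenever the dot
#' product with the previous frame's axis is negative) so the series cannot
#' jump by 180 degrees, and the angle magnitude is reported in
#' `[0, 180]` degrees. The series is invariant under rigid motion of the
#' whole system applied per frame.
#'
#' @param traj a [trajectory()].
#' @param domain_a,domain_b `selection`s (or index vectors) of the two
#'   domains.
#' @return a `descriptor_series` in degrees.
#' @export
interdomain_torsion_series <- function(traj, domain_a, domain_b) {
  ia <- selection_indices(domain_a, traj)
  ib <- selection_indices(domain_b, traj)
  ca <- xyz_columns(ia); cb <- xyz_columns(ib)
  prev_a <- prev_b <- NULL
  vals <- numeric(n_frames(traj))
  # Axis-sign handling must not depend on the lab frame, or the series would
  # change under a per-frame rigid motion of the whole system. Both rules
  # therefore work on the per-atom projection pattern (rotation invariant):
  # the first frame is oriented along the sign of the projection skewness
  # (falling back to the farthest atom for skewness-free shapes), and later
  # frames keep the sign whose projection pattern overlaps the previous
  # frame's (continuity, preventing spurious 180-degree jumps).
  oriented_axis <- function(u, m, ctr, prev_proj) {
    proj <- as.numeric(sweep(m, 2, ctr) %*% u)
    s <- if (is.null(prev_proj)) {
      sk <- sum(proj^3)
      if (abs(sk) < 1e-9 * max(abs(proj))^3) proj[which.max(abs(proj))] else sk
    } else sum(proj * prev_proj)
    if (s < 0) list(u = -u, proj = -proj) else list(u = u, proj = proj)
  }
  for (f in seq_len(n_frames(traj))) {
    A <- matrix(traj$xyz[f, ca], ncol = 3L, byrow = TRUE)
    B <- matrix(traj$xyz[f, cb], ncol = 3L, byrow = TRUE)
    pa <- principal_axes(A); pb <- principal_axes(B)
    oa <- oriented_axis(pa$axes[, 1], A, pa$centroid, prev_a)
    ob <- oriented_axis(pb$axes[, 1], B, pb$centroid, prev_b)
    ua <- oa$u; ub <- ob$u
    prev_a <- oa$proj; prev_b <- ob$proj
    if (vec_norm(pb$centroid - pa$centroid) < 1e-6)
      stop_fd("domain centroids coincide; torsion undefined")
    vals[f] <- abs(dihedral_angle(pa$centroid + ua, pa$centroid,
                                  pb$centroid, pb$centroid + ub))
  }
  descriptor_series("interdomain_torsion", vals, "deg", traj$replica)
}

# signed dihedral of p1-p2-p3-p4 in degrees (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, unit(b2)) * n2)
  deg(atan2(y, x))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- aromatic stacking ------------------------------------------------------

# heavy ring atoms per aromatic residue type; TRP has both the full bicyclic
# set (default centroid definition) and the six-membered ring alone
ring_atom_table <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TRP6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

ring_atom_indices <- function(structure, residue, trp_ring = "full") {
  parts <- strsplit(residue, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_fd("residue label must be 'chain:resno', got '%s'", residue)
  a <- structure$atoms
  sel <- which(a$chain == parts[1] & a$resno == as.integer(parts[2]))
  if (!length(sel)) stop_fd("residue %s not found", residue)
  resn <- a$resid[sel[1]]
  key <- if (resn == "TRP" && trp_ring == "six") "TRP6" else resn
  ring <- ring_atom_table[[key]]
  if (is.null(ring)) stop_fd("residue %s (%s) has no aromatic ring", residue, resn)
  idx <- sel[a$elety[sel] %in% ring]
  if (length(idx) < 3L) stop_fd("residue %s is missing ring atoms", residue)
  idx
}

# unit normal of the best-fit plane: smallest-eigenvector of the atom
# covariance (total least squares)
ring_plane <- function(m) {
  mc <- sweep(m, 2, colMeans(m))
  e <- eigen(crossprod(mc) / nrow(mc), symmetric = TRUE)
  list(centroid = colMeans(m), normal = e$vectors[, 3])
}

#' Aromatic ring pair geometry series
#'
#' Per frame: the centroid-centroid distance of two aromatic rings and the
#' interplanar angle theta between their best-fit plane normals, folded to
#' `[0, 90]` degrees (so it is independent of normal sign and of ring atom
#' ordering). Two classifications are reported: `paired` for centroid
#' distance below `pair_cutoff` (default 12 Angstrom), and `stacked` for
#' geometry inside the general hydrophobic pi-stacking window covering
#' stacked and T-shaped arrangements (centroid distance within
#' `stack_window`, default 4.9-10.4 Angstrom, and theta within
#' `theta_window`, default 1.2-89.9 degrees).
#'
#' The tryptophan centroid uses all nine bicyclic heavy atoms by default;
#' `trp_ring = "six"` restricts it to the six-membered ring.
#'
#' @param traj a [trajectory()].
#' @param residue_a,residue_b residue labels `"chain:resno"`.
#' @param pair_cutoff pairing distance cutoff (Angstrom).
#' @param stack_window length-2 stacking distance window (Angstrom).
#' @param theta_window length-2 stacking angle window (degrees).
#' @param trp_ring `"full"` or `"six"`.
#' @return class `stacking_geometry`: per-frame `distance`, `theta`,
#'   `paired`, `stacked`, plus the residue labels and windows used.
#' @export
stacking_series <- function(traj, residue_a, residue_b,
                            pair_cutoff = 12, stack_window = c(4.9, 10.4),
                            theta_window = c(1.2, 89.9), trp_ring = c("full", "six")) {
  trp_ring <- match.arg(trp_ring)
  ia <- ring_atom_indices(traj$structure, residue_a, trp_ring)
  ib <- ring_atom_indices(traj$structure, residue_b, trp_ring)
  ca <- xyz_columns(ia); cb <- xyz_columns(ib)
  F <- n_frames(traj)
  dist_v <- theta_v <- numeric(F)
  for (f in seq_len(F)) {
    pa <- ring_plane(matrix(traj$xyz[f, ca], ncol = 3L, byrow = TRUE))
    pb <- ring_plane(matrix(traj$xyz[f, cb], ncol = 3L, byrow = TRUE))
    dist_v[f] <- vec_norm(pb$centroid - pa$centroid)
    cosang <- abs(sum(pa$normal * pb$normal))
    theta_v[f] <- deg(acos(min(max(cosang, 0), 1)))
  }
  structure(list(residues = c(residue_a, residue_b),
                 distance = dist_v, theta = theta_v,
                 paired = dist_v < pair_cutoff,
                 stacked = dist_v >= stack_window[1] & dist_v <= stack_window[2] &
                   theta_v >= theta_window[1] & theta_v <= theta_window[2],
                 pair_cutoff = pair_cutoff, stack_window = stack_window,
                 theta_window = theta_window, replica = traj$replica),
            class = "stacking_geometry")
}

#' @export
print.stacking_geometry <- function(x, ...) {
  cat(sprintf("stacking %s - %s: %d frames, mean d %.2f A, mean theta %.1f deg; paired %.0f%%, stacked %.0f%%\n",
              x$residues[1], x$residues[2], length(x$distance),
              mean(x$distance), mean(x$theta),
              100 * mean(x$paired), 100 * mean(x$stacked)))
  invisible(x)
}

# --- hydrogen bonds and salt bridges ----------------------------------------

saltbridge_atoms <- list(
  basic = list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2")),
  acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
)

#' Hydrogen-bond and salt-bridge occupancy
#'
#' Occupancy is the percentage of analysed frames (pooled over replicas) in
#' which an interaction is present. Criteria (all configurable): a hydrogen
#' bond requires donor-acceptor heavy-atom distance at or below
#' `hbond_cutoff` (default 3.5 Angstrom) and, when a hydrogen atom is given,
#' a donor-H...acceptor angle of at least `hbond_angle` (default 120
#' degrees); without hydrogens the distance criterion alone is used. A salt
#' bridge requires any basic side-chain nitrogen within `salt_cutoff`
#' (default 4.0 Angstrom) of a carboxylate oxygen.
#'
#' Candidates are either given explicitly (`pairs`) or scanned automatically
#' between two atom groups: N/O atoms for hydrogen bonds and the canonical
#' charged-group atoms for salt bridges, prefiltered by distance in the
#' first frame plus a margin.
#'
#' @param trajs a [trajectory()] or list of replicas.
#' @param pairs optional data.frame with columns `a`, `b` (atom labels
#'   `"chain:resno:name"`), optional `hydrogen` (label or NA), optional
#'   `type` ("hbond"/"salt").
#' @param group_a,group_b `selection`s used for the automatic scan when
#'   `pairs` is NULL.
#' @param hbond_cutoff,hbond_angle,salt_cutoff criteria (Angstrom, degrees).
#' @param min_occupancy report only interactions at or above this percentage
#'   (default 1, the conventional reporting floor).
#' @return data.frame with columns `a`, `b`, `type`, `occupancy` (percent of
#'   total analysed time), `n_frames`; empty (with a warning) when no
#'   candidates exist.
#' @export
hbond_saltbridge_occupancy <- function(trajs, pairs = NULL,
                                       group_a = NULL, group_b = NULL,
                                       hbond_cutoff = 3.5, hbond_angle = 120,
                                       salt_cutoff = 4.0, min_occupancy = 1) {
  trajs <- as_trajectory_list(trajs)
  st <- trajs[[1]]$structure
  if (is.null(pairs)) {
    if (is.null(group_a) || is.null(group_b))
      stop_fd("either pairs or both group_a and group_b must be given")
    pairs <- scan_candidate_pairs(trajs[[1]], group_a, group_b,
                                  max(hbond_cutoff, salt_cutoff) + 2.0)
  }
  if (!nrow(pairs)) {
    warn_fd("no candidate donor/acceptor pairs found")
    return(data.frame(a = character(), b = character(), type = character(),
                      occupancy = numeric(), n_frames = integer()))
  }
  if (is.null(pairs$type)) pairs$type <- "hbond"
  if (is.null(pairs$hydrogen)) pairs$hydrogen <- NA_character_
  ia <- vapply(pairs$a, function(l) resolve_atom(st, l), 0L)
  ib <- vapply(pairs$b, function(l) resolve_atom(st, l), 0L)
  ih <- ifelse(is.na(pairs$hydrogen), NA_integer_,
               vapply(pairs$hydrogen, function(l) if (is.na(l)) NA_integer_ else resolve_atom(st, l), 0L))
  ntot <- 0L
  hits <- integer(nrow(pairs))
  for (tr in trajs) {
    F <- n_frames(tr)
    ntot <- ntot + F
    for (p in seq_len(nrow(pairs))) {
      da <- sqrt(rowSums((tr$xyz[, xyz_columns(ia[p]), drop = FALSE] -
                          tr$xyz[, xyz_columns(ib[p]), drop = FALSE])^2))
      cut <- if (pairs$type[p] == "salt") salt_cutoff else hbond_cutoff
      ok <- da <= cut
      if (pairs$type[p] != "salt" && !is.na(ih[p])) {
        for (f in which(ok)) {
          h <- tr$xyz[f, xyz_columns(ih[p])]
          d <- tr$xyz[f, xyz_columns(ia[p])]
          acc <- tr$xyz[f, xyz_columns(ib[p])]
          v1 <- d - h; v2 <- acc - h
          ang <- deg(acos(min(max(sum(unit(v1) * unit(v2)), -1), 1)))
          if (ang < hbond_angle) ok[f] <- FALSE
        }
      }
      hits[p] <- hits[p] + sum(ok)
    }
  }
  out <- data.frame(a = pairs$a, b = pairs$b, type = pairs$type,
                    occupancy = 100 * hits / ntot, n_frames = ntot,
                    stringsAsFactors = FALSE)
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  out[order(-out$occupancy), , drop = FALSE]
}

# candidate pairs between two groups from first-frame proximity
scan_candidate_pairs <- function(traj, group_a, group_b, prefilter) {
  st <- traj$structure
  a <- st$atoms
  ia <- selection_indices(group_a, traj)
  ib <- selection_indices(group_b, traj)
  polar <- function(i) i[guess_element(a$elety[i]) %in% c("N", "O")]
  pa <- polar(ia); pb <- polar(ib)
  m <- coords(st)
  rows <- list()
  lab <- function(i) sprintf("%s:%d%s:%s", a$chain[i], a$resno[i],
                             ifelse(nzchar(a$insert[i]), a$insert[i], ""), a$elety[i])
  is_salt_atom <- function(i, side) {
    tab <- saltbridge_atoms[[side]]
    !is.null(tab[[a$resid[i]]]) && a$elety[i] %in% tab[[a$resid[i]]]
  }
  for (i in pa) for (j in pb) {
    if (vec_norm(m[i, ] - m[j, ]) > prefilter) next
    type <- if ((is_salt_atom(i, "basic") && is_salt_atom(j, "acidic")) ||
                (is_salt_atom(i, "acidic") && is_salt_atom(j, "basic"))) "salt" else "hbond"
    rows[[length(rows) + 1L]] <- data.frame(a = lab(i), b = lab(j), type = type,
                                            hydrogen = NA_character_,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(a = character(), b = character(), type = character(),
                  hydrogen = character())
}

#' Histogram of a descriptor series
#'
#' Freedman-Diaconis binning by default, with explicit `breaks` override;
#' returns bin edges and counts (plus densities) ready for CSV export.
#'
#' @param series a `descriptor_series` or numeric vector.
#' @param breaks passed to [graphics::hist()] logic: `"FD"` or a numeric
#'   vector of edges.
#' @return data.frame with `lower`, `upper`, `count`, `density`.
#' @export
descriptor_histogram <- function(series, breaks = "FD") {
  v <- if (inherits(series, "descriptor_series")) series$values else as.numeric(series)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1), upper = h$breaks[-1],
             count = h$counts, density = h$density)
}
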