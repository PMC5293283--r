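#' Synthetic trajectories with known ground truth
#'
#' Generators for trajectories whose statistical and geometric properties are
#' known by construction: Gaussian ensembles with prescribed block
#' covariance, rigid two-domain hinge sweeps, aromatic ring pairs at
#' prescribed centroid distance and interplanar angle, two-state
#' conformational switches, and tagged metal-site particles. They emulate the
#' *analysable features* of multi-replica protein MD ensembles — coordinated
#' fluctuation structure, inter-domain rotation, stacking geometry, rotamer
#' populations — not the physics that produces them; there is no force field,
#' solvent or thermostat here. Every generator is a pure function of its
#' spec and seed.
#'
#' @name synthetic_trajectories
NULL

# --- helpers ----------------------------------------------------------------

# A Calpha-only chain template: elongated, slightly puckered so principal
# axes are well defined (non-collinear), and end-asymmetric so the axis
# orientation is unambiguous.
ca_chain_template <- function(n, spacing = 1.8) {
  i <- seq_len(n)
  cbind(x = (i - (n + 1) / 2) * spacing + 0.02 * spacing * i^2,
        y = 0.5 * (-1)^i,
        z = 0.3 * (-1)^(i %/% 2))
}

ca_structure <- function(coord_list, chains = NULL, resid = "GLY") {
  # coord_list: named list of n_k x 3 matrices, one per chain
  if (is.null(chains)) chains <- LETTERS[seq_along(coord_list)]
  atoms <- do.call(rbind, lapply(seq_along(coord_list), function(k) {
    m <- as_coord_matrix(coord_list[[k]])
    data.frame(elety = "CA", resid = resid, chain = chains[k],
               resno = seq_len(nrow(m)), x = m[, 1], y = m[, 2], z = m[, 3],
               het = FALSE, stringsAsFactors = FALSE)
  }))
  structure_model(atoms, title = "synthetic")
}

# Rodrigues rotation of points (n x 3) about an axis through `point` with
# direction `dir` by `angle` radians.
rotate_about_axis <- function(pts, point, dir, angle) {
  u <- unit(dir)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(pts, 2, point) %*% t(R), 2, point, `+`)
}

# Block covariance over atoms: within a block, variance `var` and pairwise
# correlation `rho_intra`; between different blocks, correlation `rho_inter`.
#' Build a block-structured atom covariance matrix
#' @param n number of atoms.
#' @param blocks list of disjoint atom-index vectors; atoms outside all
#'   blocks are independent.
#' @param var per-block (recycled) variance, Angstrom^2.
#' @param rho_intra per-block (recycled) within-block correlation.
#' @param rho_inter correlation between atoms of different blocks.
#' @return n x n covariance matrix.
#' @export
block_covariance <- function(n, blocks, var = 0.04, rho_intra = 0.8, rho_inter = 0) {
  idx <- unlist(blocks)
  if (anyDuplicated(idx)) stop_fd("blocks must be disjoint")
  var <- rep_len(var, length(blocks))
  rho_intra <- rep_len(rho_intra, length(blocks))
  sig <- rep(sqrt(var[1]), n)  # default sd for unblocked atoms: first block's
  for (k in seq_along(blocks)) sig[blocks[[k]]] <- sqrt(var[k])
  C <- matrix(0, n, n)
  memb <- integer(n)
  for (k in seq_along(blocks)) memb[blocks[[k]]] <- k
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    C[b, b] <- rho_intra[k]
  }
  if (rho_inter != 0) {
    for (k in seq_along(blocks)) for (l in seq_along(blocks)) if (k != l)
      C[blocks[[k]], blocks[[l]]] <- rho_inter
  }
  diag(C) <- 1
  C <- C * tcrossprod(sig)
  C
}

# --- Gaussian ensembles -----------------------------------------------------

#' Specification of a Gaussian coordinate ensemble
#'
#' Frames are `base + displacement`, with per-atom displacements drawn from a
#' prescribed atom covariance applied independently and identically to the
#' x, y and z axes (isotropic fluctuations). This is the synthetic stand-in
#' for a sampled equilibrium ensemble with known pairwise coordination
#' structure.
#'
#' @param base a `structure_model`.
#' @param covariance n x n symmetric positive semi-definite atom covariance
#'   (Angstrom^2), e.g. from [block_covariance()].
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @export
gaussian_ensemble_spec <- function(base, covariance, n_frames, seed = 1) {
  stopifnot(inherits(base, "structure_model"))
  covariance <- as.matrix(covariance)
  n <- n_atoms(base)
  if (!all(dim(covariance) == c(n, n))) stop_fd("covariance must be %d x %d", n, n)
  if (max(abs(covariance - t(covariance))) > 1e-10) stop_fd("covariance must be symmetric")
  if (n_frames < 2L) stop_fd("n_frames must be >= 2")
  structure(list(base = base, covariance = covariance,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "gaussian_ensemble_spec")
}

#' Generate a Gaussian ensemble trajectory
#' @param spec a [gaussian_ensemble_spec()].
#' @param replica replica label.
#' @return a [trajectory()]; errors if the covariance is not positive
#'   semi-definite.
#' @export
generate_gaussian_ensemble <- function(spec, replica = "synthetic") {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  C <- spec$covariance
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop_fd("covariance is not positive semi-definite (min eigenvalue %.3g)", min(e$values))
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
  n <- n_atoms(spec$base); F <- spec$n_frames
  base <- as_xyz_vector(coords(spec$base))
  xyz <- with_seed(spec$seed, {
    out <- matrix(0, F, 3L * n)
    for (ax in 1:3) {
      disp <- matrix(rnorm(F * n), F, n) %*% t(L)   # F x n, cov = C per axis
      out[, seq(ax, 3L * n, by = 3L)] <- disp
    }
    out
  })
  trajectory(spec$base, sweep(xyz, 2, base, `+`), replica = replica)
}

# --- hinge sweep ------------------------------------------------------------

#' Specification of a rigid two-domain hinge trajectory
#'
#' Domain A stays fixed; domain B is rotated about a given axis by a
#' deterministic sweep `amplitude * cos(pi * (f-1)/(F-1))`, which covers the
#' closed interval `[-amplitude, +amplitude]` exactly (so the measured
#' rotation range is `2 * amplitude` by construction, rather than a random
#' walk whose range would itself be random). Isotropic Gaussian noise of
#' width `sigma` is added to every atom after placement, in the lab frame.
#'
#' @param domain_a,domain_b n x 3 coordinate templates (Angstrom).
#' @param axis_point,axis_dir rotation axis (point + direction).
#' @param amplitude_deg sweep amplitude in degrees, in `[0, 180)`.
#' @param sigma per-atom isotropic noise sd (Angstrom, >= 0).
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @export
hinge_spec <- function(domain_a, domain_b, axis_point, axis_dir,
                       amplitude_deg, sigma = 0, n_frames = 100, seed = 1) {
  if (vec_norm(axis_dir) < 1e-12) stop_fd("degenerate (zero-length) rotation axis")
  if (amplitude_deg < 0 || amplitude_deg >= 180) stop_fd("amplitude must be in [0, 180) degrees")
  if (sigma < 0) stop_fd("sigma must be >= 0")
  structure(list(domain_a = as_coord_matrix(domain_a),
                 domain_b = as_coord_matrix(domain_b),
                 axis_point = axis_point, axis_dir = axis_dir,
                 amplitude_deg = amplitude_deg, sigma = sigma,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "hinge_spec")
}

#' Generate a hinge trajectory
#' @param spec a [hinge_spec()].
#' @param replica replica label.
#' @return a [trajectory()] over a two-chain (A, B) Calpha structure.
#' @export
generate_hinge_trajectory <- function(spec, replica = "synthetic") {
  stopifnot(inherits(spec, "hinge_spec"))
  base <- ca_structure(list(spec$domain_a, spec$domain_b))
  na <- nrow(spec$domain_a); nb <- nrow(spec$domain_b)
  F <- spec$n_frames
  sweep_angle <- if (F == 1L) 0 else rad(spec$amplitude_deg) * cos(pi * (seq_len(F) - 1) / (F - 1))
  xyz <- matrix(0, F, 3L * (na + nb))
  for (f in seq_len(F)) {
    b <- rotate_about_axis(spec$domain_b, spec$axis_point, spec$axis_dir, sweep_angle[f])
    xyz[f, ] <- as_xyz_vector(rbind(spec$domain_a, b))
  }
  if (spec$sigma > 0) {
    xyz <- xyz + with_seed(spec$seed, matrix(rnorm(length(xyz), sd = spec$sigma),
                                             nrow = F))
  }
  trajectory(base, xyz, replica = replica)
}

#' Ready-made hinge fixture with exactly recoverable torsion sweep
#'
#' Builds two elongated domains whose centroid-to-centroid line is the
#' rotation axis, with both principal axes initially perpendicular to it at
#' a 90-degree baseline offset. Under the tip-centroid-centroid-tip torsion
#' convention of [interdomain_torsion_series()] the measured torsion then
#' equals `90 + sweep` degrees frame by frame, so an amplitude of A degrees
#' yields a measured range of exactly 2A.
#'
#' @inheritParams hinge_spec
#' @param n_atoms atoms per domain.
#' @export
hinge_fixture <- function(amplitude_deg = 30, sigma = 0, n_frames = 200,
                          seed = 1, n_atoms = 12) {
  a <- ca_chain_template(n_atoms)                  # elongated along x
  a <- sweep(a, 2, colMeans(a))                    # centroid exactly at origin
  b <- sweep(a %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
             2, c(0, 0, 25), `+`)                  # rotated 90 deg, shifted up z
  hinge_spec(a, b, axis_point = c(0, 0, 25), axis_dir = c(0, 0, 1),
             amplitude_deg = amplitude_deg, sigma = sigma,
             n_frames = n_frames, seed = seed)
}

# --- aromatic ring pairs ----------------------------------------------------

#' Specification of an aromatic ring-pair trajectory
#'
#' Two ideal hexagonal six-carbon rings (bond geometry of a phenyl ring,
#' ring radius 1.39 Angstrom) are placed at exactly the prescribed centroid
#' distance `d` and interplanar angle `theta` before any jitter is added.
#'
#' @param d centroid-centroid distance, Angstrom (> 0).
#' @param theta_deg interplanar angle, degrees, in `[0, 90]`.
#' @param sigma per-atom jitter sd (Angstrom).
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @export
ring_pair_spec <- function(d, theta_deg, sigma = 0, n_frames = 1, seed = 1) {
  if (d <= 0) stop_fd("centroid distance must be > 0")
  if (theta_deg < 0 || theta_deg > 90) stop_fd("theta must be in [0, 90] degrees")
  structure(list(d = d, theta_deg = theta_deg, sigma = sigma,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "ring_pair_spec")
}

hexagon_ring <- function(radius = 1.39) {
  ang <- rad(seq(0, 300, by = 60))
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

#' Generate a ring-pair trajectory
#'
#' The structure carries two phenylalanine-named residues (ring atoms CG,
#' CD1, CD2, CE1, CE2, CZ) on chains A and B so that aromatic-geometry
#' analyses resolve them like real side chains.
#'
#' @param spec a [ring_pair_spec()].
#' @param replica replica label.
#' @export
generate_ring_pair <- function(spec, replica = "synthetic") {
  stopifnot(inherits(spec, "ring_pair_spec"))
  ring1 <- hexagon_ring()
  ring2 <- rotate_about_axis(hexagon_ring(), c(0, 0, 0), c(1, 0, 0), rad(spec$theta_deg))
  ring2 <- sweep(ring2, 2, c(0, 0, spec$d), `+`)
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  atoms <- rbind(
    data.frame(elety = nm, resid = "PHE", chain = "A", resno = 1L,
               x = ring1[, 1], y = ring1[, 2], z = ring1[, 3], het = FALSE),
    data.frame(elety = nm, resid = "PHE", chain = "B", resno = 1L,
               x = ring2[, 1], y = ring2[, 2], z = ring2[, 3], het = FALSE))
  base <- structure_model(atoms, title = "synthetic ring pair")
  F <- spec$n_frames
  xyz <- matrix(rep(as_xyz_vector(coords(base)), each = F), nrow = F)
  if (spec$sigma > 0)
    xyz <- xyz + with_seed(spec$seed, matrix(rnorm(length(xyz), sd = spec$sigma), F))
  trajectory(base, xyz, replica = replica)
}

# --- two-state switches -----------------------------------------------------

#' Specification of a two-state switch trajectory
#'
#' Each frame independently adopts conformation 1 with probability `p`, else
#' conformation 2 — a stand-in for side-chain rotamer flipping with known
#' state populations. True per-frame labels are returned alongside the
#' trajectory (attribute `"labels"`).
#'
#' @param conf1,conf2 n x 3 conformations.
#' @param p probability of conformation 1, in `[0, 1]`.
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @export
switch_spec <- function(conf1, conf2, p, n_frames, seed = 1) {
  conf1 <- as_coord_matrix(conf1); conf2 <- as_coord_matrix(conf2)
  stopifnot(all(dim(conf1) == dim(conf2)))
  if (p < 0 || p > 1) stop_fd("p must be in [0, 1]")
  if (max(abs(conf1 - conf2)) < 1e-12)
    warn_fd("the two conformations are identical; state labels are meaningless")
  structure(list(conf1 = conf1, conf2 = conf2, p = p,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "switch_spec")
}

#' Generate a two-state switch trajectory
#' @param spec a [switch_spec()].
#' @param replica replica label.
#' @return a [trajectory()] with attribute `"labels"` (1 or 2 per frame).
#' @export
generate_switch_trajectory <- function(spec, replica = "synthetic") {
  stopifnot(inherits(spec, "switch_spec"))
  base <- ca_structure(list(spec$conf1))
  v1 <- as_xyz_vector(spec$conf1); v2 <- as_xyz_vector(spec$conf2)
  labels <- with_seed(spec$seed, ifelse(runif(spec$n_frames) < spec$p, 1L, 2L))
  xyz <- t(vapply(labels, function(l) if (l == 1L) v1 else v2, numeric(length(v1))))
  tr <- trajectory(base, xyz, replica = replica)
  attr(tr, "labels") <- labels
  tr
}

# --- tagged metal sites -----------------------------------------------------

#' Tagged metal-site fixture
#'
#' A minimal structure carrying a methionine backbone (CA, C, carbonyl O) and
#' one or two Mn particles tagged as HETATM records, placed at prescribed
#' distances: `d_carbonyl_mn` from the carbonyl oxygen to the first metal
#' ("ADMIDAS"-like site) and `d_mn_mn` between the two metals
#' ("MIDAS"-"ADMIDAS" spacing). Defaults are the crystallographic
#' carbonyl-to-metal separations of the agonist-bound (14.6 Angstrom) and
#' antagonist-bound (2.9 Angstrom) integrin states; pass the value for the
#' state being emulated. Optional isotropic jitter makes a multi-frame
#' distance series with known mean.
#'
#' @param d_carbonyl_mn carbonyl O to first metal distance, Angstrom.
#' @param d_mn_mn metal-metal distance, Angstrom (NULL for a single metal).
#' @param sigma per-atom jitter sd (Angstrom).
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @return a [trajectory()]; atoms are labelled so that
#'   `"B:335:O"`, `"B:9001:MN"` and `"B:9002:MN"` resolve.
#' @export
metal_site_fixture <- function(d_carbonyl_mn = 14.6, d_mn_mn = NULL,
                               sigma = 0, n_frames = 1, seed = 1) {
  stopifnot(d_carbonyl_mn > 0)
  atoms <- data.frame(
    elety = c("CA", "C", "O"), resid = "MET", chain = "B", resno = 335L,
    x = c(-1.5, -0.8, 0), y = c(1.2, 0.4, 0), z = 0, het = FALSE,
    stringsAsFactors = FALSE)
  mn1 <- data.frame(elety = "MN", resid = "MN", chain = "B", resno = 9001L,
                    x = d_carbonyl_mn, y = 0, z = 0, het = TRUE)
  atoms <- rbind(atoms, mn1)
  if (!is.null(d_mn_mn)) {
    stopifnot(d_mn_mn > 0)
    atoms <- rbind(atoms, data.frame(elety = "MN", resid = "MN", chain = "B",
                                     resno = 9002L, x = d_carbonyl_mn,
                                     y = d_mn_mn, z = 0, het = TRUE))
  }
  base <- structure_model(atoms, title = "synthetic metal site")
  F <- as.integer(n_frames)
  xyz <- matrix(rep(as_xyz_vector(coords(base)), each = F), nrow = F)
  if (sigma > 0)
    xyz <- xyz + with_seed(seed, matrix(rnorm(length(xyz), sd = sigma), F))
  trajectory(base, xyz, replica = "synthetic")
}
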