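test_that("pca recovers a prescribed coordinate covariance", {
  set.seed(19)
  n_at <- 3                                   # 9 coordinate dimensions
  st <- make_ca_structure(list(chain_coords(n_at)))
  vals <- c(9, 1, 1, 0.5, 0.5, 0.2, 0.2, 0.1, 0.1)
  V <- qr.Q(qr(matrix(rnorm(81), 9)))
  F <- 10000
  X <- matrix(rnorm(F * 9), F) %*% diag(sqrt(vals)) %*% t(V)
  tr <- trajectory(st, sweep(X, 2, as.numeric(t(coords(st))), `+`))
  ed <- fit_pca(tr)
  expect_equal(ed$values[1], 9, tolerance = 0.05)
  expect_gt(abs(sum(ed$vectors[, 1] * V[, 1])), 0.99)
  # sum of eigenvalues equals the covariance trace
  Xc <- sweep(tr$xyz, 2, colMeans(tr$xyz))
  expect_equal(sum(ed$values), sum(diag(crossprod(Xc) / F)), tolerance = 1e-6)
  # eigenvectors orthonormal
  G <- crossprod(ed$vectors)
  expect_lt(max(abs(G - diag(9))), 1e-8)
  expect_error(fit_pca(trajectory(st, tr$xyz[1, , drop = FALSE])), "one frame")
})

test_that("projections are consistent with the decomposition", {
  set.seed(23)
  st <- make_ca_structure(list(chain_coords(5)))
  tr <- generate_gaussian_ensemble(gaussian_ensemble_spec(
    st, block_covariance(5, list(1:5), var = 0.3, rho_intra = 0.5), 400, seed = 5))
  ed <- fit_pca(tr, n_modes = 15)
  # projecting the mean structure gives 0 on all modes
  mean_traj <- trajectory(st, ed$mean)
  expect_lt(max(abs(project_trajectory(mean_traj, ed, modes = 1:10))), 1e-10)
  # variance of the fit ensemble's projection on mode k equals eigenvalue k
  p1 <- project_trajectory(tr, ed, modes = 1)
  expect_equal(mean((p1 - mean(p1))^2), ed$values[1], tolerance = 1e-6)
  # completeness: reconstruction from all modes reproduces centred frames
  all_p <- project_trajectory(tr, ed, modes = seq_along(ed$values))
  rec <- all_p %*% t(ed$vectors)
  expect_lt(max(abs(rec - sweep(tr$xyz, 2, ed$mean))), 1e-8)
  expect_error(project_trajectory(tr, ed, modes = 99), "out of range")
})

test_that("pca is equivariant under a global rotation of the input", {
  set.seed(29)
  st <- make_ca_structure(list(chain_coords(6)))
  tr <- generate_gaussian_ensemble(gaussian_ensemble_spec(
    st, block_covariance(6, list(1:3, 4:6), var = 0.4, rho_intra = 0.6), 300, seed = 7))
  R <- random_rotation()
  rot <- rigidly_move_frames(tr, rot = R, shift = c(0, 0, 0))
  e1 <- fit_pca(tr)
  e2 <- fit_pca(rot)
  expect_equal(e1$values, e2$values, tolerance = 1e-8)
  # rotating mode 1 of the unrotated ensemble matches mode 1 of the rotated
  v1 <- matrix(e1$vectors[, 1], ncol = 3, byrow = TRUE) %*% R
  expect_equal(abs(sum(as.numeric(t(v1)) * e2$vectors[, 1])), 1, tolerance = 1e-6)
})

test_that("cosine content flags diffusive projections and passes closed forms", {
  F <- 1000
  tmid <- (seq_len(F) - 0.5) / F
  expect_equal(cosine_content(cos(pi * tmid), 1), 1.0, tolerance = 1e-12)
  expect_equal(cosine_content(cos(2 * pi * tmid), 2), 1.0, tolerance = 1e-12)
  expect_lt(cosine_content(rep(3.2, F), 1), 1e-12)
  expect_warning(cc0 <- cosine_content(rep(0, F), 1), "all-zero")
  expect_equal(cc0, 0)
  # white noise: small cosine content with overwhelming probability
  set.seed(41)
  cc <- replicate(100, cosine_content(rnorm(5000), 1))
  expect_lt(stats::quantile(cc, 0.99), 0.1)
})

test_that("subspace overlap matches its brute-force double loop", {
  set.seed(43)
  d <- 12; m <- 3
  A <- qr.Q(qr(matrix(rnorm(d * m), d)))
  B <- qr.Q(qr(matrix(rnorm(d * m), d)))
  expect_equal(subspace_overlap(A, A), 1.0, tolerance = 1e-12)
  # orthogonal complements: zero overlap
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  expect_equal(subspace_overlap(Q[, 1:m], Q[, (m + 1):(2 * m)]), 0, tolerance = 1e-12)
  brute <- 0
  for (i in 1:m) for (j in 1:m) brute <- brute + sum(A[, i] * B[, j])^2
  expect_equal(subspace_overlap(A, B), sqrt(brute / m), tolerance = 1e-12)
  expect_error(subspace_overlap(A, B[, 1:2]), "mismatch")
})

test_that("split-half overlap of a stationary gaussian ensemble grows with sampling", {
  # distinct eigenvalues so the essential subspace is well defined
  st <- make_ca_structure(list(chain_coords(3)))
  vals <- c(9, 4, 1, 0.5, 0.3, 0.2, 0.1, 0.05, 0.02)
  set.seed(13)
  V <- qr.Q(qr(matrix(rnorm(81), 9)))
  ov <- function(F, seed) {
    set.seed(seed)
    X <- matrix(rnorm(F * 9), F) %*% diag(sqrt(vals)) %*% t(V)
    tr <- trajectory(st, sweep(X, 2, as.numeric(t(coords(st))), `+`))
    sampling_diagnostics(tr, m = 2)$per_replica$split_half_overlap
  }
  o_small <- mean(vapply(1:5, function(s) ov(12, s), 0))
  o_big <- ov(4000, 1)
  expect_gt(o_big, o_small)
  expect_gt(o_big, 0.95)
})
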