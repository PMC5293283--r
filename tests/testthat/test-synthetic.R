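test_that("gaussian ensembles realise the prescribed covariance", {
  st <- make_ca_structure(list(chain_coords(12)))
  # zero covariance: all frames identical to base
  z <- generate_gaussian_ensemble(gaussian_ensemble_spec(st, matrix(0, 12, 12), 5))
  expect_equal(max(abs(sweep(z$xyz, 2, as.numeric(t(coords(st)))))), 0)
  # diagonal 0.04 A^2: per-coordinate sample variance within 5%
  tr <- generate_gaussian_ensemble(gaussian_ensemble_spec(st, diag(0.04, 12), 5000, seed = 4))
  v <- apply(sweep(tr$xyz, 2, as.numeric(t(coords(st)))), 2, function(x) mean(x^2))
  expect_true(all(abs(v - 0.04) / 0.04 < 0.15))
  expect_lt(abs(mean(v) - 0.04) / 0.04, 0.05)
  # same seed twice -> bit-identical
  tr2 <- generate_gaussian_ensemble(gaussian_ensemble_spec(st, diag(0.04, 12), 5000, seed = 4))
  expect_identical(tr$xyz, tr2$xyz)
  # non-PSD covariance is refused
  bad <- diag(12); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(generate_gaussian_ensemble(gaussian_ensemble_spec(st, bad, 10)),
               "positive semi-definite")
})

test_that("empirical covariance converges to the spec with frame count", {
  st <- make_ca_structure(list(chain_coords(8)))
  C <- block_covariance(8, list(1:4, 5:8), var = 0.25, rho_intra = 0.7)
  frob <- function(F, seed) {
    tr <- generate_gaussian_ensemble(gaussian_ensemble_spec(st, C, F, seed = seed))
    xs <- tr$xyz[, seq(1, 24, by = 3)]      # x coordinates only
    Ch <- crossprod(sweep(xs, 2, colMeans(xs))) / F
    sqrt(sum((Ch - C)^2))
  }
  expect_lt(frob(20000, 9), frob(200, 9))
})

test_that("hinge trajectories impose an exact torsion sweep", {
  # amplitude 0, sigma 0: constant torsion series
  tr0 <- generate_hinge_trajectory(hinge_fixture(amplitude_deg = 0, n_frames = 20))
  ts0 <- interdomain_torsion_series(tr0, 1:12, 13:24)
  expect_lt(diff(range(ts0$values)), 1e-8)
  # amplitude 30, sigma 0: measured range 60 +/- 0.5 degrees
  tr <- generate_hinge_trajectory(hinge_fixture(amplitude_deg = 30, n_frames = 101))
  ts <- interdomain_torsion_series(tr, 1:12, 13:24)
  expect_equal(diff(range(ts$values)), 60, tolerance = 0.5 / 60)
  # rigid bodies: intra-domain DF exactly zero for both domains
  dfm <- df_matrix(tr)
  expect_lt(max(dfm$mat[1:12, 1:12]), 1e-10)
  expect_lt(max(dfm$mat[13:24, 13:24]), 1e-10)
  # inter-domain DF dwarfs intra-domain DF by construction
  expect_gt(max(dfm$mat[1:12, 13:24]), 1)
  # degenerate axis is refused
  expect_error(hinge_spec(chain_coords(5), chain_coords(5), c(0, 0, 0),
                          c(0, 0, 0), 10), "axis")
})

test_that("ring pairs are built at exactly the prescribed geometry", {
  # the crystallographic tyrosine-tryptophan packing geometry of the
  # antagonist complex: 4.9 A centroids, 25.8 degree interplanar angle
  rp <- generate_ring_pair(ring_pair_spec(4.9, 25.8))
  sg <- stacking_series(rp, "A:1", "B:1")
  expect_equal(sg$distance[1], 4.9, tolerance = 1e-6)
  expect_equal(sg$theta[1], 25.8, tolerance = 1e-6)
  # recovery over a (d, theta) grid
  for (d in c(3.5, 5, 8, 12)) for (th in c(0, 10, 45, 88)) {
    s <- stacking_series(generate_ring_pair(ring_pair_spec(d, th)), "A:1", "B:1")
    expect_equal(s$distance[1], d, tolerance = 1e-6)
    expect_equal(s$theta[1], th, tolerance = 1e-6)
  }
  expect_error(ring_pair_spec(-1, 10), "distance")
  expect_error(ring_pair_spec(5, 95), "theta")
})

test_that("switch trajectories respect the prescribed state populations", {
  c1 <- chain_coords(6)
  c2 <- c1 + 10
  # p = 1: every frame is conformation 1
  all1 <- generate_switch_trajectory(switch_spec(c1, c2, 1, 50))
  expect_true(all(attr(all1, "labels") == 1L))
  expect_equal(max(abs(sweep(all1$xyz, 2, as.numeric(t(c1))))), 0)
  # p = 0.7, F = 1000: binomial 99% interval around 700
  sw <- generate_switch_trajectory(switch_spec(c1, c2, 0.7, 1000, seed = 12))
  n1 <- sum(attr(sw, "labels") == 1L)
  expect_true(abs(n1 - 700) < 2.58 * sqrt(1000 * 0.7 * 0.3) + 1)
  # seed reproducibility
  sw2 <- generate_switch_trajectory(switch_spec(c1, c2, 0.7, 1000, seed = 12))
  expect_identical(sw$xyz, sw2$xyz)
  expect_warning(switch_spec(c1, c1, 0.5, 10), "identical")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(77)
  before <- rnorm(1)
  set.seed(77)
  invisible(generate_gaussian_ensemble(
    gaussian_ensemble_spec(make_ca_structure(list(chain_coords(4))), diag(4), 5)))
  expect_identical(rnorm(1), before)
})
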