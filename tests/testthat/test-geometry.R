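test_that("radius of gyration matches closed forms and the direct formula", {
  # two points d apart: Rg = d/2
  st2 <- make_ca_structure(list(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)))
  tr2 <- trajectory(st2, as.numeric(t(coords(st2))))
  expect_equal(radius_of_gyration(tr2)$values, 1.5)
  # unit square corners: Rg = sqrt(2)/2
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  st4 <- make_ca_structure(list(sq))
  expect_equal(radius_of_gyration(trajectory(st4, as.numeric(t(sq))))$values,
               sqrt(2) / 2)
  # random cloud: direct-formula oracle
  set.seed(51)
  m <- matrix(rnorm(60), 20, 3)
  stm <- make_ca_structure(list(m))
  rg <- radius_of_gyration(trajectory(stm, as.numeric(t(m))))$values
  expect_equal(rg, sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2))), tolerance = 1e-12)
})

test_that("tagged pair distances work for metal-site particles", {
  # coincident atoms
  tr <- metal_site_fixture(d_carbonyl_mn = 1e-9 + 5, d_mn_mn = 5)
  d0 <- pair_distance_series(tr, "B:9001:MN", "B:9001:MN")
  expect_equal(d0$values, 0)
  # carbonyl-to-metal distances at the two crystallographic states
  agonist <- metal_site_fixture(d_carbonyl_mn = 14.6)
  expect_equal(pair_distance_series(agonist, "B:335:O", "B:9001:MN")$values, 14.6)
  antagonist <- metal_site_fixture(d_carbonyl_mn = 2.9)
  expect_equal(pair_distance_series(antagonist, "B:335:O", "B:9001:MN")$values, 2.9)
  # metal-metal spacing
  paired <- metal_site_fixture(d_carbonyl_mn = 14.6, d_mn_mn = 8.5)
  expect_equal(pair_distance_series(paired, "B:9001:MN", "B:9002:MN")$values, 8.5)
  expect_error(pair_distance_series(agonist, "B:9002:MN", "B:335:O"), "resolves to 0")
})

test_that("principal axes match the gyration-tensor oracle", {
  # collinear-ish points on the x axis (plus tiny spread to stay full rank)
  m <- cbind(seq(-5, 5), 0.01 * c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1),
             0.005 * rep(c(1, -1), length.out = 11))
  pa <- principal_axes(m)
  expect_gt(abs(pa$axes[1, 1]), 0.999)
  expect_gt(pa$axes[which.max(abs(pa$axes[, 1])), 1], 0)   # sign rule
  set.seed(52)
  cloud <- matrix(rnorm(90), 30, 3) %*% diag(c(3, 2, 1))
  pa2 <- principal_axes(cloud)
  g <- crossprod(sweep(cloud, 2, colMeans(cloud))) / 30
  e <- eigen(g, symmetric = TRUE)
  for (k in 1:3)
    expect_equal(abs(sum(pa2$axes[, k] * e$vectors[, k])), 1, tolerance = 1e-10)
  expect_equal(pa2$extents, e$values, tolerance = 1e-10)
  expect_error(principal_axes(cbind(1:5, 0, 0)), "collinear")
})

test_that("interdomain torsion tracks imposed rotations and ignores global motion", {
  # static structure: constant series
  tr0 <- generate_hinge_trajectory(hinge_fixture(amplitude_deg = 0, n_frames = 10))
  ts0 <- interdomain_torsion_series(tr0, 1:12, 13:24)
  expect_lt(diff(range(ts0$values)), 1e-9)
  # imposed 30-degree amplitude: measured range 60 +/- 0.5
  tr <- generate_hinge_trajectory(hinge_fixture(amplitude_deg = 30, n_frames = 101))
  ts <- interdomain_torsion_series(tr, 1:12, 13:24)
  expect_equal(diff(range(ts$values)), 60, tolerance = 0.5 / 60)
  # frame-wise global rigid motion leaves the series unchanged
  set.seed(53)
  moved <- rigidly_move_frames(tr)
  ts2 <- interdomain_torsion_series(moved, 1:12, 13:24)
  expect_lt(max(abs(ts$values - ts2$values)), 1e-8)
})

test_that("stacking classification applies the printed geometry windows", {
  # (5.0 A, 0 deg): paired and stacked
  s1 <- stacking_series(generate_ring_pair(ring_pair_spec(5, 0)), "A:1", "B:1")
  expect_equal(s1$distance[1], 5, tolerance = 1e-9)
  expect_equal(s1$theta[1], 0, tolerance = 1e-6)
  expect_true(s1$paired[1])
  expect_false(s1$stacked[1])   # theta 0 < 1.2 window floor
  # 15 A apart: not paired under the 12 A rule
  s2 <- stacking_series(generate_ring_pair(ring_pair_spec(15, 20)), "A:1", "B:1")
  expect_false(s2$paired[1])
  expect_false(s2$stacked[1])
  # boundary behaviour of the stacking window [4.9, 10.4] A x [1.2, 89.9] deg
  inside <- stacking_series(generate_ring_pair(ring_pair_spec(4.9, 1.2)), "A:1", "B:1")
  expect_true(inside$stacked[1])
  upper <- stacking_series(generate_ring_pair(ring_pair_spec(10.4, 89.9)), "A:1", "B:1")
  expect_true(upper$stacked[1])
  expect_true(upper$paired[1])
  far <- stacking_series(generate_ring_pair(ring_pair_spec(10.5, 45)), "A:1", "B:1")
  expect_false(far$stacked[1])
  tilt <- stacking_series(generate_ring_pair(ring_pair_spec(6, 0.5)), "A:1", "B:1")
  expect_false(tilt$stacked[1])
})

test_that("theta is independent of ring atom ordering and normal sign", {
  rp <- generate_ring_pair(ring_pair_spec(6, 30))
  base <- stacking_series(rp, "A:1", "B:1")$theta[1]
  # permute ring-B atom order in the structure (same geometry)
  perm <- c(1:6, sample(7:12))
  st <- structure_model(rp$structure$atoms[perm, ], title = "perm")
  tr <- trajectory(st, rp$xyz[, as.integer(rbind(3 * perm - 2, 3 * perm - 1, 3 * perm))])
  expect_equal(stacking_series(tr, "A:1", "B:1")$theta[1], base, tolerance = 1e-9)
  # global rigid motion: invariant
  moved <- rigidly_move_frames(rp)
  sm <- stacking_series(moved, "A:1", "B:1")
  expect_equal(sm$theta[1], base, tolerance = 1e-8)
  expect_equal(sm$distance[1], 6, tolerance = 1e-8)
  expect_error(stacking_series(rp, "A:2", "B:1"), "not found")
})

# a donor/acceptor pair at prescribed distance, with a hydrogen at a
# prescribed donor-H...acceptor angle
hbond_fixture <- function(d, angle_deg = 180, frames = 1) {
  ang <- (180 - angle_deg) * pi / 180
  atoms <- data.frame(
    elety = c("N", "H", "O"), resid = c("ASN", "ASN", "HOH"),
    chain = c("A", "A", "B"), resno = c(1L, 1L, 1L),
    x = c(0, 1, 1 + (d - 1) * cos(ang)), y = c(0, 0, (d - 1) * sin(ang)),
    z = 0, het = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  st <- structure_model(atoms)
  trajectory(st, matrix(rep(as.numeric(t(coords(st))), frames), frames, byrow = TRUE))
}

test_that("hydrogen bonds apply distance and angle criteria", {
  pairs <- data.frame(a = "A:1:N", b = "B:1:O", hydrogen = "A:1:H",
                      type = "hbond", stringsAsFactors = FALSE)
  # D-A 2.8 A, angle 180: present every frame, occupancy 100%
  occ <- hbond_saltbridge_occupancy(hbond_fixture(2.8, 180, frames = 5), pairs = pairs)
  expect_equal(occ$occupancy, 100)
  # D-A 4.0 A: beyond the 3.5 A cutoff
  occ2 <- hbond_saltbridge_occupancy(hbond_fixture(4.0, 180), pairs = pairs,
                                     min_occupancy = 0)
  expect_equal(occ2$occupancy, 0)
  # close but bent (angle 90 < 120): rejected
  occ3 <- hbond_saltbridge_occupancy(hbond_fixture(2.8, 90), pairs = pairs,
                                     min_occupancy = 0)
  expect_equal(occ3$occupancy, 0)
  # distance-only fallback when no hydrogen is given
  occ4 <- hbond_saltbridge_occupancy(hbond_fixture(2.8, 90),
                                     pairs = data.frame(a = "A:1:N", b = "B:1:O"))
  expect_equal(occ4$occupancy, 100)
})

test_that("occupancy counts the constructed fraction of frames and is additive", {
  # bridge present in exactly 38% of 100 frames by construction
  tr_in <- hbond_fixture(2.8, 180, frames = 1)
  base <- tr_in$xyz[1, ]
  apart <- base; apart[7] <- 20   # move acceptor away
  xyz <- matrix(rep(base, 100), 100, byrow = TRUE)
  xyz[39:100, ] <- matrix(rep(apart, 62), 62, byrow = TRUE)
  tr <- trajectory(tr_in$structure, xyz)
  pairs <- data.frame(a = "A:1:N", b = "B:1:O")
  occ <- hbond_saltbridge_occupancy(tr, pairs = pairs)
  expect_equal(occ$occupancy, 38.0)
  # additivity: occupancy over two replicas = frame-weighted mean of parts
  r1 <- trajectory(tr_in$structure, xyz[1:40, , drop = FALSE])    # 38/40
  r2 <- trajectory(tr_in$structure, xyz[41:100, , drop = FALSE])  # 0/60
  o1 <- hbond_saltbridge_occupancy(r1, pairs = pairs, min_occupancy = 0)$occupancy
  o2 <- hbond_saltbridge_occupancy(r2, pairs = pairs, min_occupancy = 0)$occupancy
  oc <- hbond_saltbridge_occupancy(list(r1, r2), pairs = pairs, min_occupancy = 0)$occupancy
  expect_equal(oc, (40 * o1 + 60 * o2) / 100)
})

test_that("salt bridges are detected by charged-group proximity", {
  atoms <- data.frame(
    elety = c("NH1", "CZ", "OD1"), resid = c("ARG", "ARG", "ASP"),
    chain = c("A", "A", "B"), resno = c(10L, 10L, 5L),
    x = c(0, -1, 3.8), y = 0, z = 0, het = FALSE, stringsAsFactors = FALSE)
  st <- structure_model(atoms)
  tr <- trajectory(st, as.numeric(t(coords(st))))
  occ <- hbond_saltbridge_occupancy(tr, group_a = resolve_selection(st, "chain A"),
                                    group_b = resolve_selection(st, "chain B"))
  expect_true(any(occ$type == "salt" & occ$occupancy == 100))
  # beyond 4.0 A: no salt bridge
  tr2 <- trajectory(st, as.numeric(t(coords(st))) + c(0, 0, 0, 0, 0, 0, 1.5, 0, 0))
  occ2 <- hbond_saltbridge_occupancy(tr2, group_a = resolve_selection(st, "chain A"),
                                     group_b = resolve_selection(st, "chain B"),
                                     min_occupancy = 0)
  expect_true(all(occ2$occupancy[occ2$type == "salt"] == 0))
})
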