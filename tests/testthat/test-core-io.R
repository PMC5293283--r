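test_that("PDB records parse with fixed-column semantics", {
  f <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1.234, -2.5, 3.75),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 10.001, 0, -7.125),
    "END"))
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(coords(s)[1, ], c(1.234, -2.5, 3.75), ignore_attr = TRUE)
  expect_equal(coords(s)[2, ], c(10.001, 0, -7.125), ignore_attr = TRUE)
  expect_equal(s$atoms$resno, c(1L, 2L))
})

test_that("malformed and empty PDB inputs fail informatively", {
  bad <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2      xx.xxx   0.000   0.000"))
  expect_error(read_structure(bad), "line 2")
  empty <- write_mini_pdb("END")
  expect_error(read_structure(empty), "no ATOM")
})

test_that("altloc policy keeps 'A' or blank and drops the rest", {
  f <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 0.5, 0, 0, altloc = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_atom_line(4, "CB", "SER", "A", 1, 1, 1, 0, altloc = "C")))
  # hand-count oracle over the raw text: altloc column 17
  lines <- readLines(f)
  rec <- grepl("^ATOM", lines)
  expected <- sum(substr(lines[rec], 17, 17) %in% c(" ", "A"))
  expect_message(s <- read_structure(f), "dropped 2")
  expect_equal(nrow(s$atoms), expected)
  expect_false(any(s$atoms$alt == "B"))
})

test_that("selection resolution is deterministic interval arithmetic", {
  # one Calpha per residue 1..500 on chain B: the hybrid-domain intervals
  # (55-108, 353-434) must give 54 + 82 = 136 atoms
  s <- make_ca_structure(list(chain_coords(500)), chains = "B")
  hybrid <- domain_definition("hybrid", "B", list(c(55, 108), c(353, 434)))
  sel <- resolve_selection(s, hybrid, atom_filter = "CA")
  expect_length(sel, 136L)
  sel2 <- resolve_selection(s, "chain B and resid 55-108,353-434 and name CA")
  expect_identical(sel$indices, sel2$indices)
  # pure function of (structure, expression)
  expect_identical(resolve_selection(s, "chain B and resid 1-10")$indices,
                   resolve_selection(s, "chain B and resid 1-10")$indices)
  expect_error(resolve_selection(s, "chain Z"), "no atoms")
  expect_error(resolve_selection(s, "chain B and resid 900-950"), "no atoms")
})

test_that("domain definitions reject overlapping intervals", {
  expect_error(domain_definition("x", "A", list(c(1, 10), c(10, 20))), "overlap")
  expect_silent(domain_definition("x", "A", list(c(1, 10), c(11, 20))))
})

test_that("trajectory readers round-trip generated fixtures", {
  set.seed(11)
  st <- make_ca_structure(list(chain_coords(7)))
  xyz <- matrix(rnorm(3 * 21, sd = 4), 3, 21)
  tr <- trajectory(st, xyz)
  # multi-model PDB: 3 frames x 7 atoms, coordinates at file precision (1e-3)
  fp <- tempfile(fileext = ".pdb")
  write_trajectory(tr, fp)
  tr2 <- read_trajectory(st, fp)
  expect_equal(n_frames(tr2), 3L)
  expect_lt(max(abs(tr2$xyz - xyz)), 1e-3 + 1e-9)
  # DCD: binary round trip at float32 precision
  fd <- tempfile(fileext = ".dcd")
  write_trajectory(tr, fd)
  tr3 <- read_trajectory(st, fd)
  expect_lt(max(abs(tr3$xyz - xyz)), 1e-5)
  # atom-count mismatch is an error
  st8 <- make_ca_structure(list(chain_coords(8)))
  expect_error(read_trajectory(st8, fd), "atoms")
})

test_that("superposition recovers rigid motions with proper rotations only", {
  set.seed(21)
  st <- make_ca_structure(list(chain_coords(10)))
  ref <- coords(st)
  R <- random_rotation()
  moved <- sweep(ref %*% R, 2, c(3, -2, 8), `+`)
  tr <- trajectory(st, as.numeric(t(moved)))
  fitted <- superpose_trajectory(tr, st)
  expect_lt(rmsd(frame_coords(fitted, 1), ref), 1e-8)
  # idempotence
  fitted2 <- superpose_trajectory(fitted, st)
  expect_lt(max(abs(fitted2$xyz - fitted$xyz)), 1e-8)
  # mirror image: no reflection allowed, so the fit cannot be perfect
  mir <- ref; mir[, 1] <- -mir[, 1]
  expect_gt(rmsd(mir, ref, fit = TRUE), 0.1)
  # quaternion-method oracle agreement on random pairs
  for (i in 1:5) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    Rk <- fluctdyn:::kabsch_rotation(sweep(P, 2, colMeans(P)),
                                     sweep(Q, 2, colMeans(Q)))
    Rq <- quaternion_rotation(P, Q)
    expect_lt(max(abs(Rk - Rq)), 1e-8)
    expect_equal(det(Rk), 1, tolerance = 1e-10)
  }
})

test_that("rmsd satisfies its metric properties", {
  set.seed(31)
  a <- matrix(rnorm(24), 8, 3)
  b <- matrix(rnorm(24), 8, 3)
  cc <- matrix(rnorm(24), 8, 3)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_lte(rmsd(a, cc), rmsd(a, b) + rmsd(b, cc) + 1e-12)
  # rigid 1 A translation: 1.0 unfitted, 0 fitted
  shifted <- sweep(a, 2, c(1, 0, 0), `+`)
  expect_equal(rmsd(a, shifted), 1.0)
  expect_lt(rmsd(a, shifted, fit = TRUE), 1e-10)
  expect_error(rmsd(a, b[1:4, ]), "mismatch")
})
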