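# offline-testable parts of the crystal-structure machinery, exercised on
# synthetic models built to the ectodomain numbering scheme

# one Calpha per residue of the full construct numbering, three chains
make_synthetic_ectodomain <- function() {
  resnos <- list(A = 1:599, B = 55:434, C = 1417:1507)
  atoms <- do.call(rbind, lapply(names(resnos), function(ch) {
    rn <- resnos[[ch]]
    m <- chain_coords(length(rn), offset = switch(ch, A = c(0, 0, 0),
                                                  B = c(0, 8, 0), C = c(0, 16, 0)))
    data.frame(elety = "CA", resid = "GLY", chain = ch, resno = rn,
               x = m[, 1], y = m[, 2], z = m[, 3], het = FALSE,
               stringsAsFactors = FALSE)
  }))
  structure_model(atoms, title = "synthetic ectodomain")
}

test_that("the construct selection reproduces the published particle counts", {
  s <- make_synthetic_ectodomain()
  # full complex: 599 (propeller+thigh) + 380 (betaA+hybrid) + 91 (FN10) = 1070
  full <- md_construct_selection(s, "A", "B", "C")
  expect_length(full, 1070L)
  # integrin only: 979 particles
  expect_length(md_construct_selection(s, "A", "B"), 979L)
  doms <- integrin_domains("A", "B", "C")
  expect_length(resolve_selection(s, doms$hybrid, atom_filter = "CA"), 136L)
  expect_length(resolve_selection(s, doms$betaA, atom_filter = "CA"), 244L)
  expect_length(resolve_selection(s, doms$fn10, atom_filter = "CA"), 91L)
})

test_that("residue-paired rmsd drops unpaired residues and measures the rest", {
  s1 <- make_synthetic_ectodomain()
  # second structure: subset of residues, rigidly moved, one atom perturbed
  keep <- s1$atoms$chain != "C" & !(s1$atoms$resno %in% 1:50 & s1$atoms$chain == "A")
  at2 <- s1$atoms[keep, ]
  s2 <- structure_model(at2, title = "moved")
  R <- random_rotation()
  m <- as.matrix(at2[, c("x", "y", "z")]) %*% R
  m <- sweep(m, 2, c(5, -3, 2), `+`)
  s2$atoms$x <- m[, 1]; s2$atoms$y <- m[, 2]; s2$atoms$z <- m[, 3]
  res <- suppressMessages(paired_ca_rmsd(s1, s2, c("A", "B")))
  expect_equal(res$n_paired, 979L - 50L)
  expect_equal(res$n_dropped, 50L + 91L * 0)   # FN chain excluded by the map
  expect_lt(res$rmsd, 1e-8)                    # pure rigid motion fits away
  # a real deformation registers in nm
  s3 <- s2
  s3$atoms$x <- s3$atoms$x + rnorm(nrow(at2), sd = 2)
  res3 <- suppressMessages(paired_ca_rmsd(s1, s3, c("A", "B")))
  expect_gt(res3$rmsd_nm, 0.1)
  expect_equal(res3$rmsd, res3$rmsd_nm * 10)
})

test_that("metal sites are located from their coordination shells", {
  # betaA-like fragment: coordinating oxygens + two metals
  atoms <- rbind(
    data.frame(elety = "OD1", resid = "ASP", chain = "B", resno = 126L,
               x = 0, y = 0, z = 0, het = FALSE),
    data.frame(elety = "OD1", resid = "ASP", chain = "B", resno = 127L,
               x = 1.5, y = 0, z = 0, het = FALSE),
    data.frame(elety = "OG", resid = "SER", chain = "B", resno = 121L,
               x = 8, y = 0, z = 0, het = FALSE),
    data.frame(elety = "OE1", resid = "GLU", chain = "B", resno = 220L,
               x = 9.5, y = 0, z = 0, het = FALSE),
    data.frame(elety = "O", resid = "MET", chain = "B", resno = 335L,
               x = 0.75, y = 2.9, z = 0, het = FALSE),
    data.frame(elety = "MN", resid = "MN", chain = "B", resno = 9001L,
               x = 0.75, y = 0, z = 0, het = TRUE),
    data.frame(elety = "MN", resid = "MN", chain = "B", resno = 9002L,
               x = 8.75, y = 0, z = 0, het = TRUE))
  atoms$elesy <- NULL
  s <- structure_model(atoms, title = "synthetic metal shell")
  sites <- find_metal_sites(s, "B")
  expect_equal(s$atoms$resno[sites["ADMIDAS"]], 9001L)
  expect_equal(s$atoms$resno[sites["MIDAS"]], 9002L)
  expect_true(is.na(sites["LIMBS"]))
  expect_equal(m335_admidas_distance(s, "B"), 2.9, tolerance = 1e-9)
})

test_that("gnm control compares full-length and truncated constructs", {
  s <- make_synthetic_ectodomain()
  ctrl <- gnm_control(list(sys = s), list(sys = c("A", "B", "C")),
                      cutoff = 10, sensitivity_cutoffs = c(9, 11))
  expect_true(ctrl$full_length > 0 && ctrl$full_length <= 1)
  expect_true(ctrl$truncated > 0 && ctrl$truncated <= 1)
  expect_equal(nrow(ctrl$sensitivity), 2L)
})

test_that("fetch_pdb validates accessions before touching the network", {
  expect_error(fetch_pdb("not-an-id"), "grepl")
})
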