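# Shared fixture builders. Everything is generated in code at test time.

# Calpha-only structure from a list of per-chain n x 3 coordinate matrices.
make_ca_structure <- function(coord_list, chains = LETTERS[seq_along(coord_list)]) {
  atoms <- do.call(rbind, lapply(seq_along(coord_list), function(k) {
    m <- coord_list[[k]]
    data.frame(elety = "CA", resid = "GLY", chain = chains[k],
               resno = seq_len(nrow(m)), x = m[, 1], y = m[, 2], z = m[, 3],
               het = FALSE, stringsAsFactors = FALSE)
  }))
  structure_model(atoms, title = "fixture")
}

# compact folded-chain coordinates: connected at a 10 A contact cutoff
chain_coords <- function(n, spacing = 1.8, offset = c(0, 0, 0)) {
  i <- seq_len(n)
  sweep(cbind((i - (n + 1) / 2) * spacing,
              0.6 * (-1)^i,
              0.4 * sin(i)), 2, offset, `+`)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion (random rotation + translation) to every frame
rigidly_move_frames <- function(traj, rot = NULL, shift = NULL) {
  out <- traj$xyz
  for (f in seq_len(nrow(out))) {
    R <- rot %||% random_rotation()
    s <- shift %||% rnorm(3, sd = 5)
    m <- matrix(out[f, ], ncol = 3, byrow = TRUE) %*% R
    out[f, ] <- as.numeric(t(sweep(m, 2, s, `+`)))
  }
  trajectory(traj$structure, out, replica = traj$replica)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Horn's quaternion method for the optimal proper rotation: the independent
# superposition oracle. Returns R with rowvec convention (P %*% R ~ Q).
quaternion_rotation <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P, Q)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  M <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  t(M)  # column-vector rotation -> row-vector convention
}

# independent brute-force GROMOS reference: literal restatement of the
# greedy neighbour-count procedure on a distance matrix
gromos_reference <- function(M, cutoff) {
  pool <- seq_len(nrow(M))
  assignment <- integer(nrow(M))
  k <- 0L
  while (length(pool)) {
    counts <- sapply(pool, function(i) sum(M[i, pool] <= cutoff) - 1L)
    center <- pool[which(counts == max(counts))[1]]
    members <- pool[M[center, pool] <= cutoff]
    k <- k + 1L
    assignment[members] <- k
    pool <- setdiff(pool, members)
  }
  assignment
}

# minimal hand-written PDB text
write_mini_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          altloc = " ", het = FALSE) {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          if (het) "HETATM" else "ATOM", serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resn, chain, resno, x, y, z)
}
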