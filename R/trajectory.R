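#' Trajectories
#'
#' A `trajectory` holds F coordinate frames over the fixed topology of a
#' reference [structure_model()]. Frames are stored as an F x 3N matrix in
#' the flat xyz layout (x1, y1, z1, x2, ...), always in Angstrom.
#'
#' @param structure reference `structure_model` (N atoms).
#' @param xyz F x 3N numeric matrix, Angstrom.
#' @param times optional per-frame times (ps).
#' @param replica replica label.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(structure, xyz, times = NULL, replica = "") {
  stopifnot(inherits(structure, "structure_model"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  n <- n_atoms(structure)
  if (ncol(xyz) != 3L * n)
    stop_fd("frame width %d does not match 3 x %d atoms", ncol(xyz), n)
  if (nrow(xyz) < 1L) stop_fd("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop_fd("non-finite coordinates in trajectory")
  if (!is.null(times) && length(times) != nrow(xyz))
    stop_fd("times length must equal the frame count")
  structure(list(structure = structure, xyz = xyz, times = times,
                 replica = as.character(replica)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s: %d frames x %d atoms\n",
              if (nzchar(x$replica)) paste0(" [", x$replica, "]") else "",
              n_frames(x), n_atoms(x$structure)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

as_trajectory_list <- function(trajs) {
  if (inherits(trajs, "trajectory")) list(trajs) else {
    stopifnot(all(vapply(trajs, inherits, TRUE, "trajectory")))
    trajs
  }
}

#' Read a trajectory from DCD or multi-model PDB
#'
#' Binary DCD (CHARMM/NAMD flavour, as read by bio3d) and multi-model PDB are
#' supported; there is no XTC reader in this package's R dependency stack, so
#' XTC inputs must be converted to DCD upstream. Units are normalised to
#' Angstrom. The atom count of every frame must match the reference
#' structure; a short final frame in a truncated file is reported with the
#' index of the last complete frame.
#'
#' @param structure reference `structure_model`.
#' @param file path to `.dcd` or multi-model `.pdb`.
#' @param replica replica label.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(structure, file, replica = "") {
  if (!file.exists(file)) stop_fd("no such file: %s", file)
  ext <- tolower(tools::file_ext(file))
  n <- n_atoms(structure)
  if (ext == "dcd") {
    hdr <- read_dcd_header(file)
    if (hdr$natoms != n)
      stop_fd("DCD has %d atoms but the structure has %d", hdr$natoms, n)
    xyz <- tryCatch(
      suppressWarnings(bio3d::read.dcd(file, verbose = FALSE)),
      error = function(e) stop_fd("failed to read '%s': %s", file, conditionMessage(e)))
    xyz <- unclass(xyz)
    if (hdr$nframes > 0 && nrow(xyz) < hdr$nframes)
      stop_fd("truncated DCD '%s': header promises %d frames, last good frame is %d",
              file, hdr$nframes, nrow(xyz))
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * n)
      stop_fd("multi-model PDB has %d atoms per model but the structure has %d",
              ncol(xyz) / 3, n)
  } else stop_fd("unsupported trajectory format '.%s' (use DCD or multi-model PDB)", ext)
  trajectory(structure, xyz, replica = replica)
}

#' Write a trajectory
#'
#' Multi-model PDB (plain text) or CHARMM-format DCD (binary). The DCD writer
#' emits the minimal fixed-header flavour that standard readers (including
#' the bio3d reader used by [read_trajectory()]) accept, so generated
#' fixtures can exercise the real binary reader round-trip.
#'
#' @param traj a `trajectory`.
#' @param file output path ending in `.pdb` or `.dcd`.
#' @export
write_trajectory <- function(traj, file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "pdb") {
    a <- traj$structure$atoms
    bio3d::write.pdb(file = file, xyz = traj$xyz,
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = a$chain, elesy = a$elesy)
  } else if (ext == "dcd") {
    write_dcd(traj$xyz, file)
  } else stop_fd("unsupported output format '.%s'", ext)
  invisible(file)
}

# --- minimal CHARMM DCD binary I/O ------------------------------------------

read_dcd_header <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  len <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (!identical(len, 84L)) {
    seek(con, 0); len <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (!identical(len, 84L)) stop_fd("'%s' does not look like a DCD file", file)
    endian <- "big"
  }
  magic <- readChar(con, 4, useBytes = TRUE)
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)  # closing record marker
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, tlen, origin = "current"); readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  natoms <- readBin(con, "integer", 1, size = 4, endian = endian)
  list(magic = magic, nframes = icntrl[1], natoms = natoms, endian = endian)
}

write_dcd <- function(xyz, file) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz); natoms <- ncol(xyz) / 3L
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record: "CORD" + 20 control ints (slot 10 is a float timestep;
  # slot 20 the CHARMM version stamp that marks the format flavour)
  wi(84L); writeChar("CORD", con, 4, eos = NULL)
  wi(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(1.0, con, size = 4, endian = "little")
  wi(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wi(84L)
  title <- sprintf("%-80s", "written by fluctdyn")
  wi(4L + 80L); wi(1L); writeChar(title, con, 80, eos = NULL); wi(4L + 80L)
  wi(4L); wi(natoms); wi(4L)
  ix <- seq(1L, 3L * natoms, by = 3L)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (off in 0:2) {
      wi(4L * natoms)
      writeBin(as.numeric(fr[ix + off]), con, size = 4, endian = "little")
      wi(4L * natoms)
    }
  }
  invisible(file)
}
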