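#' Structure models
#'
#' A `structure_model` is an ordered atom table with coordinates in Angstrom.
#' It is the reference topology for every trajectory-based analysis in the
#' package. Atom order is stable: selections are index lists into this table.
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name), `alt`,
#'   `resid` (residue name), `chain`, `resno` (author numbering), `insert`,
#'   `x`, `y`, `z` (Angstrom), `het` (logical, HETATM record), and optionally
#'   `elesy` (element symbol).
#' @param title free-text tag (e.g. a PDB accession).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_fd("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop_fd("structure has no atoms")
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(n)
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  co <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(co))) stop_fd("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    stop_fd("duplicate atom key (chain, resno, insert, name, altloc): %s",
            key[anyDuplicated(key)][1L])
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model%s: %d atoms (%d HETATM), %d residues, chains: %s\n",
              if (nzchar(x$title)) paste0(" [", x$title, "]") else "",
              nrow(a), sum(a$het),
              length(unique(paste(a$chain, a$resno, a$insert))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a structure model
#' @param structure a `structure_model`.
#' @return n x 3 matrix in Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

guess_element <- function(elety) {
  e <- toupper(trimws(elety))
  two <- e %in% c("MN", "MG", "ZN", "FE", "CA2", "NA", "CL", "BR")
  out <- substr(gsub("[0-9']", "", e), 1, 1)
  out[two] <- substr(e[two], 1, 2)
  out
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records with fixed-column semantics (via the bio3d
#' reader). The altloc policy keeps records with altloc 'A' or blank and logs
#' the number of dropped alternate-location records. Insertion codes are part
#' of the residue key; author residue numbering is kept throughout.
#'
#' @param file path to a PDB file.
#' @param title optional tag; defaults to the file name.
#' @param quiet suppress the dropped-altloc message.
#' @return a [structure_model()].
#' @export
read_structure <- function(file, title = NULL, quiet = FALSE) {
  if (!file.exists(file)) stop_fd("no such file: %s", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop_fd("no ATOM/HETATM records in %s", file)
  # fixed-column sanity scan so malformed records fail with a line number
  ln <- which(rec)
  for (i in ln) {
    l <- lines[i]
    if (nchar(l) < 54L)
      stop_fd("%s line %d: record shorter than the mandatory coordinate columns", file, i)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))))
    if (any(is.na(xyz)))
      stop_fd("%s line %d: unparseable coordinate field", file, i)
  }
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  if (!all(keep) && !quiet)
    message(sprintf("read_structure: dropped %d alternate-location record(s) (kept altloc 'A'/blank)",
                    sum(!keep)))
  a <- a[keep, , drop = FALSE]
  atoms <- data.frame(
    eleno = a$eleno, elety = a$elety, alt = alt[keep],
    resid = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    elesy = ifelse(is.na(a$elesy), guess_element(a$elety), a$elesy),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, title = title %||% basename(file))
}

#' Write a structure model to a PDB file
#' @param structure a `structure_model`.
#' @param file output path.
#' @export
write_structure <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = file, xyz = as_xyz_vector(coords(structure)),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = a$eleno, elety = a$elety,
    chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, NA),
    elesy = a$elesy
  )
  invisible(file)
}

#' Read / write compact coordinate tables
#'
#' CSV coordinate tables are a plain-text side format for shipping reduced
#' atom subsets (for example Calpha-only models) compactly. Columns: chain,
#' resno, insert, resid, elety, het, x, y, z.
#'
#' @param file path to a coordinate CSV.
#' @param title optional tag.
#' @return a [structure_model()].
#' @export
read_structure_csv <- function(file, title = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(chain = "character"))
  if (is.null(d$insert)) d$insert <- "" else d$insert[is.na(d$insert)] <- ""
  if (is.null(d$het)) d$het <- FALSE
  structure_model(d, title = title %||% basename(file))
}

#' @rdname read_structure_csv
#' @param structure a `structure_model`.
#' @param digits coordinate precision (decimal places).
#' @export
write_structure_csv <- function(structure, file, digits = 3) {
  a <- structure$atoms
  out <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                    resid = a$resid, elety = a$elety, het = a$het,
                    x = round(a$x, digits), y = round(a$y, digits),
                    z = round(a$z, digits))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Subset a structure model by atom indices
#' @param structure a `structure_model`.
#' @param indices atom indices (or a `selection`).
#' @export
subset_structure <- function(structure, indices) {
  if (inherits(indices, "selection")) indices <- indices$indices
  structure_model(structure$atoms[indices, , drop = FALSE], title = structure$title)
}

# residue-level labels "chain:resno" (insert appended when present)
residue_labels <- function(structure, indices = seq_len(n_atoms(structure))) {
  a <- structure$atoms[indices, , drop = FALSE]
  paste0(a$chain, ":", a$resno, ifelse(nzchar(a$insert), a$insert, ""))
}
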