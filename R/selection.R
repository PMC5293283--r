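#' Domain definitions
#'
#' A domain is a named set of inclusive author-numbered residue intervals on
#' one chain, e.g. the integrin hybrid domain (residues 55-108 and 353-434 of
#' the beta chain). Intervals must not overlap.
#'
#' @param name domain name.
#' @param chain chain identifier.
#' @param intervals a list of `c(from, to)` pairs (inclusive), or a single
#'   pair, or a 2-column matrix.
#' @return an object of class `domain_definition`.
#' @export
domain_definition <- function(name, chain, intervals) {
  if (is.numeric(intervals) && length(intervals) == 2L) intervals <- list(intervals)
  if (is.matrix(intervals)) intervals <- split(intervals, row(intervals)[, 1])
  intervals <- lapply(intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] > iv[2]) stop_fd("bad interval in domain '%s'", name)
    iv
  })
  o <- order(vapply(intervals, `[`, integer(1), 1L))
  intervals <- intervals[o]
  if (length(intervals) > 1L) {
    for (i in seq_len(length(intervals) - 1L))
      if (intervals[[i]][2] >= intervals[[i + 1L]][1])
        stop_fd("overlapping intervals in domain '%s'", name)
  }
  structure(list(name = name, chain = as.character(chain), intervals = intervals),
            class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  iv <- paste(vapply(x$intervals, function(i) paste(i, collapse = "-"), ""), collapse = ",")
  cat(sprintf("domain '%s': chain %s, resid %s\n", x$name, x$chain, iv))
  invisible(x)
}

domain_resnos <- function(domain) {
  unlist(lapply(domain$intervals, function(iv) iv[1]:iv[2]))
}

new_selection <- function(indices, provenance = "") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop_fd("selection indices must be unique")
  structure(list(indices = sort(indices), provenance = provenance),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection: %d atoms [%s]\n", length(x$indices), x$provenance))
  invisible(x)
}

#' @export
length.selection <- function(x) length(x$indices)

#' Resolve an atom selection on a structure
#'
#' Selections are expressed either as a [domain_definition()] or as a string
#' of clauses joined by `and`:
#' `"chain B and resid 55-108,353-434 and name CA"`. Supported clauses:
#' `chain <id>`, `resid <a>-<b>[,<c>-<d>,...]` (single residues allowed),
#' `name <atom name>`, `resname <residue name>`, `protein`, `hetero`.
#' Resolution is a pure function of (structure, expression) and returns a
#' deterministic ordered index list; an empty result is an error, since it
#' almost always signals a wrong chain id or numbering scheme.
#'
#' @param structure a `structure_model`.
#' @param expr selection string or `domain_definition`.
#' @param atom_filter optional extra atom-name filter applied after `expr`,
#'   e.g. `"CA"` for Calpha-only (the default used throughout the package's
#'   residue-level analyses is set by each caller, not here).
#' @return a `selection`.
#' @export
resolve_selection <- function(structure, expr, atom_filter = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (inherits(expr, "domain_definition")) {
    keep <- a$chain == expr$chain & a$resno %in% domain_resnos(expr)
    prov <- sprintf("domain %s", expr$name)
  } else if (is.character(expr) && length(expr) == 1L) {
    clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
    for (cl in clauses) {
      cl <- trimws(cl)
      if (cl == "") next
      if (cl == "protein") { keep <- keep & !a$het; next }
      if (cl == "hetero")  { keep <- keep & a$het;  next }
      parts <- strsplit(cl, "\\s+")[[1]]
      if (length(parts) < 2L) stop_fd("cannot parse selection clause '%s'", cl)
      key <- parts[1]; val <- paste(parts[-1], collapse = " ")
      keep <- keep & switch(
        key,
        chain = a$chain %in% strsplit(val, ",")[[1]],
        name = a$elety %in% strsplit(val, ",")[[1]],
        resname = a$resid %in% strsplit(val, ",")[[1]],
        resid = a$resno %in% parse_resid_ranges(val),
        stop_fd("unknown selection keyword '%s'", key)
      )
    }
    prov <- expr
  } else stop_fd("expr must be a selection string or a domain_definition")
  if (!is.null(atom_filter)) {
    keep <- keep & a$elety %in% atom_filter
    prov <- paste(prov, "and name", paste(atom_filter, collapse = ","))
  }
  idx <- which(keep)
  if (!length(idx))
    stop_fd("selection '%s' matches no atoms (wrong chain or numbering?)", prov)
  new_selection(idx, prov)
}

parse_resid_ranges <- function(val) {
  unlist(lapply(strsplit(val, ",")[[1]], function(tok) {
    tok <- trimws(tok)
    if (grepl("^-?\\d+--?\\d+$", tok)) {
      # a-b with possible negative bounds: split on the dash between digits
      m <- regmatches(tok, regexec("^(-?\\d+)-(-?\\d+)$", tok))[[1]]
      as.integer(m[2]):as.integer(m[3])
    } else as.integer(tok)
  }))
}

#' Resolve an atom by label
#'
#' Atom labels name single atoms as `"chain:resno:name"` (e.g. `"B:335:O"`
#' for a backbone carbonyl oxygen, `"B:9001:MN"` for a metal particle).
#' An insertion code may follow the residue number (`"A:100A:CA"`).
#'
#' @param structure a `structure_model`.
#' @param label atom label string.
#' @return single atom index.
#' @export
resolve_atom <- function(structure, label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop_fd("atom label must be 'chain:resno:name', got '%s'", label)
  a <- structure$atoms
  m <- regexec("^(-?\\d+)([A-Za-z]?)$", parts[2])[[1]]
  rm_ <- regmatches(parts[2], regexec("^(-?\\d+)([A-Za-z]?)$", parts[2]))[[1]]
  if (!length(rm_)) stop_fd("bad residue number in label '%s'", label)
  idx <- which(a$chain == parts[1] & a$resno == as.integer(rm_[2]) &
               a$insert == rm_[3] & a$elety == parts[3])
  if (length(idx) != 1L)
    stop_fd("label '%s' resolves to %d atoms (expected exactly 1)", label, length(idx))
  idx
}
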