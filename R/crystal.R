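#' Crystal-structure comparative analyses
#'
#' Helpers for the structure-level end of a comparative study: fetching
#' deposited PDB entries, the integrin ectodomain domain table, residue-paired
#' cross-structure RMSD, metal-site identification in the betaA domain, and
#' the GNM full-length-versus-truncated control.
#'
#' @name crystal_analyses
NULL

#' Fetch a PDB entry from the RCSB
#'
#' Downloads `<id>.pdb` into a cache directory and returns the local path.
#' Requires network access; downloaded files are reused on later calls.
#'
#' @param id 4-character PDB accession (e.g. `"4MMZ"`).
#' @param destdir download directory (default: a per-user cache).
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(id, destdir = tools::R_user_dir("fluctdyn", "cache")) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  dir.create(destdir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(destdir, paste0(toupper(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(dest)) {
      unlink(dest)
      stop_fd("could not download %s from the RCSB (network unavailable?)", id)
    }
  }
  dest
}

#' Integrin ectodomain domain definitions
#'
#' The canonical author-numbered domain table of the alphaV-beta3 ectodomain
#' head: beta-propeller (1-438) and thigh (439-599) on the alpha chain, betaA
#' (109-352) and hybrid (55-108, 353-434) on the beta chain, and optionally
#' the 10th fibronectin type-III repeat (1417-1507).
#'
#' @param alpha_chain,beta_chain,fn_chain chain identifiers in the structure
#'   at hand (`fn_chain = NULL` omits the fibronectin domain).
#' @return named list of [domain_definition()]s.
#' @export
integrin_domains <- function(alpha_chain = "A", beta_chain = "B", fn_chain = NULL) {
  out <- list(
    propeller = domain_definition("propeller", alpha_chain, c(1, 438)),
    thigh = domain_definition("thigh", alpha_chain, c(439, 599)),
    betaA = domain_definition("betaA", beta_chain, c(109, 352)),
    hybrid = domain_definition("hybrid", beta_chain, list(c(55, 108), c(353, 434)))
  )
  if (!is.null(fn_chain))
    out$fn10 <- domain_definition("fn10", fn_chain, c(1417, 1507))
  out
}

#' Calpha selection of the truncated simulation construct
#'
#' The upper-ectodomain construct: alpha chain residues 1-599 (propeller +
#' thigh), beta chain 55-434 (betaA + hybrid), and, when present, the
#' fibronectin repeat 1417-1507.
#'
#' @param structure a `structure_model`.
#' @inheritParams integrin_domains
#' @return a `selection` of Calpha atoms.
#' @export
md_construct_selection <- function(structure, alpha_chain = "A",
                                   beta_chain = "B", fn_chain = NULL) {
  a <- structure$atoms
  keep <- (a$chain == alpha_chain & a$resno >= 1 & a$resno <= 599) |
          (a$chain == beta_chain & a$resno >= 55 & a$resno <= 434)
  if (!is.null(fn_chain))
    keep <- keep | (a$chain == fn_chain & a$resno >= 1417 & a$resno <= 1507)
  keep <- keep & a$elety == "CA" & !a$het
  if (!any(keep)) stop_fd("construct selection matched no Calpha atoms")
  new_selection(which(keep), "MD construct Calpha")
}

#' Residue-paired Calpha RMSD between two structures
#'
#' Calpha atoms are paired across structures by (chain role, author residue
#' number, insertion code) intersection; residues present in only one
#' structure are dropped with a logged count. The paired sets are then
#' superposed (proper rotation) and the RMSD computed.
#'
#' @param a,b `structure_model`s.
#' @param chain_map_a,chain_map_b equal-length chain-id vectors giving the
#'   corresponding chains in `a` and `b` (role-wise, e.g.
#'   `c("A", "B")` vs `c("A", "B")`).
#' @param fit superpose before measuring (default TRUE).
#' @param quiet suppress the dropped-residue message.
#' @return list: `rmsd` (Angstrom), `rmsd_nm`, `n_paired`, `n_dropped`.
#' @export
paired_ca_rmsd <- function(a, b, chain_map_a, chain_map_b = chain_map_a,
                           fit = TRUE, quiet = FALSE) {
  stopifnot(length(chain_map_a) == length(chain_map_b))
  ca_table <- function(s, chains) {
    at <- s$atoms
    keep <- at$elety == "CA" & !at$het & at$chain %in% chains
    role <- match(at$chain[keep], chains)
    data.frame(idx = which(keep), key = paste(role, at$resno[keep], at$insert[keep]))
  }
  ta <- ca_table(a, chain_map_a); tb <- ca_table(b, chain_map_b)
  common <- intersect(ta$key, tb$key)
  if (length(common) < 3L) stop_fd("fewer than 3 paired Calpha atoms")
  dropped <- (nrow(ta) - length(common)) + (nrow(tb) - length(common))
  if (dropped > 0 && !quiet)
    message(sprintf("paired_ca_rmsd: %d unpaired Calpha residues dropped", dropped))
  ma <- coords(a)[ta$idx[match(common, ta$key)], , drop = FALSE]
  mb <- coords(b)[tb$idx[match(common, tb$key)], , drop = FALSE]
  r <- rmsd(ma, mb, fit = fit)
  list(rmsd = r, rmsd_nm = r / 10, n_paired = length(common), n_dropped = dropped)
}

#' Locate the betaA-domain metal sites
#'
#' Identifies the MIDAS, ADMIDAS and LIMBS divalent-metal positions among a
#' structure's metal HETATM records by proximity to their canonical
#' coordinating residues on the beta chain: the ADMIDAS ion sits on the
#' D126/D127 carboxylates, MIDAS on the S121/S123/E220 shell, LIMBS on
#' D158/N215/D217. The nearest metal to each coordinating-atom centroid is
#' reported.
#'
#' @param structure a `structure_model`.
#' @param beta_chain beta-subunit chain id.
#' @param elements metal element symbols to consider.
#' @return named integer vector of atom indices (NA when a site's metal is
#'   absent, e.g. apo structures crystallised without these ions).
#' @export
find_metal_sites <- function(structure, beta_chain = "B",
                             elements = c("MN", "MG", "CA")) {
  a <- structure$atoms
  met <- which(a$het & toupper(a$elesy) %in% elements)
  shells <- list(
    MIDAS = list(resno = c(121, 123, 220), elety = c("OG", "OG", "OE1", "OE2")),
    ADMIDAS = list(resno = c(126, 127), elety = c("OD1", "OD2")),
    LIMBS = list(resno = c(158, 215, 217), elety = c("OD1", "OD2", "OD1"))
  )
  out <- stats::setNames(rep(NA_integer_, length(shells)), names(shells))
  if (!length(met)) return(out)
  m <- coords(structure)
  for (s in names(shells)) {
    co <- which(a$chain == beta_chain & a$resno %in% shells[[s]]$resno &
                a$elety %in% c("OD1", "OD2", "OE1", "OE2", "OG", "OG1", "O"))
    if (!length(co)) next
    ctr <- colMeans(m[co, , drop = FALSE])
    d <- sqrt(rowSums(sweep(m[met, , drop = FALSE], 2, ctr)^2))
    if (min(d) < 6) out[s] <- met[which.min(d)]
  }
  out
}

#' Carbonyl-oxygen to ADMIDAS metal distance
#'
#' The distance between the backbone carbonyl oxygen of beta-chain residue
#' `resno` (default 335, the beta6-alpha7 loop methionine) and the ADMIDAS
#' metal — a structural reporter of the closed-to-open transition of the
#' betaA domain.
#'
#' @param structure a `structure_model` with metal ions present.
#' @param beta_chain beta-subunit chain id.
#' @param resno reporter residue number.
#' @return distance in Angstrom.
#' @export
m335_admidas_distance <- function(structure, beta_chain = "B", resno = 335) {
  sites <- find_metal_sites(structure, beta_chain)
  if (is.na(sites["ADMIDAS"])) stop_fd("no ADMIDAS metal found")
  io <- resolve_atom(structure, sprintf("%s:%d:O", beta_chain, resno))
  m <- coords(structure)
  vec_norm(m[io, ] - m[sites["ADMIDAS"], ])
}

#' GNM control: full-length versus truncated models
#'
#' For each supplied structure, computes the mean collectivity of the two
#' slowest non-zero GNM modes on (a) the complete crystal Calpha set and
#' (b) the truncated simulation construct ([md_construct_selection()]), and
#' averages each across structures. A cutoff-sensitivity table accompanies
#' the point estimates, since the collectivity of slow modes depends on the
#' contact cutoff.
#'
#' @param structures named list of `structure_model`s (e.g. the two
#'   liganded complexes).
#' @param chain_maps list (same names) of `c(alpha, beta, fn)` chain ids;
#'   `fn` may be NA for structures without the ligand chain.
#' @param cutoff contact cutoff, Angstrom.
#' @param sensitivity_cutoffs cutoffs for the sensitivity table.
#' @return list: `full_length`, `truncated` (mean collectivities),
#'   `per_structure` data.frame, `sensitivity` data.frame.
#' @export
gnm_control <- function(structures, chain_maps, cutoff = 10,
                        sensitivity_cutoffs = 7:13) {
  stopifnot(length(structures) == length(chain_maps))
  rows <- list(); sens <- list()
  for (nm in names(structures)) {
    s <- structures[[nm]]
    cm <- chain_maps[[nm]]
    full_sel <- resolve_selection(s, "protein", atom_filter = "CA")
    trunc_sel <- md_construct_selection(s, cm[1], cm[2],
                                        if (length(cm) > 2 && !is.na(cm[3])) cm[3] else NULL)
    kf <- slow_mode_summary(gnm_modes(s, full_sel, cutoff))$mean_collectivity
    kt <- slow_mode_summary(gnm_modes(s, trunc_sel, cutoff))$mean_collectivity
    rows[[nm]] <- data.frame(structure = nm, full_length = kf, truncated = kt)
    st_full <- gnm_cutoff_sensitivity(s, full_sel, sensitivity_cutoffs)
    st_trunc <- gnm_cutoff_sensitivity(s, trunc_sel, sensitivity_cutoffs)
    sens[[nm]] <- data.frame(structure = nm, cutoff = st_full$cutoff,
                             full_length = st_full$mean_collectivity,
                             truncated = st_trunc$mean_collectivity)
  }
  per <- do.call(rbind, rows)
  list(full_length = mean(per$full_length), truncated = mean(per$truncated),
       per_structure = per, sensitivity = do.call(rbind, sens))
}
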