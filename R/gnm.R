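#' Gaussian network model slow modes and collectivity
#'
#' The GNM places a node at each selected atom (conventionally Calpha) and
#' connects nodes within a distance cutoff with uniform unit springs. The
#' Kirchhoff (connectivity Laplacian) matrix has Gamma_ij = -1 for contacts,
#' diagonal = node degree, row sums zero; for a connected contact graph it
#' has exactly one zero eigenvalue, and the smallest non-zero modes
#' approximate the protein's slowest collective motions. It is the standard
#' control for checking that a truncated simulation construct preserves the
#' collective dynamics of the full-length structure.
#'
#' @param structure a `structure_model`.
#' @param selection a `selection` (or index vector), typically Calpha.
#' @param cutoff contact cutoff, Angstrom (default 10).
#' @return class `gnm_result`: `kirchhoff`, `values` (ascending),
#'   `vectors`, `labels`, `cutoff`, `zero_mode` (index of the null mode).
#'   Disconnected contact graphs are an error naming the component sizes.
#' @export
gnm_modes <- function(structure, selection = NULL, cutoff = 10) {
  idx <- selection_indices(selection, structure)
  m <- coords(structure)[idx, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop_fd("GNM needs at least 2 nodes")
  D <- as.matrix(dist(m))
  A <- (D <= cutoff)
  diag(A) <- FALSE
  comp <- graph_components(A)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop_fd("contact graph is disconnected at cutoff %.1f A: %d components of sizes %s",
            cutoff, length(sizes), paste(sizes, collapse = ", "))
  }
  K <- -1 * A
  diag(K) <- rowSums(A)
  e <- eigen(K, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(kirchhoff = K, values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 labels = residue_labels(structure, idx),
                 cutoff = cutoff, zero_mode = 1L),
            class = "gnm_result")
}

graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.gnm_result <- function(x, ...) {
  nz <- slow_mode_indices(x, 2)
  cat(sprintf("gnm_result: %d nodes, cutoff %.1f A; slowest non-zero eigenvalues %.4f, %.4f; collectivity %.3f, %.3f\n",
              nrow(x$kirchhoff), x$cutoff, x$values[nz[1]], x$values[nz[2]],
              collectivity(x$vectors[, nz[1]]), collectivity(x$vectors[, nz[2]])))
  invisible(x)
}

# indices of the n slowest non-zero modes (the single null mode excluded)
slow_mode_indices <- function(gnm, n = 2) {
  tol <- max(abs(gnm$values)) * 1e-9
  nz <- which(gnm$values > tol)
  utils::head(nz, n)
}

#' Mode collectivity
#'
#' The entropy-based (Brueschweiler) measure of how many nodes a mode
#' engages:
#' \deqn{\kappa = \frac{1}{N}\exp\left(-\sum_i p_i \ln p_i\right),\quad
#'       p_i = u_i^2 / \sum_j u_j^2.}
#' 1 for a fully collective (uniform-magnitude) mode, 1/N for a mode
#' localised on one node.
#'
#' @param mode eigenvector (non-zero).
#' @return collectivity in `(0, 1]`.
#' @export
collectivity <- function(mode) {
  u2 <- as.numeric(mode)^2
  s <- sum(u2)
  if (s == 0) stop_fd("zero mode vector")
  p <- u2 / s
  p <- p[p > 0]
  exp(-sum(p * log(p))) / length(u2)
}

#' Per-domain contribution to GNM modes
#'
#' The fraction of a (normalised) mode's weight carried by each domain:
#' `sum over domain nodes of u_i^2`. Over a full disjoint partition of the
#' nodes the fractions of each mode sum to 1. Domains must resolve to
#' disjoint node sets.
#'
#' @param gnm a `gnm_result`.
#' @param domains named list of node-index vectors (into the GNM node set),
#'   or of `domain_definition`s resolved against `structure`.
#' @param modes mode indices (into the ascending-eigenvalue order).
#' @param structure needed only when `domains` are `domain_definition`s.
#' @return matrix domains x modes of fractions.
#' @export
domain_mode_contribution <- function(gnm, domains, modes = NULL, structure = NULL) {
  stopifnot(inherits(gnm, "gnm_result"))
  if (is.null(modes)) modes <- slow_mode_indices(gnm, 2)
  doms <- lapply(domains, function(d) {
    if (inherits(d, "domain_definition")) {
      if (is.null(structure)) stop_fd("structure needed to resolve domain definitions")
      match(which(structure$atoms$chain == d$chain &
                  structure$atoms$resno %in% domain_resnos(d) &
                  structure$atoms$elety == "CA"),
            selection_indices(NULL, structure))
    } else as.integer(d)
  })
  allidx <- unlist(doms)
  if (anyDuplicated(allidx)) stop_fd("domains must cover disjoint node sets")
  out <- vapply(modes, function(k) {
    u2 <- gnm$vectors[, k]^2
    u2 <- u2 / sum(u2)
    vapply(doms, function(d) sum(u2[d]), 0)
  }, numeric(length(doms)))
  out <- matrix(out, nrow = length(doms),
                dimnames = list(names(domains), paste0("mode", modes)))
  out
}

#' Slow-mode summary of a GNM
#'
#' Mean collectivity of the `n` slowest non-zero modes and their cumulative
#' contribution to the overall mobility, measured as their share of
#' `sum_k 1/lambda_k` over all non-zero modes (the GNM pseudo-inverse
#' fluctuation weight).
#'
#' @param gnm a `gnm_result`.
#' @param n number of slow modes (default 2).
#' @return list with `mean_collectivity`, `collectivity` (per mode),
#'   `eigenvalues`, `mobility_fraction`.
#' @export
slow_mode_summary <- function(gnm, n = 2) {
  nz <- slow_mode_indices(gnm, Inf)
  sel <- utils::head(nz, n)
  kappa <- vapply(sel, function(k) collectivity(gnm$vectors[, k]), 0)
  inv <- 1 / gnm$values[nz]
  list(mean_collectivity = mean(kappa), collectivity = kappa,
       eigenvalues = gnm$values[sel],
       mobility_fraction = sum(1 / gnm$values[sel]) / sum(inv))
}

#' Cutoff sensitivity of GNM slow-mode collectivity
#'
#' Recomputes the slow-mode summary across a cutoff range (default 7-13
#' Angstrom); cutoffs whose contact graph is disconnected are reported as NA.
#'
#' @param structure a `structure_model`.
#' @param selection a `selection`.
#' @param cutoffs numeric vector of cutoffs (Angstrom).
#' @param n number of slow modes.
#' @return data.frame: cutoff, mean_collectivity, mobility_fraction.
#' @export
gnm_cutoff_sensitivity <- function(structure, selection = NULL,
                                   cutoffs = 7:13, n = 2) {
  rows <- lapply(cutoffs, function(cf) {
    res <- tryCatch(slow_mode_summary(gnm_modes(structure, selection, cf), n),
                    error = function(e) NULL)
    data.frame(cutoff = cf,
               mean_collectivity = res$mean_collectivity %||% NA_real_,
               mobility_fraction = res$mobility_fraction %||% NA_real_)
  })
  do.call(rbind, rows)
}

#' Export GNM results
#'
#' Mode table CSV (eigenvalue, collectivity, optional per-domain fractions)
#' and the Kirchhoff matrix as a sparse triplet TSV.
#'
#' @param gnm a `gnm_result`.
#' @param mode_csv,kirchhoff_tsv output paths (NULL skips).
#' @param n_modes number of non-zero modes in the table.
#' @param domains optional named list of node-index vectors.
#' @export
write_gnm_result <- function(gnm, mode_csv = NULL, kirchhoff_tsv = NULL,
                             n_modes = 10, domains = NULL) {
  if (!is.null(mode_csv)) {
    sel <- slow_mode_indices(gnm, n_modes)
    tab <- data.frame(mode = sel, eigenvalue = gnm$values[sel],
                      collectivity = vapply(sel, function(k) collectivity(gnm$vectors[, k]), 0))
    if (!is.null(domains)) {
      fr <- t(domain_mode_contribution(gnm, domains, modes = sel))
      tab <- cbind(tab, fr)
    }
    utils::write.csv(tab, mode_csv, row.names = FALSE)
  }
  if (!is.null(kirchhoff_tsv)) {
    nzi <- which(gnm$kirchhoff != 0, arr.ind = TRUE)
    nzi <- nzi[nzi[, 1] <= nzi[, 2], , drop = FALSE]
    utils::write.table(data.frame(i = nzi[, 1], j = nzi[, 2],
                                  value = gnm$kirchhoff[nzi]),
                       kirchhoff_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(gnm)
}
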