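#' Comparative pipeline over multiple systems and replicas
#'
#' Orchestrates the full analysis battery — distance fluctuations, RMSF,
#' essential dynamics with sampling diagnostics, generalized correlation,
#' scalar descriptors with histograms, stacking geometry, contact occupancy,
#' conformational clustering, GNM — over a set of systems with one or more
#' replica trajectories each, writes per-system outputs plus cross-system
#' deltas, and records a machine-readable manifest. Outputs are a pure
#' function of (config, input files, seed) for all deterministic stages; the
#' seed only feeds the duplicate-frame jitter fallback of the mutual
#' information estimator.
#'
#' @param config a `run_config` (see [run_config()]) or a YAML path.
#' @param out_dir output directory (created; default from the config).
#' @param seed RNG seed for the stochastic fallbacks.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 0, verbose = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$output %||% "fluctdyn-out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(as.integer(seed))
  an <- cfg$analysis
  df_list <- list()
  stage <- function(name, sysname, expr) {
    tryCatch(expr, error = function(e)
      stop_fd("pipeline stage '%s' failed for system '%s': %s (partial outputs retained in %s)",
              name, sysname, conditionMessage(e), out_dir))
  }
  for (nm in names(cfg$systems)) {
    sys <- cfg$systems[[nm]]
    dirn <- file.path(out_dir, nm)
    dir.create(dirn, showWarnings = FALSE)
    say("[%s] loading %d replica(s)", nm, length(sys[["trajectories"]]))
    st <- sys[["structure"]]
    sel <- resolve_selection(st, an[["selection"]] %||% "protein", atom_filter = "CA")
    trajs <- lapply(seq_along(sys[["trajectories"]]), function(i)
      read_trajectory(st, sys[["trajectories"]][[i]], replica = sprintf("r%d", i)))
    ref <- sys[["reference"]] %||% st
    trajs <- lapply(trajs, superpose_trajectory, reference = ref, fit_selection = sel)
    if (isTRUE(an[["df"]] %||% TRUE)) stage("df", nm, {
      say("[%s] distance fluctuations", nm)
      dfm <- df_matrix(trajs, sel)
      write_df_matrix(dfm, file.path(dirn, "df.tsv"), file.path(dirn, "df_long.csv"))
      df_list[[nm]] <- dfm
      rp <- rmsf_profile(trajs, sel)
      utils::write.csv(data.frame(label = rp$labels, rmsf = rp$rmsf, sd = rp$sd),
                       file.path(dirn, "rmsf.csv"), row.names = FALSE)
    })
    if (isTRUE(an[["ed"]] %||% TRUE)) stage("ed", nm, {
      say("[%s] essential dynamics", nm)
      ed <- fit_pca(trajs, sel)
      utils::write.csv(data.frame(mode = seq_along(ed$values), eigenvalue = ed$values,
                                  variance_fraction = ed$variance_fraction),
                       file.path(dirn, "ed_eigenvalues.csv"), row.names = FALSE)
      pr <- as.data.frame(ed$projections)
      names(pr) <- paste0("mode", seq_len(ncol(pr)))
      pr <- cbind(frame = seq_len(nrow(pr)), replica = ed$frame_replica, pr)
      utils::write.csv(pr, file.path(dirn, "ed_projections.csv"), row.names = FALSE)
      diag <- sampling_diagnostics(trajs, sel)
      jsonlite::write_json(diag$per_replica, file.path(dirn, "ed_diagnostics.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    })
    if (isTRUE(an[["lmi"]] %||% FALSE)) stage("lmi", nm, {
      say("[%s] generalized correlation (k = %d)", nm, an[["lmi_k"]] %||% 6)
      lmi <- generalized_correlation_matrix(trajs, sel, k = an[["lmi_k"]] %||% 6,
                                            stride = an[["lmi_stride"]])
      write_lmi_matrix(lmi, file.path(dirn, "lmi.tsv"), file.path(dirn, "lmi_long.csv"))
    })
    if (isTRUE(an[["geometry"]] %||% TRUE)) stage("geometry", nm, {
      say("[%s] descriptors", nm)
      series <- list()
      for (tr in trajs) series[[length(series) + 1L]] <- radius_of_gyration(tr, sel)
      write_series(series, file.path(dirn, "rg.csv"), file.path(dirn, "rg_hist.csv"))
      for (pair_name in names(sys[["tagged_pairs"]] %||% list())) {
        p <- sys[["tagged_pairs"]][[pair_name]]
        series <- lapply(trajs, pair_distance_series, atom_a = p[1], atom_b = p[2])
        write_series(series, file.path(dirn, paste0(pair_name, ".csv")),
                     file.path(dirn, paste0(pair_name, "_hist.csv")))
      }
      if (!is.null(sys[["torsion_domains"]])) {
        da <- resolve_selection(st, sys[["torsion_domains"]][[1]], atom_filter = "CA")
        db <- resolve_selection(st, sys[["torsion_domains"]][[2]], atom_filter = "CA")
        series <- lapply(trajs, interdomain_torsion_series, domain_a = da, domain_b = db)
        write_series(series, file.path(dirn, "torsion.csv"),
                     file.path(dirn, "torsion_hist.csv"))
      }
    })
    if (!is.null(sys[["aromatic_pairs"]])) stage("stacking", nm, {
      say("[%s] stacking geometry", nm)
      rows <- list()
      for (ap in sys[["aromatic_pairs"]]) for (tr in trajs) {
        sg <- stacking_series(tr, ap[1], ap[2])
        rows[[length(rows) + 1L]] <-
          data.frame(pair = paste(ap, collapse = "-"), replica = tr$replica,
                     frame = seq_along(sg$distance), distance = sg$distance,
                     theta = sg$theta, paired = sg$paired, stacked = sg$stacked)
      }
      utils::write.csv(do.call(rbind, rows), file.path(dirn, "stacking.csv"),
                       row.names = FALSE)
    })
    if (!is.null(sys[["contact_groups"]])) stage("contacts", nm, {
      say("[%s] contact occupancy", nm)
      ga <- resolve_selection(st, sys[["contact_groups"]][[1]])
      gb <- resolve_selection(st, sys[["contact_groups"]][[2]])
      occ <- hbond_saltbridge_occupancy(trajs, group_a = ga, group_b = gb,
                                        min_occupancy = an[["min_occupancy"]] %||% 1)
      utils::write.table(occ, file.path(dirn, "contacts.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    })
    if (!is.null(sys[["cluster_region"]])) stage("cluster", nm, {
      say("[%s] conformational clustering", nm)
      reg <- resolve_selection(st, sys[["cluster_region"]])
      for (i in seq_along(trajs)) {
        cl <- gromos_cluster(trajs[[i]], reg,
                             cutoff = an[["cluster_cutoff"]] %||% 2.0,
                             stride = an[["cluster_stride"]] %||% 1L)
        write_cluster_result(cl, trajs[[i]],
                             assignments_csv = file.path(dirn, sprintf("clusters_r%d.csv", i)),
                             summary_json = file.path(dirn, sprintf("clusters_r%d.json", i)),
                             centers_pdb = file.path(dirn, sprintf("cluster_centers_r%d.pdb", i)))
      }
    })
    if (isTRUE(an[["gnm"]] %||% TRUE)) stage("gnm", nm, {
      say("[%s] GNM", nm)
      g <- gnm_modes(st, sel, cutoff = an[["gnm_cutoff"]] %||% 10)
      write_gnm_result(g, mode_csv = file.path(dirn, "gnm_modes.csv"),
                       kirchhoff_tsv = file.path(dirn, "gnm_kirchhoff.tsv"))
    })
  }
  # cross-system deltas
  if (length(df_list) > 1L) {
    nms <- names(df_list)
    for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
      ok <- identical(df_list[[i]]$labels, df_list[[j]]$labels)
      if (!ok) next
      d <- df_difference(df_list[[nms[i]]], df_list[[nms[j]]])
      utils::write.table(d, file.path(out_dir, sprintf("df_delta_%s_vs_%s.tsv", nms[i], nms[j])),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  manifest <- list(
    package = "fluctdyn",
    version = as.character(utils::packageVersion("fluctdyn")),
    seed = seed,
    analysis = an,
    systems = lapply(cfg$systems, function(s)
      list(topology = s$topology,
           trajectories = as.list(s$trajectories),
           file_md5 = as.list(tools::md5sum(unlist(c(s$topology, s$trajectories)))))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(manifest)
}

write_series <- function(series_list, csv, hist_csv = NULL) {
  rows <- do.call(rbind, lapply(series_list, function(s)
    data.frame(replica = s$replica, frame = seq_along(s$values),
               value = s$values, unit = s$unit)))
  utils::write.csv(rows, csv, row.names = FALSE)
  if (!is.null(hist_csv))
    utils::write.csv(descriptor_histogram(rows$value), hist_csv, row.names = FALSE)
  invisible(csv)
}

#' Load and validate a run configuration
#'
#' The configuration is a YAML document (or an equivalent nested list):
#'
#' ```yaml
#' output: results
#' systems:
#'   wt:
#'     topology: wt.pdb          # reference structure (.pdb or .csv table)
#'     trajectories: [wt_r1.dcd, wt_r2.dcd]
#'     tagged_pairs:
#'       m335_admidas: ["B:335:O", "B:9001:MN"]
#'     aromatic_pairs: [["B:122", "C:1496"]]
#'     torsion_domains: ["chain B", "chain C"]
#'     contact_groups: ["chain C", "chain A,B"]
#'     cluster_region: "chain B and resid 124-131"
#' analysis:
#'   selection: protein
#'   lmi: false
#'   gnm_cutoff: 10
#'   cluster_cutoff: 2.0
#' ```
#'
#' Validation is fail-fast: every referenced file, selection and atom label
#' is resolved against its topology before any analysis starts. Relative
#' paths are resolved against the config file's directory.
#'
#' @param config YAML path or nested list.
#' @return a validated `run_config` object.
#' @export
run_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_fd("no such config file: %s", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), is.list(config$systems), length(config$systems) >= 1L)
  rp <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  systems <- lapply(names(config$systems), function(nm) {
    s <- config$systems[[nm]]
    if (is.null(s$topology)) stop_fd("system '%s': no topology", nm)
    s$topology <- rp(s$topology)
    if (!file.exists(s$topology)) stop_fd("system '%s': missing topology %s", nm, s$topology)
    s$structure <- if (grepl("\\.csv$", s$topology)) read_structure_csv(s$topology)
                   else read_structure(s$topology, quiet = TRUE)
    s$trajectories <- vapply(s$trajectories %||% list(), rp, "")
    if (!length(s$trajectories)) stop_fd("system '%s': no trajectories", nm)
    missing <- s$trajectories[!file.exists(s$trajectories)]
    if (length(missing)) stop_fd("system '%s': missing trajectory %s", nm, missing[1])
    for (p in s$tagged_pairs %||% list())
      for (lab in p) resolve_atom(s$structure, lab)
    for (ap in s$aromatic_pairs %||% list())
      for (r in ap) ring_atom_indices(s$structure, r)
    for (ts in s$torsion_domains %||% list())
      resolve_selection(s$structure, ts, atom_filter = "CA")
    if (!is.null(s$cluster_region)) resolve_selection(s$structure, s$cluster_region)
    s
  })
  names(systems) <- names(config$systems)
  structure(list(systems = systems, analysis = config$analysis %||% list(),
                 output = config$output),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %d system(s): %s\n", length(x$systems),
              paste(names(x$systems), collapse = ", ")))
  invisible(x)
}
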