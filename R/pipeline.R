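#' Configuration for a full ensemble analysis
#'
#' Validated bundle of every stage's parameters; a run's configuration is
#' echoed into its report (and serialized to JSON when an output directory is
#' given) for provenance.
#'
#' @param pca_selection atom selection for the PCA (`"ca"` or `"all"`).
#' @param mass_weighted mass-weight the covariance matrix.
#' @param n_vectors eigenvectors to retain in exports.
#' @param fel_bins histogram bins per FEL axis (each >= 2).
#' @param temperature_K temperature for `kT`, K.
#' @param min_depth_kT basin depth threshold in units of kT.
#' @param min_population basin population fraction below which it is minor.
#' @param cluster_cutoffs Gromos RMSD cutoffs for the disorder profile, nm.
#' @param cluster_selection atom selection for clustering RMSDs.
#' @param msd_scale order-parameter reference `<D^2>`, nm^2.
#' @param interaction_classes interaction classes analyzed per basin.
#' @param persistence_threshold edge threshold of the interaction graphs.
#' @param hub_min_degree hub degree threshold.
#' @param sas_probe SAS probe radius, nm.
#' @param sas_n_points SAS quadrature points per atom.
#' @param sas_max_frames_per_basin SAS frames evaluated per basin (evenly
#'   subsampled for tractability).
#' @param analyze_minor_basins run per-basin analyses on minor basins too.
#' @param seed seed echoed for provenance (analysis itself is deterministic).
#' @param output_dir optional directory for delimited-text exports.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(pca_selection = "ca", mass_weighted = FALSE,
                            n_vectors = 10, fel_bins = c(32, 32),
                            temperature_K = 300, min_depth_kT = 1,
                            min_population = 0.02,
                            cluster_cutoffs = c(0.3, 0.4, 0.5),
                            cluster_selection = "mainchain",
                            msd_scale = 0.27,
                            interaction_classes = "salt_bridge",
                            persistence_threshold = 0.2, hub_min_degree = 3,
                            sas_probe = 0.14, sas_n_points = 240,
                            sas_max_frames_per_basin = 30,
                            analyze_minor_basins = FALSE,
                            seed = 1, output_dir = NULL) {
  fel_bins <- rep_len(as.integer(fel_bins), 2)
  if (any(fel_bins < 2)) stop("fel_bins must be >= 2 per axis")
  if (temperature_K <= 0) stop("temperature_K must be positive")
  if (any(cluster_cutoffs <= 0)) stop("cluster_cutoffs must be positive")
  if (msd_scale <= 0) stop("msd_scale must be positive")
  if (min_population < 0 || min_population > 1)
    stop("min_population must lie in [0, 1]")
  if (persistence_threshold < 0 || persistence_threshold > 1)
    stop("persistence_threshold must lie in [0, 1]")
  if (sas_n_points < 10) stop("sas_n_points too small")
  if (!all(interaction_classes %in%
           c("salt_bridge", "aromatic", "amino_aromatic", "hydrophobic")))
    stop("unknown interaction class")
  structure(as.list(environment()), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in setdiff(names(x), "output_dir"))
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Run the full ensemble-characterization pipeline
#'
#' Orchestrates every stage on one ensemble: superposition, essential-dynamics
#' PCA, projection on the first two PCs, free-energy-landscape estimation and
#' basin decomposition, the cluster/order-parameter disorder profile,
#' secondary-structure and SAS profiling, the per-basin structure report, and
#' per-basin interaction networks with hubs and connected components. The run
#' is deterministic given the ensemble and configuration; per-stage wall
#' times and parameters are logged.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param config an [analysis_config()].
#' @return an object of class `idpens_report` (a list of every stage's
#'   result, the configuration echo and the stage log). If
#'   `config$output_dir` is set, delimited-text tables and a JSON summary are
#'   written there as a side effect.
#' @export
run_full_analysis <- function(ensemble, config = analysis_config()) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(config, "analysis_config"))
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  ens <- stage("superpose", superpose_ensemble(ensemble, "ca", "mean"))
  eig <- stage("pca", fit_pca(ens, config$pca_selection,
                              config$mass_weighted))
  proj <- stage("project", project_frames(ens, eig, k = 2))
  fes <- stage("fel", estimate_fel(proj$values[, 1], proj$values[, 2],
                                   bins = config$fel_bins,
                                   temperature_K = config$temperature_K,
                                   coord_names = c("PC1", "PC2")))
  basins <- stage("basins", detect_basins(
    fes, min_depth = config$min_depth_kT * fes$kT,
    min_population = config$min_population))
  basin_frames <- stage("assign", assign_frames_to_basins(
    fes, basins, proj$values[, 1], proj$values[, 2]))
  disorder <- stage("disorder_profile", disorder_profile(
    ens, config$cluster_cutoffs, config$cluster_selection, config$msd_scale))
  ss <- stage("secondary_structure", assign_secondary_structure(ens))

  analyzed <- vapply(basins$basins, function(b)
    config$analyze_minor_basins || !b$minor, TRUE)
  sas_frames <- sort(unique(unlist(lapply(basins$basins[analyzed], function(b) {
    fr <- which(basin_frames == b$label)
    fr[unique(round(seq(1, length(fr),
                        length.out = min(length(fr),
                                         config$sas_max_frames_per_basin))))]
  }))))
  sas <- stage("sas", shrake_rupley_sas(ens, config$sas_probe,
                                        config$sas_n_points,
                                        frames = sas_frames))
  report_labels <- basin_frames
  report_labels[!(basin_frames %in%
                    vapply(basins$basins[analyzed], `[[`, "", "label"))] <- NA
  basin_report <- stage("basin_report",
                        basin_structure_report(report_labels, ss, sas))

  networks <- stage("networks", {
    out <- list()
    for (b in basins$basins[analyzed]) {
      fr <- which(basin_frames == b$label)
      if (length(fr) == 0) next
      per_class <- list()
      for (cl in config$interaction_classes) {
        pm <- contact_persistence(ens, cl, frames = fr)
        g <- build_interaction_graph(pm, config$persistence_threshold)
        per_class[[cl]] <- list(
          persistence = pm,
          hubs = find_hubs(g, config$hub_min_degree),
          components = connected_components(g),
          n_edges = igraph::ecount(g))
      }
      out[[b$label]] <- per_class
    }
    out
  })

  report <- structure(list(config = config, pca = eig, projections = proj,
                           fel = fes, basins = basins,
                           basin_frames = basin_frames,
                           disorder_profile = disorder, ss = ss, sas = sas,
                           basin_report = basin_report, networks = networks,
                           log = do.call(rbind, log)),
                      class = "idpens_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.idpens_report <- function(x, ...) {
  cat("Ensemble analysis report\n")
  cat(sprintf("  frames: %d   basins: %d (%d analyzed)\n",
              length(x$basin_frames), length(x$basins$basins),
              length(x$networks)))
  cat("  disorder profile:\n")
  print(x$disorder_profile, row.names = FALSE)
  cat("  per-basin structure:\n")
  print(x$basin_report[, c("basin", "n_frames", "total_helical_pct",
                           "sas_mean")], row.names = FALSE)
  hubs <- vapply(x$networks, function(nb)
    length(unique(unlist(lapply(nb, `[[`, "hubs")))), 1L)
  if (length(hubs))
    cat("  hub residues per basin:",
        paste(sprintf("%s:%d", names(hubs), hubs), collapse = "  "), "\n")
  invisible(x)
}

# delimited-text + JSON export of a report bundle
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$disorder_profile, "disorder_profile.tsv")
  w(report$basin_report, "basin_report.tsv")
  w(data.frame(frame = seq_along(report$basin_frames),
               basin = report$basin_frames,
               PC1 = report$projections$values[, 1],
               PC2 = report$projections$values[, 2]),
    "projections.tsv")
  w(data.frame(pc = seq_along(report$pca$eigenvalues),
               eigenvalue = report$pca$eigenvalues),
    "eigenvalues.tsv")
  for (lab in names(report$networks)) {
    for (cl in names(report$networks[[lab]])) {
      pm <- report$networks[[lab]][[cl]]$persistence
      utils::write.table(pm$matrix,
                         file.path(dir, sprintf("persistence_%s_%s.tsv", lab, cl)),
                         sep = "\t", quote = FALSE)
    }
  }
  cfg <- report$config
  cfg$output_dir <- NULL
  summary <- list(
    config = unclass(cfg),
    n_basins = length(report$basins$basins),
    basin_populations = stats::setNames(
      lapply(report$basins$basins, `[[`, "population"),
      vapply(report$basins$basins, `[[`, "", "label")),
    hubs = lapply(report$networks, function(nb)
      lapply(nb, `[[`, "hubs")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
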