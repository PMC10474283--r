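# Workflow commands tying the stages together:
# ensemble -> CVs -> free-energy landscape -> clusters -> central structures
# -> modes/PCA/overlap -> contacts/occupancy. Each command reads a flat
# configuration (YAML file or list), writes TSV/PDB/DX outputs plus a run
# manifest into an output directory, and is deterministic given
# (input, config, seed).

#' Build a run configuration
#'
#' Flat key-value configuration with the analysis defaults: 120 bins and
#' 310 K for the landscape, 4.0 A GROMOS cutoff, 3.5 A contact cutoff,
#' 1.0 A occupancy grid spacing with 0.44 isovalue. Values from a YAML file
#' and explicit arguments override the defaults (arguments win).
#'
#' @param path optional YAML file of overrides
#' @param ... named overrides (highest precedence)
#' @return a named list with class `run_config`
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    input = NULL, outdir = ".", seed = 0,
    bins = 120, temperature = 310,
    cv_x = "phe63_asnrepeat_distance", cv_y = "interdomain_theta",
    cluster_cutoff = 4.0, cluster_selection = "backbone",
    fit_selection = "ca", enm_cutoff = 8.0, enm_spring = "uniform",
    contact_cutoff = 3.5, contact_group_a = "protein",
    contact_group_b = NULL,
    grid_spacing = 1.0, isovalue = 0.44,
    water_selection = "water and heavy",
    time_window_start = NULL, time_window_end = NULL,
    n_modes = 3, mode_amplitude = 2.0
  )
  cfg <- defaults
  if (!is.null(path)) {
    file_vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_vals), names(defaults))
    if (length(unknown) > 0)
      warning("unknown config key(s): ", paste(unknown, collapse = ", "),
              call. = FALSE)
    cfg[intersect(names(file_vals), names(defaults))] <-
      file_vals[intersect(names(file_vals), names(defaults))]
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (key in c("bins", "temperature", "cluster_cutoff", "contact_cutoff",
                "grid_spacing", "isovalue", "enm_cutoff", "mode_amplitude"))
    if (cfg[[key]] <= 0) stop("config parameter '", key, "' must be positive")
  class(cfg) <- "run_config"
  cfg
}

.load_input <- function(config) {
  if (is.null(config$input)) stop("config lacks an input path")
  ens <- if (inherits(config$input, "Ensemble")) config$input
         else read_ensemble(config$input)
  if (!is.null(config$time_window_start) || !is.null(config$time_window_end)) {
    ens <- if (is.null(ens$times))
      time_window(ens, frame_start = config$time_window_start,
                  frame_end = config$time_window_end)
    else
      time_window(ens, t_start = config$time_window_start,
                  t_end = config$time_window_end)
  }
  ens
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

.write_manifest <- function(config, outdir, stage) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$input_checksum <- if (is.character(cfg$input) && file.exists(cfg$input))
    as.vector(tools::md5sum(cfg$input)) else NA
  if (inherits(cfg$input, "Ensemble")) cfg$input <- "<in-memory ensemble>"
  manifest <- c(
    sprintf("stage: %s", stage),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("confens"))),
    yaml::as.yaml(cfg)
  )
  writeLines(manifest, file.path(outdir, sprintf("manifest_%s.yaml", stage)))
}

#' Landscape command: CV series, free-energy landscape and minima report
#'
#' @param config a [run_config()]; uses `input`, `cv_x`, `cv_y`, `bins`,
#'   `temperature`, `time_window_*`, `outdir`
#' @return invisibly, a list with the `fel` and the minima data.frame
#' @export
cmd_landscape <- function(config) {
  ens <- .load_input(config)
  outdir <- config$outdir
  .write_manifest(config, outdir, "landscape")
  .stage_log("landscape", "input: %d frames, %d atoms", n_frames(ens),
             n_atoms(ens))
  sx <- evaluate_cv(ens, config$cv_x)
  sy <- evaluate_cv(ens, config$cv_y)
  .write_tsv(data.frame(frame = seq_along(sx$values),
                        time_ps = if (is.null(ens$times)) NA else ens$times,
                        x = sx$values, y = sy$values),
             file.path(outdir, "cv_series.tsv"),
             sprintf("# %s (%s)\t%s (%s)", sx$name, sx$units, sy$name,
                     sy$units))
  fel <- build_fel(sx, sy, bins = config$bins,
                   temperature = config$temperature)
  write_fel_tsv(fel, file.path(outdir, "fel.tsv"))
  minima <- locate_minima(fel)
  .write_tsv(minima, file.path(outdir, "fel_minima.tsv"),
             "# free-energy basins, ascending G (kT)")
  .stage_log("landscape", "%d basins; global minimum at (%.3f, %.3f)",
             nrow(minima), minima$x[1], minima$y[1])
  invisible(list(fel = fel, minima = minima))
}

#' Cluster command: GROMOS clustering with central-structure extraction
#'
#' @param config a [run_config()]; uses `input`, `cluster_selection`,
#'   `cluster_cutoff`, `time_window_*`, `outdir`
#' @return invisibly, the `ClusteringResult`
#' @export
cmd_cluster <- function(config) {
  ens <- .load_input(config)
  outdir <- config$outdir
  .write_manifest(config, outdir, "cluster")
  sel <- config$cluster_selection
  if (length(resolve_selection(ens, sel, allow_empty = TRUE)) == 0L) {
    warning("cluster selection '", sel, "' matches no atoms; using 'ca'",
            call. = FALSE)
    sel <- "ca"
  }
  .stage_log("cluster", "%d frames, cutoff %.2f A, selection '%s'",
             n_frames(ens), config$cluster_cutoff, sel)
  m <- pairwise_rmsd_matrix(ens, sel)
  res <- gromos_cluster(m, cutoff = config$cluster_cutoff)
  write_clustering_tsv(res, file.path(outdir, "cluster_assignments.tsv"),
                       file.path(outdir, "cluster_summary.tsv"),
                       times = ens$times)
  centrals <- central_structures(res, ens)
  write_ensemble(centrals, file.path(outdir, "central_structures.pdb"))
  .stage_log("cluster", "%d clusters; %s holds %.1f%%", length(res$centers),
             cluster_label(1), res$populations[1])
  invisible(res)
}

#' Modes command: elastic-network modes, PCA, and the overlap report
#'
#' Builds RTB-reduced elastic-network modes (one residue per block) of the
#' ensemble-average structure, essential-dynamics PCA of the ensemble, and
#' reports the overlap of the main PCA eigenvector with normal modes 7-9
#' (numbering counts the six rigid-body modes first). Mode animations are
#' written as multi-model PDB.
#'
#' @param config a [run_config()]; uses `input`, `fit_selection`,
#'   `enm_cutoff`, `enm_spring`, `n_modes`, `mode_amplitude`, `outdir`
#' @return invisibly, a list with `pca`, `nma`, and the overlap data.frame
#' @export
cmd_modes <- function(config) {
  ens <- .load_input(config)
  outdir <- config$outdir
  .write_manifest(config, outdir, "modes")
  sel <- resolve_selection(ens, config$fit_selection)
  avg <- average_structure(ens, sel)
  .stage_log("modes", "ENM on %d atoms (cutoff %.1f A), PCA on %d frames",
             n_atoms(ens), config$enm_cutoff, n_frames(ens))
  hess <- build_enm_hessian(avg, cutoff = config$enm_cutoff,
                            spring = config$enm_spring)
  nma <- rtb_modes(hess, avg)
  pc <- pca(ens, fit_selection = sel)
  mode_ids <- nma$n_zero + seq_len(config$n_modes)
  ov <- vapply(mode_ids, function(m)
    mode_overlap(pc$vectors[, 1], mode_subvector(nma$vectors[, m], sel)),
    numeric(1))
  report <- as.data.frame(as.list(setNames(round(ov, 4),
                                           sprintf("mode%d", mode_ids))))
  report <- cbind(data.frame(pca_mode = 1), report)
  .write_tsv(report, file.path(outdir, "overlap_report.tsv"),
             "# overlap of PCA mode 1 with elastic-network modes")
  write_modes_tsv(nma, file.path(outdir, "nma_modes.tsv"),
                  which = c(seq_len(nma$n_zero), mode_ids))
  for (m in mode_ids) {
    anim <- animate_mode(avg, nma$vectors[, m],
                         amplitude = config$mode_amplitude)
    write_ensemble(anim, file.path(outdir, sprintf("mode%d_animation.pdb", m)))
  }
  .stage_log("modes", "PCA1 x mode%d overlap = %.3f", mode_ids[1], ov[1])
  invisible(list(pca = pc, nma = nma, overlap = report))
}

#' Contacts command: prevalence, matrix, classified tables and occupancy
#'
#' @param config a [run_config()]; uses `input`, `contact_group_a`,
#'   `contact_group_b`, `contact_cutoff`, `water_selection`,
#'   `grid_spacing`, `isovalue`, `outdir`. The occupancy grid is written
#'   only when the water selection matches atoms.
#' @return invisibly, a list with the prevalence table, matrix, classified
#'   table and (possibly NULL) occupancy grid
#' @export
cmd_contacts <- function(config) {
  ens <- .load_input(config)
  outdir <- config$outdir
  .write_manifest(config, outdir, "contacts")
  if (is.null(config$contact_group_b))
    stop("config needs contact_group_b (the partner selection)")
  .stage_log("contacts", "cutoff %.2f A; A = '%s', B = '%s'",
             config$contact_cutoff, config$contact_group_a,
             config$contact_group_b)
  tab <- contact_prevalence(ens, config$contact_group_a,
                            config$contact_group_b,
                            cutoff = config$contact_cutoff)
  write_contacts_tsv(tab, file.path(outdir, "contact_prevalence.tsv"))
  cm <- contact_matrix(ens, config$contact_group_a, config$contact_group_b,
                       cutoff = config$contact_cutoff)
  cm_df <- data.frame(residue_a = rownames(cm), as.data.frame(cm),
                      check.names = FALSE)
  .write_tsv(cm_df, file.path(outdir, "contact_matrix.tsv"),
             sprintf("# residue-pair contact percentages (cutoff %.2f A)",
                     attr(cm, "cutoff")))
  cls <- classify_residue_contacts(tab)
  .write_tsv(as.data.frame(cls), file.path(outdir, "contact_classified.tsv"),
             "# contact prevalence partitioned by residue chemistry")
  grid <- NULL
  widx <- resolve_selection(ens, config$water_selection, allow_empty = TRUE)
  if (length(widx) > 0) {
    grid <- occupancy_grid(ens, widx, spacing = config$grid_spacing,
                           isovalue = config$isovalue)
    write_dx(grid, file.path(outdir, "occupancy.dx"))
    .write_tsv(grid$sites, file.path(outdir, "occupancy_sites.tsv"),
               sprintf("# voxels with occupancy >= %.2f", grid$isovalue))
  }
  .stage_log("contacts", "%d residues tabulated; top %.1f%%", nrow(tab),
             max(tab$percentage))
  invisible(list(prevalence = tab, matrix = cm, classified = cls,
                 occupancy = grid))
}

#' Simulate command: write a synthetic hinge ensemble and its ground truth
#'
#' @param config a [run_config()]; uses `seed` and `outdir`; generator
#'   parameters take the documented [hinge_spec()] defaults
#' @param ... overrides forwarded to [hinge_spec()]
#' @return invisibly, the generator output
#' @export
cmd_simulate <- function(config, ...) {
  outdir <- config$outdir
  .write_manifest(config, outdir, "simulate")
  gen <- make_hinge_ensemble(hinge_spec(seed = config$seed, ...))
  write_ensemble(gen$ensemble, file.path(outdir, "hinge_ensemble.xyz"))
  gt <- gen$ground_truth
  .write_tsv(data.frame(frame = seq_along(gt$state), state = gt$state,
                        angle_deg = gt$angle),
             file.path(outdir, "ground_truth.tsv"),
             "# planted per-frame state labels and exact hinge angles")
  .stage_log("simulate", "%d frames written", n_frames(gen$ensemble))
  invisible(gen)
}
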