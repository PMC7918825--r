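#' Validated run configuration
#'
#' One declarative configuration drives the whole analysis battery.  A
#' config is a named list (typically read from YAML via [read_config()])
#' with keys:
#' \describe{
#'   \item{input}{either `preset` (a name from [apc_presets()]) or
#'     `trajectory` (path to a multi-model PDB); `n_frames` applies to
#'     presets.}
#'   \item{selection}{analysis atom selection (default `"name CA"`).}
#'   \item{equil_frac}{equilibration fraction (default 0.125).}
#'   \item{landscape}{`bins`, `kB`, `temperature`, `depth_cut`,
#'     `min_separation`, `smooth_sigma`, `half_widths` (length 2).}
#'   \item{dccm}{`mask` threshold.}
#'   \item{gbsa}{`energy_table` path (optional stage).}
#'   \item{outdir}{output directory.}
#'   \item{seed}{integer seed for every stochastic stage.}
#' }
#' Unknown keys are rejected before anything runs.
#'
#' @param config a named list.
#' @return the validated config with defaults filled in.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    input = list(preset = "apo", n_frames = 5000L, trajectory = NULL),
    selection = "name CA",
    equil_frac = 0.125,
    landscape = list(bins = 200L, kB = 3.30e-4, temperature = 300,
                     depth_cut = 0.2, min_separation = 20L,
                     smooth_sigma = 2, half_widths = c(0.75, 20)),
    dccm = list(mask = 0.3),
    gbsa = list(energy_table = NULL),
    outdir = tempfile("trajscape-run-"),
    seed = 1L)
  check <- function(given, def, path = "") {
    unknown <- setdiff(names(given), names(def))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", ": ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(given)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]])))
        def[[k]] <- check(given[[k]], def[[k]], paste0(k, "."))
      else def[[k]] <- given[[k]]
    }
    def
  }
  cfg <- check(config, defaults)
  stopifnot(cfg$equil_frac >= 0, cfg$equil_frac < 1)
  cfg
}

#' @param path YAML config file.
#' @rdname run_config
#' @export
read_config <- function(path) run_config(yaml::read_yaml(path))

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis battery
#'
#' Stages run in dependency order: trajectory acquisition (synthetic
#' preset or PDB input), collective variables, free-energy landscape with
#' basin occupancies and representative frames, RMSD/RMSF fluctuation
#' statistics, the DCCM, and (when an energy table is configured) the
#' MM/GBSA aggregation.  Identical config + seed gives identical output
#' files.
#'
#' @param config a list accepted by [run_config()].
#' @return an `analysis_report`: paths of every written table plus the
#'   in-memory results and a provenance block (config, seed, package
#'   version).
#' @export
run_all <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  files <- character(0)
  t0 <- Sys.time()

  # --- trajectory -----------------------------------------------------
  if (!is.null(cfg$input$trajectory)) {
    stage_log("input", "reading %s", cfg$input$trajectory)
    traj <- read_pdb_models(cfg$input$trajectory)
    truth <- NULL
  } else {
    spec <- apc_presets(cfg$input$preset, n_frames = cfg$input$n_frames,
                        seed = cfg$seed)
    stage_log("input", "generating preset '%s' (%d frames, seed %d)",
              cfg$input$preset, spec$n_frames, spec$seed)
    straj <- generate_ensemble(spec)
    traj <- straj$trajectory
    truth <- straj$labels_truth
    write_truth_table(straj, out("cv_truth.tsv"))
    files <- c(files, out("cv_truth.tsv"))
  }
  nf <- nframes(traj)
  win <- equilibration_window(nf, cfg$equil_frac)

  # --- collective variables ------------------------------------------
  stage_log("colvars", "computing CV series for %d frames", nf)
  cv <- cv_series(traj)
  write_cv_series(cv, out("cv_series.tsv"))
  files <- c(files, out("cv_series.tsv"))

  # --- landscape ------------------------------------------------------
  ls_cfg <- cfg$landscape
  stage_log("landscape", "PMF on %dx%d bins", ls_cfg$bins, ls_cfg$bins)
  grid <- pmf(joint_histogram(cv, ls_cfg$bins), kB = ls_cfg$kB,
              T = ls_cfg$temperature)
  basins <- find_basins(grid, depth_cut = ls_cfg$depth_cut,
                        min_separation = ls_cfg$min_separation,
                        smooth_sigma = ls_cfg$smooth_sigma)
  dGmat <- grid$dG
  dimnames(dGmat) <- list(sprintf("%.4f", grid$xmids),
                          sprintf("%.4f", grid$ymids))
  write_matrix(dGmat, out("pmf.tsv"))
  files <- c(files, out("pmf.tsv"))
  assignment <- NULL
  reps <- NULL
  if (nrow(basins) > 0L) {
    assignment <- assign_frames(cv, basins,
                                half_widths = ls_cfg$half_widths)
    utils::write.table(assignment$occupancy, out("occupancy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, out("occupancy.tsv"))
    reps <- vapply(basins$label, function(b) {
      if (!any(assignment$labels == b)) return(NA_integer_)
      representative_frame(traj, assignment$labels, b,
                           selection = cfg$selection,
                           max_frames = 150L)
    }, 1L)
    stage_log("landscape", "%d basin(s); representative frames: %s",
              nrow(basins), paste(reps, collapse = ", "))
  }

  # --- fluctuations ---------------------------------------------------
  stage_log("fluct", "RMSD/RMSF over window %d-%d", min(win), max(win))
  rs <- rmsd_series(traj, cfg$selection)
  rstat <- mean_rmsd(rs, win)
  prof <- rmsf(traj, cfg$selection, window = win)
  utils::write.table(rs, out("rmsd.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(prof, out("rmsf.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, out("rmsd.tsv"), out("rmsf.tsv"))

  # --- dccm -----------------------------------------------------------
  stage_log("dccm", "correlation matrix (%s)", cfg$selection)
  C <- dccm(traj, cfg$selection, window = win)
  write_matrix(unclass(C), out("dccm.tsv"), digits = 6)
  files <- c(files, out("dccm.tsv"))

  # --- gbsa (optional) ------------------------------------------------
  gbsa <- NULL
  if (!is.null(cfg$gbsa$energy_table)) {
    stage_log("gbsa", "aggregating %s", cfg$gbsa$energy_table)
    et <- load_energy_table(cfg$gbsa$energy_table)
    gbsa <- aggregate_gbsa(et)
    utils::write.table(gbsa$summary, out("gbsa_summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, out("gbsa_summary.tsv"))
    if (!is.null(et$pairs) && !is.null(et$residues)) {
      dec <- decompose_gbsa(et)
      utils::write.table(dec, out("gbsa_decomposition.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, out("gbsa_decomposition.tsv"))
    }
  }

  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("pipeline finished but output missing: ",
         paste(missing, collapse = ", "))
  stage_log("done", "%.1f s elapsed",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(
    config = cfg, files = files, cv = cv, pmf = grid, basins = basins,
    occupancy = if (!is.null(assignment)) assignment$occupancy,
    labels = if (!is.null(assignment)) assignment$labels,
    representative_frames = reps, rmsd = rs, rmsd_stats = rstat,
    rmsf = prof, dccm = C, gbsa = gbsa, labels_truth = truth,
    provenance = list(seed = cfg$seed,
                      package = as.character(utils::packageVersion("trajscape")),
                      r_version = R.version.string)),
    class = "analysis_report")
}

#' @param x an `analysis_report`.
#' @param ... ignored.
#' @export
print.analysis_report <- function(x, ...) {
  cat("trajscape analysis report (seed ", x$provenance$seed, ")\n",
      sep = "")
  cat("  basins found: ", nrow(x$basins), "\n", sep = "")
  if (!is.null(x$occupancy)) print(x$occupancy)
  cat(sprintf("  mean RMSD %.2f +/- %.2f A (post-equilibration)\n",
              x$rmsd_stats["mean"], x$rmsd_stats["sd"]))
  cat("  outputs:\n")
  for (f in x$files) cat("    ", f, "\n", sep = "")
  invisible(x)
}
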