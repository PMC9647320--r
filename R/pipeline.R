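#' Pipeline configuration
#'
#' Bundles every stage configuration for end-to-end runs. All randomness
#' flows from `design$seed`. `grid_drift_step_ms` / `grid_retention_step_s`
#' set the simulation grid resolution; full-campaign simulations typically
#' use a coarser grid than single-spectrum work.
#'
#' @param device a [device_config()]
#' @param detection a [detection_config()]
#' @param matching a [match_config()]
#' @param design a [study_design()]
#' @param base_amplitudes_V see [study_amplitudes()]
#' @param noise_sd spectrum noise SD (V)
#' @param sigma_drift_ms,sigma_retention_s simulated peak widths
#' @param rip_amplitude_V,rip_sigma_ms simulated RIP ridge parameters
#' @param grid_drift_step_ms,grid_retention_step_s simulation grid steps
#' @param outdoor_floor_V censoring floor for [build_profiles()]
#' @param log_level `"quiet"`, `"info"` or `"debug"`
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(device = device_config(),
                            detection = detection_config(),
                            matching = match_config(),
                            design = study_design(),
                            base_amplitudes_V = 1,
                            noise_sd = 0.005,
                            sigma_drift_ms = 0.010,
                            sigma_retention_s = 1.0,
                            rip_amplitude_V = 5,
                            rip_sigma_ms = 0.012,
                            grid_drift_step_ms = 0.004,
                            grid_retention_step_s = 1,
                            outdoor_floor_V = 1e-3,
                            log_level = "info") {
  stopifnot(inherits(device, "device_config"),
            inherits(detection, "detection_config"),
            inherits(matching, "match_config"),
            inherits(design, "study_design"),
            log_level %in% c("quiet", "info", "debug"))
  check_positive(grid_drift_step_ms = grid_drift_step_ms,
                 grid_retention_step_s = grid_retention_step_s,
                 outdoor_floor_V = outdoor_floor_V)
  structure(list(device = device, detection = detection,
                 matching = matching, design = design,
                 base_amplitudes_V = base_amplitudes_V,
                 noise_sd = noise_sd,
                 sigma_drift_ms = sigma_drift_ms,
                 sigma_retention_s = sigma_retention_s,
                 rip_amplitude_V = rip_amplitude_V,
                 rip_sigma_ms = rip_sigma_ms,
                 grid_drift_step_ms = grid_drift_step_ms,
                 grid_retention_step_s = grid_retention_step_s,
                 outdoor_floor_V = outdoor_floor_V,
                 log_level = log_level),
            class = "pipeline_config")
}

pipeline_grid <- function(config)
  default_grid(config$grid_drift_step_ms, config$grid_retention_step_s,
               anchor_ms = config$device$rip_drift_time_ms)

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_deep(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

log_msg <- function(config, level, fmt, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]])
    message(sprintf(fmt, ...))
}

#' Read a pipeline configuration from YAML
#'
#' Every key is optional; omitted keys take the package defaults, so an
#' empty file yields `pipeline_config()`. Recognised top-level keys:
#' `device`, `detection`, `matching`, `design` (with `locations`,
#' `replicates`, `folds`, `cv`, `seed`, `outdoor_name`), `simulation`
#' (`base_amplitudes`, `noise_sd`, `sigma_drift_ms`, `sigma_retention_s`,
#' `rip_amplitude_V`, `rip_sigma_ms`, `grid_drift_step_ms`,
#' `grid_retention_step_s`), `outdoor_floor_V`, `log_level`.
#'
#' @param path YAML file path
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  y <- y %||% list()
  call_with <- function(f, args) do.call(f, args %||% list())
  dev <- call_with(device_config, y$device)
  det <- call_with(detection_config, y$detection)
  mat <- call_with(match_config, y$matching)
  dsn <- y$design %||% list()
  design <- study_design(
    location_names = unlist(dsn$locations) %||% default_locations(),
    replicates_per_location = dsn$replicates %||% 31,
    fold_map = dsn$folds %||% list(),
    replicate_cv = dsn$cv %||% 0.2,
    seed = dsn$seed %||% 1,
    outdoor_name = dsn$outdoor_name %||% "outdoor")
  sim <- y$simulation %||% list()
  pipeline_config(device = dev, detection = det, matching = mat,
                  design = design,
                  base_amplitudes_V = sim$base_amplitudes %||% 1,
                  noise_sd = sim$noise_sd %||% 0.005,
                  sigma_drift_ms = sim$sigma_drift_ms %||% 0.010,
                  sigma_retention_s = sim$sigma_retention_s %||% 1.0,
                  rip_amplitude_V = sim$rip_amplitude_V %||% 5,
                  rip_sigma_ms = sim$rip_sigma_ms %||% 0.012,
                  grid_drift_step_ms = sim$grid_drift_step_ms %||% 0.004,
                  grid_retention_step_s = sim$grid_retention_step_s %||% 1,
                  outdoor_floor_V = y$outdoor_floor_V %||% 1e-3,
                  log_level = y$log_level %||% "info")
}

spectrum_filename <- function(location, replicate)
  sprintf("%s__rep%02d.csv", location, replicate)

#' Simulate a campaign to disk
#'
#' Writes one long-form spectrum CSV per (location, replicate), named
#' `location__repNN.csv`, plus `manifest.json` holding the design, the
#' configuration hash, and the ground-truth peak placements and replicate
#' amplitudes. Re-running with the same configuration reproduces the
#' output bit for bit.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory (created if needed)
#' @param library a [reference_library()]
#' @return invisibly, list with `files` and `manifest` paths
#' @export
cmd_simulate <- function(config, outdir, library = default_library()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop("output directory not writable: ", outdir, call. = FALSE)
  grid <- pipeline_grid(config)
  log_msg(config, "info", "simulate: seed=%d config=%s",
          config$design$seed, config_hash(config))
  files <- study_apply(
    config$design, library, config$base_amplitudes_V,
    fn = function(loc, r, sp, truth) {
      f <- file.path(outdir, spectrum_filename(loc, r))
      write_spectrum_csv(sp, f)
      f
    },
    device = config$device, noise_sd = config$noise_sd, grid = grid,
    sigma_drift_ms = config$sigma_drift_ms,
    sigma_retention_s = config$sigma_retention_s,
    rip_amplitude_V = config$rip_amplitude_V,
    rip_sigma_ms = config$rip_sigma_ms)
  truth <- attr(files, "truth")
  placements <- library[, c("group_id", "compound_name", "form",
                            "retention_time_s", "relative_drift_time")]
  placements$drift_time_ms <- library_drift_times(library, config$device)
  manifest <- list(
    seed = config$design$seed,
    config_hash = config_hash(config),
    locations = config$design$location_names,
    replicates_per_location = config$design$replicates_per_location,
    fold_map = config$design$fold_map,
    replicate_cv = config$design$replicate_cv,
    placements = placements,
    amplitudes = truth)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  log_msg(config, "info", "simulate: wrote %d spectra to %s",
          length(files), outdir)
  invisible(list(files = unlist(files), manifest = mpath))
}

parse_spectrum_filename <- function(f) {
  b <- sub("\\.csv$", "", basename(f))
  m <- regmatches(b, regexec("^(.*)__rep([0-9]+)$", b))[[1]]
  if (length(m) != 3) return(NULL)
  list(location = m[2], replicate = as.integer(m[3]))
}

#' Run the analysis pipeline on a directory of spectra
#'
#' Reads every `location__repNN.csv` spectrum, detects peaks per
#' replicate, builds per-location consensus tables, identifies compounds,
#' computes outdoor-normalized location profiles and the replicate
#' stability report, and writes peak tables, identification and profile
#' CSVs, radar and stability figures, and `summary.json`. Study-wide
#' detection counts come from clustering the per-location consensus tables
#' into one campaign-level peak table and identifying it.
#'
#' @param config a [pipeline_config()]
#' @param spectra_dir directory produced by [cmd_simulate()] (or any
#'   directory of long-form spectrum CSVs following the naming scheme)
#' @param outdir output directory
#' @param library a [reference_library()]
#' @param write_figures logical; write radar/stability PNGs
#' @return invisibly, the summary list (counts, per-location profiles,
#'   stability ranking)
#' @export
cmd_run <- function(config, spectra_dir, outdir,
                    library = default_library(), write_figures = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- sort(list.files(spectra_dir, pattern = "__rep[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0)
    stop("no spectrum CSV files found in ", spectra_dir, call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg(config, "info", "run: %d spectra, config=%s", length(files),
          config_hash(config))
  by_loc <- list()
  for (f in files) {
    info <- parse_spectrum_filename(f)
    if (is.null(info)) next
    sp <- read_spectrum_csv(f, config$device)
    pk <- detect_peaks(sp, config$detection)
    log_msg(config, "debug", "  %s: %d peaks", basename(f), nrow(pk))
    by_loc[[info$location]] <- c(by_loc[[info$location]], list(pk))
  }
  # majority filter: a consensus peak must occur in more than half of a
  # location's replicates; screens out isolated noise detections
  consensus <- lapply(by_loc, function(pks) {
    tab <- consensus_peaks(pks, config = config$detection)
    tab[tab$occurrence >= ceiling(length(pks) / 2) | tab$is_rip, ,
        drop = FALSE]
  })
  for (loc in names(consensus))
    write_peak_table(consensus[[loc]],
                     file.path(outdir, sprintf("peaks__%s.csv", loc)))

  # campaign-wide peak table: cluster the location consensus tables
  campaign <- consensus_peaks(unname(consensus), config = config$detection)
  idents <- match_peaks(campaign, library, config$matching)
  write_identifications(idents, file.path(outdir, "identifications.csv"))
  summ <- summarize_identifications(idents)

  outdoor <- config$design$outdoor_name
  profiles <- NULL
  if (outdoor %in% names(consensus) && length(consensus) > 1) {
    profiles <- build_profiles(consensus, library, outdoor_name = outdoor,
                               config = config$matching,
                               outdoor_floor = config$outdoor_floor_V)
    write_profiles(profiles, file.path(outdir, "profiles.csv"))
  }
  stability <- NULL
  n_rep <- if (length(by_loc)) length(by_loc[[1]]) else 0
  if (n_rep >= 2)
    stability <- stability_report(consensus, library, config$matching)

  if (write_figures && !is.null(profiles)) {
    for (loc in unique(profiles$location)) {
      grDevices::png(file.path(outdir, sprintf("radar__%s.png", loc)),
                     width = 700, height = 700)
      plot_profile_radar(profiles, loc)
      grDevices::dev.off()
    }
  }
  summary <- list(
    seed = config$design$seed,
    config_hash = config_hash(config),
    n_spectra = length(files),
    n_locations = length(by_loc),
    counts = list(detected = summ$n_detected,
                  identified = summ$n_identified,
                  distinct_compounds = summ$n_distinct_compounds),
    stability_ranking = if (!is.null(stability))
      stability$location_ranking else NULL,
    profiles = if (!is.null(profiles)) as.data.frame(profiles) else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  log_msg(config, "info",
          "run: detected=%d identified=%d distinct=%d",
          summ$n_detected, summ$n_identified, summ$n_distinct_compounds)
  invisible(summary)
}
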