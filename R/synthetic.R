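#' Analyte peak specification for the simulator
#'
#' A simulated analyte signal is a separable 2D Gaussian on the retention x
#' drift plane. The drift coordinate is given RIP-relative so that specs
#' can be built directly from library entries. Default widths (sigma 0.010
#' ms in drift, 1.0 s in retention) are chosen so that every entry of the
#' packaged library remains a distinct local maximum on the default grid:
#' the closest pairs of entries are then separated by about 3.1 combined
#' sigma, which leaves a deep saddle between them.
#'
#' @param retention_time_s peak centre on the retention axis (s)
#' @param relative_drift_time peak centre as RIP-relative drift time
#' @param amplitude_V apex amplitude (V)
#' @param sigma_drift_ms Gaussian width along drift (ms)
#' @param sigma_retention_s Gaussian width along retention (s)
#' @param group_id optional library group id carried as ground truth
#' @param form optional form label (monomer/dimer/trimer)
#' @return one-row data.frame of class `peak_spec`
#' @export
peak_spec <- function(retention_time_s, relative_drift_time,
                      amplitude_V = 1, sigma_drift_ms = 0.010,
                      sigma_retention_s = 1.0, group_id = NA_integer_,
                      form = NA_character_) {
  check_positive(retention_time_s = retention_time_s,
                 relative_drift_time = relative_drift_time,
                 amplitude_V = amplitude_V,
                 sigma_drift_ms = sigma_drift_ms,
                 sigma_retention_s = sigma_retention_s)
  structure(data.frame(retention_time_s = retention_time_s,
                       relative_drift_time = relative_drift_time,
                       amplitude_V = amplitude_V,
                       sigma_drift_ms = sigma_drift_ms,
                       sigma_retention_s = sigma_retention_s,
                       group_id = as.integer(group_id),
                       form = as.character(form),
                       stringsAsFactors = FALSE),
            class = c("peak_spec", "data.frame"))
}

#' Build peak specs for every entry of a library
#'
#' @param library a [reference_library()]
#' @param amplitudes_V either a single amplitude applied to all entries or
#'   a named vector/list mapping group id to amplitude; groups without an
#'   amplitude are dropped
#' @param sigma_drift_ms,sigma_retention_s peak widths, as in [peak_spec()]
#' @return data.frame of peak specs (class `peak_spec`)
#' @export
#' @examples
#' specs <- library_peak_specs(default_library(), 1)
#' nrow(specs)  # 31
library_peak_specs <- function(library, amplitudes_V = 1,
                               sigma_drift_ms = 0.010,
                               sigma_retention_s = 1.0) {
  stopifnot(inherits(library, "reference_library"))
  if (length(amplitudes_V) == 1L && is.null(names(amplitudes_V))) {
    amp <- rep(as.numeric(amplitudes_V), nrow(library))
    keep <- rep(TRUE, nrow(library))
  } else {
    amap <- unlist(amplitudes_V)
    keep <- as.character(library$group_id) %in% names(amap)
    amp <- as.numeric(amap[as.character(library$group_id[keep])])
  }
  df <- data.frame(retention_time_s = library$retention_time_s[keep],
                   relative_drift_time = library$relative_drift_time[keep],
                   amplitude_V = amp,
                   sigma_drift_ms = sigma_drift_ms,
                   sigma_retention_s = sigma_retention_s,
                   group_id = library$group_id[keep],
                   form = library$form[keep],
                   stringsAsFactors = FALSE)
  check_positive(amplitude_V = df$amplitude_V)
  structure(df, class = c("peak_spec", "data.frame"))
}

#' Simulate a GC-IMS spectrum
#'
#' The simulated intensity field is the sum of three components: a RIP
#' ridge (Gaussian profile in drift centred at the device RIP drift time,
#' constant along retention), one separable 2D Gaussian per peak spec, and
#' i.i.d. zero-mean Gaussian noise of standard deviation `noise_sd`. With a
#' fixed seed the result is bit-reproducible.
#'
#' The grid must cover at least drift 4-7 ms and retention 0-300 s and
#' must contain the device RIP drift time exactly (see [default_grid()]).
#'
#' @param peak_specs a `peak_spec` data.frame (possibly zero rows)
#' @param device a [device_config()]
#' @param noise_sd noise standard deviation (V)
#' @param grid list with `drift_axis_ms`, `retention_axis_s`
#' @param seed integer seed; `NULL` uses the current RNG state
#' @param rip_amplitude_V apex amplitude of the RIP ridge (V); 0 removes it
#' @param rip_sigma_ms drift width of the RIP ridge (ms)
#' @return an [ims_spectrum()]
#' @export
#' @examples
#' sp <- generate_spectrum(peak_spec(73, 1.056), noise_sd = 0, seed = 1)
generate_spectrum <- function(peak_specs, device = device_config(),
                              noise_sd = 0.005, grid = default_grid(),
                              seed = NULL, rip_amplitude_V = 5,
                              rip_sigma_ms = 0.012) {
  dr <- grid$drift_axis_ms
  rt <- grid$retention_axis_s
  rip <- device$rip_drift_time_ms
  if (min(dr) > 4 + 1e-9 || max(dr) < 7 - 1e-9 ||
      min(rt) > 0 + 1e-9 || max(rt) < 300 - 1e-9)
    stop("grid must cover drift 4-7 ms and retention 0-300 s",
         call. = FALSE)
  if (!any(abs(dr - rip) < 1e-9))
    stop(sprintf("grid drift axis must contain the RIP drift time %.3f ms",
                 rip), call. = FALSE)
  M <- matrix(0, nrow = length(rt), ncol = length(dr))
  if (rip_amplitude_V > 0)
    M <- M + rip_amplitude_V *
      (rep(1, length(rt)) %o% exp(-(dr - rip)^2 / (2 * rip_sigma_ms^2)))
  if (!is.null(peak_specs) && nrow(peak_specs) > 0) {
    for (i in seq_len(nrow(peak_specs))) {
      p <- peak_specs[i, ]
      mu_d <- p$relative_drift_time * rip
      M <- M + p$amplitude_V *
        (exp(-(rt - p$retention_time_s)^2 / (2 * p$sigma_retention_s^2)) %o%
         exp(-(dr - mu_d)^2 / (2 * p$sigma_drift_ms^2)))
    }
  }
  if (noise_sd > 0)
    M <- M + with_seed(seed,
                       matrix(stats::rnorm(length(M), 0, noise_sd),
                              nrow = nrow(M)))
  ims_spectrum(dr, rt, M, device)
}

#' Default campaign locations
#'
#' The 15 indoor sampling sites of the reference campaign plus the outdoor
#' baseline site.
#'
#' @return character vector of 16 location names
#' @export
default_locations <- function() {
  c("administration_building", "mechanical_engineering_building",
    "electronic_engineering_building", "atomic_molecular_physics_lab",
    "biomedical_engineering_lab", "chemistry_lab",
    "analytical_instrumentation_lab", "electronics_lab",
    "materials_engineering_lab", "conservation_restoration_lab",
    "fablab", "canteen", "bathroom", "workshop", "cleaning_storeroom",
    "outdoor")
}

#' Sampling campaign design
#'
#' Describes the simulated study: which locations are sampled, how many
#' replicate measurements each receives (31 by default, matching a
#' two-day sampling protocol per site), the per-location intensity
#' fold-changes relative to the outdoor baseline, and the replicate-level
#' lognormal coefficient of variation. The outdoor location always has all
#' folds equal to 1.
#'
#' @param location_names ordered location names; must include
#'   `outdoor_name`
#' @param replicates_per_location replicate measurements per location
#' @param fold_map named list: location -> named vector mapping group id to
#'   fold ratio versus outdoor; unlisted locations/groups default to 1
#' @param replicate_cv lognormal coefficient of variation of replicate
#'   amplitudes (dimensionless)
#' @param seed root seed for the campaign
#' @param outdoor_name name of the baseline location
#' @return an object of class `study_design`
#' @export
#' @examples
#' d <- study_design(fold_map = list(
#'   materials_engineering_lab = c(`7` = 5, `17` = 10, `15` = 15)))
study_design <- function(location_names = default_locations(),
                         replicates_per_location = 31,
                         fold_map = list(), replicate_cv = 0.2,
                         seed = 1, outdoor_name = "outdoor") {
  stopifnot(length(location_names) >= 1,
            !anyDuplicated(location_names),
            outdoor_name %in% location_names)
  if (replicates_per_location < 1)
    stop("replicates_per_location must be >= 1", call. = FALSE)
  if (replicate_cv < 0)
    stop("replicate_cv must be >= 0", call. = FALSE)
  if (length(fold_map)) {
    stopifnot(all(names(fold_map) %in% location_names))
    for (loc in names(fold_map)) {
      f <- unlist(fold_map[[loc]])
      if (any(!is.finite(f)) || any(f <= 0))
        stop("all folds must be strictly positive", call. = FALSE)
      if (loc == outdoor_name && any(f != 1))
        stop("outdoor folds must all equal 1", call. = FALSE)
    }
  }
  structure(list(location_names = location_names,
                 replicates_per_location = as.integer(replicates_per_location),
                 fold_map = fold_map,
                 replicate_cv = replicate_cv,
                 seed = as.integer(seed),
                 outdoor_name = outdoor_name),
            class = "study_design")
}

fold_for <- function(design, location, group_id) {
  f <- design$fold_map[[location]]
  if (is.null(f)) return(rep(1, length(group_id)))
  f <- unlist(f)
  out <- rep(1, length(group_id))
  hit <- as.character(group_id) %in% names(f)
  out[hit] <- as.numeric(f[as.character(group_id[hit])])
  out
}

#' Ground-truth replicate amplitudes for a campaign
#'
#' The amplitude of compound group g in replicate r at location l is
#' `base_amplitude(g) * fold(l, g) * m`, where `m` is a lognormal
#' multiplier with unit mean and coefficient of variation
#' `design$replicate_cv`, drawn from a stream seeded deterministically by
#' (seed, location, replicate). With `replicate_cv = 0` all replicates of a
#' location are identical.
#'
#' @param design a [study_design()]
#' @param library a [reference_library()] (groups must cover the fold map)
#' @param base_amplitudes_V named vector mapping group id to outdoor-level
#'   apex amplitude (V); a single unnamed value applies to all library
#'   groups
#' @return data.frame with columns `location`, `replicate`, `group_id`,
#'   `amplitude_V`
#' @export
study_amplitudes <- function(design, library, base_amplitudes_V = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(library, "reference_library"))
  groups <- sort(unique(library$group_id))
  if (length(base_amplitudes_V) == 1L && is.null(names(base_amplitudes_V))) {
    base <- stats::setNames(rep(as.numeric(base_amplitudes_V),
                                length(groups)), groups)
  } else {
    base <- unlist(base_amplitudes_V)
    groups <- groups[as.character(groups) %in% names(base)]
    base <- base[as.character(groups)]
  }
  for (loc in names(design$fold_map)) {
    unknown <- setdiff(names(unlist(design$fold_map[[loc]])),
                       as.character(groups))
    if (length(unknown))
      stop(sprintf("fold_map[%s] references unknown group(s): %s", loc,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cv <- design$replicate_cv
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- -sdlog^2 / 2  # unit-mean multiplier
  rows <- vector("list",
                 length(design$location_names) * design$replicates_per_location)
  k <- 0L
  for (li in seq_along(design$location_names)) {
    loc <- design$location_names[li]
    folds <- fold_for(design, loc, groups)
    for (r in seq_len(design$replicates_per_location)) {
      mult <- if (cv > 0)
        with_seed(mix_seed(design$seed, li, r, 0L),
                  stats::rlnorm(length(groups), meanlog, sdlog))
      else rep(1, length(groups))
      k <- k + 1L
      rows[[k]] <- data.frame(location = loc, replicate = r,
                              group_id = groups,
                              amplitude_V = base * folds * mult,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stream over the spectra of a simulated campaign
#'
#' Generates each replicate spectrum in turn and passes it to `fn`,
#' avoiding holding the whole campaign in memory. Spectrum noise is seeded
#' deterministically per (seed, location, replicate), independently of the
#' amplitude streams.
#'
#' @param design a [study_design()]
#' @param library a [reference_library()]
#' @param base_amplitudes_V see [study_amplitudes()]
#' @param fn function `(location, replicate, spectrum, truth)` called per
#'   replicate; `truth` is the per-group amplitude data.frame for that
#'   replicate
#' @param device a [device_config()]
#' @param noise_sd spectrum noise SD (V)
#' @param grid measurement grid (see [default_grid()])
#' @param sigma_drift_ms,sigma_retention_s peak widths
#' @param rip_amplitude_V,rip_sigma_ms RIP ridge parameters
#' @return list of `fn` results (one per replicate) with the full
#'   amplitude table attached as attribute `truth`
#' @export
study_apply <- function(design, library, base_amplitudes_V = 1, fn,
                        device = device_config(), noise_sd = 0.005,
                        grid = default_grid(), sigma_drift_ms = 0.010,
                        sigma_retention_s = 1.0, rip_amplitude_V = 5,
                        rip_sigma_ms = 0.012) {
  amp <- study_amplitudes(design, library, base_amplitudes_V)
  lib_use <- library[as.character(library$group_id) %in%
                       as.character(unique(amp$group_id)), , drop = FALSE]
  res <- vector("list",
                length(design$location_names) * design$replicates_per_location)
  k <- 0L
  for (li in seq_along(design$location_names)) {
    loc <- design$location_names[li]
    for (r in seq_len(design$replicates_per_location)) {
      truth <- amp[amp$location == loc & amp$replicate == r, , drop = FALSE]
      a <- stats::setNames(truth$amplitude_V, truth$group_id)
      specs <- library_peak_specs(reference_library(lib_use), a,
                                  sigma_drift_ms = sigma_drift_ms,
                                  sigma_retention_s = sigma_retention_s)
      sp <- generate_spectrum(specs, device = device, noise_sd = noise_sd,
                              grid = grid,
                              seed = mix_seed(design$seed, li, r, 1L),
                              rip_amplitude_V = rip_amplitude_V,
                              rip_sigma_ms = rip_sigma_ms)
      k <- k + 1L
      res[[k]] <- fn(loc, r, sp, truth)
    }
  }
  attr(res, "truth") <- amp
  res
}

#' Generate a full simulated campaign in memory
#'
#' Eager counterpart of [study_apply()]: returns every replicate spectrum.
#' For the default 16 x 31 campaign on a fine grid this is memory-hungry;
#' prefer [study_apply()] or a coarser grid for full-size runs.
#'
#' @inheritParams study_apply
#' @return list with `spectra` (list of `location`, `replicate`,
#'   `spectrum`) and `truth` (amplitude table from [study_amplitudes()])
#' @export
generate_study <- function(design, library, base_amplitudes_V = 1, ...) {
  res <- study_apply(design, library, base_amplitudes_V,
                     fn = function(loc, r, sp, truth)
                       list(location = loc, replicate = r, spectrum = sp),
                     ...)
  list(spectra = res, truth = attr(res, "truth"))
}
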