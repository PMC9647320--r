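# Shared fixtures; everything is generated in code, no files.

lib_fix <- default_library()
named_fix <- named_entries(lib_fix)

# fast grids: same coverage as the default grid, coarser sampling
fast_grid <- function() default_grid(0.004, 1)
tiny_grid <- function() default_grid(0.01, 2)

# peaks placed exactly at library coordinates (no simulation involved)
exact_library_peaks <- function(library = lib_fix,
                                device = device_config()) {
  data.frame(retention_time_s = library$retention_time_s,
             drift_time_ms = library_drift_times(library, device),
             relative_drift_time = library$relative_drift_time,
             intensity_V = 1,
             is_rip = FALSE)
}

# full-composite spectrum at the default fine grid (heavier; ~5 s)
composite_spectrum <- function(noise_sd = 0, seed = 1,
                               amplitudes = 1, grid = default_grid()) {
  generate_spectrum(library_peak_specs(lib_fix, amplitudes),
                    noise_sd = noise_sd, grid = grid, seed = seed)
}

# run a small two-location campaign through detection and consensus
run_small_study <- function(design, base_amplitudes = 1, noise_sd = 0.005,
                            grid = fast_grid(),
                            det = detection_config(),
                            min_occurrence = 1L) {
  res <- study_apply(design, lib_fix, base_amplitudes,
                     fn = function(loc, r, sp, truth)
                       detect_peaks(sp, det),
                     noise_sd = noise_sd, grid = grid)
  idx <- split(seq_along(res),
               rep(design$location_names,
                   each = design$replicates_per_location))
  tabs <- lapply(design$location_names, function(loc) {
    tab <- consensus_peaks(res[idx[[loc]]], det)
    tab[tab$occurrence >= min_occurrence | tab$is_rip, , drop = FALSE]
  })
  names(tabs) <- design$location_names
  tabs
}
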