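#' GC-IMS spectrum
#'
#' A rectangular intensity grid over drift time (ms, columns) and GC
#' retention time (s, rows), together with the device configuration that
#' produced it. Intensities are in volts.
#'
#' @param drift_axis_ms strictly increasing drift-time axis (ms)
#' @param retention_axis_s strictly increasing retention-time axis (s)
#' @param intensity numeric matrix, `length(retention_axis_s)` rows by
#'   `length(drift_axis_ms)` columns, all values finite
#' @param device a [device_config()]
#' @return an object of class `ims_spectrum`
#' @export
ims_spectrum <- function(drift_axis_ms, retention_axis_s, intensity,
                         device = device_config()) {
  stopifnot(inherits(device, "device_config"))
  if (length(drift_axis_ms) == 0 || length(retention_axis_s) == 0)
    stop("spectrum grid must be non-empty", call. = FALSE)
  if (any(diff(drift_axis_ms) <= 0))
    stop("drift_axis_ms must be strictly increasing", call. = FALSE)
  if (any(diff(retention_axis_s) <= 0))
    stop("retention_axis_s must be strictly increasing", call. = FALSE)
  if (!is.matrix(intensity) ||
      nrow(intensity) != length(retention_axis_s) ||
      ncol(intensity) != length(drift_axis_ms))
    stop("intensity must be a |retention| x |drift| matrix", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensity values must be finite", call. = FALSE)
  structure(list(drift_axis_ms = as.numeric(drift_axis_ms),
                 retention_axis_s = as.numeric(retention_axis_s),
                 intensity = intensity,
                 device = device),
            class = "ims_spectrum")
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf(paste0("GC-IMS spectrum: %d retention x %d drift cells\n",
                     "  drift %.3f-%.3f ms, retention %.0f-%.0f s, ",
                     "max intensity %.3g V\n"),
              nrow(x$intensity), ncol(x$intensity),
              min(x$drift_axis_ms), max(x$drift_axis_ms),
              min(x$retention_axis_s), max(x$retention_axis_s),
              max(x$intensity)))
  invisible(x)
}

#' Measurement grid anchored on the RIP drift time
#'
#' Builds drift and retention axes for simulation. The drift axis is
#' anchored so that the RIP drift time (4.889 ms by default) falls exactly
#' on a grid point, and both axes cover at least the required simulation
#' window (drift 4-7 ms, retention 0-300 s). Coarser steps give faster,
#' lower-resolution grids for large simulated campaigns.
#'
#' @param drift_step_ms drift sampling step (ms), default 0.001
#' @param retention_step_s retention sampling step (s), default 1
#' @param drift_range_ms drift window to cover (ms)
#' @param retention_range_s retention window to cover (s)
#' @param anchor_ms drift value that must lie exactly on the grid (ms)
#' @return list with `drift_axis_ms` and `retention_axis_s`
#' @export
#' @examples
#' g <- default_grid()
#' any(abs(g$drift_axis_ms - 4.889) < 1e-12)
default_grid <- function(drift_step_ms = 0.001, retention_step_s = 1,
                         drift_range_ms = c(4, 7),
                         retention_range_s = c(0, 300),
                         anchor_ms = 4.889) {
  check_positive(drift_step_ms = drift_step_ms,
                 retention_step_s = retention_step_s)
  k1 <- ceiling((anchor_ms - drift_range_ms[1]) / drift_step_ms - 1e-9)
  k2 <- ceiling((drift_range_ms[2] - anchor_ms) / drift_step_ms - 1e-9)
  drift <- anchor_ms + drift_step_ms * seq.int(-k1, k2)
  ret <- seq(retention_range_s[1], retention_range_s[2],
             by = retention_step_s)
  if (max(ret) < retention_range_s[2])
    ret <- c(ret, retention_range_s[2])
  list(drift_axis_ms = drift, retention_axis_s = ret)
}

#' Read a spectrum from long-form CSV
#'
#' The long-form dialect has a header row and columns `retention_time_s`,
#' `drift_time_ms`, `intensity_V`, one row per grid cell, row-major by
#' retention time. The file must describe a complete rectangular grid.
#'
#' @param path CSV file path
#' @param device a [device_config()] to attach
#' @return an [ims_spectrum()]
#' @export
read_spectrum_csv <- function(path, device = device_config()) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          showProgress = FALSE)
  need <- c("retention_time_s", "drift_time_ms", "intensity_V")
  if (!all(need %in% names(dt)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s: malformed %s at data row %d", path, col, bad[1]),
           call. = FALSE)
    data.table::set(dt, j = col, value = v)
  }
  ret <- sort(unique(dt$retention_time_s))
  dr <- sort(unique(dt$drift_time_ms))
  if (nrow(dt) != length(ret) * length(dr))
    stop(sprintf("%s: rows do not form a complete %d x %d grid", path,
                 length(ret), length(dr)), call. = FALSE)
  data.table::setorder(dt, retention_time_s, drift_time_ms)
  M <- matrix(dt$intensity_V, nrow = length(ret), ncol = length(dr),
              byrow = TRUE)
  ims_spectrum(dr, ret, M, device)
}

#' Write a spectrum to long-form CSV
#'
#' @param spectrum an [ims_spectrum()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ims_spectrum"))
  dt <- data.table::data.table(
    retention_time_s = rep(spectrum$retention_axis_s,
                           each = length(spectrum$drift_axis_ms)),
    drift_time_ms = rep(spectrum$drift_axis_ms,
                        times = length(spectrum$retention_axis_s)),
    intensity_V = as.vector(t(spectrum$intensity)))
  data.table::fwrite(dt, path)
  invisible(path)
}
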