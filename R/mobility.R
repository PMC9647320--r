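#' Ion drift velocity
#'
#' Drift velocity of a product ion: the drift-region length divided by the
#' time the ion needs to traverse it. Time is supplied in milliseconds, as
#' read off a spectrum, and converted to seconds internally.
#'
#' @param drift_length_cm drift region length (cm)
#' @param drift_time_ms drift time (ms)
#' @return drift velocity in cm/s
#' @export
#' @examples
#' drift_velocity(9.8, 4.889)  # the reactant ion peak
drift_velocity <- function(drift_length_cm, drift_time_ms) {
  check_positive(drift_length_cm = drift_length_cm,
                 drift_time_ms = drift_time_ms)
  drift_length_cm / (drift_time_ms / 1000)
}

#' Ion mobility constant K
#'
#' Ratio of the drift velocity to the applied electric field.
#'
#' @param drift_velocity_cm_s drift velocity (cm/s)
#' @param field_strength_V_cm electric field intensity (V/cm)
#' @return mobility constant in cm^2 V^-1 s^-1
#' @export
mobility_constant <- function(drift_velocity_cm_s, field_strength_V_cm) {
  check_positive(drift_velocity_cm_s = drift_velocity_cm_s,
                 field_strength_V_cm = field_strength_V_cm)
  drift_velocity_cm_s / field_strength_V_cm
}

#' Normalized ion mobility constant K0
#'
#' K depends on the drift-gas pressure and temperature, so it is customary
#' to reduce it to standard conditions (760 Torr, 273.15 K):
#' `K0 = K * (P / 760) * (273.15 / T)`. At standard conditions K0 equals K.
#'
#' @param K mobility constant (cm^2 V^-1 s^-1)
#' @param pressure_Torr drift-tube pressure (Torr)
#' @param temperature_K drift-tube temperature (K)
#' @return K0 in cm^2 V^-1 s^-1
#' @export
normalize_mobility <- function(K, pressure_Torr, temperature_K) {
  check_positive(K = K, pressure_Torr = pressure_Torr,
                 temperature_K = temperature_K)
  K * (pressure_Torr / .P0_TORR) * (.T0_K / temperature_K)
}

#' RIP-relative drift time
#'
#' Drift times divided by the reactant ion peak drift time give a
#' dimensionless coordinate that is robust against slow instrumental drift;
#' it is the drift coordinate used for library identification.
#'
#' @param drift_time_ms drift time (ms)
#' @param rip_drift_time_ms drift time of the reactant ion peak (ms)
#' @return dimensionless relative drift time
#' @export
#' @examples
#' relative_drift_time(5.1628, 4.889)  # ~1.056, an ethanol monomer
relative_drift_time <- function(drift_time_ms, rip_drift_time_ms) {
  check_positive(drift_time_ms = drift_time_ms,
                 rip_drift_time_ms = rip_drift_time_ms)
  drift_time_ms / rip_drift_time_ms
}

#' Full mobility computation for an observed drift time
#'
#' Convenience wrapper chaining [drift_velocity()], [mobility_constant()]
#' and [normalize_mobility()] for a device configuration.
#'
#' @param device a [device_config()]
#' @param drift_time_ms observed drift time (ms)
#' @return a `mobility_result` list with components `drift_velocity_cm_s`,
#'   `mobility_K` and `mobility_K0` (cm^2 V^-1 s^-1)
#' @export
#' @examples
#' ion_mobility(device_config(), 5.1628)
ion_mobility <- function(device, drift_time_ms) {
  stopifnot(inherits(device, "device_config"))
  vd <- drift_velocity(device$drift_length_cm, drift_time_ms)
  K <- mobility_constant(vd, device$field_strength_V_cm)
  K0 <- normalize_mobility(K, device$pressure_Torr, device$temperature_K)
  structure(list(drift_velocity_cm_s = vd, mobility_K = K, mobility_K0 = K0),
            class = "mobility_result")
}

#' @export
print.mobility_result <- function(x, ...) {
  cat(sprintf("v_d = %.1f cm/s, K = %.4f, K0 = %.4f cm^2 V^-1 s^-1\n",
              x$drift_velocity_cm_s, x$mobility_K, x$mobility_K0))
  invisible(x)
}
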