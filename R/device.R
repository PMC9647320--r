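#' GC-IMS device configuration
#'
#' Bundles the instrument parameters that the mobility calculations and the
#' spectrum simulator depend on. Defaults follow a BreathSpec-class drift
#' tube: a 9.8 cm drift region under a 500 V/cm field (5 kV switchable
#' polarity), positive mode, ambient drift-gas conditions, and a reactant
#' ion peak (RIP) at 4.889 ms. Pressure and temperature default to the
#' midpoints of the operating ranges 757-760 Torr and 297.15-301.15 K.
#'
#' The stored drift voltage is metadata; all field computations use
#' `field_strength_V_cm`. Construction fails if the voltage implied by
#' field x length disagrees with the stored voltage by more than 10%.
#'
#' @param drift_length_cm drift region length (cm)
#' @param field_strength_V_cm electric field intensity (V/cm)
#' @param drift_voltage_kV drift potential difference (kV), metadata only
#' @param pressure_Torr drift-tube pressure (Torr)
#' @param temperature_K drift-tube temperature (K)
#' @param rip_drift_time_ms drift time of the reactant ion peak (ms)
#' @param sample_loop_mL sample loop volume (mL)
#' @param carrier_flow_mL_min carrier gas flow (mL/min)
#' @param drift_flow_mL_min drift gas flow (mL/min)
#'
#' @return an object of class `device_config`
#' @export
#' @examples
#' dev <- device_config()
#' dev$rip_drift_time_ms
device_config <- function(drift_length_cm = 9.8,
                          field_strength_V_cm = 500,
                          drift_voltage_kV = 5,
                          pressure_Torr = 758.5,
                          temperature_K = 299.15,
                          rip_drift_time_ms = 4.889,
                          sample_loop_mL = 1,
                          carrier_flow_mL_min = 10,
                          drift_flow_mL_min = 150) {
  check_positive(drift_length_cm = drift_length_cm,
                 field_strength_V_cm = field_strength_V_cm,
                 drift_voltage_kV = drift_voltage_kV,
                 pressure_Torr = pressure_Torr,
                 temperature_K = temperature_K,
                 rip_drift_time_ms = rip_drift_time_ms,
                 sample_loop_mL = sample_loop_mL,
                 carrier_flow_mL_min = carrier_flow_mL_min,
                 drift_flow_mL_min = drift_flow_mL_min)
  implied_V <- field_strength_V_cm * drift_length_cm
  stored_V <- drift_voltage_kV * 1000
  if (abs(implied_V - stored_V) > 0.1 * stored_V)
    stop(sprintf(paste0("field_strength x drift_length (%.0f V) is ",
                        "inconsistent with drift_voltage (%.0f V) by more ",
                        "than 10%%"), implied_V, stored_V), call. = FALSE)
  structure(list(drift_length_cm = drift_length_cm,
                 field_strength_V_cm = field_strength_V_cm,
                 drift_voltage_kV = drift_voltage_kV,
                 pressure_Torr = pressure_Torr,
                 temperature_K = temperature_K,
                 rip_drift_time_ms = rip_drift_time_ms,
                 sample_loop_mL = sample_loop_mL,
                 carrier_flow_mL_min = carrier_flow_mL_min,
                 drift_flow_mL_min = drift_flow_mL_min),
            class = "device_config")
}

#' @export
print.device_config <- function(x, ...) {
  cat("GC-IMS device configuration\n")
  cat(sprintf("  drift region: %.2f cm at %.0f V/cm (%.1f kV)\n",
              x$drift_length_cm, x$field_strength_V_cm, x$drift_voltage_kV))
  cat(sprintf("  conditions:   %.1f Torr, %.2f K\n",
              x$pressure_Torr, x$temperature_K))
  cat(sprintf("  RIP drift time: %.3f ms\n", x$rip_drift_time_ms))
  invisible(x)
}
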