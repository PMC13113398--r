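#' Voltage- and current-clamp stimulation protocols
#'
#' A protocol describes the command waveform of a family of sweeps. Five
#' kinds are supported:
#' \describe{
#'   \item{IV_STEP}{step depolarizations from a holding potential, one sweep
#'     per test voltage (current-voltage families).}
#'   \item{SSI_TWO_STEP}{conditioning prepulse at graded voltages followed by
#'     a fixed test pulse (steady-state inactivation).}
#'   \item{RECOVERY_TWO_PULSE}{two identical pulses separated by a growing
#'     interpulse interval at holding (recovery from inactivation).}
#'   \item{MONITOR_PULSE}{a single repeated step (effect monitoring).}
#'   \item{CURRENT_CLAMP_STEPS}{square current injections of increasing
#'     amplitude (firing-frequency measurements).}
#' }
#'
#' @param kind Protocol kind, one of the five strings above.
#' @param holding_mV Holding potential, mV.
#' @param step_start_mV,step_stop_mV,step_increment_mV Step family definition;
#'   the increment must divide the span exactly.
#' @param step_duration_ms Duration of the (test) step, ms.
#' @param prepulse_duration_ms Duration of the conditioning prepulse
#'   (SSI_TWO_STEP), ms.
#' @param test_pulse_mV Test-pulse voltage (SSI_TWO_STEP) or pulse voltage
#'   (RECOVERY_TWO_PULSE), mV.
#' @param interpulse_ms Strictly increasing vector of interpulse intervals,
#'   ms (RECOVERY_TWO_PULSE).
#' @param sample_rate_kHz Sampling rate, kHz.
#' @param baseline_ms Pre-step segment at holding included in every sweep, ms.
#' @param stim_amplitudes_nA,stim_duration_ms,interstim_s Current-clamp step
#'   amplitudes (nA), duration (ms) and interstimulus interval (s).
#' @return An object of class `protocol_spec`.
#' @seealso [protocol_preset()] for the named presets used throughout.
#' @export
protocol_spec <- function(kind,
                          holding_mV,
                          step_start_mV = NULL, step_stop_mV = NULL,
                          step_increment_mV = NULL,
                          step_duration_ms = NULL,
                          prepulse_duration_ms = NULL,
                          test_pulse_mV = NULL,
                          interpulse_ms = NULL,
                          sample_rate_kHz = 20,
                          baseline_ms = 2,
                          stim_amplitudes_nA = NULL,
                          stim_duration_ms = NULL,
                          interstim_s = NULL) {
  kinds <- c("IV_STEP", "SSI_TWO_STEP", "RECOVERY_TWO_PULSE",
             "MONITOR_PULSE", "CURRENT_CLAMP_STEPS")
  kind <- match.arg(kind, kinds)
  p <- structure(
    list(kind = kind, holding_mV = holding_mV,
         step_start_mV = step_start_mV, step_stop_mV = step_stop_mV,
         step_increment_mV = step_increment_mV,
         step_duration_ms = step_duration_ms,
         prepulse_duration_ms = prepulse_duration_ms,
         test_pulse_mV = test_pulse_mV,
         interpulse_ms = interpulse_ms,
         sample_rate_kHz = sample_rate_kHz,
         baseline_ms = baseline_ms,
         stim_amplitudes_nA = stim_amplitudes_nA,
         stim_duration_ms = stim_duration_ms,
         interstim_s = interstim_s),
    class = "protocol_spec"
  )
  validate_protocol(p)
}

validate_protocol <- function(p) {
  fail <- function(msg) stop("invalid protocol_spec: ", msg, call. = FALSE)
  if (p$sample_rate_kHz <= 0) fail("sample_rate_kHz must be > 0")
  if (p$baseline_ms < 0) fail("baseline_ms must be >= 0")
  if (p$kind %in% c("IV_STEP", "SSI_TWO_STEP")) {
    if (is.null(p$step_start_mV) || is.null(p$step_stop_mV) ||
        is.null(p$step_increment_mV)) {
      fail("step family (start/stop/increment) required")
    }
    span <- p$step_stop_mV - p$step_start_mV
    if (p$step_increment_mV <= 0) fail("step_increment_mV must be > 0")
    if (abs(span / p$step_increment_mV - round(span / p$step_increment_mV)) > 1e-9) {
      fail("step_increment_mV must divide (stop - start)")
    }
  }
  if (p$kind != "CURRENT_CLAMP_STEPS" && is.null(p$step_duration_ms)) {
    fail("step_duration_ms required")
  }
  if (!is.null(p$step_duration_ms) && any(p$step_duration_ms <= 0)) {
    fail("step_duration_ms must be > 0")
  }
  if (p$kind == "SSI_TWO_STEP") {
    if (is.null(p$prepulse_duration_ms) || p$prepulse_duration_ms <= 0) {
      fail("prepulse_duration_ms must be > 0")
    }
    if (is.null(p$test_pulse_mV)) fail("test_pulse_mV required")
  }
  if (p$kind == "RECOVERY_TWO_PULSE") {
    if (is.null(p$test_pulse_mV)) fail("test_pulse_mV (pulse voltage) required")
    if (is.null(p$interpulse_ms) || length(p$interpulse_ms) < 1 ||
        any(diff(p$interpulse_ms) <= 0) || any(p$interpulse_ms <= 0)) {
      fail("interpulse_ms must be a strictly increasing positive vector")
    }
  }
  if (p$kind == "CURRENT_CLAMP_STEPS") {
    if (is.null(p$stim_amplitudes_nA) || is.null(p$stim_duration_ms)) {
      fail("stim_amplitudes_nA and stim_duration_ms required")
    }
    if (any(p$stim_duration_ms <= 0)) fail("stim_duration_ms must be > 0")
  }
  p
}

step_voltages <- function(p) {
  seq(p$step_start_mV, p$step_stop_mV, by = p$step_increment_mV)
}

#' Named protocol presets
#'
#' Ready-made protocols matching the two recording configurations the
#' package emulates.
#'
#' Oocyte two-electrode voltage clamp:
#' \describe{
#'   \item{oocyte_iv}{holding -90 mV, 50 ms steps -80 to +65 mV in 5 mV
#'     increments.}
#'   \item{oocyte_ssi}{100 ms prepulses -80 to 0 mV in 5 mV steps, then a
#'     test pulse to 0 mV.}
#'   \item{oocyte_monitor}{repeated 100 ms depolarizations to 0 mV.}
#' }
#' Snail (Helix) neuron whole-cell patch:
#' \describe{
#'   \item{helix_iv}{holding -50 mV, 200 ms steps -60 to +60 mV in 10 mV
#'     increments.}
#'   \item{helix_ssi}{200 ms prepulses over the same range, then a 200 ms
#'     test pulse at -20 mV.}
#'   \item{helix_recovery}{two pulses at -20 mV separated by interpulse
#'     intervals of 5 to 80 ms in 5 ms increments.}
#'   \item{helix_cc}{current-clamp steps of 0.5, 1.0 and 1.5 nA, 500 ms each,
#'     3 s apart.}
#' }
#'
#' @param name Preset name (see Details).
#' @return A [protocol_spec()] object.
#' @export
#' @examples
#' protocol_preset("helix_iv")
protocol_preset <- function(name = c("oocyte_iv", "oocyte_ssi",
                                     "oocyte_monitor", "helix_iv",
                                     "helix_ssi", "helix_recovery",
                                     "helix_cc")) {
  name <- match.arg(name)
  switch(
    name,
    oocyte_iv = protocol_spec("IV_STEP", holding_mV = -90,
                              step_start_mV = -80, step_stop_mV = 65,
                              step_increment_mV = 5, step_duration_ms = 50),
    oocyte_ssi = protocol_spec("SSI_TWO_STEP", holding_mV = -90,
                               step_start_mV = -80, step_stop_mV = 0,
                               step_increment_mV = 5,
                               prepulse_duration_ms = 100,
                               test_pulse_mV = 0, step_duration_ms = 50),
    oocyte_monitor = protocol_spec("MONITOR_PULSE", holding_mV = -90,
                                   step_start_mV = 0, step_stop_mV = 0,
                                   step_increment_mV = 1,
                                   step_duration_ms = 100),
    helix_iv = protocol_spec("IV_STEP", holding_mV = -50,
                             step_start_mV = -60, step_stop_mV = 60,
                             step_increment_mV = 10, step_duration_ms = 200),
    helix_ssi = protocol_spec("SSI_TWO_STEP", holding_mV = -50,
                              step_start_mV = -60, step_stop_mV = 60,
                              step_increment_mV = 10,
                              prepulse_duration_ms = 200,
                              test_pulse_mV = -20, step_duration_ms = 200),
    helix_recovery = protocol_spec("RECOVERY_TWO_PULSE", holding_mV = -50,
                                   test_pulse_mV = -20,
                                   step_duration_ms = 20,
                                   interpulse_ms = seq(5, 80, by = 5)),
    helix_cc = protocol_spec("CURRENT_CLAMP_STEPS", holding_mV = NA,
                             stim_amplitudes_nA = c(0.5, 1.0, 1.5),
                             stim_duration_ms = 500, interstim_s = 3,
                             sample_rate_kHz = 10, baseline_ms = 50)
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>", x$kind, "\n")
  if (x$kind == "CURRENT_CLAMP_STEPS") {
    cat(sprintf("  stimuli %s nA, %g ms each\n",
                paste(x$stim_amplitudes_nA, collapse = "/"),
                x$stim_duration_ms))
  } else {
    cat(sprintf("  holding %g mV", x$holding_mV))
    if (!is.null(x$step_start_mV)) {
      cat(sprintf(", steps %g to %g mV by %g mV", x$step_start_mV,
                  x$step_stop_mV, x$step_increment_mV))
    }
    if (!is.null(x$step_duration_ms)) cat(sprintf(", %g ms", x$step_duration_ms))
    cat("\n")
    if (x$kind == "SSI_TWO_STEP") {
      cat(sprintf("  prepulse %g ms, test pulse %g mV\n",
                  x$prepulse_duration_ms, x$test_pulse_mV))
    }
    if (x$kind == "RECOVERY_TWO_PULSE") {
      cat(sprintf("  pulses at %g mV, interpulse %g-%g ms\n",
                  x$test_pulse_mV, min(x$interpulse_ms), max(x$interpulse_ms)))
    }
  }
  cat(sprintf("  sampled at %g kHz\n", x$sample_rate_kHz))
  invisible(x)
}
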