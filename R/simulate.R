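#' Simulated voltage-clamp and current-clamp recordings
#'
#' @description
#' `simulate_iv()`, `simulate_ssi()` and `simulate_recovery()` generate
#' voltage-clamp current sweeps of a Boltzmann-gated sodium conductance under
#' a step protocol; `simulate_current_clamp()` (documented separately)
#' generates current-clamp voltage sweeps of a single-compartment neuron.
#'
#' Because the command potential is piecewise constant, the first-order gate
#' equations have exact solutions within each epoch and the simulator
#' evaluates them analytically on the sample grid: during a step the
#' activation gate relaxes as
#' `m(t) = m_inf + (m0 - m_inf) exp(-t / tau_act)` (or tracks `m_inf`
#' exactly when `tau_act = 0`), and the availability follows
#' `h_eff(t) = pf + (1 - pf) h(t)` with `pf` the persistent fraction and
#' `h(t)` relaxing toward `h_inf(V)` as a weighted sum of a fast and a slow
#' exponential (weights `1 - slow_frac` and `slow_frac`). When the target
#' availability is higher than the current one (repolarization), relaxation
#' uses the single recovery time constant instead. The current is
#' `I(t) = gmax (V - vrev) m(t)^p h_eff(t)`; inward current is negative.
#'
#' Gaussian noise with standard deviation `noise_sd` times the set-wide
#' maximum absolute signal is added after simulation; identical arguments and
#' seed give bit-identical output.
#'
#' @param params A [gating_params()] object.
#' @param protocol A [protocol_spec()] of the matching kind (see
#'   [protocol_preset()]).
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   absolute signal (default 0.01).
#' @param seed Integer RNG seed; recorded in the result.
#' @param cell_id,condition Labels stored with every sweep.
#' @return A `sweep_set`: a long-form tibble with columns `cell_id`,
#'   `condition`, `sweep`, `command` (step voltage, prepulse voltage or
#'   interpulse interval), `epoch`, `t_ms`, `value`, plus protocol/unit/seed
#'   metadata in attributes.
#' @seealso [extract_peaks()], [analyze_iv()], [analyze_ssi()],
#'   [recovery_fractions()]
#' @export
#' @examples
#' p <- gating_params()
#' sw <- simulate_iv(p, protocol_preset("oocyte_iv"), noise_sd = 0, seed = 1)
#' extract_peaks(sw)
simulate_iv <- function(params, protocol = protocol_preset("oocyte_iv"),
                        noise_sd = 0.01, seed = 1L,
                        cell_id = "cell1", condition = "control") {
  validate_gating_params(params)
  if (protocol$kind != "IV_STEP" && protocol$kind != "MONITOR_PULSE") {
    stop("`protocol` must have kind IV_STEP or MONITOR_PULSE", call. = FALSE)
  }
  steps <- step_voltages(protocol)
  sweeps <- purrr::imap(steps, function(v_step, i) {
    seg <- clamp_epochs(protocol, v_step)
    df <- clamp_current_trace(params, seg, protocol$sample_rate_kHz)
    df$sweep <- i
    df$command <- v_step
    df
  })
  df <- dplyr::bind_rows(sweeps)
  df <- add_sweep_noise(df, noise_sd, seed)
  finish_clamp_set(df, params, protocol, seed, cell_id, condition)
}

#' @rdname simulate_iv
#' @export
simulate_ssi <- function(params, protocol = protocol_preset("oocyte_ssi"),
                         noise_sd = 0.01, seed = 1L,
                         cell_id = "cell1", condition = "control") {
  validate_gating_params(params)
  if (protocol$kind != "SSI_TWO_STEP") {
    stop("`protocol` must have kind SSI_TWO_STEP", call. = FALSE)
  }
  steps <- step_voltages(protocol)
  sweeps <- purrr::imap(steps, function(v_pre, i) {
    seg <- tibble::tibble(
      epoch = c("baseline", "prepulse", "test"),
      v = c(protocol$holding_mV, v_pre, protocol$test_pulse_mV),
      dur = c(protocol$baseline_ms, protocol$prepulse_duration_ms,
              protocol$step_duration_ms)
    )
    df <- clamp_current_trace(params, seg, protocol$sample_rate_kHz)
    df$sweep <- i
    df$command <- v_pre
    df
  })
  df <- dplyr::bind_rows(sweeps)
  df <- add_sweep_noise(df, noise_sd, seed)
  finish_clamp_set(df, params, protocol, seed, cell_id, condition)
}

#' @rdname simulate_iv
#' @export
simulate_recovery <- function(params,
                              protocol = protocol_preset("helix_recovery"),
                              noise_sd = 0.01, seed = 1L,
                              cell_id = "cell1", condition = "control") {
  validate_gating_params(params)
  if (protocol$kind != "RECOVERY_TWO_PULSE") {
    stop("`protocol` must have kind RECOVERY_TWO_PULSE", call. = FALSE)
  }
  sweeps <- purrr::imap(protocol$interpulse_ms, function(dt_ms, i) {
    seg <- tibble::tibble(
      epoch = c("baseline", "pulse1", "interpulse", "pulse2"),
      v = c(protocol$holding_mV, protocol$test_pulse_mV,
            protocol$holding_mV, protocol$test_pulse_mV),
      dur = c(protocol$baseline_ms, protocol$step_duration_ms, dt_ms,
              protocol$step_duration_ms)
    )
    df <- clamp_current_trace(params, seg, protocol$sample_rate_kHz)
    df$sweep <- i
    df$command <- dt_ms
    df
  })
  df <- dplyr::bind_rows(sweeps)
  df <- add_sweep_noise(df, noise_sd, seed)
  finish_clamp_set(df, params, protocol, seed, cell_id, condition)
}

# epochs of a plain step sweep
clamp_epochs <- function(protocol, v_step) {
  tibble::tibble(
    epoch = c("baseline", "step"),
    v = c(protocol$holding_mV, v_step),
    dur = c(protocol$baseline_ms, protocol$step_duration_ms)
  )
}

# exact piecewise-analytic current trace over a sequence of constant-voltage
# epochs; gates start at steady state for the first epoch's voltage
clamp_current_trace <- function(params, segments, rate_khz) {
  p <- params
  pf <- p$persistent_frac
  m0 <- gate_minf(p, segments$v[1])
  h0 <- gate_hinf(p, segments$v[1])
  out <- vector("list", nrow(segments))
  t_offset <- 0
  for (i in seq_len(nrow(segments))) {
    v <- segments$v[i]
    dur <- segments$dur[i]
    t <- sweep_time_grid(dur, rate_khz)
    minf <- gate_minf(p, v)
    hinf <- gate_hinf(p, v)
    m <- if (p$tau_act == 0) rep(minf, length(t)) else
      minf + (m0 - minf) * exp(-t / p$tau_act)
    h <- h_relax(p, h0, hinf, t)
    h_eff <- pf + (1 - pf) * h
    i_na <- p$gmax * (v - p$vrev) * m^p$act_exponent * h_eff
    out[[i]] <- tibble::tibble(epoch = segments$epoch[i],
                               t_ms = t + t_offset, value = i_na)
    # carry end-of-epoch state forward
    m0 <- if (p$tau_act == 0) minf else minf + (m0 - minf) * exp(-dur / p$tau_act)
    h0 <- h_relax(p, h0, hinf, dur)
    t_offset <- t_offset + dur
  }
  dplyr::bind_rows(out)
}

gate_minf <- function(p, v) 1 / (1 + exp(-(v - p$act_vhalf) / p$act_k))
gate_hinf <- function(p, v) 1 / (1 + exp((v - p$inact_vhalf) / p$inact_k))

# h-gate relaxation from h0 toward the steady state of the epoch voltage.
# The kinetic regime is set by the voltage (through its steady state), not
# by the direction of relaxation: at depolarized potentials (h_inf < 0.5)
# the two-component inactivation mixture applies to every sweep alike, at
# hyperpolarized potentials the single recovery time constant does.
h_relax <- function(p, h0, target, t) {
  if (target >= 0.5) {
    target + (h0 - target) * exp(-t / p$recovery_tau)
  } else {
    decay <- p$slow_frac * exp(-t / p$tau_inact_slow) +
      (1 - p$slow_frac) * exp(-t / p$tau_inact_fast)
    target + (h0 - target) * decay
  }
}

finish_clamp_set <- function(df, params, protocol, seed, cell_id, condition) {
  df$cell_id <- cell_id
  df$condition <- condition
  df <- dplyr::select(df, "cell_id", "condition", "sweep", "command",
                      "epoch", "t_ms", "value")
  # numerically, conductance in uS times driving force in mV gives nA;
  # oocyte-scale gmax (~tens of uS) puts peaks on the uA scale
  units <- if (protocol$holding_mV <= -80) "uA" else "nA"
  new_sweep_set(df, signal_kind = "current", units = units,
                protocol = protocol, seed = seed, gen_params = params)
}
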