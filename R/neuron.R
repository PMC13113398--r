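#' Minimal conductance-based neuron for current-clamp simulation
#'
#' A single-compartment membrane carrying the Boltzmann-gated sodium
#' conductance of [gating_params()], a delayed-rectifier potassium
#' conductance with first-order activation, and a linear leak. This is the
#' smallest model able to reproduce repetitive firing of a large
#' invertebrate soma under square current injection; it does not attempt
#' calcium currents, adaptation or multi-compartment structure.
#'
#' In these units (capacitance nF, conductance uS, voltage mV, time ms) the
#' membrane equation `C dV/dt = -I_Na - I_K - I_leak + I_stim` balances with
#' currents in nA. The sodium inactivation time constant interpolates between
#' the fast decay tau (depolarized) and the recovery tau (hyperpolarized)
#' through `h_inf(V)`.
#'
#' @param c_nF Membrane capacitance, nF.
#' @param g_leak_uS,e_leak_mV Leak conductance (uS) and reversal (mV).
#' @param g_k_uS,e_k_mV Delayed-rectifier conductance (uS) and potassium
#'   reversal (mV).
#' @param k_vhalf,k_k,k_tau_ms Potassium activation midpoint (mV), slope
#'   (mV) and time constant (ms).
#' @param sodium A [gating_params()] object (patch scale, uS).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(c_nF = 1,
                          g_leak_uS = 0.04, e_leak_mV = -65,
                          g_k_uS = 2, e_k_mV = -75,
                          k_vhalf = -15, k_k = 9, k_tau_ms = 4,
                          sodium = gating_params(
                            gmax = 4, vrev = 55,
                            act_vhalf = -32, act_k = 3.5,
                            inact_vhalf = -40, inact_k = 6,
                            tau_act = 0.3,
                            tau_inact_fast = 2, tau_inact_slow = 10,
                            slow_frac = 0, persistent_frac = 0,
                            recovery_tau = 8
                          )) {
  stopifnot(c_nF > 0, g_leak_uS >= 0, g_k_uS >= 0, k_k > 0, k_tau_ms > 0)
  validate_gating_params(sodium)
  structure(
    list(c_nF = c_nF, g_leak_uS = g_leak_uS, e_leak_mV = e_leak_mV,
         g_k_uS = g_k_uS, e_k_mV = e_k_mV,
         k_vhalf = k_vhalf, k_k = k_k, k_tau_ms = k_tau_ms,
         sodium = sodium),
    class = "neuron_params"
  )
}

#' Simulate current-clamp step responses
#'
#' Integrates the membrane equation of a [neuron_params()] neuron under
#' square current injections with a fixed-step explicit (forward Euler)
#' scheme, `dt = 0.025 ms` by default. One sweep is produced per stimulus
#' amplitude; each sweep has a pre-stimulus baseline and a post-stimulus
#' tail at zero injected current, and the state is reset between sweeps
#' (sweeps are treated as independent, mirroring the seconds-long
#' interstimulus intervals of the recordings). The voltage is sampled at the
#' protocol rate. Output is deterministic given parameters and seed.
#'
#' @param neuron A [neuron_params()] object.
#' @param protocol A `CURRENT_CLAMP_STEPS` [protocol_spec()].
#' @param seed Integer seed, recorded in the result (used only when
#'   `noise_sd > 0`).
#' @param noise_sd Additive voltage noise as a fraction of the maximum
#'   absolute voltage (default 0: noise-free).
#' @param dt_ms Integration step, ms.
#' @param tail_ms Post-stimulus segment, ms.
#' @param cell_id,condition Labels.
#' @return A voltage `sweep_set`; `command` holds the stimulus amplitude in
#'   nA and `epoch` is `"baseline"`, `"stim"` or `"tail"`.
#' @export
#' @examples
#' sw <- simulate_current_clamp(neuron_params(), protocol_preset("helix_cc"),
#'                              seed = 1)
#' analyze_excitability(sw)
simulate_current_clamp <- function(neuron,
                                   protocol = protocol_preset("helix_cc"),
                                   seed = 1L, noise_sd = 0,
                                   dt_ms = 0.025, tail_ms = 50,
                                   cell_id = "cell1", condition = "control") {
  if (!inherits(neuron, "neuron_params")) {
    stop("`neuron` must be a neuron_params object", call. = FALSE)
  }
  if (protocol$kind != "CURRENT_CLAMP_STEPS") {
    stop("`protocol` must have kind CURRENT_CLAMP_STEPS", call. = FALSE)
  }
  sweeps <- purrr::imap(protocol$stim_amplitudes_nA, function(amp, i) {
    df <- integrate_cc_sweep(neuron, amp,
                             baseline_ms = protocol$baseline_ms,
                             stim_ms = protocol$stim_duration_ms,
                             tail_ms = tail_ms, dt_ms = dt_ms,
                             rate_khz = protocol$sample_rate_kHz)
    df$sweep <- i
    df$command <- amp
    df
  })
  df <- dplyr::bind_rows(sweeps)
  df <- add_sweep_noise(df, noise_sd, seed)
  df$cell_id <- cell_id
  df$condition <- condition
  df <- dplyr::select(df, "cell_id", "condition", "sweep", "command",
                      "epoch", "t_ms", "value")
  new_sweep_set(df, signal_kind = "voltage", units = "mV",
                protocol = protocol, seed = seed, gen_params = neuron)
}

integrate_cc_sweep <- function(neuron, amp_nA, baseline_ms, stim_ms, tail_ms,
                               dt_ms, rate_khz) {
  na <- neuron$sodium
  total_ms <- baseline_ms + stim_ms + tail_ms
  n_steps <- round(total_ms / dt_ms)
  sample_every <- max(1L, round(1 / (rate_khz * dt_ms)))

  # start from the leak reversal with gates at steady state; the baseline
  # segment lets the membrane settle to its true resting point
  v <- neuron$e_leak_mV
  m <- gate_minf(na, v)
  h <- gate_hinf(na, v)
  n <- 1 / (1 + exp(-(v - neuron$k_vhalf) / neuron$k_k))

  keep <- seq(1L, n_steps, by = sample_every)
  v_out <- numeric(length(keep))
  t_out <- numeric(length(keep))
  ki <- 1L
  stim_on <- baseline_ms
  stim_off <- baseline_ms + stim_ms
  for (s in seq_len(n_steps)) {
    t_now <- (s - 1) * dt_ms
    if (ki <= length(keep) && s == keep[ki]) {
      v_out[ki] <- v
      t_out[ki] <- t_now
      ki <- ki + 1L
    }
    i_stim <- if (t_now >= stim_on && t_now < stim_off) amp_nA else 0
    i_na <- na$gmax * m^na$act_exponent * h * (v - na$vrev)
    i_k <- neuron$g_k_uS * n * (v - neuron$e_k_mV)
    i_leak <- neuron$g_leak_uS * (v - neuron$e_leak_mV)
    dv <- (-i_na - i_k - i_leak + i_stim) / neuron$c_nF
    minf <- gate_minf(na, v)
    hinf <- gate_hinf(na, v)
    ninf <- 1 / (1 + exp(-(v - neuron$k_vhalf) / neuron$k_k))
    tau_m <- max(na$tau_act, dt_ms)
    tau_h <- na$tau_inact_fast + (na$recovery_tau - na$tau_inact_fast) * hinf
    v <- v + dt_ms * dv
    m <- m + dt_ms * (minf - m) / tau_m
    h <- h + dt_ms * (hinf - h) / tau_h
    n <- n + dt_ms * (ninf - n) / neuron$k_tau_ms
    if (!is.finite(v) || abs(v) > 200) {
      stop(sprintf(paste0("current-clamp integration unstable at t = %.2f ms",
                          " (V = %.1f mV); reduce dt_ms or check parameters"),
                   t_now, v), call. = FALSE)
    }
  }
  epoch <- ifelse(t_out < stim_on, "baseline",
                  ifelse(t_out < stim_off, "stim", "tail"))
  tibble::tibble(epoch = epoch, t_ms = t_out, value = v_out)
}
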