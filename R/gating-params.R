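#' Generative parameters of a Boltzmann-gated sodium conductance
#'
#' Bundles the quantities that define a voltage-gated sodium conductance in
#' the Hodgkin-Huxley sense: a maximal conductance, a reversal potential,
#' Boltzmann voltage dependences for the activation (m) and inactivation (h)
#' gates, and the time constants governing activation, two-component decay,
#' and recovery from inactivation. These are the generative counterparts of
#' the quantities the analysis side estimates (V1/2, k, Gmax, Vrev, decay
#' taus, recovery tau).
#'
#' @param gmax Maximal conductance, microsiemens (oocyte scale; use nS-scale
#'   values for patch presets). Must be positive.
#' @param vrev Reversal potential, mV.
#' @param act_vhalf,act_k Activation midpoint (mV) and slope factor (mV > 0).
#' @param inact_vhalf,inact_k Inactivation midpoint (mV) and slope factor
#'   (mV > 0).
#' @param tau_act Activation time constant, ms. `0` selects instantaneous
#'   activation (the gate tracks its steady state exactly), used for
#'   closed-form checks.
#' @param tau_inact_fast,tau_inact_slow Fast and slow inactivation decay time
#'   constants, ms; `tau_inact_fast < tau_inact_slow`.
#' @param slow_frac Weight of the slow decay component, in `[0, 1]`.
#' @param persistent_frac Non-inactivating fraction of the conductance, in
#'   `[0, 1)`. A value of 0.1 leaves a 10 % residual current at the end of a
#'   long depolarizing step.
#' @param recovery_tau Time constant of recovery from inactivation at the
#'   holding potential, ms.
#' @param act_exponent Integer gate exponent p (1, 2 or 3). The default 1
#'   makes the Boltzmann fit of the resulting conductance an unbiased
#'   estimator of `act_vhalf`/`act_k`; with p > 1 the apparent midpoint of
#'   m^p is displaced positive relative to `act_vhalf`.
#'
#' @return An object of class `gating_params` (a validated named list).
#' @export
#' @examples
#' p <- gating_params(gmax = 10, vrev = 50, act_vhalf = -25, act_k = 5)
#' steady_state_gates(p, seq(-80, 40, 10))
gating_params <- function(gmax = 10, vrev = 50,
                          act_vhalf = -25, act_k = 5,
                          inact_vhalf = -35, inact_k = 6,
                          tau_act = 0.5,
                          tau_inact_fast = 1.5, tau_inact_slow = 8,
                          slow_frac = 0.2,
                          persistent_frac = 0,
                          recovery_tau = 10,
                          act_exponent = 1L) {
  p <- structure(
    list(
      gmax = gmax, vrev = vrev,
      act_vhalf = act_vhalf, act_k = act_k,
      inact_vhalf = inact_vhalf, inact_k = inact_k,
      tau_act = tau_act,
      tau_inact_fast = tau_inact_fast, tau_inact_slow = tau_inact_slow,
      slow_frac = slow_frac,
      persistent_frac = persistent_frac,
      recovery_tau = recovery_tau,
      act_exponent = as.integer(act_exponent)
    ),
    class = "gating_params"
  )
  validate_gating_params(p)
}

#' @export
print.gating_params <- function(x, ...) {
  cat("<gating_params>\n")
  cat(sprintf("  gmax %.4g, vrev %+.4g mV, gate exponent p = %d\n",
              x$gmax, x$vrev, x$act_exponent))
  cat(sprintf("  activation:   V1/2 %+.4g mV, k %.4g mV, tau %.4g ms\n",
              x$act_vhalf, x$act_k, x$tau_act))
  cat(sprintf("  inactivation: V1/2 %+.4g mV, k %.4g mV, tau_f %.4g / tau_s %.4g ms (slow frac %.3g)\n",
              x$inact_vhalf, x$inact_k, x$tau_inact_fast, x$tau_inact_slow,
              x$slow_frac))
  cat(sprintf("  persistent fraction %.3g, recovery tau %.4g ms\n",
              x$persistent_frac, x$recovery_tau))
  invisible(x)
}

validate_gating_params <- function(p) {
  fail <- function(field, why) {
    stop("invalid gating_params: `", field, "` ", why, call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a finite number")
    }
    v
  }
  if (num1("gmax") <= 0) fail("gmax", "must be > 0")
  num1("vrev")
  num1("act_vhalf"); num1("inact_vhalf")
  if (num1("act_k") <= 0) fail("act_k", "must be > 0")
  if (num1("inact_k") <= 0) fail("inact_k", "must be > 0")
  if (num1("tau_act") < 0) fail("tau_act", "must be >= 0 (0 = instantaneous)")
  if (num1("tau_inact_fast") <= 0) fail("tau_inact_fast", "must be > 0")
  if (num1("tau_inact_slow") <= 0) fail("tau_inact_slow", "must be > 0")
  if (p$tau_inact_fast >= p$tau_inact_slow) {
    fail("tau_inact_fast", "must be < tau_inact_slow")
  }
  if (num1("slow_frac") < 0 || p$slow_frac > 1) fail("slow_frac", "must be in [0, 1]")
  if (num1("persistent_frac") < 0 || p$persistent_frac >= 1) {
    fail("persistent_frac", "must be in [0, 1)")
  }
  if (num1("recovery_tau") <= 0) fail("recovery_tau", "must be > 0")
  if (!p$act_exponent %in% 1:3) fail("act_exponent", "must be 1, 2 or 3")
  p
}

#' Steady-state activation and inactivation of the two gates
#'
#' Evaluates the Boltzmann steady states of the activation gate,
#' `m_inf(V) = 1 / (1 + exp(-(V - act_vhalf) / act_k))`, and of the
#' inactivation gate, `h_inf(V) = 1 / (1 + exp((V - inact_vhalf) / inact_k))`.
#' `m_inf` is strictly increasing and `h_inf` strictly decreasing in voltage.
#'
#' @param params A [gating_params()] object.
#' @param v Membrane voltage(s), mV.
#' @return A tibble with columns `v`, `m_inf`, `h_inf`.
#' @export
steady_state_gates <- function(params, v) {
  validate_gating_params(params)
  stopifnot(is.numeric(v))
  tibble::tibble(
    v = v,
    m_inf = 1 / (1 + exp(-(v - params$act_vhalf) / params$act_k)),
    h_inf = 1 / (1 + exp((v - params$inact_vhalf) / params$inact_k))
  )
}

#' Describe a toxin exposure as a perturbation of the gating parameters
#'
#' A toxin condition is modelled generatively: midpoints shift additively,
#' slope factors, conductance and time constants scale multiplicatively, and
#' the persistent fraction changes additively. This covers the effect classes
#' seen for scorpion alpha- and beta-toxins on sodium channels: V1/2
#' displacements, voltage-sensitivity changes, conductance block, slowed or
#' incomplete inactivation, and recovery deficits.
#'
#' @param label Condition name (e.g. `"Tch3"`).
#' @param exposure_min Exposure time in minutes (metadata).
#' @param d_act_vhalf,d_inact_vhalf Additive midpoint shifts, mV.
#' @param scale_act_k,scale_inact_k Multiplicative slope-factor scales (> 0).
#' @param scale_gmax Conductance scale (> 0).
#' @param scale_tau_fast,scale_tau_slow Decay-tau scales (> 0).
#' @param d_persistent_frac Additive change to the persistent fraction.
#' @param scale_recovery_tau Recovery-tau scale (> 0).
#' @return An object of class `toxin_effect`.
#' @export
#' @examples
#' # a depressant beta-toxin-like profile: positive activation shift,
#' # strong negative inactivation shift, halved conductance
#' tch3 <- toxin_effect("Tch3", exposure_min = 20,
#'                      d_act_vhalf = 3.94, d_inact_vhalf = -19.36,
#'                      scale_gmax = 0.5)
#' apply_toxin(gating_params(), tch3)
toxin_effect <- function(label, exposure_min = 0,
                         d_act_vhalf = 0, d_inact_vhalf = 0,
                         scale_act_k = 1, scale_inact_k = 1,
                         scale_gmax = 1,
                         scale_tau_fast = 1, scale_tau_slow = 1,
                         d_persistent_frac = 0,
                         scale_recovery_tau = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  structure(
    list(
      label = label, exposure_min = exposure_min,
      d_act_vhalf = d_act_vhalf, d_inact_vhalf = d_inact_vhalf,
      scale_act_k = scale_act_k, scale_inact_k = scale_inact_k,
      scale_gmax = scale_gmax,
      scale_tau_fast = scale_tau_fast, scale_tau_slow = scale_tau_slow,
      d_persistent_frac = d_persistent_frac,
      scale_recovery_tau = scale_recovery_tau
    ),
    class = "toxin_effect"
  )
}

#' Apply a toxin effect to gating parameters
#'
#' Additive fields are added, scale fields multiplied. The perturbed
#' parameter set is re-validated; a perturbation that drives any parameter
#' out of its admissible range (for example `scale_gmax = 0`) is rejected
#' with an error naming the violated field.
#'
#' @param params A [gating_params()] object.
#' @param effect A [toxin_effect()] object.
#' @return A new `gating_params` object.
#' @export
apply_toxin <- function(params, effect) {
  validate_gating_params(params)
  if (!inherits(effect, "toxin_effect")) {
    stop("`effect` must be a toxin_effect object", call. = FALSE)
  }
  out <- params
  out$act_vhalf <- params$act_vhalf + effect$d_act_vhalf
  out$inact_vhalf <- params$inact_vhalf + effect$d_inact_vhalf
  out$act_k <- params$act_k * effect$scale_act_k
  out$inact_k <- params$inact_k * effect$scale_inact_k
  out$gmax <- params$gmax * effect$scale_gmax
  out$tau_inact_fast <- params$tau_inact_fast * effect$scale_tau_fast
  out$tau_inact_slow <- params$tau_inact_slow * effect$scale_tau_slow
  out$persistent_frac <- params$persistent_frac + effect$d_persistent_frac
  out$recovery_tau <- params$recovery_tau * effect$scale_recovery_tau
  validate_gating_params(out)
}
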