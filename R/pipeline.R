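#' One-call gating analysis of a voltage-clamp sweep set
#'
#' @description
#' `analyze_iv()` runs the full activation pipeline on an I-V family:
#' peak extraction, reversal-potential estimate (unless supplied),
#' conductance transform and Boltzmann activation fit.
#' `analyze_ssi()` runs the inactivation pipeline on a two-step set:
#' test-pulse peak extraction and Boltzmann inactivation fit.
#'
#' @param sweeps A current `sweep_set` (`IV_STEP` or `SSI_TWO_STEP`).
#' @param vrev Reversal potential, mV; estimated from the data with
#'   [estimate_vrev()] when `NULL`.
#' @param blank_ms,polarity,window_ms Passed to [extract_peaks()];
#'   `analyze_iv()` defaults to the signed absolute extremum within a 20 ms
#'   window, which handles the sign change at the reversal potential.
#' @param exclusion_mV Passed to [conductance()]; `analyze_iv()` widens the
#'   default to 5 mV because its reversal potential is itself estimated
#'   from noisy peaks, so points within one step of it carry unbounded
#'   relative error.
#' @param amplitude Amplitude measure. For `analyze_iv()`,
#'   `"extrapolated"` (default) reconstructs inactivation-corrected onset
#'   amplitudes via [extract_amplitudes()] and `"peak"` uses raw peaks.
#'   For `analyze_ssi()`, `"level"` (default) uses fixed-window test-pulse
#'   levels ([extract_ssi_levels()]), which are exactly affine in prepulse
#'   availability and therefore give an unbiased midpoint with a floor
#'   term; the other two options behave as in `analyze_iv()`.
#' @param floor Passed to [fit_inactivation()]; default `NULL` enables the
#'   floor exactly when the `"level"` measure is used.
#' @param fixed_amplitude Optional fixed Boltzmann amplitude for the
#'   inactivation fit (see [fit_inactivation()]): in paired recordings the
#'   treated condition can inherit the control cell's fitted amplitude.
#' @param floor Passed to [fit_inactivation()].
#' @return `analyze_iv()`: a list with `iv` (peak table), `vrev`, `g`
#'   (conductance table) and `fit` (activation `boltzmann_fit`).
#'   `analyze_ssi()`: a list with `peaks` and `fit` (inactivation
#'   `boltzmann_fit`).
#' @export
#' @examples
#' p <- gating_params()
#' sw <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0, seed = 1)
#' analyze_iv(sw)$fit
analyze_iv <- function(sweeps, vrev = NULL, blank_ms = 0.2,
                       polarity = "absolute", exclusion_mV = 5,
                       window_ms = 20,
                       amplitude = c("extrapolated", "peak")) {
  amplitude <- match.arg(amplitude)
  iv <- if (amplitude == "extrapolated") {
    extract_amplitudes(sweeps, epoch = "step")
  } else {
    extract_peaks(sweeps, epoch = "step", blank_ms = blank_ms,
                  polarity = polarity, window_ms = window_ms)
  }
  if (is.null(vrev)) vrev <- estimate_vrev(iv)
  g <- conductance(iv, vrev = vrev, exclusion_mV = exclusion_mV)
  fit <- fit_activation(g, weights = (g$step_mV - vrev)^2)
  list(iv = iv, vrev = vrev, g = g, fit = fit)
}

#' @rdname analyze_iv
#' @export
analyze_ssi <- function(sweeps, blank_ms = 0.2, polarity = "inward",
                        floor = NULL, window_ms = 20,
                        amplitude = c("level", "extrapolated", "peak"),
                        fixed_amplitude = NULL) {
  amplitude <- match.arg(amplitude)
  peaks <- switch(
    amplitude,
    level = extract_ssi_levels(sweeps),
    extrapolated = extract_amplitudes(sweeps, epoch = "test"),
    peak = extract_peaks(sweeps, epoch = "test", blank_ms = blank_ms,
                         polarity = polarity, window_ms = window_ms)
  )
  # the fixed-window level sits on a non-zero pedestal (see
  # extract_ssi_levels), so its fit needs the floor term
  if (is.null(floor)) floor <- amplitude == "level"
  fit <- fit_inactivation(peaks, floor = floor,
                          amplitude = fixed_amplitude)
  list(peaks = peaks, fit = fit)
}

#' Per-cell gating summary across paired conditions
#'
#' Condenses the fitted gating quantities of one cell and condition into a
#' single row, the unit the condition-level report works on.
#'
#' @param cell_id,condition Labels.
#' @param act,inact `boltzmann_fit` objects (activation / inactivation);
#'   either may be `NULL`.
#' @param gmax_fit A `gmax_fit` object, or `NULL`.
#' @param window A `window_result`, or `NULL`.
#' @param decay A `decay_fit`, or `NULL`.
#' @param persistent Persistent fraction, or `NA`.
#' @return A one-row tibble with columns `cell_id`, `condition`,
#'   `act_vhalf`, `act_k`, `inact_vhalf`, `inact_k`, `gmax`, `vrev`,
#'   `window_area`, `tau_fast`, `tau_slow`, `persistent_frac`.
#' @export
gating_summary <- function(cell_id, condition, act = NULL, inact = NULL,
                           gmax_fit = NULL, window = NULL, decay = NULL,
                           persistent = NA_real_) {
  tibble::tibble(
    cell_id = cell_id, condition = condition,
    act_vhalf = if (is.null(act)) NA_real_ else act$vhalf,
    act_k = if (is.null(act)) NA_real_ else act$k,
    inact_vhalf = if (is.null(inact)) NA_real_ else inact$vhalf,
    inact_k = if (is.null(inact)) NA_real_ else inact$k,
    gmax = if (is.null(gmax_fit)) NA_real_ else gmax_fit$gmax,
    vrev = if (is.null(gmax_fit)) NA_real_ else gmax_fit$vrev,
    window_area = if (is.null(window)) NA_real_ else window$area,
    tau_fast = if (is.null(decay)) NA_real_ else decay$tau_fast,
    tau_slow = if (is.null(decay)) NA_real_ else decay$tau_slow,
    persistent_frac = persistent
  )
}

#' Thresholds for the heuristic effect labelling
#'
#' The label rules mirror the pharmacological taxonomy of scorpion
#' sodium-channel toxins: alpha-like toxins slow or remove fast
#' inactivation; beta-like excitatory toxins shift activation to more
#' negative voltages; beta-like depressant toxins shift activation positive
#' and depress the maximal conductance. The rules are heuristics over fitted
#' deltas, and every threshold is exposed here.
#'
#' @param alpha_tau_fold Minimum fast-tau fold change for `alpha-like`.
#' @param alpha_persistent Minimum persistent-fraction increase for
#'   `alpha-like`.
#' @param beta_excit_shift Maximum (most positive) activation shift, mV, for
#'   `beta-like-excitatory` (default -3: at least 3 mV hyperpolarizing).
#' @param beta_depress_shift Minimum activation shift, mV, for
#'   `beta-like-depressant`.
#' @param beta_depress_gmax Maximum Gmax ratio for `beta-like-depressant`.
#' @return A named list of thresholds.
#' @export
report_rules <- function(alpha_tau_fold = 2, alpha_persistent = 0.05,
                         beta_excit_shift = -3, beta_depress_shift = 3,
                         beta_depress_gmax = 0.8) {
  list(alpha_tau_fold = alpha_tau_fold, alpha_persistent = alpha_persistent,
       beta_excit_shift = beta_excit_shift,
       beta_depress_shift = beta_depress_shift,
       beta_depress_gmax = beta_depress_gmax)
}

#' Condition-level report of toxin effects
#'
#' Summarizes paired control/treated gating summaries into the deltas and
#' ratios a pharmacologist reads off a toxin experiment — V1/2 shifts, slope
#' ratios, Gmax ratio, window-area ratio, tau fold changes, persistent
#' fraction change — and assigns a heuristic effect label from
#' [report_rules()].
#'
#' @param control,treated Tibbles of [gating_summary()] rows (one per cell),
#'   paired by `cell_id`.
#' @param rules A [report_rules()] list.
#' @return A list of class `condition_report`: `deltas` (one-row tibble of
#'   the summary quantities), `extra_deltas` (mean differences of any
#'   further shared numeric columns, e.g. per-interpulse recovery or
#'   per-stimulus firing frequency), `label`, `rules`, `n_cells`.
#' @export
#' @examples
#' ctl <- gating_summary("c1", "control",
#'                       act = fit_boltzmann_exact(-30, 5, "activation"))
#' trt <- gating_summary("c1", "toxin",
#'                       act = fit_boltzmann_exact(-26, 5, "activation"))
#' build_condition_report(ctl, trt)$deltas$d_act_vhalf
build_condition_report <- function(control, treated, rules = report_rules()) {
  stopifnot(is.data.frame(control), is.data.frame(treated))
  m <- dplyr::inner_join(control, treated, by = "cell_id",
                         suffix = c("_ctl", "_trt"))
  if (nrow(m) == 0) stop("no matched cells between conditions", call. = FALSE)
  mdiff <- function(col) {
    mean(m[[paste0(col, "_trt")]] - m[[paste0(col, "_ctl")]], na.rm = TRUE)
  }
  mratio <- function(col) {
    ctl <- m[[paste0(col, "_ctl")]]; trt <- m[[paste0(col, "_trt")]]
    ok <- is.finite(ctl) & is.finite(trt) & ctl > 0 & trt > 0
    if (!any(ok)) return(NA_real_)
    exp(mean(log(trt[ok] / ctl[ok])))
  }
  deltas <- tibble::tibble(
    d_act_vhalf = mdiff("act_vhalf"),
    d_inact_vhalf = mdiff("inact_vhalf"),
    act_k_ratio = mratio("act_k"),
    inact_k_ratio = mratio("inact_k"),
    gmax_ratio = mratio("gmax"),
    window_ratio = mratio("window_area"),
    tau_fast_fold = mratio("tau_fast"),
    tau_slow_fold = mratio("tau_slow"),
    d_persistent = mdiff("persistent_frac")
  )
  # any further shared numeric columns (e.g. recovery_mean, mff_0.5)
  # are summarised as treated-minus-control mean differences
  std <- c("cell_id", "condition", "act_vhalf", "act_k", "inact_vhalf",
           "inact_k", "gmax", "vrev", "window_area", "tau_fast",
           "tau_slow", "persistent_frac")
  extra_cols <- setdiff(intersect(names(control), names(treated)), std)
  extra_cols <- extra_cols[vapply(control[extra_cols], is.numeric,
                                  logical(1))]
  extra <- if (length(extra_cols)) {
    tibble::as_tibble(lapply(stats::setNames(extra_cols, extra_cols),
                             mdiff))
  } else {
    NULL
  }
  fired <- character()
  if ((is.finite(deltas$tau_fast_fold) &&
       deltas$tau_fast_fold >= rules$alpha_tau_fold) ||
      (is.finite(deltas$d_persistent) &&
       deltas$d_persistent >= rules$alpha_persistent)) {
    fired <- c(fired, "alpha-like")
  }
  if (is.finite(deltas$d_act_vhalf) &&
      deltas$d_act_vhalf <= rules$beta_excit_shift) {
    fired <- c(fired, "beta-like-excitatory")
  }
  if (is.finite(deltas$d_act_vhalf) &&
      deltas$d_act_vhalf >= rules$beta_depress_shift &&
      is.finite(deltas$gmax_ratio) &&
      deltas$gmax_ratio <= rules$beta_depress_gmax) {
    fired <- c(fired, "beta-like-depressant")
  }
  label <- if (length(fired) == 0) "none"
  else if (length(fired) == 1) fired
  else "mixed"
  structure(
    list(deltas = deltas, extra_deltas = extra, label = label,
         fired = fired, rules = rules, n_cells = nrow(m)),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %d matched cell(s), label: %s\n",
              x$n_cells, x$label))
  d <- x$deltas
  cat(sprintf("  dV1/2 act %+.2f mV, inact %+.2f mV\n",
              d$d_act_vhalf, d$d_inact_vhalf))
  cat(sprintf("  k ratios act %.2f / inact %.2f, Gmax ratio %.2f, window ratio %.2f\n",
              d$act_k_ratio, d$inact_k_ratio, d$gmax_ratio, d$window_ratio))
  cat(sprintf("  tau folds fast %.2f / slow %.2f, persistent %+0.3f\n",
              d$tau_fast_fold, d$tau_slow_fold, d$d_persistent))
  invisible(x)
}

#' Shift-recovery experiment: inject a gating displacement, recover it
#'
#' The calibration experiment behind the package's parameter-recovery
#' claims: `n_cells` synthetic cells are simulated under the Helix voltage
#' protocols for a control condition and for a treated condition whose
#' gating parameters carry a [toxin_effect()]; each cell is pushed through
#' the full analysis chain (amplitude extraction, conductance transform and
#' activation fit, or SSI level fit), and the fitted midpoint displacement
#' treated-minus-control is reported per cell.
#'
#' @param effect A [toxin_effect()] describing the treated condition.
#' @param gate Which midpoint to recover: `"activation"` (I-V pipeline) or
#'   `"inactivation"` (SSI pipeline).
#' @param params Control [gating_params()].
#' @param protocol Protocol; defaults to the matching Helix preset.
#' @param n_cells Cells per condition.
#' @param noise_sd Trace noise level (fraction of max signal).
#' @param seed_base Integer; cell seeds are derived from it (control
#'   `seed_base + i`, treated `seed_base + 500 + i`).
#' @return A tibble with one row per cell (`cell`, `vhalf_control`,
#'   `vhalf_treated`, `shift`) plus the injected shift and its mean fitted
#'   estimate in attributes `injected` and `mean_shift`.
#' @export
#' @examples
#' \donttest{
#' eff <- toxin_effect("Tch3", 20, d_act_vhalf = 3.94)
#' r <- recover_shift(eff, "activation", n_cells = 2)
#' attr(r, "mean_shift")
#' }
recover_shift <- function(effect, gate = c("activation", "inactivation"),
                          params = gating_params(), protocol = NULL,
                          n_cells = 6, noise_sd = 0.02, seed_base = 0L) {
  gate <- match.arg(gate)
  treated <- apply_toxin(params, effect)
  if (is.null(protocol)) {
    protocol <- protocol_preset(if (gate == "activation") "helix_iv"
                                else "helix_ssi")
  }
  one <- function(par, s) {
    if (gate == "activation") {
      analyze_iv(simulate_iv(par, protocol, noise_sd = noise_sd,
                             seed = s))$fit$vhalf
    } else {
      analyze_ssi(simulate_ssi(par, protocol, noise_sd = noise_sd,
                               seed = s))$fit$vhalf
    }
  }
  rows <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tibble::tibble(
      cell = i,
      vhalf_control = one(params, seed_base + i),
      vhalf_treated = one(treated, seed_base + 500L + i)
    )
  })
  rows$shift <- rows$vhalf_treated - rows$vhalf_control
  injected <- if (gate == "activation") effect$d_act_vhalf
  else effect$d_inact_vhalf
  attr(rows, "injected") <- injected
  attr(rows, "mean_shift") <- mean(rows$shift)
  rows
}

#' Maximal-conductance recovery experiment
#'
#' Simulates paired control and conductance-scaled I-V families under the
#' oocyte protocol, fits each with the full Boltzmann I-V relation
#' ([fit_iv_gmax()]), and reports the percent decrease in mean fitted Gmax.
#'
#' @param scale_gmax Generative conductance scale of the treated condition.
#' @param params Control [gating_params()] (oocyte scale).
#' @param n_cells,noise_sd,seed_base As in [recover_shift()].
#' @return A list: `gmax_control`, `gmax_treated` (per-cell vectors) and
#'   `pct_decrease` (100 x (1 - mean treated / mean control)).
#' @export
recover_gmax_decrease <- function(scale_gmax = 0.5,
                                  params = gating_params(gmax = 100),
                                  n_cells = 6, noise_sd = 0.01,
                                  seed_base = 0L) {
  treated <- apply_toxin(params, toxin_effect("venom",
                                              scale_gmax = scale_gmax))
  proto <- protocol_preset("oocyte_iv")
  one <- function(par, s) {
    sw <- simulate_iv(par, proto, noise_sd = noise_sd, seed = s)
    fit_iv_gmax(extract_amplitudes(sw))$gmax
  }
  gc_ <- vapply(seq_len(n_cells), function(i) one(params, seed_base + i),
                numeric(1))
  gt <- vapply(seq_len(n_cells), function(i) one(treated, seed_base + 500L + i),
               numeric(1))
  list(gmax_control = gc_, gmax_treated = gt,
       pct_decrease = 100 * (1 - mean(gt) / mean(gc_)))
}
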