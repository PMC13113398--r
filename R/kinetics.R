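#' Two-component exponential fit of current decay
#'
#' Fits the decaying phase of a current trace with
#' `I(t) = a_f exp(-(t - t0)/tau_f) + a_s exp(-(t - t0)/tau_s) + c`
#' over the window `[t_start, t_end]`, using a deterministic multi-start
#' grid (`tau_f` in 0.5/1/2 ms by `tau_s` in 5/10/20 ms, rescaled to the
#' window length) and post-fit ordering so that `tau_f < tau_s` always holds
#' regardless of starting values. A single exponential
#' `a exp(-(t - t0)/tau) + c` is fitted alongside, and the simpler model is
#' kept unless the two-component model is favoured by a small-sample
#' corrected information criterion (AICc) difference greater than 2 — this
#' avoids degenerate twin-tau fits on clean single-exponential decays. A
#' near-constant trace is flagged non-decaying.
#'
#' @param trace A data frame with columns `t_ms` and `value` (one sweep), or
#'   a `sweep_set` filtered to one sweep.
#' @param t_start Window start, ms — typically the time of peak.
#' @param t_end Window end, ms — typically the end of the step.
#' @return A `decay_fit` object: `a_fast`, `a_slow`, `tau_fast`, `tau_slow`,
#'   `offset`, `model` (`"biexponential"` or `"single_exponential"`), `rms`,
#'   `converged`, `non_decaying`, `window`.
#' @export
fit_decay <- function(trace, t_start, t_end) {
  stopifnot(is.data.frame(trace), all(c("t_ms", "value") %in% names(trace)))
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  d <- trace[trace$t_ms >= t_start & trace$t_ms <= t_end, , drop = FALSE]
  if (nrow(d) < 50) stop("fit window holds fewer than 50 samples", call. = FALSE)
  s <- d$t_ms - t_start
  y <- d$value
  n <- length(y)

  out_flat <- function() {
    structure(
      list(a_fast = 0, a_slow = 0, tau_fast = NA_real_, tau_slow = NA_real_,
           offset = mean(y), model = "single_exponential", rms = stats::sd(y),
           converged = TRUE, non_decaying = TRUE,
           window = c(t_start, t_end), data = tibble::tibble(t = s, y = y)),
      class = "decay_fit"
    )
  }
  amp0 <- y[1] - y[n]
  if (abs(amp0) < 1e-9 * max(abs(y), 1e-300) || stats::sd(y) < 1e-15) {
    return(out_flat())
  }

  aicc <- function(rss, k) {
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  span <- t_end - t_start
  scale_tau <- span / 50  # grid tuned for a ~50 ms window; rescale with it
  tf_grid <- c(0.5, 1, 2) * max(scale_tau, 1)
  ts_grid <- c(5, 10, 20) * max(scale_tau, 1)

  single <- run_multistart_nls(
    y ~ a * exp(-s / tau) + c0,
    data = data.frame(s = s, y = y),
    starts = lapply(c(tf_grid, ts_grid), function(tau0) {
      list(a = amp0, tau = tau0, c0 = y[n])
    }),
    lower = c(a = -Inf, tau = 1e-3, c0 = -Inf),
    upper = c(a = Inf, tau = Inf, c0 = Inf)
  )
  bi_starts <- purrr::pmap(expand.grid(tf = tf_grid, ts = ts_grid),
                           function(tf, ts) {
                             list(a1 = amp0 / 2, a2 = amp0 / 2,
                                  tf = tf, ts = ts, c0 = y[n])
                           })
  bi <- run_multistart_nls(
    y ~ a1 * exp(-s / tf) + a2 * exp(-s / ts) + c0,
    data = data.frame(s = s, y = y), starts = bi_starts,
    lower = c(a1 = -Inf, a2 = -Inf, tf = 1e-3, ts = 1e-3, c0 = -Inf),
    upper = c(a1 = Inf, a2 = Inf, tf = Inf, ts = Inf, c0 = Inf)
  )

  # a constant competes too: a trace whose wiggles are pure noise must not
  # be awarded spurious decay components
  rss_const <- sum((y - mean(y))^2)
  aicc_const <- aicc(rss_const, 1)
  aicc_single <- if (is.null(single)) Inf else aicc(single$rss, 3)
  aicc_bi <- if (is.null(bi)) Inf else aicc(bi$rss, 5)
  if (aicc_const <= min(aicc_single, aicc_bi) + 2) {
    return(out_flat())
  }
  use_bi <- !is.null(bi) &&
    (is.null(single) || aicc_single - aicc_bi > 2)
  if (use_bi) {
    cf <- stats::coef(bi$fit)
    tf <- cf[["tf"]]; ts <- cf[["ts"]]; af <- cf[["a1"]]; as_ <- cf[["a2"]]
    if (tf > ts) {  # canonical ordering, independent of starting guesses
      tmp <- tf; tf <- ts; ts <- tmp
      tmp <- af; af <- as_; as_ <- tmp
    }
    res <- list(a_fast = af, a_slow = as_, tau_fast = tf, tau_slow = ts,
                offset = cf[["c0"]], model = "biexponential",
                rms = sqrt(bi$rss / n), converged = TRUE,
                non_decaying = FALSE)
  } else if (!is.null(single)) {
    cf <- stats::coef(single$fit)
    res <- list(a_fast = cf[["a"]], a_slow = 0, tau_fast = cf[["tau"]],
                tau_slow = NA_real_, offset = cf[["c0"]],
                model = "single_exponential",
                rms = sqrt(single$rss / n), converged = TRUE,
                non_decaying = FALSE)
  } else {
    res <- list(a_fast = NA_real_, a_slow = NA_real_, tau_fast = NA_real_,
                tau_slow = NA_real_, offset = NA_real_,
                model = "single_exponential", rms = NA_real_,
                converged = FALSE, non_decaying = FALSE)
  }
  res$window <- c(t_start, t_end)
  res$data <- tibble::tibble(t = s, y = y)
  structure(res, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s%s%s\n", x$model,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$non_decaying) "  [non-decaying]" else ""))
  if (x$model == "biexponential") {
    cat(sprintf("  tau_fast = %.3g ms (a = %.3g), tau_slow = %.3g ms (a = %.3g)\n",
                x$tau_fast, x$a_fast, x$tau_slow, x$a_slow))
  } else {
    cat(sprintf("  tau = %.3g ms (a = %.3g)\n", x$tau_fast, x$a_fast))
  }
  cat(sprintf("  offset %.3g, rms %.3g\n", x$offset, x$rms))
  invisible(x)
}

#' Persistent (non-inactivating) current fraction
#'
#' The mean of the final `tail_frac` of the step window divided by the peak
#' current, both signed consistently. A non-inactivating current gives 1, a
#' fully inactivating one gives ~0.
#'
#' @param trace Data frame with `t_ms`, `value` covering the step window.
#' @param peak Peak current (signed). If `NULL`, the inward extremum of the
#'   trace is used.
#' @param window Length-2 vector `(start, end)` of the step, ms; defaults to
#'   the trace range.
#' @param tail_frac Final fraction of the window to average (default 0.1).
#' @return The persistent fraction (dimensionless); `NA` with a warning when
#'   the peak is indistinguishable from zero.
#' @export
persistent_fraction <- function(trace, peak = NULL, window = NULL,
                                tail_frac = 0.1) {
  stopifnot(is.data.frame(trace), all(c("t_ms", "value") %in% names(trace)))
  if (is.null(window)) window <- range(trace$t_ms)
  d <- trace[trace$t_ms >= window[1] & trace$t_ms <= window[2], , drop = FALSE]
  if (is.null(peak)) peak <- d$value[which.max(abs(d$value))]
  if (abs(peak) < 1e-12) {
    warning("peak is ~0: persistent fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  t_cut <- window[2] - tail_frac * diff(window)
  tail_mean <- mean(d$value[d$t_ms >= t_cut])
  tail_mean / peak
}

#' Recovery from inactivation: fraction recovered per interpulse interval
#'
#' For each sweep of a two-pulse recovery set, the peak of the second pulse
#' is divided by the peak of the first, giving the fraction of channels that
#' recovered from inactivation during the interpulse interval at holding.
#' Optionally a single-exponential recovery curve
#' `f(dt) = a - (a - f0) exp(-dt / tau)` is fitted.
#'
#' @param sweeps A `RECOVERY_TWO_PULSE` current `sweep_set` (the `command`
#'   column holds the interpulse interval in ms).
#' @param blank_ms,polarity Passed to [extract_peaks()].
#' @param fit Also fit the exponential recovery curve?
#' @return A tibble (class `recovery_curve`) with columns `interpulse_ms`,
#'   `peak1`, `peak2`, `fraction`; when `fit = TRUE` the fitted `tau`,
#'   asymptote `a` and intercept `f0` are stored in the `fit` attribute.
#' @export
recovery_fractions <- function(sweeps, blank_ms = 0.2, polarity = "inward",
                               fit = FALSE) {
  p1 <- extract_peaks(sweeps, epoch = "pulse1", blank_ms = blank_ms,
                      polarity = polarity)
  p2 <- extract_peaks(sweeps, epoch = "pulse2", blank_ms = blank_ms,
                      polarity = polarity)
  merged <- dplyr::inner_join(
    dplyr::select(p1, "sweep", interpulse_ms = "step_mV", peak1 = "peak"),
    dplyr::select(p2, "sweep", peak2 = "peak"),
    by = "sweep"
  )
  if (nrow(merged) < length(unique(sweeps$sweep))) {
    stop("missing pulse pair in at least one sweep", call. = FALSE)
  }
  out <- merged |>
    dplyr::mutate(fraction = .data$peak2 / .data$peak1) |>
    dplyr::arrange(.data$interpulse_ms) |>
    dplyr::select("interpulse_ms", "peak1", "peak2", "fraction")
  if (fit && nrow(out) >= 4) {
    fobj <- run_multistart_nls(
      fraction ~ a - (a - f0) * exp(-dt / tau),
      data = data.frame(dt = out$interpulse_ms, fraction = out$fraction),
      starts = lapply(c(5, 10, 20, 40), function(tau0) {
        list(a = max(out$fraction), f0 = min(out$fraction), tau = tau0)
      }),
      lower = c(a = 0, f0 = -1, tau = 1e-3),
      upper = c(a = 2, f0 = 1, tau = Inf)
    )
    if (!is.null(fobj)) {
      cf <- stats::coef(fobj$fit)
      attr(out, "fit") <- list(tau = cf[["tau"]], asymptote = cf[["a"]],
                               f0 = cf[["f0"]],
                               rms = sqrt(fobj$rss / nrow(out)))
    }
  }
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Fold change of decay time constants between paired conditions
#'
#' Computes the geometric mean fold change of the fast and slow decay time
#' constants across cell-paired control/treated decay fits, with paired
#' significance tests on the log time constants delegated to
#' [paired_compare()].
#'
#' @param control,treated Data frames with one row per cell and columns
#'   `cell_id`, `tau_fast`, `tau_slow` (e.g. built from [fit_decay()]
#'   results). Rows are paired by `cell_id`.
#' @return A tibble with one row per component: `component`, `fold`
#'   (geometric mean treated/control), `n`, plus the [paired_compare()]
#'   columns when `n >= 3`.
#' @export
fold_change <- function(control, treated) {
  need <- c("cell_id", "tau_fast", "tau_slow")
  stopifnot(all(need %in% names(control)), all(need %in% names(treated)))
  m <- dplyr::inner_join(control, treated, by = "cell_id",
                         suffix = c("_ctl", "_trt"))
  if (nrow(m) == 0) stop("no cells shared between conditions", call. = FALSE)
  if (nrow(m) < nrow(control) || nrow(m) < nrow(treated)) {
    stop("conditions are not fully paired by cell_id", call. = FALSE)
  }
  one <- function(component) {
    ctl <- m[[paste0(component, "_ctl")]]
    trt <- m[[paste0(component, "_trt")]]
    keep <- is.finite(ctl) & is.finite(trt) & ctl > 0 & trt > 0
    ctl <- ctl[keep]; trt <- trt[keep]
    fold <- exp(mean(log(trt / ctl)))
    row <- tibble::tibble(component = component, fold = fold,
                          n = length(ctl))
    if (length(ctl) >= 3) {
      row <- dplyr::bind_cols(row, paired_compare(log(trt), log(ctl)))
    }
    row
  }
  dplyr::bind_rows(one("tau_fast"), one("tau_slow"))
}

#' Step voltage of maximal treatment effect
#'
#' Decay kinetics are conventionally quantified at the voltage where the
#' treatment changes the current most. This is operationalised as the step
#' voltage maximising the absolute difference between treated and control
#' peak currents; pass `override` to pin a voltage instead.
#'
#' @param iv_control,iv_treated I-V tables from [extract_peaks()] (same
#'   step grid).
#' @param override Optional voltage, returned as-is.
#' @return A step voltage, mV.
#' @export
voltage_of_max_effect <- function(iv_control, iv_treated, override = NULL) {
  if (!is.null(override)) return(override)
  m <- dplyr::inner_join(
    dplyr::select(iv_control, "step_mV", peak_ctl = "peak"),
    dplyr::select(iv_treated, "step_mV", peak_trt = "peak"),
    by = "step_mV"
  )
  if (nrow(m) == 0) stop("no shared step voltages", call. = FALSE)
  m$step_mV[which.max(abs(m$peak_trt - m$peak_ctl))]
}
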