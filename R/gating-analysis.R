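#' Extract peak currents from a voltage-clamp sweep set
#'
#' For each sweep, the signed extremum of the chosen polarity within the
#' target epoch is located after blanking the first `blank_ms` of the epoch
#' (capacitive-transient guard). An all-flat sweep yields a peak of 0 with
#' its `flat` flag set and a warning.
#'
#' @param sweeps A current `sweep_set`.
#' @param epoch Epoch to search: `"step"` (I-V families, default), `"test"`
#'   (inactivation test pulses), `"pulse1"`/`"pulse2"` (recovery pairs).
#' @param blank_ms Blanking interval at the start of the epoch, ms.
#' @param polarity `"inward"` (minimum, default for sodium currents),
#'   `"outward"` (maximum) or `"absolute"` (signed extremum of largest
#'   magnitude — appropriate for I-V families that cross the reversal
#'   potential, where the current changes sign).
#' @param window_ms Length of the search window after blanking, ms
#'   (default `Inf`: the whole epoch). A bounded window emulates peak
#'   cursors placed around the expected time of peak and limits the
#'   extreme-value bias of searching long noisy traces.
#' @return An I-V tibble with one row per sweep: `sweep`, `step_mV` (the
#'   sweep's command value), `peak` (signed, signal units), `t_peak_ms`
#'   (absolute sweep time), `flat`.
#' @export
extract_peaks <- function(sweeps, epoch = "step", blank_ms = 0.2,
                          polarity = c("inward", "outward", "absolute"),
                          window_ms = Inf) {
  polarity <- match.arg(polarity)
  stopifnot(is.data.frame(sweeps))
  if (identical(attr(sweeps, "signal_kind"), "voltage")) {
    stop("`sweeps` must be a voltage-clamp (current) sweep set", call. = FALSE)
  }
  target <- epoch
  df <- dplyr::filter(sweeps, .data$epoch == target)
  if (nrow(df) == 0) {
    stop("no samples in epoch '", target, "'", call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$sweep, .data$command) |>
    dplyr::group_modify(function(d, key) {
      t0 <- min(d$t_ms)
      d <- d[d$t_ms >= t0 + blank_ms & d$t_ms <= t0 + blank_ms + window_ms, ,
             drop = FALSE]
      if (nrow(d) == 0) stop("blank_ms leaves an empty step window", call. = FALSE)
      flat <- max(abs(d$value)) < 1e-12
      if (flat) {
        return(tibble::tibble(peak = 0, t_peak_ms = t0, flat = TRUE))
      }
      i <- switch(polarity,
                  inward = which.min(d$value),
                  outward = which.max(d$value),
                  absolute = which.max(abs(d$value)))
      tibble::tibble(peak = d$value[i], t_peak_ms = d$t_ms[i], flat = FALSE)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(step_mV = "command") |>
    dplyr::arrange(.data$step_mV)
  if (any(out$flat)) warning("flat sweep(s): peak reported as 0", call. = FALSE)
  attr(out, "units") <- attr(sweeps, "units")
  attr(out, "polarity") <- polarity
  out
}

#' Inactivation-corrected I-V amplitudes by decay back-extrapolation
#'
#' The raw peak of a transient sodium current is contaminated by
#' inactivation: by the time the activation gate has opened, part of the
#' availability is already lost, and the lost fraction varies with voltage
#' through `h_inf(V)`, which biases Boltzmann fits of the peak conductance.
#' The classical correction extrapolates the decaying phase back to the
#' step onset, reconstructing the amplitude the current would have had with
#' instantaneous activation and no decay.
#'
#' Decay time constants of a channel population are shared across the
#' sweeps of a family, so the extrapolation is stabilised by a family-level
#' fit: two global time constants are optimised over all sweeps at once
#' while each sweep keeps its own fast/slow/steady amplitudes (solved
#' linearly given the taus — a variable-projection least squares). Each
#' sweep then reports `a_f exp(settle/tau_f) + a_s exp(settle/tau_s) + c`,
#' its fitted value extrapolated to the step onset. Noise-dominated sweeps
#' (near the reversal potential) get near-zero amplitudes from the linear
#' solve instead of the extreme-value-biased raw peak.
#'
#' @param sweeps A current `sweep_set`.
#' @param epoch Epoch holding the step, as in [extract_peaks()].
#' @param settle_ms Fit-window start after step onset, ms; should exceed
#'   ~3 activation time constants so the activation gate has settled.
#' @param fit_ms Fit-window length, ms.
#' @return An I-V tibble: `sweep`, `step_mV`, `peak` (the back-extrapolated
#'   onset amplitude, signed), `t_peak_ms` (window start), `flat`; the
#'   shared time constants are in the `taus` attribute.
#' @export
extract_amplitudes <- function(sweeps, epoch = "step", settle_ms = 1.5,
                               fit_ms = 40) {
  stopifnot(is.data.frame(sweeps))
  target <- epoch
  df <- dplyr::filter(sweeps, .data$epoch == target)
  if (nrow(df) == 0) stop("no samples in epoch '", target, "'", call. = FALSE)
  sw_split <- split(df, df$sweep)
  windows <- lapply(sw_split, function(d) {
    t0 <- min(d$t_ms)
    d <- d[d$t_ms >= t0 + settle_ms & d$t_ms <= t0 + settle_ms + fit_ms, ,
           drop = FALSE]
    list(u = d$t_ms - t0 - settle_ms, y = d$value,
         command = d$command[1], sweep = d$sweep[1], t0 = t0)
  })

  # variable projection: given (tau_f, tau_s), amplitudes are linear
  family_rss <- function(lt) {
    tf <- exp(lt[1]); ts <- exp(lt[2])
    if (ts <= tf * 1.05) return(1e300)
    sum(vapply(windows, function(w) {
      X <- cbind(exp(-w$u / tf), exp(-w$u / ts), 1)
      sum(stats::lm.fit(X, w$y)$residuals^2)
    }, numeric(1)))
  }
  span <- max(vapply(windows, function(w) max(w$u), numeric(1)))
  grid <- expand.grid(tf = c(0.5, 1.5, 4), ts = c(8, 20, span))
  grid <- grid[grid$ts > grid$tf * 2, ]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    o <- stats::optim(log(c(grid$tf[i], grid$ts[i])), family_rss,
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  tf <- exp(best$par[1]); ts <- exp(best$par[2])

  rows <- lapply(windows, function(w) {
    X <- cbind(exp(-w$u / tf), exp(-w$u / ts), 1)
    cf <- stats::lm.fit(X, w$y)$coefficients
    val <- cf[1] * exp(settle_ms / tf) + cf[2] * exp(settle_ms / ts) + cf[3]
    tibble::tibble(sweep = w$sweep, step_mV = w$command, peak = unname(val),
                   t_peak_ms = w$t0 + settle_ms,
                   flat = max(abs(w$y)) < 1e-12)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$step_mV)
  attr(out, "units") <- attr(sweeps, "units")
  attr(out, "taus") <- c(tau_fast = tf, tau_slow = ts)
  out
}

#' Fixed-window test-pulse levels for steady-state inactivation
#'
#' Averages the test-pulse current over a fixed early window (default 2 to
#' 6 ms after test onset, past the activation settling but before the decay
#' completes). Because every test pulse runs at the same voltage, the gate
#' kinetics during the window are identical across sweeps, and the level is
#' exactly affine in the prepulse-end availability:
#' `I = G h_inf_test (1 - d) + G d h_pre`, with `d` the mean decay factor
#' over the window. A Boltzmann fit with a free floor term
#' ([fit_inactivation()] with `floor = TRUE`) therefore recovers the
#' inactivation midpoint and slope without bias, while averaging ~dozens of
#' samples keeps the per-point noise far below that of a single peak.
#'
#' @param sweeps An `SSI_TWO_STEP` current `sweep_set`.
#' @param t_from,t_to Averaging window relative to test-pulse onset, ms.
#' @return An I-V tibble: `sweep`, `step_mV` (prepulse voltage), `peak`
#'   (mean windowed current, signed), `flat`.
#' @export
extract_ssi_levels <- function(sweeps, t_from = 2, t_to = 6) {
  stopifnot(is.data.frame(sweeps), t_to > t_from)
  df <- dplyr::filter(sweeps, .data$epoch == "test")
  if (nrow(df) == 0) stop("no samples in epoch 'test'", call. = FALSE)
  out <- df |>
    dplyr::group_by(.data$sweep, .data$command) |>
    dplyr::group_modify(function(d, key) {
      t0 <- min(d$t_ms)
      w <- d$value[d$t_ms >= t0 + t_from & d$t_ms <= t0 + t_to]
      if (length(w) == 0) stop("level window is empty", call. = FALSE)
      tibble::tibble(peak = mean(w), flat = max(abs(w)) < 1e-12)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(step_mV = "command") |>
    dplyr::arrange(.data$step_mV)
  attr(out, "units") <- attr(sweeps, "units")
  out
}

#' Conductance transform of an I-V table
#'
#' Computes `g = I_peak / (V - vrev)` for every step whose driving force
#' exceeds `exclusion_mV` in magnitude. Points within the exclusion window
#' around the reversal potential are flagged `excluded`, not dropped: the
#' quotient blows up there and would otherwise dominate any fit.
#'
#' @param iv An I-V table from [extract_peaks()] (columns `step_mV`, `peak`).
#' @param vrev Reversal potential, mV (measured or fitted).
#' @param exclusion_mV Half-width of the exclusion window around `vrev`.
#' @return The input with columns `g` (conductance, signal units per mV) and
#'   `excluded` added.
#' @export
conductance <- function(iv, vrev, exclusion_mV = 1) {
  stopifnot(is.data.frame(iv), all(c("step_mV", "peak") %in% names(iv)))
  if (!is.finite(vrev)) stop("`vrev` must be finite", call. = FALSE)
  drive <- iv$step_mV - vrev
  excluded <- abs(drive) <= exclusion_mV
  if (all(excluded)) {
    stop("all points within ", exclusion_mV, " mV of vrev = ", vrev,
         call. = FALSE)
  }
  iv$g <- ifelse(excluded, NA_real_, iv$peak / drive)
  iv$excluded <- excluded
  iv
}

#' Estimate the reversal potential from an I-V table
#'
#' Interpolates the zero crossing of the peak current on the ascending limb
#' (voltages above the peak-current voltage). When no sign change exists the
#' full Boltzmann I-V fit ([fit_iv_gmax()]) supplies `vrev`, flagged
#' `"fit-derived"` in the `source` attribute.
#'
#' @param iv An I-V table from [extract_peaks()].
#' @param temperature_K Passed to the fallback [fit_iv_gmax()].
#' @return Reversal potential in mV, with attribute `source` equal to
#'   `"zero-crossing"` or `"fit-derived"`.
#' @export
estimate_vrev <- function(iv, temperature_K = 294.15) {
  stopifnot(is.data.frame(iv), all(c("step_mV", "peak") %in% names(iv)))
  iv <- dplyr::arrange(iv, .data$step_mV)
  i_peak <- which.max(abs(iv$peak))
  asc <- iv[iv$step_mV >= iv$step_mV[i_peak], , drop = FALSE]
  s <- sign(asc$peak)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (length(flip) > 0) {
    i <- flip[1]
    v1 <- asc$step_mV[i]; v2 <- asc$step_mV[i + 1]
    y1 <- asc$peak[i]; y2 <- asc$peak[i + 1]
    vrev <- v1 - y1 * (v2 - v1) / (y2 - y1)
    attr(vrev, "source") <- "zero-crossing"
    return(vrev)
  }
  zero <- which(asc$peak == 0 & asc$step_mV > iv$step_mV[i_peak])
  if (length(zero) > 0) {
    vrev <- asc$step_mV[zero[1]]
    attr(vrev, "source") <- "zero-crossing"
    return(vrev)
  }
  fit <- fit_iv_gmax(iv, temperature_K = temperature_K)
  if (!fit$converged) {
    stop("no zero crossing on the ascending limb and the Boltzmann I-V fit ",
         "did not converge: reversal potential unavailable", call. = FALSE)
  }
  vrev <- fit$vrev
  attr(vrev, "source") <- "fit-derived"
  vrev
}

new_boltzmann_fit <- function(vhalf, k, amplitude, floor, rms, converged, n,
                              direction, data) {
  structure(
    list(vhalf = vhalf, k = k, amplitude = amplitude, floor = floor,
         rms = rms, converged = converged, n = n, direction = direction,
         data = data),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s%s\n", x$direction,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  V1/2 = %.3f mV, k = %.3f mV, amplitude = %.4g",
              x$vhalf, x$k, x$amplitude))
  if (!is.null(x$floor) && x$floor != 0) cat(sprintf(", floor = %.3g", x$floor))
  cat(sprintf("\n  rms residual %.3g on %d points\n", x$rms, x$n))
  invisible(x)
}

# deterministic multi-start voltages: interpolated 20/35/50/65/80 % rise
# points of the observed amplitude
vhalf_starts <- function(v, y) {
  rng <- range(y)
  targets <- rng[1] + c(0.2, 0.35, 0.5, 0.65, 0.8) * diff(rng)
  ord <- order(v)
  vapply(targets, function(tt) {
    stats::approx(y[ord], v[ord], xout = tt, ties = mean, rule = 2)$y
  }, numeric(1))
}

run_multistart_nls <- function(formula, data, starts, lower, upper,
                               weights = NULL) {
  best <- NULL
  if (is.null(weights)) weights <- rep(1, nrow(data))
  # nls resolves `weights` in the formula environment; bind it here
  environment(formula) <- environment()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper, weights = weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Boltzmann fit of steady-state activation
#'
#' Least-squares fit of `g(V) = A / (1 + exp(-(V - vhalf) / k))` to a
#' conductance table, with five deterministic multi-starts (midpoint started
#' at the interpolated 20/35/50/65/80 % rise voltages) and the slope factor
#' bounded to `[0.5, 30]` mV. The normalized open-probability curve `g / A`
#' is returned alongside. A monotone-decreasing input cannot be an
#' activation curve and is returned unconverged rather than silently
#' sign-flipped.
#'
#' @param g_table Output of [conductance()]; excluded rows are dropped.
#' @param normalize `"fitted_amplitude"` (default; Po = g divided by the
#'   fitted A, robust to a noisy extreme point) or `"max_g"` (Po = g /
#'   max g).
#' @param weights Optional per-point weights. Conductance points inherit a
#'   noise scale proportional to `1 / |V - vrev|` from the division by the
#'   driving force, so weighting by `(V - vrev)^2` (done by [analyze_iv()])
#'   restores least squares on the current scale.
#' @return A `boltzmann_fit` object (fields `vhalf`, `k`, `amplitude`,
#'   `rms`, `converged`, `n`, `direction`, and `data` with the fitted points
#'   and their `po` values). Use [tidy()] / [glance()] to extract tabular
#'   summaries.
#' @export
fit_activation <- function(g_table,
                           normalize = c("fitted_amplitude", "max_g"),
                           weights = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(g_table), all(c("step_mV", "g") %in% names(g_table)))
  keep <- !is.na(g_table$g) &
    (!("excluded" %in% names(g_table)) | !g_table$excluded)
  d <- g_table[keep, ]
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(g_table))
    weights <- weights[keep]
  }
  if (nrow(d) < 5) stop("need >= 5 usable conductance points", call. = FALSE)
  v <- d$step_mV; y <- d$g
  unconverged <- function() {
    new_boltzmann_fit(NA_real_, NA_real_, NA_real_, 0, NA_real_, FALSE,
                      length(v), "activation",
                      tibble::tibble(v = v, y = y, po = NA_real_))
  }
  # wrong-direction guard: activation must rise with voltage overall
  if (stats::cor(v, y) < 0) return(unconverged())
  starts <- lapply(vhalf_starts(v, y), function(v0) {
    list(A = max(y), vhalf = v0, k = 5)
  })
  best <- run_multistart_nls(
    y ~ A / (1 + exp(-(v - vhalf) / k)),
    data = data.frame(v = v, y = y), starts = starts,
    lower = c(A = 1e-12, vhalf = min(v) - 50, k = 0.5),
    upper = c(A = Inf, vhalf = max(v) + 50, k = 30),
    weights = weights
  )
  if (is.null(best)) return(unconverged())
  cf <- stats::coef(best$fit)
  amp_ref <- if (normalize == "fitted_amplitude") cf[["A"]] else max(y)
  new_boltzmann_fit(
    vhalf = cf[["vhalf"]], k = cf[["k"]], amplitude = cf[["A"]], floor = 0,
    rms = sqrt(best$rss / length(v)), converged = TRUE, n = length(v),
    direction = "activation",
    data = tibble::tibble(v = v, y = y, po = y / amp_ref)
  )
}

#' Boltzmann fit of steady-state inactivation
#'
#' Least-squares fit of `I(V) = c + A / (1 + exp((V - vhalf) / k))` to
#' test-pulse peaks against prepulse voltage. The floor term `c` captures
#' partial (incomplete) inactivation, where availability plateaus above zero
#' at depolarized prepulses; it is fitted only when `floor = TRUE`, and
#' fixed at 0 otherwise. Fitting is on the magnitude of the peaks, so inward
#' (negative) test currents can be passed directly.
#'
#' @param ssi_peaks I-V table of test-pulse peaks versus prepulse voltage
#'   (columns `step_mV`, `peak`), e.g. `extract_peaks(x, epoch = "test")`.
#' @param floor Fit a non-zero availability floor?
#' @param amplitude Optional fixed amplitude `A` (magnitude scale). In a
#'   paired recording the control and treated conditions share the cell's
#'   maximal test current, so fixing `A` at the control's fitted value
#'   identifies a treated curve whose hyperpolarized plateau lies outside
#'   the prepulse range (strong negative shifts).
#' @inherit fit_activation return
#' @export
fit_inactivation <- function(ssi_peaks, floor = FALSE, amplitude = NULL) {
  stopifnot(is.data.frame(ssi_peaks),
            all(c("step_mV", "peak") %in% names(ssi_peaks)))
  d <- ssi_peaks
  if (nrow(d) < 5) stop("need >= 5 points", call. = FALSE)
  v <- d$step_mV; y <- abs(d$peak)
  unconverged <- function() {
    new_boltzmann_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                      length(v), "inactivation",
                      tibble::tibble(v = v, y = y, po = NA_real_))
  }
  # inactivation availability must fall with prepulse voltage overall
  if (stats::cor(v, y) > 0) return(unconverged())
  fixed_A <- !is.null(amplitude)
  if (fixed_A) stopifnot(is.numeric(amplitude), amplitude > 0)
  starts <- lapply(vhalf_starts(v, y), function(v0) {
    st <- list(vhalf = v0, k = 6)
    if (!fixed_A) st <- c(list(A = max(y)), st)
    if (floor) st <- c(st, list(cc = 0))
    st
  })
  lo <- c(vhalf = min(v) - 50, k = 0.5)
  hi <- c(vhalf = max(v) + 50, k = 30)
  if (!fixed_A) { lo <- c(A = 1e-12, lo); hi <- c(A = Inf, hi) }
  if (floor) { lo <- c(lo, cc = 0); hi <- c(hi, cc = Inf) }
  rhs <- paste0(if (floor) "cc + " else "",
                if (fixed_A) "A0" else "A",
                " / (1 + exp((v - vhalf) / k))")
  fml <- stats::as.formula(paste("y ~", rhs))
  dat <- data.frame(v = v, y = y)
  if (fixed_A) dat$A0 <- amplitude
  best <- run_multistart_nls(fml, data = dat, starts = starts,
                             lower = lo, upper = hi)
  if (is.null(best)) return(unconverged())
  cf <- stats::coef(best$fit)
  cc <- if (floor) cf[["cc"]] else 0
  A_hat <- if (fixed_A) amplitude else cf[["A"]]
  new_boltzmann_fit(
    vhalf = cf[["vhalf"]], k = cf[["k"]], amplitude = A_hat, floor = cc,
    rms = sqrt(best$rss / length(v)), converged = TRUE, n = length(v),
    direction = "inactivation",
    data = tibble::tibble(v = v, y = y, po = (y - cc) / A_hat)
  )
}

#' Maximal conductance from the full Boltzmann I-V relation
#'
#' Fits the whole current-voltage relation with
#' `I(V) = Gmax (V - Vrev) / (1 + exp(-zact (V - V1/2) F / (R T)))`, where
#' `zact` is the apparent gating valence, `F = 96485 C/mol`,
#' `R = 8.314 J/(mol K)` and `T` the absolute temperature. The equivalent
#' Boltzmann slope `k_equiv = R T / (zact F)` (in mV) is reported for
#' comparison with the conductance-fit slope factor.
#'
#' @param iv I-V table from [extract_peaks()]; needs at least 8 points
#'   covering both limbs of the relation.
#' @param temperature_K Temperature, K. Default 294.15 K (21 deg C, the
#'   middle of the room-temperature range of the recordings).
#' @return A `gmax_fit` object with fields `gmax`, `vrev`, `vhalf`, `zact`,
#'   `k_equiv_mV`, `temperature_K`, `rms`, `converged`, `n`, `data`.
#' @export
fit_iv_gmax <- function(iv, temperature_K = 294.15) {
  stopifnot(is.data.frame(iv), all(c("step_mV", "peak") %in% names(iv)))
  d <- dplyr::arrange(iv, .data$step_mV)
  if (nrow(d) < 8) stop("need >= 8 I-V points", call. = FALSE)
  v <- d$step_mV; y <- d$peak
  FARADAY <- 96485; RGAS <- 8.314
  beta <- FARADAY / (RGAS * temperature_K) / 1000  # per mV
  # starting values: vrev from the zero crossing beyond the peak (or the
  # top of the range), gmax from the ascending-limb slope, vhalf near the
  # foot of the activation range
  i_pk <- which.max(abs(y))
  vrev0 <- max(v)
  asc <- which(v > v[i_pk])
  if (length(asc) >= 2) {
    s <- sign(y[asc])
    flip <- which(s[-1] * s[-length(s)] < 0)
    if (length(flip) > 0) {
      i <- asc[flip[1]]
      vrev0 <- v[i] - y[i] * (v[i + 1] - v[i]) / (y[i + 1] - y[i])
    }
  }
  gmax0 <- abs(y[i_pk] / (v[i_pk] - vrev0))
  grid <- expand.grid(zact = c(2, 4, 6), dvh = c(-10, 0, 10))
  starts <- purrr::pmap(grid, function(zact, dvh) {
    list(gmax = gmax0, vrev = vrev0, vhalf = v[i_pk] - 10 + dvh, zact = zact)
  })
  best <- run_multistart_nls(
    y ~ gmax * (v - vrev) / (1 + exp(-zact * (v - vhalf) * beta)),
    data = data.frame(v = v, y = y, beta = beta), starts = starts,
    lower = c(gmax = 1e-12, vrev = min(v) - 100, vhalf = min(v) - 50,
              zact = 0.2),
    upper = c(gmax = Inf, vrev = max(v) + 150, vhalf = max(v) + 50,
              zact = 20)
  )
  if (is.null(best)) {
    return(structure(
      list(gmax = NA_real_, vrev = NA_real_, vhalf = NA_real_,
           zact = NA_real_, k_equiv_mV = NA_real_,
           temperature_K = temperature_K, rms = NA_real_, converged = FALSE,
           n = length(v), data = tibble::tibble(v = v, y = y)),
      class = "gmax_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  structure(
    list(gmax = cf[["gmax"]], vrev = cf[["vrev"]], vhalf = cf[["vhalf"]],
         zact = cf[["zact"]],
         k_equiv_mV = 1000 * RGAS * temperature_K / (cf[["zact"]] * FARADAY),
         temperature_K = temperature_K,
         rms = sqrt(best$rss / length(v)), converged = TRUE, n = length(v),
         data = tibble::tibble(v = v, y = y)),
    class = "gmax_fit"
  )
}

#' @export
print.gmax_fit <- function(x, ...) {
  cat(sprintf("<gmax_fit>%s\n", if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  Gmax = %.4g, Vrev = %.2f mV, V1/2 = %.2f mV\n",
              x$gmax, x$vrev, x$vhalf))
  cat(sprintf("  zact = %.3f (k_equiv = %.2f mV) at T = %.2f K\n",
              x$zact, x$k_equiv_mV, x$temperature_K))
  invisible(x)
}

#' Window-current area of a gating-curve pair
#'
#' The window current is the voltage region where the steady-state
#' activation and inactivation curves overlap, so a fraction of channels is
#' persistently open. The statistic is the trapezoidal integral over
#' `[v_lo, v_hi]` of the pointwise minimum of the two normalized sigmoids,
#' with open probability expressed in percent, giving an area in
#' percent x mV. The crossing voltage
#' `(vhalf_act * k_inact + vhalf_inact * k_act) / (k_act + k_inact)` (where
#' the two sigmoids intersect) is reported alongside.
#'
#' @param act,inact Converged `boltzmann_fit` objects of directions
#'   `"activation"` and `"inactivation"` (floors are ignored: the normalized
#'   sigmoid components are integrated).
#' @param v_lo,v_hi Integration range, mV; defaults to the span of the
#'   fitted data.
#' @param dv Integration grid step, mV.
#' @return A list of class `window_result`: `area` (percent x mV),
#'   `crossing_mV`, `v_lo`, `v_hi`, `dv`.
#' @export
#' @examples
#' # symmetric pair: area = 2 k ln 2 x 100 percent mV
#' a <- fit_boltzmann_exact(-30, 5, "activation")
#' b <- fit_boltzmann_exact(-30, 5, "inactivation")
#' window_area(a, b, v_lo = -130, v_hi = 70)$area  # ~693.1
window_area <- function(act, inact, v_lo = NULL, v_hi = NULL, dv = 0.1) {
  for (f in list(act, inact)) {
    if (!inherits(f, "boltzmann_fit") || !f$converged) {
      stop("`act` and `inact` must be converged boltzmann_fit objects",
           call. = FALSE)
    }
  }
  if (act$direction != "activation" || inact$direction != "inactivation") {
    stop("fit directions must be activation and inactivation", call. = FALSE)
  }
  if (is.null(v_lo)) v_lo <- min(c(act$data$v, inact$data$v))
  if (is.null(v_hi)) v_hi <- max(c(act$data$v, inact$data$v))
  stopifnot(v_hi > v_lo, dv > 0)
  v <- seq(v_lo, v_hi, by = dv)
  po_act <- 100 / (1 + exp(-(v - act$vhalf) / act$k))
  po_inact <- 100 / (1 + exp((v - inact$vhalf) / inact$k))
  y <- pmin(po_act, po_inact)
  area <- sum((y[-1] + y[-length(y)]) / 2 * diff(v))
  crossing <- (act$vhalf * inact$k + inact$vhalf * act$k) / (act$k + inact$k)
  structure(
    list(area = area, crossing_mV = crossing, v_lo = v_lo, v_hi = v_hi,
         dv = dv),
    class = "window_result"
  )
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf("<window_result> area %.2f percent.mV over [%g, %g] mV (dv = %g)\n",
              x$area, x$v_lo, x$v_hi, x$dv))
  cat(sprintf("  curves cross at %.2f mV\n", x$crossing_mV))
  invisible(x)
}

#' Exact Boltzmann fit object from known parameters
#'
#' Builds a converged `boltzmann_fit` directly from parameter values, with
#' synthetic data points on a default voltage grid. Useful for window-area
#' calculations from published or generative V1/2 / k pairs without raw
#' sweeps.
#'
#' @param vhalf,k Midpoint and slope factor, mV.
#' @param direction `"activation"` or `"inactivation"`.
#' @param amplitude Curve amplitude.
#' @param v Voltage grid for the embedded data points.
#' @return A `boltzmann_fit` object.
#' @export
fit_boltzmann_exact <- function(vhalf, k,
                                direction = c("activation", "inactivation"),
                                amplitude = 1,
                                v = seq(vhalf - 60, vhalf + 60, by = 5)) {
  direction <- match.arg(direction)
  sgn <- if (direction == "activation") 1 else -1
  y <- amplitude / (1 + exp(-sgn * (v - vhalf) / k))
  new_boltzmann_fit(vhalf, k, amplitude, 0, 0, TRUE, length(v), direction,
                    tibble::tibble(v = v, y = y, po = y / amplitude))
}
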