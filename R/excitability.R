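#' Detect action potentials in a current-clamp voltage trace
#'
#' A spike is scored when the depolarization slope `dV/dt` first reaches
#' `slope_threshold` and the voltage attains at least `min_peak` within the
#' following `search_ms`. The onset sample defines the spike time and the
#' threshold voltage; the waveform maximum within the search window defines
#' the peak. Detection then skips past the peak plus a refractory interval.
#' The slope-plus-peak criterion is more robust on slow invertebrate
#' waveforms than a plain voltage crossing, and all thresholds are
#' parameters.
#'
#' @param trace Data frame with columns `t_ms`, `value` (mV), uniformly
#'   sampled — one sweep.
#' @param slope_threshold Onset slope criterion, mV/ms.
#' @param min_peak Minimum peak voltage, mV.
#' @param refractory_ms Dead time after each detected peak, ms.
#' @param search_ms Window after onset within which the peak must occur, ms.
#' @return A tibble of class `spike_train`: `onset_ms`, `threshold_mV`,
#'   `peak_ms`, `peak_mV`, `max_dvdt`. An empty train is a valid result.
#' @export
detect_spikes <- function(trace, slope_threshold = 10, min_peak = 0,
                          refractory_ms = 2, search_ms = 5) {
  stopifnot(is.data.frame(trace), all(c("t_ms", "value") %in% names(trace)))
  t <- trace$t_ms
  v <- trace$value
  n <- length(v)
  empty <- tibble::tibble(onset_ms = numeric(), threshold_mV = numeric(),
                          peak_ms = numeric(), peak_mV = numeric(),
                          max_dvdt = numeric())
  class(empty) <- c("spike_train", class(empty))
  if (n < 3) return(empty)
  dt <- stats::median(diff(t))
  if (max(abs(diff(t) - dt)) > dt * 1e-6) {
    stop("trace is not uniformly sampled", call. = FALSE)
  }
  dvdt <- c(diff(v) / dt, 0)
  w <- max(1L, round(search_ms / dt))
  spikes <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (dvdt[i] >= slope_threshold) {
      j_hi <- min(n, i + w)
      seg <- v[i:j_hi]
      j_pk <- i + which.max(seg) - 1L
      if (v[j_pk] >= min_peak && v[j_pk] > v[i]) {
        spikes[[length(spikes) + 1L]] <- tibble::tibble(
          onset_ms = t[i], threshold_mV = v[i],
          peak_ms = t[j_pk], peak_mV = v[j_pk],
          max_dvdt = max(dvdt[i:max(i, j_pk - 1L)])
        )
        i <- j_pk + max(1L, round(refractory_ms / dt))
        next
      }
      # slope reached but no qualifying peak: move past this upstroke
      i <- j_hi + 1L
      next
    }
    i <- i + 1L
  }
  out <- if (length(spikes)) dplyr::bind_rows(spikes) else empty
  class(out) <- unique(c("spike_train", class(out)))
  out
}

#' Mean firing frequency of a spike train
#'
#' The number of spike onsets inside the stimulus window divided by the
#' window duration in seconds. Count-over-duration (rather than inverse mean
#' interspike interval) is well defined for 0 or 1 spikes and matches a
#' frequency reported in Hz for a fixed-length current injection.
#'
#' @param train A `spike_train` from [detect_spikes()].
#' @param window Length-2 numeric, stimulus window `(start, end)` in ms.
#' @return Firing frequency in Hz.
#' @export
#' @examples
#' tr <- tibble::tibble(onset_ms = c(60, 160, 260, 360, 460))
#' mean_firing_frequency(tr, window = c(50, 550))  # 5 spikes / 0.5 s = 10 Hz
mean_firing_frequency <- function(train, window) {
  stopifnot(length(window) == 2, is.numeric(window))
  dur_s <- (window[2] - window[1]) / 1000
  if (dur_s <= 0) stop("stimulus window has non-positive length", call. = FALSE)
  n <- sum(train$onset_ms >= window[1] & train$onset_ms < window[2])
  n / dur_s
}

#' Waveform metrics of the first action potential
#'
#' Latency from stimulus onset to the first spike onset, the threshold
#' voltage at onset, and the maximum depolarization slope between onset and
#' peak. Slower early depolarization (smaller max dV/dt, longer latency) is
#' the signature of reduced sodium conductance.
#'
#' @param train A `spike_train`.
#' @param trace The voltage trace the train was detected in.
#' @param stim_onset_ms Stimulus onset time, ms.
#' @return A one-row tibble `latency_ms`, `threshold_mV`, `max_dvdt`; all
#'   `NA` (with `no_spike = TRUE`) for an empty train.
#' @export
first_ap_metrics <- function(train, trace, stim_onset_ms) {
  if (nrow(train) == 0) {
    return(tibble::tibble(latency_ms = NA_real_, threshold_mV = NA_real_,
                          max_dvdt = NA_real_, no_spike = TRUE))
  }
  first <- train[order(train$onset_ms), ][1, ]
  seg <- trace[trace$t_ms >= first$onset_ms & trace$t_ms <= first$peak_ms, ]
  dvdt <- if (nrow(seg) >= 2) {
    max(diff(seg$value) / diff(seg$t_ms))
  } else {
    first$max_dvdt
  }
  tibble::tibble(latency_ms = first$onset_ms - stim_onset_ms,
                 threshold_mV = first$threshold_mV,
                 max_dvdt = dvdt, no_spike = FALSE)
}

#' Firing-frequency analysis of a current-clamp sweep set
#'
#' Runs [detect_spikes()] on every sweep of a current-clamp set and reports
#' the mean firing frequency over the stimulus window per injected
#' amplitude, plus first-spike metrics.
#'
#' @param sweeps A voltage `sweep_set` from [simulate_current_clamp()] (or
#'   data in the same shape with a `"stim"` epoch).
#' @param ... Passed to [detect_spikes()].
#' @return A tibble with one row per sweep: `sweep`, `amplitude_nA`,
#'   `n_spikes`, `mff_hz`, `latency_ms`, `threshold_mV`, `max_dvdt`.
#' @export
analyze_excitability <- function(sweeps, ...) {
  stopifnot(is.data.frame(sweeps))
  if (!identical(attr(sweeps, "signal_kind"), "voltage")) {
    stop("`sweeps` must be a voltage sweep set", call. = FALSE)
  }
  proto <- attr(sweeps, "protocol")
  sweeps |>
    dplyr::group_by(.data$sweep, amplitude_nA = .data$command) |>
    dplyr::group_modify(function(d, key) {
      stim <- if (!is.null(proto) && !is.null(proto$stim_duration_ms)) {
        proto$baseline_ms + c(0, proto$stim_duration_ms)
      } else {
        range(d$t_ms[d$epoch == "stim"])
      }
      train <- detect_spikes(d, ...)
      mff <- mean_firing_frequency(train, window = stim)
      met <- first_ap_metrics(train, d, stim_onset_ms = stim[1])
      tibble::tibble(n_spikes = nrow(train), mff_hz = mff,
                     latency_ms = met$latency_ms,
                     threshold_mV = met$threshold_mV,
                     max_dvdt = met$max_dvdt)
    }) |>
    dplyr::ungroup()
}
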