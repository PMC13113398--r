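#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap geom_boxplot theme_minimal
#' @export
ggplot2::autoplot

#' Plot a sweep set
#'
#' Overlaid traces coloured by command value (step voltage, prepulse
#' voltage, interpulse interval or stimulus amplitude).
#'
#' @param object A `sweep_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_set <- function(object, ...) {
  ylab <- paste0(attr(object, "signal_kind"), " (", attr(object, "units"), ")")
  ggplot(object, aes(x = .data$t_ms, y = .data$value,
                     group = .data$sweep, colour = .data$command)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = ylab, colour = "command") +
    theme_minimal()
}

#' Plot a Boltzmann gating fit
#'
#' Normalized open-probability points with the fitted sigmoid.
#'
#' @param object A converged `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  d <- object$data
  vv <- seq(min(d$v), max(d$v), length.out = 200)
  sgn <- if (object$direction == "activation") 1 else -1
  curve <- tibble::tibble(
    v = vv, po = 1 / (1 + exp(-sgn * (vv - object$vhalf) / object$k))
  )
  ggplot(d, aes(x = .data$v, y = .data$po)) +
    geom_point() +
    geom_line(data = curve, colour = "steelblue") +
    labs(x = "voltage (mV)", y = "open probability",
         title = sprintf("%s: V1/2 = %.2f mV, k = %.2f mV",
                         object$direction, object$vhalf, object$k)) +
    theme_minimal()
}

#' Plot the window current of an activation/inactivation pair
#'
#' Both normalized sigmoids with the shared (window) region that defines
#' the window-current area.
#'
#' @param act,inact Converged `boltzmann_fit` objects.
#' @param v_lo,v_hi,dv Voltage range and grid, as in [window_area()].
#' @return A ggplot object.
#' @export
plot_window <- function(act, inact, v_lo = NULL, v_hi = NULL, dv = 0.1) {
  w <- window_area(act, inact, v_lo = v_lo, v_hi = v_hi, dv = dv)
  v <- seq(w$v_lo, w$v_hi, by = dv)
  d <- tibble::tibble(
    v = v,
    activation = 100 / (1 + exp(-(v - act$vhalf) / act$k)),
    inactivation = 100 / (1 + exp((v - inact$vhalf) / inact$k))
  )
  long <- tidyr::pivot_longer(d, c("activation", "inactivation"),
                              names_to = "gate", values_to = "po")
  ggplot(long, aes(x = .data$v, y = .data$po, colour = .data$gate)) +
    geom_line() +
    ggplot2::geom_area(
      data = tibble::tibble(v = v, po = pmin(d$activation, d$inactivation)),
      aes(x = .data$v, y = .data$po), inherit.aes = FALSE,
      fill = "grey70", alpha = 0.6
    ) +
    labs(x = "voltage (mV)", y = "open probability (%)",
         title = sprintf("window area %.1f %%.mV (crossing %.1f mV)",
                         w$area, w$crossing_mV)) +
    theme_minimal()
}

#' Plot a recovery-from-inactivation curve
#'
#' @param object A `recovery_curve` from [recovery_fractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$interpulse_ms, y = .data$fraction)) +
    geom_point() + geom_line(linetype = "dashed", alpha = 0.5) +
    labs(x = "interpulse interval (ms)", y = "fraction recovered") +
    theme_minimal()
  f <- attr(object, "fit")
  if (!is.null(f)) {
    dt <- seq(0, max(object$interpulse_ms), length.out = 200)
    curve <- tibble::tibble(
      interpulse_ms = dt,
      fraction = f$asymptote - (f$asymptote - f$f0) * exp(-dt / f$tau)
    )
    p <- p + geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Boxplot of best docking energies per site
#'
#' @param best Output of [best_energy_per_replicate()].
#' @return A ggplot object.
#' @export
plot_site_energies <- function(best) {
  ggplot(best, aes(x = .data$site, y = .data$best_energy)) +
    geom_boxplot() + geom_point() +
    labs(x = "binding site", y = "best energy (a.u.)") +
    theme_minimal()
}
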