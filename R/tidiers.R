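#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per estimated parameter; `glance()` returns a
#' one-row fit summary (residual scale, convergence, number of points).
#'
#' @param x A `boltzmann_fit`, `gmax_fit` or `decay_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name navclamp-tidiers
NULL

#' @rdname navclamp-tidiers
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vhalf", "k", "amplitude", "floor"),
    estimate = c(x$vhalf, x$k, x$amplitude, x$floor)
  )
}

#' @rdname navclamp-tidiers
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(direction = x$direction, rms = x$rms,
                 converged = x$converged, n = x$n)
}

#' @rdname navclamp-tidiers
#' @export
tidy.gmax_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gmax", "vrev", "vhalf", "zact", "k_equiv_mV"),
    estimate = c(x$gmax, x$vrev, x$vhalf, x$zact, x$k_equiv_mV)
  )
}

#' @rdname navclamp-tidiers
#' @export
glance.gmax_fit <- function(x, ...) {
  tibble::tibble(temperature_K = x$temperature_K, rms = x$rms,
                 converged = x$converged, n = x$n)
}

#' @rdname navclamp-tidiers
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a_fast", "tau_fast", "a_slow", "tau_slow", "offset"),
    estimate = c(x$a_fast, x$tau_fast, x$a_slow, x$tau_slow, x$offset)
  )
}

#' @rdname navclamp-tidiers
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rms = x$rms, converged = x$converged,
                 non_decaying = x$non_decaying)
}
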