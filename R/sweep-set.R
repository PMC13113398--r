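#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

new_sweep_set <- function(df, signal_kind, units, protocol, seed,
                          gen_params = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "signal_kind") <- signal_kind
  attr(out, "units") <- units
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  attr(out, "gen_params") <- gen_params
  class(out) <- c("sweep_set", class(out))
  out
}

#' Metadata of a sweep set
#'
#' Accessors for the recording metadata carried alongside the long-form
#' sweep table: the stimulation protocol, the signal kind (`"current"` or
#' `"voltage"`), the physical units of the signal and the RNG seed used when
#' the set was simulated.
#'
#' @param x A `sweep_set` as returned by the `simulate_*()` functions or
#'   [read_sweeps()].
#' @return `sweep_protocol()` a [protocol_spec()]; the others length-1
#'   vectors.
#' @export
sweep_protocol <- function(x) attr(x, "protocol")

#' @rdname sweep_protocol
#' @export
sweep_units <- function(x) attr(x, "units")

#' @rdname sweep_protocol
#' @export
sweep_signal_kind <- function(x) attr(x, "signal_kind")

#' @rdname sweep_protocol
#' @export
sweep_seed <- function(x) attr(x, "seed")

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s sweeps of %s (%s), %s protocol\n",
              length(unique(x$sweep)), attr(x, "signal_kind"),
              attr(x, "units"),
              if (is.null(attr(x, "protocol"))) "?" else attr(x, "protocol")$kind))
  NextMethod()
}

# add zero-mean gaussian noise scaled to the set-wide max |signal|;
# bit-identical for identical seeds
add_sweep_noise <- function(df, noise_sd, seed) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(df)
  scale <- max(abs(df$value))
  set.seed(seed)
  df$value <- df$value + stats::rnorm(nrow(df), sd = noise_sd * scale)
  df
}

# time grid for one sweep: samples at dt = 1/rate, starting at dt/2-free 0
sweep_time_grid <- function(total_ms, rate_khz) {
  dt <- 1 / rate_khz
  seq(0, total_ms - dt, by = dt)
}
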