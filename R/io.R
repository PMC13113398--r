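#' Write and read sweep sets as delimited text with a JSON sidecar
#'
#' `write_sweeps()` stores the long-form sweep table as CSV (columns
#' `cell_id`, `condition`, `protocol`, `sweep_index`, `command_value`,
#' `epoch`, `time_ms`, `signal`) and the metadata (signal kind, units, seed,
#' protocol, and — for simulated fixtures — the generative parameters) in a
#' `<path>.json` sidecar. `read_sweeps()` restores the `sweep_set`,
#' normalizing row order by sweep and time, so a shuffled file reads back
#' identical; values round-trip at 9 significant digits.
#'
#' @param sweeps A `sweep_set`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `write_sweeps()` the path, invisibly; `read_sweeps()` a
#'   `sweep_set`.
#' @export
write_sweeps <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  proto <- attr(sweeps, "protocol")
  out <- tibble::tibble(
    cell_id = sweeps$cell_id, condition = sweeps$condition,
    protocol = if (is.null(proto)) "" else proto$kind,
    sweep_index = sweeps$sweep, command_value = sweeps$command,
    epoch = sweeps$epoch,
    time_ms = signif(sweeps$t_ms, 9), signal = signif(sweeps$value, 9)
  )
  readr::write_csv(out, path)
  gp <- attr(sweeps, "gen_params")
  meta <- list(
    signal_kind = attr(sweeps, "signal_kind"),
    units = attr(sweeps, "units"),
    seed = attr(sweeps, "seed"),
    protocol = if (is.null(proto)) NULL else unclass(proto),
    gen_params = if (is.null(gp)) NULL else unclass(gp)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "condition", "sweep_index", "command_value",
            "time_ms", "signal")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("sweep file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"epoch" %in% names(df)) df$epoch <- "step"
  df <- dplyr::arrange(df, .data$sweep_index, .data$time_ms)
  # every sweep must sit on a uniform time grid with one shared sample
  # interval (sweep lengths may differ, e.g. two-pulse protocols)
  grids <- split(df$time_ms, df$sweep_index)
  dt_ref <- stats::median(diff(grids[[1]]))
  for (g in grids) {
    dg <- diff(g)
    if (any(dg <= 0) || max(abs(dg - dt_ref)) > dt_ref * 1e-6) {
      stop("non-uniform time grid: sweeps are not uniformly sampled at a ",
           "shared interval", call. = FALSE)
    }
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  if (is.null(meta$units)) {
    stop("sweep metadata sidecar missing or lacks required field `units` (",
         meta_path, ")", call. = FALSE)
  }
  proto <- NULL
  if (!is.null(meta$protocol)) {
    proto <- meta$protocol
    class(proto) <- "protocol_spec"
  }
  tab <- tibble::tibble(
    cell_id = df$cell_id, condition = df$condition,
    sweep = df$sweep_index, command = df$command_value,
    epoch = df$epoch, t_ms = df$time_ms, value = df$signal
  )
  gp <- meta$gen_params
  if (!is.null(gp) && !is.null(gp$gmax)) class(gp) <- "gating_params"
  new_sweep_set(tab, signal_kind = meta$signal_kind %||% "current",
                units = meta$units, protocol = proto,
                seed = meta$seed, gen_params = gp)
}

#' Paired comparison with a normality pre-test
#'
#' Differences are first checked with a Shapiro-Wilk test; when normality is
#' not rejected at `alpha` a paired Student's t-test is used, otherwise a
#' Wilcoxon signed-rank test (exact for n <= 25). Identical vectors, or
#' differences with zero spread, cannot support either test and are
#' returned flagged `degenerate` instead.
#'
#' @param x,y Paired measurement vectors of equal length >= 3.
#' @param alpha Normality-test level steering the test choice.
#' @return A one-row tibble: `test`, `statistic`, `df_or_n`, `p_value`,
#'   `normality_p`, `direction` (sign of the mean difference), `degenerate`.
#' @export
#' @examples
#' paired_compare(c(5.1, 6.2, 5.8, 6.0, 5.5), c(4.2, 5.0, 5.1, 5.2, 4.7))
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  direction <- sign(mean(d))
  if (stats::sd(d) < 1e-12) {
    return(tibble::tibble(test = "paired-t", statistic = NA_real_,
                          df_or_n = length(d) - 1, p_value = NA_real_,
                          normality_p = NA_real_, direction = direction,
                          degenerate = TRUE))
  }
  norm_p <- stats::shapiro.test(d)$p.value
  if (norm_p >= alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(test = "paired-t", statistic = unname(tt$statistic),
                   df_or_n = unname(tt$parameter), p_value = tt$p.value,
                   normality_p = norm_p, direction = direction,
                   degenerate = FALSE)
  } else {
    wt <- stats::wilcox.test(x, y, paired = TRUE,
                             exact = length(x) <= 25)
    tibble::tibble(test = "wilcoxon-signed-rank",
                   statistic = unname(wt$statistic),
                   df_or_n = length(x), p_value = wt$p.value,
                   normality_p = norm_p, direction = direction,
                   degenerate = FALSE)
  }
}

#' Multiple-testing adjustment
#'
#' Bonferroni or Benjamini-Hochberg step-up false-discovery-rate adjustment,
#' clipped at 1 (thin wrapper over [stats::p.adjust()] with input
#' validation).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini-hochberg"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "benjamini-hochberg")
adjust_pvalues <- function(p, method = c("bonferroni",
                                         "benjamini-hochberg")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni"
                  else "BH")
}
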