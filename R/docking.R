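#' Simulate a replicate docking-score table
#'
#' Generates per-site, per-replicate, per-rank binding energies in arbitrary
#' units (more negative = stronger predicted binding), emulating repeated
#' rigid-docking runs against candidate binding sites: each replicate draws
#' `n_ranks` energies from a normal distribution around the site mean and
#' orders them by score.
#'
#' @param site_means Named numeric vector of mean energies per site (names
#'   become site labels, e.g. `c(DI = -270, DII = -350, ...)`).
#' @param sd Within-replicate energy standard deviation.
#' @param n_replicates,n_ranks Replicates per site and poses per replicate.
#' @param seed Integer seed.
#' @return A tibble `site`, `replicate`, `rank`, `energy` (rank 1 = most
#'   negative).
#' @export
simulate_docking_scores <- function(site_means = c(DI = -270, DII = -350,
                                                   DIII = -265, DIV = -300,
                                                   Turret = -240),
                                    sd = 10, n_replicates = 3, n_ranks = 10,
                                    seed = 1L) {
  stopifnot(!is.null(names(site_means)), sd >= 0)
  set.seed(seed)
  purrr::imap_dfr(site_means, function(mu, site) {
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      e <- sort(stats::rnorm(n_ranks, mean = mu, sd = sd))
      tibble::tibble(site = site, replicate = rep,
                     rank = seq_len(n_ranks), energy = e)
    })
  })
}

#' Best (most negative) energy per site and replicate
#'
#' Selects the most negative binding energy of each (site, replicate) group
#' — the highest predicted affinity among the ranked poses of that run.
#'
#' @param scores A docking-score tibble with columns `site`, `replicate`,
#'   `rank`, `energy` (at most 10 ranks per group; energies finite).
#' @return A tibble `site`, `replicate`, `best_energy`, one row per group.
#'   Every site must have every replicate present; a missing combination is
#'   an error naming it.
#' @export
best_energy_per_replicate <- function(scores) {
  need <- c("site", "replicate", "energy")
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  if (any(!is.finite(scores$energy))) {
    stop("non-finite energies in score table", call. = FALSE)
  }
  counts <- dplyr::count(scores, .data$site, .data$replicate)
  if (any(counts$n > 10)) {
    stop("more than 10 ranks in at least one (site, replicate) group",
         call. = FALSE)
  }
  full <- tidyr::expand_grid(site = unique(scores$site),
                             replicate = unique(scores$replicate))
  missing <- dplyr::anti_join(full, counts, by = c("site", "replicate"))
  if (nrow(missing) > 0) {
    stop("missing (site, replicate) group: ",
         paste(missing$site, missing$replicate, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  scores |>
    dplyr::group_by(.data$site, .data$replicate) |>
    dplyr::summarise(best_energy = min(.data$energy), .groups = "drop") |>
    dplyr::arrange(.data$site, .data$replicate)
}

#' Replicate-level statistics of best docking energies
#'
#' One-way ANOVA of best energy by site followed by Tukey's HSD pairwise
#' comparisons, plus a principal component analysis of the replicate-by-site
#' energy matrix (observations = replicates, variables = sites, columns
#' centered, unscaled) with the variance fraction per component. When every
#' site has zero within-group variance the ANOVA F is undefined and the
#' result is flagged `degenerate`.
#'
#' @param best Output of [best_energy_per_replicate()].
#' @return A list of class `site_stats`: `anova_f`, `anova_p`, `tukey` (a
#'   tibble of pairwise differences with adjusted p), `pca_var_frac`,
#'   `site_means`, `degenerate`.
#' @export
site_stats <- function(best) {
  stopifnot(all(c("site", "replicate", "best_energy") %in% names(best)))
  best$site <- factor(best$site)
  within_var <- best |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(v = stats::var(.data$best_energy)) |>
    dplyr::pull("v")
  degenerate <- all(within_var < 1e-24 | is.na(within_var))
  if (degenerate) {
    fstat <- NA_real_; pval <- NA_real_; tk <- NULL
  } else {
    fit <- stats::aov(best_energy ~ site, data = best)
    an <- summary(fit)[[1]]
    fstat <- an[["F value"]][1]
    pval <- an[["Pr(>F)"]][1]
    th <- stats::TukeyHSD(fit)$site
    tk <- tibble::tibble(pair = rownames(th), diff = th[, "diff"],
                         lwr = th[, "lwr"], upr = th[, "upr"],
                         p_adj = th[, "p adj"])
  }
  wide <- best |>
    tidyr::pivot_wider(names_from = "site", values_from = "best_energy") |>
    dplyr::select(-"replicate") |>
    as.matrix()
  pca <- stats::prcomp(wide, center = TRUE, scale. = FALSE)
  var_frac <- pca$sdev^2 / sum(pca$sdev^2)
  means <- best |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(mean_energy = mean(.data$best_energy), .groups = "drop")
  structure(
    list(anova_f = fstat, anova_p = pval, tukey = tk,
         pca_var_frac = var_frac, pca = pca, site_means = means,
         degenerate = degenerate),
    class = "site_stats"
  )
}

#' @export
print.site_stats <- function(x, ...) {
  cat("<site_stats>\n")
  if (x$degenerate) {
    cat("  zero within-group variance everywhere: ANOVA undefined\n")
  } else {
    cat(sprintf("  one-way ANOVA: F = %.3g, p = %.3g\n", x$anova_f,
                x$anova_p))
  }
  cat(sprintf("  PC variance fractions: %s\n",
              paste(sprintf("%.3f", x$pca_var_frac), collapse = ", ")))
  best_site <- x$site_means$site[which.min(x$site_means$mean_energy)]
  cat(sprintf("  most negative mean energy: %s\n", best_site))
  invisible(x)
}
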