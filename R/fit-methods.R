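#' Tidy posterior summaries of a fitted ACE x M model
#'
#' One row per parameter: posterior mean (`estimate`), posterior standard
#' deviation (`std.error`) and the HPD interval (`conf.low`, `conf.high`).
#' With `variance_scale = TRUE`, per-draw transforms are appended: the
#' variance components at both moderator levels (`exp(beta0x)` and
#' `exp(beta0x + beta1x)`) and the heritability `h2` at the reference level.
#'
#' @param x An `acem_fit`.
#' @param conf.level HPD coverage (default 0.95).
#' @param variance_scale Append variance-scale transforms of the draws.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.acem_fit <- function(x, conf.level = 0.95, variance_scale = FALSE, ...) {
  draws <- x$draws
  if (variance_scale) {
    wide <- tidyr::pivot_wider(draws, names_from = "parameter",
                               values_from = "value")
    for (comp in c("a", "c", "e")) {
      b0 <- wide[[paste0("beta0", comp)]] %||%
        rep(x$fixed[[paste0("beta0", comp)]], nrow(wide))
      b1 <- wide[[paste0("beta1", comp)]] %||%
        rep(x$fixed[[paste0("beta1", comp)]], nrow(wide))
      if (is.null(b0) || is.null(b1)) next
      wide[[paste0("exp_beta0", comp)]] <- exp(b0)
      wide[[paste0("var_", comp, "_m1")]] <- exp(b0 + b1)
    }
    if (all(c("exp_beta0a", "exp_beta0c", "exp_beta0e") %in% names(wide))) {
      wide$h2 <- wide$exp_beta0a /
        (wide$exp_beta0a + wide$exp_beta0c + wide$exp_beta0e)
    }
    draws <- tidyr::pivot_longer(wide, cols = -c("chain", "iteration"),
                                 names_to = "parameter", values_to = "value")
  }
  out <- dplyr::summarise(
    dplyr::group_by(draws, .data$parameter),
    estimate = mean(.data$value),
    std.error = sd(.data$value),
    conf.low = hpd_interval(.data$value, conf.level)[["lower"]],
    conf.high = hpd_interval(.data$value, conf.level)[["upper"]],
    .groups = "drop")
  dplyr::rename(out, term = "parameter")
}

#' One-row summary of a fitted ACE x M model
#'
#' @param x An `acem_fit`.
#' @param ... Unused.
#' @return A tibble with the model label, family counts, chain/draw counts,
#'   and worst-case convergence diagnostics (`max_rhat`, `min_ess`).
#' @exportS3Method generics::glance
glance.acem_fit <- function(x, ...) {
  cv <- convergence_report(x)
  tibble::tibble(model = x$model,
                 n_families = x$n_families,
                 n_mz = x$n_mz,
                 n_dz = x$n_dz,
                 n_chains = x$mcmc$n_chains,
                 n_draws = nrow(dplyr::distinct(x$draws, .data$chain,
                                                .data$iteration)),
                 max_rhat = max(cv$rhat, na.rm = TRUE),
                 min_ess = min(cv$ess, na.rm = TRUE))
}

#' Posterior histograms of a fitted ACE x M model
#'
#' Faceted histograms of the posterior draws, one panel per parameter —
#' convenient for inspecting the interaction effects (A x M, C x M, E x M).
#'
#' @param object An `acem_fit`.
#' @param parameters Optional subset of parameter names to plot.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.acem_fit <- function(object, parameters = NULL, bins = 40, ...) {
  draws <- object$draws
  if (!is.null(parameters)) {
    draws <- dplyr::filter(draws, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "posterior draw", y = "count",
                  title = sprintf("Posterior distributions (%s model)",
                                  object$model)) +
    ggplot2::theme_minimal()
}

#' Sum-score distribution plot
#'
#' Histogram of per-twin sum scores (optionally restricted to DZ twins),
#' annotated with the moment skewness estimate — useful for eyeballing floor
#' and ceiling effects.
#'
#' @param data Twin dataset with `item_*` columns.
#' @param dz_only Restrict to DZ twins (default TRUE).
#' @return A ggplot object.
#' @export
plot_sum_scores <- function(data, dz_only = TRUE) {
  scores <- compute_sum_scores(data)
  if (dz_only) scores <- dplyr::filter(scores, .data$zygosity == "DZ")
  sk <- skewness_joanes_gill(scores$sum_score)$g1
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$sum_score)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "sum score", y = "twins",
                  title = sprintf("Sum scores (%s), skewness g1 = %.3f",
                                  if (dz_only) "DZ twins" else "all twins", sk)) +
    ggplot2::theme_minimal()
}
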