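#' Highest posterior density interval
#'
#' Shortest interval containing a fraction `prob` of the draws, found by
#' sliding a fixed-length window over the sorted sample. For variance
#' components bounded at zero the interval is not a significance test;
#' [summarize_replications()] uses HPD exclusion of zero only for the
#' unbounded interaction and mean parameters.
#'
#' @param x Numeric vector of posterior draws (length >= 2).
#' @param prob Coverage probability in (0, 1).
#' @return A named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4))
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("Need at least two draws for an HPD interval.")
  if (!(prob > 0 && prob < 1)) abort("`prob` must be in (0, 1).")
  xs <- sort(x)
  n <- length(xs)
  if (xs[1] == xs[n]) {
    warn("All draws are equal; returning a zero-width interval.")
    return(c(lower = xs[1], upper = xs[1]))
  }
  gap <- max(1L, min(n - 1L, round(n * prob)))
  lo <- seq_len(n - gap)
  width <- xs[lo + gap] - xs[lo]
  i <- which.min(width)
  c(lower = xs[i], upper = xs[i + gap])
}

#' HPD-exclusion rate over replications
#'
#' Fraction of intervals that exclude zero (`lower > 0` or `upper < 0`).
#' For a parameter whose true value is nonzero this is the power; for a
#' zero-truth parameter the same quantity is the false-positive rate.
#'
#' @param intervals A data frame with columns `lower` and `upper` (one row
#'   per replication), or a list of length-2 vectors.
#' @return A proportion in [0, 1].
#' @export
power_from_replications <- function(intervals) {
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(ci) {
      data.frame(lower = ci[[1]], upper = ci[[2]])
    }))
  }
  if (!nrow(intervals)) abort("`intervals` is empty.")
  mean(intervals$lower > 0 | intervals$upper < 0)
}

#' Joanes-Gill sample skewness estimators
#'
#' The three related estimators: the moment estimator
#' \eqn{g_1 = m_3 / m_2^{3/2}} (central moments with denominator `n`), the
#' bias-adjusted \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)}, and
#' \eqn{b_1 = g_1 ((n-1)/n)^{3/2}}. For `n > 3` and skewed data
#' `|G1| >= |g1| >= |b1|`.
#'
#' @param x Numeric vector, `n >= 3`, not constant.
#' @return A one-row tibble with columns `b1`, `g1`, `G1`.
#' @export
skewness_joanes_gill <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) abort("Need at least three observations for skewness.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort("Skewness is undefined for a constant sample.")
  g1 <- mean((x - m)^3) / m2^1.5
  tibble::tibble(b1 = g1 * ((n - 1) / n)^1.5,
                 g1 = g1,
                 G1 = g1 * sqrt(n * (n - 1)) / (n - 2))
}

#' Summarize fits across simulation replications
#'
#' Produces the replication-level table: per parameter, the truth, the mean
#' of posterior means, the mean of posterior standard deviations, and the
#' HPD-exclusion proportion (power for nonzero truths, false-positive rate
#' for zero truths).
#'
#' @param fits A list of `acem_fit` objects from replicate datasets.
#' @param truth An [acem_params()] with the generating values (optional).
#' @param model_label Label recorded in the output (defaults to the first
#'   fit's model).
#' @param prob HPD coverage (default 0.95).
#' @return A tibble with one row per parameter: `parameter`, `truth`,
#'   `mean_posterior_mean`, `mean_posterior_sd`, `hpd_exclusion_rate`,
#'   `n_replications`, `model`.
#' @export
summarize_replications <- function(fits, truth = NULL, model_label = NULL,
                                   prob = 0.95) {
  stopifnot(length(fits) >= 1)
  if (!all(vapply(fits, inherits, logical(1), "acem_fit"))) {
    abort("`fits` must be a list of acem_fit objects.")
  }
  pars <- sort(unique(fits[[1]]$draws$parameter))
  per <- purrr::imap(fits, function(f, r) {
    if (!setequal(unique(f$draws$parameter), pars)) {
      abort("All fits must carry the same parameter set.")
    }
    dplyr::summarise(
      dplyr::group_by(f$draws, .data$parameter),
      post_mean = mean(.data$value),
      post_sd = sd(.data$value),
      excl = {
        ci <- hpd_interval(.data$value, prob)
        ci["lower"] > 0 || ci["upper"] < 0
      },
      .groups = "drop")
  })
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(per), .data$parameter),
    mean_posterior_mean = mean(.data$post_mean),
    mean_posterior_sd = mean(.data$post_sd),
    hpd_exclusion_rate = mean(.data$excl),
    .groups = "drop")
  tv <- rep(NA_real_, nrow(out))
  if (!is.null(truth)) {
    truth <- as_acem_params(truth)
    idx <- match(out$parameter, names(truth))
    tv[!is.na(idx)] <- unlist(truth)[idx[!is.na(idx)]]
  }
  out$truth <- tv
  out$n_replications <- length(fits)
  out$model <- model_label %||% fits[[1]]$model
  dplyr::select(out, "parameter", "truth", "mean_posterior_mean",
                "mean_posterior_sd", "hpd_exclusion_rate",
                "n_replications", "model")
}

#' Convergence diagnostics for a fit
#'
#' Split-chain potential scale reduction (each chain is halved, so
#' diagnostics work for single-chain runs) and effective sample size per
#' parameter; parameters whose split-Rhat exceeds `threshold` are flagged.
#'
#' @param fit An `acem_fit`.
#' @param threshold Flagging threshold for split-Rhat (default 1.1).
#' @return A tibble with `parameter`, `rhat`, `ess`, `flag`.
#' @export
convergence_report <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "acem_fit"))
  pars <- sort(unique(fit$draws$parameter))
  purrr::map_dfr(pars, function(pp) {
    byc <- dplyr::filter(fit$draws, .data$parameter == pp)
    mats <- split(byc$value, byc$chain)
    tibble::tibble(parameter = pp,
                   rhat = split_rhat(mats),
                   ess = sum(vapply(mats, function(v) {
                     as.numeric(coda::effectiveSize(coda::mcmc(v)))
                   }, numeric(1))),
                   flag = .data$rhat > threshold)
  })
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2
    if (h < 2) return(list(v))
    list(v[seq_len(h)], v[seq(h + 1, 2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  if (m < 2 || n < 2) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
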