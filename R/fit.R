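#' Moderator missingness policy
#'
#' `"impute"` keeps every family and treats a missing moderator as a latent
#' Bernoulli variable inside the fit (its probability getting a Beta
#' hyperprior per zygosity group), so no data are discarded.
#' `"complete_cases"` drops families whose moderator is missing — the
#' traditional comparison mode.
#'
#' @param data A twin dataset (one row per twin).
#' @param policy `"impute"` or `"complete_cases"`.
#' @return The dataset view the fit will see (unchanged for `"impute"`).
#' @export
apply_moderator_policy <- function(data, policy = c("impute", "complete_cases")) {
  policy <- match.arg(policy)
  if (policy == "complete_cases") {
    data <- dplyr::filter(data, !is.na(.data$moderator))
  }
  data
}

validate_twin_data <- function(data, require_items = FALSE) {
  need <- c("family_id", "twin", "zygosity", "moderator")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Twin data lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  counts <- table(data$family_id)
  if (any(counts != 2)) {
    abort("Every family must contribute exactly two twins.")
  }
  if (!all(data$zygosity %in% c("MZ", "DZ"))) {
    abort("`zygosity` must be \"MZ\" or \"DZ\".")
  }
  fam <- dplyr::distinct(data, .data$family_id, .data$zygosity)
  if (anyDuplicated(fam$family_id)) {
    abort("`zygosity` must be constant within a family.")
  }
  modc <- dplyr::summarise(dplyr::group_by(data, .data$family_id),
                           ok = dplyr::n_distinct(.data$moderator) == 1L,
                           .groups = "drop")
  if (!all(modc$ok)) {
    abort("The moderator is family-level: both twins must share one value (or both be missing).")
  }
  if (!all(data$moderator %in% c(0, 1) | is.na(data$moderator))) {
    abort("`moderator` must be binary 0/1 (or missing).")
  }
  items <- grep("^item_", names(data), value = TRUE)
  if (require_items) {
    if (!length(items)) abort("Twin data contain no `item_*` columns.")
    for (it in items) {
      v <- data[[it]]
      if (!all(v %in% c(0, 1) | is.na(v))) {
        abort(paste0("Item responses must be 0/1/missing; offending column: ", it))
      }
      if (all(is.na(v))) {
        abort(paste0("Item column has no observed responses: ", it))
      }
    }
  }
  invisible(items)
}

family_view <- function(data) {
  data <- dplyr::arrange(data, .data$family_id, .data$twin)
  fam <- dplyr::distinct(data, .data$family_id, .data$zygosity, .data$moderator)
  if (!any(fam$zygosity == "MZ") || !any(fam$zygosity == "DZ")) {
    abort("Both MZ and DZ families are required to separate A from C.")
  }
  list(data = data, fam = fam,
       r = ifelse(fam$zygosity == "MZ", 1, 0.5),
       M = as.integer(fam$moderator))
}

new_acem_fit <- function(res, model, fv, priors, mcmc, fixed, extra = list()) {
  structure(c(list(draws = res$draws,
                   model = model,
                   n_families = nrow(fv$fam),
                   n_mz = sum(fv$fam$zygosity == "MZ"),
                   n_dz = sum(fv$fam$zygosity == "DZ"),
                   priors = priors, mcmc = mcmc,
                   fixed = fixed, accept = res$accept),
              extra),
            class = "acem_fit")
}

#' Fit the joint IRT + ACE x M model
#'
#' Bayesian MCMC estimation of the biometric ACE x M model and the Rasch
#' (fixed-discrimination) measurement model simultaneously, from item-level
#' twin data. Item difficulties and discriminations are fixed and known
#' (supplied via the item bank), which anchors the latent-trait scale.
#' Missing item responses simply drop out of the likelihood; families with a
#' missing moderator are handled per `moderator_policy`. The simulation-truth
#' `theta` column, if present, is never read.
#'
#' @param data Twin dataset tibble, one row per twin, with `family_id`,
#'   `twin`, `zygosity`, `moderator`, and `item_*` columns.
#' @param bank An [item_bank()] covering every `item_*` column (defaults to
#'   the bank attached by [simulate_twin_data()]).
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param moderator_policy See [apply_moderator_policy()].
#' @param fixed Optional named list/vector pinning structural parameters at
#'   known values (they are then excluded from sampling); names among
#'   `mu, beta1m, beta0a, beta1a, beta0c, beta1c, beta0e, beta1e`.
#' @return An `acem_fit` object; see [tidy.acem_fit()], [glance.acem_fit()],
#'   [convergence_report()].
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_pairs = 120, n_items = 12, n_replications = 1,
#'                        seed = 7)
#' d <- simulate_twin_data(cfg)
#' fit <- fit_acem_irt(d, mcmc = mcmc_config(500, 500, 1000, seed = 7))
#' tidy(fit)
#' }
#' @export
fit_acem_irt <- function(data, bank = attr(data, "item_bank"),
                         priors = prior_spec(), mcmc = mcmc_config(),
                         moderator_policy = c("impute", "complete_cases"),
                         fixed = NULL) {
  if (is.null(bank)) abort("An item bank is required for the IRT model.")
  bank <- validate_item_bank(bank)
  data <- apply_moderator_policy(data, moderator_policy)
  items <- validate_twin_data(data, require_items = TRUE)
  missing_items <- setdiff(items, bank$item_id)
  if (length(missing_items)) {
    abort(paste0("Item bank does not cover: ", paste(missing_items, collapse = ", ")))
  }
  bank <- bank[match(items, bank$item_id), ]
  fv <- family_view(data)
  d1 <- dplyr::filter(fv$data, .data$twin == 1)
  d2 <- dplyr::filter(fv$data, .data$twin == 2)
  Y <- list(as.matrix(d1[, items]), as.matrix(d2[, items]))
  obs <- list(model = "irt", n = nrow(fv$fam), r = fv$r, M = fv$M,
              Y = Y, a = bank$discrimination, b = bank$difficulty)
  res <- run_acem_mcmc(obs, priors, mcmc, fixed)
  new_acem_fit(res, "irt", fv, priors, mcmc, validate_fixed(fixed),
               extra = list(item_bank = bank))
}

#' Fit the biometric ACE x M model to an observed continuous phenotype
#'
#' The shared biometric kernel of the package: the same model that underlies
#' [fit_acem_irt()], but with the phenotype treated as directly observed
#' (no measurement layer). [fit_acem_sumscore()] feeds scaled sum scores
#' through this function.
#'
#' @inheritParams fit_acem_irt
#' @param phenotype Name of the phenotype column (default `"phenotype"`).
#' @return An `acem_fit`.
#' @export
fit_acem_phenotype <- function(data, phenotype = "phenotype",
                               priors = prior_spec(), mcmc = mcmc_config(),
                               moderator_policy = c("impute", "complete_cases"),
                               fixed = NULL) {
  if (!phenotype %in% names(data)) {
    abort(paste0("Phenotype column not found: ", phenotype))
  }
  data <- apply_moderator_policy(data, moderator_policy)
  validate_twin_data(data)
  fv <- family_view(data)
  ph <- cbind(dplyr::filter(fv$data, .data$twin == 1)[[phenotype]],
              dplyr::filter(fv$data, .data$twin == 2)[[phenotype]])
  if (all(is.na(ph))) abort("All phenotype values are missing.")
  obs <- list(model = "pheno", n = nrow(fv$fam), r = fv$r, M = fv$M,
              pheno = ph)
  res <- run_acem_mcmc(obs, priors, mcmc, fixed)
  new_acem_fit(res, "phenotype", fv, priors, mcmc, validate_fixed(fixed))
}

#' @export
print.acem_fit <- function(x, ...) {
  cat(sprintf("<acem_fit: %s model, %d families (%d MZ / %d DZ)>\n",
              x$model, x$n_families, x$n_mz, x$n_dz))
  cat(sprintf("  %d chain(s) x %d kept draws\n",
              x$mcmc$n_chains, x$mcmc$n_keep %/% x$mcmc$thin))
  print(tidy(x), n = Inf)
  invisible(x)
}
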