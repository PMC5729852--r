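#' Scenario configuration for the twin-family simulator
#'
#' Collects the full generative specification of one simulation scenario:
#' design (pairs, MZ proportion, item count), the item-difficulty
#' distribution, the binary family moderator, the structural parameters, and
#' replication/seed bookkeeping. The same seed always reproduces bit-identical
#' data.
#'
#' @param n_pairs Number of twin pairs per dataset.
#' @param prop_mz Proportion of MZ pairs; the MZ count is fixed at
#'   `round(prop_mz * n_pairs)` rather than drawn.
#' @param n_items Number of dichotomous items.
#' @param item_difficulty_mean,item_difficulty_sd Normal parameters for the
#'   item difficulties (drawn afresh per replication).
#' @param moderator_prob Bernoulli probability of the family-level binary
#'   moderator, strictly inside (0, 1).
#' @param params An [acem_params()] object (defaults to the benchmark
#'   scenario: variance components 0.25/0.25/0.5, moderator main effect 0.7,
#'   zero interactions).
#' @param n_replications Number of replicate datasets.
#' @param seed Integer seed driving every random draw.
#' @param moderator_missing_prob Probability that a family's moderator is
#'   masked (missing completely at random); default 0.
#' @return An object of class `scenario_config`.
#' @seealso [scenario_preset()], [simulate_twin_data()]
#' @export
scenario_config <- function(n_pairs = 2000,
                            prop_mz = 0.28,
                            n_items = 40,
                            item_difficulty_mean = 1,
                            item_difficulty_sd = 1,
                            moderator_prob = 0.5,
                            params = acem_params(mu = 0, beta1m = 0.7,
                                                 beta0a = log(0.25),
                                                 beta0c = log(0.25),
                                                 beta0e = log(0.5)),
                            n_replications = 250,
                            seed = 1L,
                            moderator_missing_prob = 0) {
  stopifnot(n_pairs >= 1, n_items >= 1, n_replications >= 1,
            prop_mz >= 0, prop_mz <= 1,
            moderator_prob > 0, moderator_prob < 1,
            moderator_missing_prob >= 0, moderator_missing_prob < 1,
            item_difficulty_sd > 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 prop_mz = prop_mz,
                 n_items = as.integer(n_items),
                 item_difficulty_mean = item_difficulty_mean,
                 item_difficulty_sd = item_difficulty_sd,
                 moderator_prob = moderator_prob,
                 params = as_acem_params(params),
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed),
                 moderator_missing_prob = moderator_missing_prob),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d pairs (%.0f%% MZ), %d items ~ N(%g, %g^2)\n",
              x$n_pairs, 100 * x$prop_mz, x$n_items,
              x$item_difficulty_mean, x$item_difficulty_sd))
  cat(sprintf("  moderator ~ Bernoulli(%g), %d replications, seed %d\n",
              x$moderator_prob, x$n_replications, x$seed))
  print(x$params)
  invisible(x)
}

#' Named simulation presets
#'
#' `"scenario1"`: 2,000 pairs (28% MZ), 40 items with difficulties
#' Normal(1, 1) — mostly hard items, a floor effect and positively skewed sum
#' scores. `"scenario2"`: the mirror image, difficulties Normal(-1, 1) —
#' ceiling effect, negatively skewed sum scores. Both use variance components
#' (0.25, 0.25, 0.5), moderator main effect 0.7 on a Bernoulli(0.5) family
#' moderator and zero true interactions, with 250 replications.
#' `"items20"`, `"items100"`, `"items250"` fix 1,000 pairs and vary the item
#' count to study how much psychometric information the model needs.
#'
#' All presets anchor the phenotypic population mean at zero by setting
#' `mu = -beta1m * moderator_prob` (-0.35), so the moderator's mean effect
#' does not shift the latent trait relative to the item difficulties.
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config.
#' @param n_replications Optional override of the preset's replication count.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("scenario1", "scenario2",
                                     "items20", "items100", "items250"),
                            seed = 1L, n_replications = NULL) {
  name <- match.arg(name)
  pars <- acem_params(mu = -0.35, beta1m = 0.7,
                      beta0a = log(0.25), beta0c = log(0.25),
                      beta0e = log(0.5))
  cfg <- switch(name,
    scenario1 = scenario_config(item_difficulty_mean = 1, seed = seed,
                                params = pars),
    scenario2 = scenario_config(item_difficulty_mean = -1, seed = seed,
                                params = pars),
    items20 = scenario_config(n_pairs = 1000, n_items = 20,
                              item_difficulty_mean = 0, seed = seed,
                              params = pars),
    items100 = scenario_config(n_pairs = 1000, n_items = 100,
                               item_difficulty_mean = 0, seed = seed,
                               params = pars),
    items250 = scenario_config(n_pairs = 1000, n_items = 250,
                               item_difficulty_mean = 0, seed = seed,
                               params = pars))
  if (!is.null(n_replications)) cfg$n_replications <- as.integer(n_replications)
  cfg
}

#' Simulate latent traits for MZ families
#'
#' Each MZ family draws a familial effect
#' `F ~ Normal(mu + beta1m * m, sigma2_A(m) + sigma2_C(m))` shared by both
#' twins; each twin then deviates independently with unique-environment
#' variance `sigma2_E(m)`.
#'
#' @param params An [acem_params()].
#' @param m Moderator value(s), one per family.
#' @param n Number of families (defaults to `length(m)`).
#' @return A tibble with columns `theta1`, `theta2`.
#' @export
simulate_mz_family <- function(params, m, n = length(m)) {
  params <- as_acem_params(params)
  m <- rep_len(m, n)
  s2 <- component_variances(params, m)
  f <- rnorm(n, params$mu + params$beta1m * m, sqrt(s2$a + s2$c))
  tibble::tibble(theta1 = rnorm(n, f, sqrt(s2$e)),
                 theta2 = rnorm(n, f, sqrt(s2$e)))
}

#' Simulate latent traits for DZ families
#'
#' A family-level standard-normal genetic value `A1` and per-twin Mendelian
#' sampling terms `A2` combine as `sqrt(1/2) * A1 + sqrt(1/2) * A2`, scaled
#' by the genetic standard deviation `sigma_A(m)`, so each twin's genetic
#' effect has variance `sigma2_A(m)` and co-twins correlate 0.5. The common
#' environmental effect `C ~ Normal(mu + beta1m * m, sigma2_C(m))` is shared;
#' unique environment is added per twin.
#'
#' @inheritParams simulate_mz_family
#' @return A tibble with columns `theta1`, `theta2`.
#' @export
simulate_dz_family <- function(params, m, n = length(m)) {
  params <- as_acem_params(params)
  m <- rep_len(m, n)
  s2 <- component_variances(params, m)
  cc <- rnorm(n, params$mu + params$beta1m * m, sqrt(s2$c))
  a1 <- rnorm(n)
  sa <- sqrt(s2$a)
  h <- sqrt(0.5)
  tibble::tibble(
    theta1 = rnorm(n, cc + sa * (h * a1 + h * rnorm(n)), sqrt(s2$e)),
    theta2 = rnorm(n, cc + sa * (h * a1 + h * rnorm(n)), sqrt(s2$e)))
}

#' Fill in Bernoulli item responses given latent traits
#'
#' Given a twin dataset holding latent traits and an item bank, draws each
#' response independently as `Y ~ Bernoulli(irt_probability(theta, item))`.
#'
#' @param data A twin dataset tibble with a `theta` column (one row per twin).
#' @param bank An [item_bank()].
#' @return `data` with one `item_*` column per bank row appended (existing
#'   item columns are replaced).
#' @export
simulate_responses <- function(data, bank) {
  bank <- validate_item_bank(bank)
  if (!"theta" %in% names(data) || anyNA(data$theta)) {
    abort("`data` must contain a complete `theta` column to simulate responses.")
  }
  p <- plogis(outer(data$theta, bank$difficulty, "-") *
                rep(bank$discrimination, each = nrow(data)))
  y <- matrix(rbinom(length(p), 1L, p), nrow = nrow(data))
  colnames(y) <- bank$item_id
  out <- dplyr::select(data, -dplyr::starts_with("item_"))
  dplyr::bind_cols(out, tibble::as_tibble(y))
}

#' Simulate one twin-family item-response dataset
#'
#' Draws, in order: the item bank, the family moderator, latent traits for
#' the MZ block then the DZ block, and the item responses. Returns one row
#' per twin. The `theta` column is the simulation truth and is unobservable
#' in practice; fitting functions never read it (it is retained only so that
#' oracle checks can compare against the generating values).
#'
#' @param config A [scenario_config()].
#' @param seed Overrides `config$seed` when given (used internally for
#'   replication substreams).
#' @return A tibble with columns `family_id`, `twin`, `zygosity`,
#'   `moderator`, `theta`, `item_1 ... item_K`, with the item bank in
#'   `attr(, "item_bank")` and the config in `attr(, "config")`.
#' @export
simulate_twin_data <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_pairs
  n_mz <- round(config$prop_mz * n)
  zyg <- rep(c("MZ", "DZ"), times = c(n_mz, n - n_mz))
  bank <- draw_item_difficulties(config$n_items,
                                 config$item_difficulty_mean,
                                 config$item_difficulty_sd)
  m <- rbinom(n, 1L, config$moderator_prob)
  th_mz <- if (n_mz > 0) simulate_mz_family(config$params, m[seq_len(n_mz)])
           else tibble::tibble(theta1 = numeric(), theta2 = numeric())
  th_dz <- if (n - n_mz > 0) simulate_dz_family(config$params, m[seq(n_mz + 1, n)])
           else tibble::tibble(theta1 = numeric(), theta2 = numeric())
  th <- dplyr::bind_rows(th_mz, th_dz)
  m_obs <- m
  if (config$moderator_missing_prob > 0) {
    m_obs[runif(n) < config$moderator_missing_prob] <- NA_integer_
  }
  data <- tibble::tibble(
    family_id = rep(seq_len(n), each = 2L),
    twin = rep(1:2, times = n),
    zygosity = rep(zyg, each = 2L),
    moderator = rep(m_obs, each = 2L),
    theta = as.vector(rbind(th$theta1, th$theta2)))
  data <- simulate_responses(data, bank)
  attr(data, "item_bank") <- bank
  attr(data, "config") <- config
  data
}

#' Generate replicate datasets
#'
#' Runs `.f` on each of `config$n_replications` independently simulated
#' datasets. Replication `r` uses a substream seed derived deterministically
#' from `config$seed`, so the full set is reproducible and any single
#' replication can be regenerated in isolation.
#'
#' @param config A [scenario_config()].
#' @param .f Function applied to each dataset (default passes the dataset
#'   through; supply a summary function to keep memory bounded).
#' @param reps Optional subset of replication indices to run.
#' @return A list with one element per replication.
#' @export
simulate_replications <- function(config, .f = identity, reps = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- replication_seeds(config)
  if (is.null(reps)) reps <- seq_len(config$n_replications)
  stopifnot(all(reps >= 1), all(reps <= config$n_replications))
  purrr::map(reps, function(r) .f(simulate_twin_data(config, seed = seeds[r])))
}

replication_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max, config$n_replications)
}
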