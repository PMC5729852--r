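test_that("family simulators reproduce the closed-form twin moments", {
  set.seed(99)
  p <- benchmark_params(mu = 0)
  n <- 1e5
  mz <- simulate_mz_family(p, m = 0, n = n)
  expect_lt(abs(cov(mz$theta1, mz$theta2) - 0.5), 0.02)
  expect_lt(abs(var(mz$theta1) - 1.0), 0.03)
  dz <- simulate_dz_family(p, m = 0, n = n)
  expect_lt(abs(cov(dz$theta1, dz$theta2) - 0.375), 0.02)
  expect_lt(abs(var(dz$theta1) - 1.0), 0.03)
  # moderator main effect shifts both zygosities by beta1m
  mz1 <- simulate_mz_family(p, m = 1, n = n)
  expect_lt(abs(mean(mz1$theta1) - mean(mz$theta1) - 0.7), 0.02)
})

test_that("degenerate variance components behave as limits", {
  set.seed(4)
  # no unique environment: MZ co-twins coincide
  p <- acem_params(beta0a = log(0.5), beta0c = log(0.5), beta0e = -40)
  mz <- simulate_mz_family(p, 0, n = 100)
  expect_equal(mz$theta1, mz$theta2, tolerance = 1e-6)
  # no genetic variance: DZ covariance collapses to sigma2_C
  p0 <- acem_params(beta0a = -40, beta0c = log(0.6), beta0e = log(0.4))
  dz <- simulate_dz_family(p0, 0, n = 1e5)
  expect_lt(abs(cov(dz$theta1, dz$theta2) - 0.6), 0.02)
})

test_that("no-interaction truth yields matched within-group variances", {
  set.seed(12)
  p <- benchmark_params(mu = 0)
  d0 <- simulate_dz_family(p, m = 0, n = 5e4)
  d1 <- simulate_dz_family(p, m = 1, n = 5e4)
  expect_lt(abs(var(d0$theta1) - var(d1$theta1)), 0.03)
  expect_lt(abs(cov(d0$theta1, d0$theta2) - cov(d1$theta1, d1$theta2)), 0.03)
})

test_that("item responses follow the Rasch probabilities", {
  set.seed(8)
  base <- tibble::tibble(family_id = rep(1:500, each = 2),
                         twin = rep(1:2, 500),
                         zygosity = "DZ", moderator = 0)
  # theta pinned at the item difficulty: proportion correct near one half
  base$theta <- 1.3
  d <- simulate_responses(base, item_bank(1.3))
  expect_lt(abs(mean(d$item_1) - 0.5), 0.05)
  # extreme trait levels saturate
  base$theta <- 30
  expect_true(all(simulate_responses(base, item_bank(c(0, 1)))$item_1 == 1))
  base$theta <- NA_real_
  expect_error(simulate_responses(base, item_bank(0)), "theta")
})

test_that("simulated datasets honor the design and are seed-deterministic", {
  cfg <- scenario_preset("scenario1", seed = 21, n_replications = 2)
  cfg$n_pairs <- 200L
  d <- simulate_twin_data(cfg)
  fam <- dplyr::distinct(d, family_id, zygosity)
  expect_equal(nrow(fam), 200)
  expect_equal(sum(fam$zygosity == "MZ"), 56) # 28% fixed, not drawn
  expect_equal(unname(table(d$family_id)), rep(2L, 200), ignore_attr = TRUE)
  items <- grep("^item_", names(d), value = TRUE)
  expect_length(items, 40)
  expect_true(all(as.matrix(d[, items]) %in% 0:1))
  # moderator is family-level
  mod <- dplyr::summarise(dplyr::group_by(d, family_id),
                          ok = dplyr::n_distinct(moderator) == 1)
  expect_true(all(mod$ok))
  # bit-identical under the same seed, different under another
  expect_identical(d, simulate_twin_data(cfg))
  expect_false(identical(d$theta, simulate_twin_data(cfg, seed = 22)$theta))
  reps <- simulate_replications(cfg, function(x) sum(x$theta))
  reps2 <- simulate_replications(cfg, function(x) sum(x$theta))
  expect_identical(reps, reps2)
})

test_that("moderator missingness mask is honored", {
  cfg <- tiny_config(n_pairs = 300, moderator_missing_prob = 0.4)
  d <- simulate_twin_data(cfg)
  fam <- dplyr::distinct(d, family_id, moderator)
  expect_gt(mean(is.na(fam$moderator)), 0.2)
  expect_lt(mean(is.na(fam$moderator)), 0.6)
})

test_that("floor and ceiling scenarios skew sum scores in opposite directions", {
  sk <- function(preset) {
    cfg <- scenario_preset(preset, seed = 9, n_replications = 3)
    cfg$n_pairs <- 500L
    pooled <- unlist(simulate_replications(cfg, function(d) {
      s <- compute_sum_scores(d)
      s$sum_score[s$zygosity == "DZ"]
    }))
    skewness_joanes_gill(pooled)$g1
  }
  expect_gt(sk("scenario1"), 0.2)
  expect_lt(sk("scenario2"), -0.2)
})

test_that("dataset and bank files round-trip", {
  cfg <- tiny_config(n_pairs = 25)
  d <- simulate_twin_data(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_twin_data(d, path)
  d2 <- read_twin_data(path)
  expect_equal(as.data.frame(d), as.data.frame(d2))
  expect_equal(attr(d, "item_bank"), attr(d2, "item_bank"))
  cfg2 <- attr(d2, "config")
  expect_equal(unclass(cfg2)[c("n_pairs", "n_items", "seed")],
               unclass(cfg)[c("n_pairs", "n_items", "seed")])
})
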