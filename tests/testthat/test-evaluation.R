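test_that("HPD interval matches closed forms and brute-force checks", {
  set.seed(2)
  u <- runif(2e4)
  ci <- hpd_interval(u, 0.95)
  expect_lt(abs((ci["upper"] - ci["lower"]) - 0.95), 0.01)
  # symmetric unimodal: close to the central quantile interval
  z <- rnorm(2e4)
  ci_z <- hpd_interval(z, 0.95)
  q_z <- quantile(z, c(0.025, 0.975))
  expect_lt(abs(ci_z["lower"] - q_z[1]), 0.08)
  expect_lt(abs(ci_z["upper"] - q_z[2]), 0.08)
  # agreement with coda's implementation
  cd <- coda::HPDinterval(coda::mcmc(z), prob = 0.95)
  expect_equal(unname(ci_z["lower"]), cd[1, "lower"], tolerance = 1e-8)
  expect_equal(unname(ci_z["upper"]), cd[1, "upper"], tolerance = 1e-8)
  # positive draws exclude zero; prob near 1 approaches the range
  x <- rexp(5000) + 0.1
  expect_gt(hpd_interval(x)["lower"], 0)
  ci_all <- hpd_interval(x, 0.9999)
  expect_equal(unname(ci_all["lower"]), min(x), tolerance = 0.01)
  expect_warning(hpd_interval(rep(1, 10)), "zero-width")
  expect_error(hpd_interval(1), "two draws")
  expect_error(hpd_interval(rnorm(10), prob = 1.5), "0, 1")
})

test_that("exclusion rate equals a direct count and ignores ordering", {
  ints <- tibble::tibble(lower = c(-1, 0.2, -0.5, 0.1, -2, 0.3, -1, -1, -1, -3),
                         upper = c(1, 0.9, -0.1, 0.8, 2, 1.2, 0.5, 2, 3, -1))
  direct <- sum(ints$lower > 0 | ints$upper < 0) / nrow(ints)
  expect_equal(power_from_replications(ints), direct)
  expect_equal(direct, 0.5)
  shuffled <- ints[sample(nrow(ints)), ]
  expect_equal(power_from_replications(shuffled), direct)
  straddle <- tibble::tibble(lower = rep(-1, 5), upper = rep(1, 5))
  expect_equal(power_from_replications(straddle), 0)
  expect_equal(power_from_replications(list(c(0.1, 1), c(-1, 1))), 0.5)
})

test_that("skewness estimators match hand-computed moments and e1071", {
  x <- c(1, 2, 3, 4, 100)
  m <- mean(x)
  g1_hand <- mean((x - m)^3) / mean((x - m)^2)^1.5
  sk <- skewness_joanes_gill(x)
  n <- 5
  expect_equal(sk$g1, g1_hand, tolerance = 1e-12)
  expect_equal(sk$G1, g1_hand * sqrt(n * (n - 1)) / (n - 2), tolerance = 1e-12)
  expect_equal(sk$b1, g1_hand * ((n - 1) / n)^1.5, tolerance = 1e-12)
  # independent implementation of the same three estimators
  expect_equal(sk$g1, e1071::skewness(x, type = 1), tolerance = 1e-10)
  expect_equal(sk$G1, e1071::skewness(x, type = 2), tolerance = 1e-10)
  expect_equal(sk$b1, e1071::skewness(x, type = 3), tolerance = 1e-10)
  # symmetric samples: all three near zero; ordering |G1| >= |g1| >= |b1|
  set.seed(6)
  z <- rnorm(5e4)
  expect_lt(abs(skewness_joanes_gill(z)$g1), 0.05)
  sk2 <- skewness_joanes_gill(rexp(50))
  expect_true(abs(sk2$G1) >= abs(sk2$g1))
  expect_true(abs(sk2$g1) >= abs(sk2$b1))
  expect_error(skewness_joanes_gill(c(1, 1, 1)), "constant")
  expect_error(skewness_joanes_gill(c(1, 2)), "three")
})

test_that("replication summaries aggregate posterior moments and exclusions", {
  d <- simulate_twin_data(tiny_config(n_pairs = 80))
  d$phenotype <- d$theta
  f1 <- fit_acem_phenotype(d, mcmc = short_mcmc(seed = 1, n_keep = 600))
  f2 <- fit_acem_phenotype(d, mcmc = short_mcmc(seed = 2, n_keep = 600))
  s1 <- summarize_replications(list(f1), truth = benchmark_params())
  td <- tidy(f1)
  expect_equal(s1$mean_posterior_mean[match(td$term, s1$parameter)],
               td$estimate)
  expect_equal(s1$truth[s1$parameter == "beta1m"], 0.7)
  expect_true(all(s1$hpd_exclusion_rate %in% c(0, 1)))
  s12 <- summarize_replications(list(f1, f2), truth = benchmark_params())
  expect_equal(s12$n_replications[1], 2)
  expect_true(all(s12$hpd_exclusion_rate >= 0 & s12$hpd_exclusion_rate <= 1))
  f3 <- f2
  f3$draws <- dplyr::filter(f3$draws, parameter != "mu")
  expect_error(summarize_replications(list(f1, f3)), "same parameter")
})

test_that("convergence report flags divergent chains and passes identical ones", {
  draws <- tidyr::expand_grid(chain = 1:2, iteration = 1:500)
  set.seed(10)
  draws$parameter <- "x"
  fit <- structure(list(draws = dplyr::mutate(draws, value = rep(rnorm(500), 2)),
                        mcmc = mcmc_config(0, 0, 500, n_chains = 2)),
                   class = "acem_fit")
  rep1 <- convergence_report(fit)
  expect_lt(rep1$rhat, 1.05)
  expect_false(rep1$flag)
  bad <- fit
  bad$draws$value[bad$draws$chain == 2] <-
    bad$draws$value[bad$draws$chain == 2] + 5
  rep2 <- convergence_report(bad)
  expect_gt(rep2$rhat, 1.5)
  expect_true(rep2$flag)
})
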