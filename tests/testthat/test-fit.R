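test_that("twin data validation rejects malformed inputs", {
  d <- simulate_twin_data(tiny_config(n_pairs = 30))
  bad <- d
  bad$moderator[1] <- 1 - bad$moderator[2] # individual-level moderator
  expect_error(fit_acem_irt(bad, mcmc = short_mcmc()), "family-level")
  bad2 <- d[-1, ] # odd twin count
  expect_error(fit_acem_irt(bad2, mcmc = short_mcmc()), "exactly two")
  bad3 <- d
  bad3$item_1 <- NA_integer_
  expect_error(fit_acem_irt(bad3, mcmc = short_mcmc()), "item_1")
  bad4 <- d
  bad4$item_2[1] <- 3L
  expect_error(fit_acem_irt(bad4, mcmc = short_mcmc()), "item_2")
  only_dz <- dplyr::filter(d, zygosity == "DZ")
  expect_error(fit_acem_irt(only_dz, mcmc = short_mcmc()), "MZ and DZ")
  # bank must cover every item column
  bank <- attr(d, "item_bank")[-1, ]
  expect_error(fit_acem_irt(d, bank = bank, mcmc = short_mcmc()),
               "does not cover")
  expect_error(fit_acem_irt(d, bank = NULL, mcmc = short_mcmc()),
               "item bank")
})

test_that("fits are reproducible given a seed and structural draws are finite", {
  d <- simulate_twin_data(tiny_config(n_pairs = 40, n_items = 6))
  f1 <- fit_acem_irt(d, mcmc = short_mcmc(seed = 9, n_keep = 400))
  f2 <- fit_acem_irt(d, mcmc = short_mcmc(seed = 9, n_keep = 400))
  expect_equal(f1$draws, f2$draws)
  f3 <- fit_acem_irt(d, mcmc = short_mcmc(seed = 10, n_keep = 400))
  expect_false(identical(f1$draws$value, f3$draws$value))
  # implied variance components positive for every draw at both levels
  wide <- tidyr::pivot_wider(f1$draws, names_from = parameter,
                             values_from = value)
  for (comp in c("a", "c", "e")) {
    b0 <- wide[[paste0("beta0", comp)]]
    b1 <- wide[[paste0("beta1", comp)]]
    expect_true(all(exp(b0) > 0) && all(exp(b0 + b1) > 0))
    expect_true(all(is.finite(b0)) && all(is.finite(b1)))
  }
  expect_equal(nrow(wide), 400)
})

test_that("moderator policies agree when nothing is missing and differ when it is", {
  cfg <- tiny_config(n_pairs = 60, n_items = 6, moderator_missing_prob = 0.5)
  d_complete <- simulate_twin_data(tiny_config(n_pairs = 60, n_items = 6))
  m <- short_mcmc(seed = 3, n_keep = 300)
  fi <- fit_acem_irt(d_complete, mcmc = m, moderator_policy = "impute")
  fc <- fit_acem_irt(d_complete, mcmc = m, moderator_policy = "complete_cases")
  expect_equal(fi$draws, fc$draws)
  d_miss <- simulate_twin_data(cfg)
  n_miss <- sum(is.na(dplyr::distinct(d_miss, family_id, moderator)$moderator))
  expect_gt(n_miss, 5)
  fi2 <- fit_acem_irt(d_miss, mcmc = m, moderator_policy = "impute")
  fc2 <- fit_acem_irt(d_miss, mcmc = m, moderator_policy = "complete_cases")
  expect_equal(fi2$n_families, 60)
  expect_equal(fc2$n_families, 60 - n_miss)
})

test_that("fixed parameters are pinned and excluded from sampling", {
  d <- simulate_twin_data(tiny_config(n_pairs = 40, n_items = 6))
  fit <- fit_acem_irt(d, mcmc = short_mcmc(seed = 2, n_keep = 300),
                      fixed = list(beta1a = 0, beta1c = 0, beta1e = 0))
  pars <- unique(fit$draws$parameter)
  expect_false(any(c("beta1a", "beta1c", "beta1e") %in% pars))
  expect_true(all(c("mu", "beta1m", "beta0a", "beta0c", "beta0e") %in% pars))
  expect_error(fit_acem_irt(d, mcmc = short_mcmc(), fixed = list(zzz = 1)),
               "Unknown fixed parameter")
})

test_that("posterior matches deterministic quadrature on a mean-only slice", {
  # all parameters but mu pinned at truth; the mu posterior from MCMC must
  # match direct grid integration of the marginal pair likelihood
  set.seed(20)
  p <- benchmark_params(mu = 0.4)
  n <- 60
  M <- rbinom(n, 1, 0.5)
  r <- rep(c(1, 0.5), times = c(17, 43))
  th <- vapply(seq_len(n), function(i) {
    mo <- twin_covariance(p, M[i], if (r[i] == 1) "MZ" else "DZ")
    drop(mo$mean + t(chol(mo$sigma)) %*% rnorm(2))
  }, numeric(2))
  d <- tibble::tibble(
    family_id = rep(seq_len(n), each = 2), twin = rep(1:2, n),
    zygosity = rep(ifelse(r == 1, "MZ", "DZ"), each = 2),
    moderator = rep(M, each = 2), phenotype = as.vector(th))
  fixed <- unlist(p)[-1] # everything except mu
  fit <- fit_acem_phenotype(d, mcmc = mcmc_config(1000, 2000, 20000, seed = 6),
                            fixed = as.list(fixed))
  oracle <- grid_posterior_mu_pheno(th[1, ], th[2, ], M, r, p)
  mcmc_mu <- post_mean(fit, "mu")
  expect_lt(abs(mcmc_mu - oracle$mean), 0.02 * max(1, abs(oracle$mean)))
  mcmc_sd <- sd(fit$draws$value[fit$draws$parameter == "mu"])
  expect_lt(abs(mcmc_sd - oracle$sd) / oracle$sd, 0.05)
})

test_that("the joint IRT posterior matches quadrature on a tiny instance", {
  set.seed(33)
  p <- benchmark_params(mu = 0)
  bank <- item_bank(c(-0.5, 0.5))
  n <- 4
  M <- c(0, 1, 0, 1)
  zyg <- c("MZ", "MZ", "DZ", "DZ")
  th <- vapply(seq_len(n), function(i) {
    mo <- twin_covariance(p, M[i], zyg[i])
    drop(mo$mean + t(chol(mo$sigma)) %*% rnorm(2))
  }, numeric(2))
  d <- tibble::tibble(
    family_id = rep(seq_len(n), each = 2), twin = rep(1:2, n),
    zygosity = rep(zyg, each = 2), moderator = rep(M, each = 2),
    theta = as.vector(th))
  d <- simulate_responses(d, bank)
  fixed <- as.list(unlist(p)[-1])
  fit <- fit_acem_irt(d, bank = bank, fixed = fixed,
                      mcmc = mcmc_config(2000, 8000, 150000, seed = 13))
  Y1 <- as.matrix(d[d$twin == 1, c("item_1", "item_2")])
  Y2 <- as.matrix(d[d$twin == 2, c("item_1", "item_2")])
  oracle_mean <- grid_posterior_mu_irt(Y1, Y2, M, ifelse(zyg == "MZ", 1, 0.5),
                                       bank, p)
  expect_lt(abs(post_mean(fit, "mu") - oracle_mean),
            0.02 * max(1, abs(oracle_mean)))
})

test_that("posteriors agree with an independent Gibbs implementation", {
  # same tiny biometric model coded independently in JAGS (augmented
  # hierarchy); posterior means and SDs must agree within Monte Carlo error
  set.seed(44)
  cfg <- scenario_config(n_pairs = 120, n_items = 6, seed = 91,
                         n_replications = 1, params = benchmark_params())
  d <- simulate_twin_data(cfg)
  d$phenotype <- d$theta
  fit <- fit_acem_phenotype(d, mcmc = mcmc_config(2000, 4000, 24000, seed = 3))
  model <- "
  model {
    mu ~ dnorm(0, 0.01); b1m ~ dnorm(0, 0.01)
    b0a ~ dnorm(0, 0.25); b1a ~ dnorm(0, 0.25)
    b0c ~ dnorm(0, 0.25); b1c ~ dnorm(0, 0.25)
    b0e ~ dnorm(0, 0.25); b1e ~ dnorm(0, 0.25)
    for (i in 1:N) {
      s2a[i] <- exp(b0a + b1a*M[i]); s2c[i] <- exp(b0c + b1c*M[i])
      s2e[i] <- exp(b0e + b1e*M[i])
    }
    for (i in 1:Nmz) {
      F[i] ~ dnorm(mu + b1m*M[i], 1/(s2a[i] + s2c[i]))
      for (j in 1:2) { th[i,j] ~ dnorm(F[i], 1/s2e[i]) }
    }
    for (i in (Nmz+1):N) {
      C[i] ~ dnorm(mu + b1m*M[i], 1/s2c[i])
      A1[i] ~ dnorm(0,1)
      for (j in 1:2) {
        A2[i,j] ~ dnorm(0,1)
        th[i,j] ~ dnorm(C[i] + sqrt(s2a[i])*0.7071068*(A1[i]+A2[i,j]),
                        1/s2e[i])
      }
    }
  }"
  d1 <- d[d$twin == 1, ]
  dat <- list(N = nrow(d1), Nmz = sum(d1$zygosity == "MZ"), M = d1$moderator,
              th = cbind(d1$theta, d[d$twin == 2, ]$theta))
  jm <- rjags::jags.model(textConnection(model), data = dat, n.chains = 1,
                          n.adapt = 1500, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 7))
  stats::update(jm, 6000)
  s <- rjags::coda.samples(jm, c("mu", "b1m", "b0a", "b1a", "b0c", "b1c",
                                 "b0e", "b1e"), 40000)
  js <- summary(s)$statistics
  map <- c(mu = "mu", b1m = "beta1m", b0a = "beta0a", b1a = "beta1a",
           b0c = "beta0c", b1c = "beta1c", b0e = "beta0e", b1e = "beta1e")
  td <- tidy(fit)
  for (nm in rownames(js)) {
    ours <- td[td$term == map[[nm]], ]
    expect_lt(abs(ours$estimate - js[nm, "Mean"]), 0.35 * js[nm, "SD"])
    expect_lt(abs(ours$std.error - js[nm, "SD"]) / js[nm, "SD"], 0.25)
  }
})
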