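# Shared fixtures and independent oracles used across the suite.

benchmark_params <- function(mu = -0.35) {
  acem_params(mu = mu, beta1m = 0.7,
              beta0a = log(0.25), beta0c = log(0.25), beta0e = log(0.5))
}

tiny_config <- function(n_pairs = 60, n_items = 8, seed = 11, ...) {
  scenario_config(n_pairs = n_pairs, n_items = n_items, seed = seed,
                  n_replications = 1, params = benchmark_params(), ...)
}

short_mcmc <- function(seed = 1, n_keep = 1500) {
  mcmc_config(n_adapt = 400, n_burnin = 800, n_keep = n_keep, seed = seed)
}

post_mean <- function(fit, par) {
  d <- fit$draws
  mean(d$value[d$parameter == par])
}

# deterministic grid posterior for mu in the observed-phenotype model with all
# other parameters fixed: posterior ~ prior(mu) * prod of bivariate normal
# pair densities, evaluated by direct summation on a fine grid
grid_posterior_mu_pheno <- function(ph1, ph2, M, r, params, prior_sd = 10,
                                    grid = seq(-4, 4, length.out = 4001)) {
  loglik <- vapply(grid, function(mu) {
    sA <- exp(params$beta0a + params$beta1a * M)
    sC <- exp(params$beta0c + params$beta1c * M)
    sE <- exp(params$beta0e + params$beta1e * M)
    v <- sA + sC + sE
    cc <- r * sA + sC
    m <- mu + params$beta1m * M
    dt <- v^2 - cc^2
    d1 <- ph1 - m; d2 <- ph2 - m
    sum(-log(2 * pi) - 0.5 * log(dt) -
          0.5 * (v * (d1^2 + d2^2) - 2 * cc * d1 * d2) / dt)
  }, numeric(1))
  logpost <- loglik + dnorm(grid, 0, prior_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(mean = sum(w * grid), sd = sqrt(sum(w * grid^2) - sum(w * grid)^2))
}

# deterministic quadrature posterior for mu in the joint IRT model on a tiny
# dataset: per family, integrate the twin-pair latent traits over a 2-D
# Gauss-Hermite-style grid of the bivariate normal, times the Bernoulli item
# likelihood; then normalize over a mu grid
grid_posterior_mu_irt <- function(Y1, Y2, M, r, bank, params, prior_sd = 10,
                                  mu_grid = seq(-3, 3, length.out = 121),
                                  th_grid = seq(-6, 6, length.out = 81)) {
  itemll_one <- function(th, y) {
    out <- numeric(length(th))
    for (k in which(!is.na(y))) {
      eta <- bank$discrimination[k] * (th - bank$difficulty[k])
      lp1 <- plogis(eta, log.p = TRUE)
      out <- out + if (y[k] == 1) lp1 else lp1 - eta
    }
    out
  }
  n <- length(M)
  loglik <- vapply(mu_grid, function(mu) {
    tot <- 0
    for (i in seq_len(n)) {
      sA <- exp(params$beta0a + params$beta1a * M[i])
      sC <- exp(params$beta0c + params$beta1c * M[i])
      sE <- exp(params$beta0e + params$beta1e * M[i])
      v <- sA + sC + sE
      cc <- r[i] * sA + sC
      m <- mu + params$beta1m * M[i]
      S <- matrix(c(v, cc, cc, v), 2)
      P <- solve(S)
      g <- as.matrix(expand.grid(t1 = th_grid, t2 = th_grid))
      d <- cbind(g[, 1] - m, g[, 2] - m)
      q <- rowSums((d %*% P) * d)
      logw <- -log(2 * pi) - 0.5 * determinant(S)$modulus - 0.5 * q
      li <- itemll_one(g[, 1], Y1[i, ]) + itemll_one(g[, 2], Y2[i, ])
      mx <- max(logw + li)
      tot <- tot + mx + log(sum(exp(logw + li - mx))) +
        2 * log(th_grid[2] - th_grid[1])
    }
    tot
  }, numeric(1))
  logpost <- loglik + dnorm(mu_grid, 0, prior_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  sum(w * mu_grid)
}
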