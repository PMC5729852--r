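# MCMC kernel for the biometric ACE x M model, optionally coupled to a Rasch
# item layer. The family-level latent effects (familial effect for MZ pairs;
# common environment, family genetic value and Mendelian terms for DZ pairs)
# are marginalized analytically: given the moderator, a twin pair's latent
# traits are bivariate normal with variance sA + sC + sE and cross-covariance
# r * sA + sC (r = 1 MZ, 0.5 DZ). Sampling scheme per sweep:
#   1. (IRT only) random-walk Metropolis on each twin's theta given the
#      co-twin (conditional-normal prior + Bernoulli-logistic item likelihood),
#      with per-twin step sizes tuned during adaptation/burn-in.
#   2. Joint adaptive Metropolis on the free log-variance coefficients
#      (Haario-style empirical-covariance proposal, frozen after burn-in),
#      interweaved (IRT model) with a non-centered companion move: theta is
#      re-expressed as standardized pair residuals, a second variance-block
#      proposal rescales theta along with the coefficients, and is accepted
#      on item likelihood plus prior. The interweaving breaks the strong
#      posterior coupling between the latent-trait scale and the variance
#      coefficients that makes the centered update mix slowly.
#   3. Exact Gibbs draw of (mu, beta1m), which are conditionally Gaussian.
#   4. Missing moderators drawn from their two-point conditional; Beta-
#      Bernoulli conjugate draws of pi_mz and pi_dz.
# The stationary distribution equals that of the fully augmented hierarchy.

.P_MU <- 1L; .P_B1M <- 2L
.P_B0A <- 3L; .P_B1A <- 4L; .P_B0C <- 5L; .P_B1C <- 6L; .P_B0E <- 7L; .P_B1E <- 8L

acem_par_names <- function() {
  c("mu", "beta1m", "beta0a", "beta1a", "beta0c", "beta1c", "beta0e", "beta1e")
}

pair_moments <- function(p, M, r) {
  sA <- exp(p[.P_B0A] + p[.P_B1A] * M)
  sC <- exp(p[.P_B0C] + p[.P_B1C] * M)
  sE <- exp(p[.P_B0E] + p[.P_B1E] * M)
  list(m = p[.P_MU] + p[.P_B1M] * M,
       v = sA + sC + sE,
       cc = r * sA + sC)
}

# log-likelihood of observed phenotype pairs (and singletons) given p and M,
# computed family-by-family
biom_loglik_family <- function(p, st, M) {
  ll <- 0
  if (length(st$pair_idx)) {
    i <- st$pair_idx
    mo <- pair_moments(p, M[i], st$r[i])
    dt <- mo$v * mo$v - mo$cc * mo$cc
    if (any(!is.finite(dt)) || any(dt <= 0)) return(-Inf)
    d1 <- st$x1[i] - mo$m
    d2 <- st$x2[i] - mo$m
    q <- (mo$v * (d1 * d1 + d2 * d2) - 2 * mo$cc * d1 * d2) / dt
    ll <- ll + sum(-log(2 * pi) - 0.5 * log(dt) - 0.5 * q)
  }
  if (length(st$single_idx)) {
    i <- st$single_idx
    mo <- pair_moments(p, M[i], st$r[i])
    ll <- ll + sum(dnorm(st$single_val, mo$m, sqrt(mo$v), log = TRUE))
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

# same likelihood from per-group sufficient statistics (phenotype model with
# fully observed moderator); groups are (zygosity, M) cells
biom_loglik_groups <- function(p, gs) {
  ll <- 0
  g <- gs$pairs
  if (nrow(g)) {
    mo <- pair_moments(p, g$M, g$r)
    dt <- mo$v * mo$v - mo$cc * mo$cc
    if (any(!is.finite(dt)) || any(dt <= 0)) return(-Inf)
    ssq <- g$Sqq - 2 * mo$m * g$S1 + 2 * g$n * mo$m^2
    scp <- g$Scp - mo$m * g$S1 + g$n * mo$m^2
    ll <- ll + sum(-g$n * log(2 * pi) - 0.5 * g$n * log(dt) -
                     0.5 * (mo$v * ssq - 2 * mo$cc * scp) / dt)
  }
  g <- gs$singles
  if (!is.null(g) && nrow(g)) {
    mo <- pair_moments(p, g$M, g$r)
    ll <- ll + sum(-0.5 * g$n * log(2 * pi * mo$v) -
                     0.5 * (g$Sxx - 2 * mo$m * g$Sx + g$n * mo$m^2) / mo$v)
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

make_group_stats <- function(st, M) {
  pairs <- NULL
  if (length(st$pair_idx)) {
    i <- st$pair_idx
    key <- interaction(st$r[i], M[i], drop = TRUE)
    pairs <- data.frame(
      r = tapply(st$r[i], key, `[`, 1L),
      M = tapply(M[i], key, `[`, 1L),
      n = as.vector(table(key)),
      S1 = tapply(st$x1[i] + st$x2[i], key, sum),
      Sqq = tapply(st$x1[i]^2 + st$x2[i]^2, key, sum),
      Scp = tapply(st$x1[i] * st$x2[i], key, sum))
  } else {
    pairs <- data.frame(r = numeric(), M = numeric(), n = numeric(),
                        S1 = numeric(), Sqq = numeric(), Scp = numeric())
  }
  singles <- NULL
  if (length(st$single_idx)) {
    i <- st$single_idx
    key <- interaction(st$r[i], M[i], drop = TRUE)
    singles <- data.frame(
      r = tapply(st$r[i], key, `[`, 1L),
      M = tapply(M[i], key, `[`, 1L),
      n = as.vector(table(key)),
      Sx = tapply(st$single_val, key, sum),
      Sxx = tapply(st$single_val^2, key, sum))
  }
  list(pairs = pairs, singles = singles)
}

# exact Gibbs draw of the free mean parameters (mu, beta1m), which are
# conditionally Gaussian given the variance coefficients and M
draw_mean_params <- function(p, st, M, priors, free_mean) {
  if (!length(free_mean)) return(p)
  w <- z <- x <- numeric(0)
  if (length(st$pair_idx)) {
    i <- st$pair_idx
    mo <- pair_moments(p, M[i], st$r[i])
    w <- 2 / (mo$v + mo$cc)
    z <- (st$x1[i] + st$x2[i]) / 2
    x <- M[i]
  }
  if (length(st$single_idx)) {
    i <- st$single_idx
    mo <- pair_moments(p, M[i], st$r[i])
    w <- c(w, 1 / mo$v)
    z <- c(z, st$single_val)
    x <- c(x, M[i])
  }
  X <- cbind(1, x)[, c(.P_MU, .P_B1M) %in% free_mean, drop = FALSE]
  off <- numeric(length(z))
  if (!(.P_MU %in% free_mean)) off <- off + p[.P_MU]
  if (!(.P_B1M %in% free_mean)) off <- off + p[.P_B1M] * x
  prec0 <- diag(1 / priors$mean_scale^2, ncol(X))
  A <- crossprod(X, X * w) + prec0
  b <- crossprod(X, w * (z - off)) + prec0 %*% rep(priors$mean_location, ncol(X))
  U <- chol(A)
  mean_post <- backsolve(U, forwardsolve(t(U), b))
  draw <- mean_post + backsolve(U, rnorm(ncol(X)))
  p[free_mean] <- as.numeric(draw)
  p
}

run_acem_chain <- function(obs, priors, mcmc, fixed, seed, keep_rows) {
  set.seed(seed)
  irt <- obs$model == "irt"
  n <- obs$n
  pn <- acem_par_names()
  free <- setdiff(pn, names(fixed))
  free_var <- intersect(pn[3:8], free)
  vi <- match(free_var, pn)
  free_mean <- match(intersect(pn[1:2], free), pn)

  # --- state: moderator ---
  M <- obs$M
  miss <- which(is.na(M))
  has_miss <- length(miss) > 0
  if (has_miss) M[miss] <- rbinom(length(miss), 1L, 0.5)
  mz_idx <- obs$r == 1
  n_mz <- sum(mz_idx); n_dz <- n - n_mz

  # --- state: phenotype / latent trait ---
  if (irt) {
    itemll <- function(th, Y0, W) {
      rasch_loglik_rows(th, obs$a, obs$b, Y0, W)
    }
    Y0 <- list(); W <- list(); theta <- matrix(0, n, 2)
    for (j in 1:2) {
      Yj <- obs$Y[[j]]
      Wj <- 1L - is.na(Yj)
      Yj[is.na(Yj)] <- 0L
      storage.mode(Yj) <- "integer"
      storage.mode(Wj) <- "integer"
      Y0[[j]] <- Yj; W[[j]] <- Wj
      s <- rowSums(Yj)
      kobs <- pmax(rowSums(Wj), 1)
      theta[, j] <- mean(obs$b) + qlogis((s + 0.5) / (kobs + 1))
    }
    # cached per-twin item log-likelihood at the current theta
    ill <- cbind(itemll(theta[, 1], Y0[[1]], W[[1]]),
                 itemll(theta[, 2], Y0[[2]], W[[2]]))
    st <- list(pair_idx = seq_len(n), single_idx = integer(0),
               x1 = theta[, 1], x2 = theta[, 2],
               single_val = numeric(0), r = obs$r)
    step <- matrix(0.8, n, 2)
  } else {
    x1 <- obs$pheno[, 1]; x2 <- obs$pheno[, 2]
    both <- which(!is.na(x1) & !is.na(x2))
    one <- which(xor(is.na(x1), is.na(x2)))
    st <- list(pair_idx = both, single_idx = one,
               x1 = x1, x2 = x2,
               single_val = ifelse(is.na(x1[one]), x2[one], x1[one]),
               r = obs$r)
  }

  # --- initial structural parameters ---
  allx <- c(st$x1[st$pair_idx], st$x2[st$pair_idx], st$single_val)
  vtot <- max(var(allx), 1e-3)
  p <- c(mean(allx), 0,
         log(vtot * 0.25), 0, log(vtot * 0.25), 0, log(vtot * 0.5), 0)
  names(p) <- pn
  jit <- rnorm(8, 0, 0.05); jit[match(names(fixed), pn)] <- 0
  p <- p + jit
  p[match(names(fixed), pn)] <- as.numeric(fixed)
  pi_mz <- rbeta(1, priors$pi_mz[1], priors$pi_mz[2])
  pi_dz <- rbeta(1, priors$pi_dz[1], priors$pi_dz[2])

  # --- adaptive Metropolis bookkeeping for the variance block ---
  d <- length(vi)
  am <- list(mean = p[vi], S = matrix(0, d, d), cnt = 0L, ls = 0)
  am_nc <- am
  eps <- diag(1e-9, d)

  am_propose <- function(state, cur) {
    if (state$cnt >= max(20, 2 * d)) {
      Sp <- exp(state$ls) * (2.38^2 / d) * (state$S / (state$cnt - 1L)) + eps
    } else {
      Sp <- diag(0.02^2, d)
    }
    cur + drop(rnorm(d) %*% chol(Sp))
  }
  am_learn <- function(state, val, acc, t) {
    state$cnt <- state$cnt + 1L
    delta <- val - state$mean
    state$mean <- state$mean + delta / state$cnt
    state$S <- state$S + outer(delta, val - state$mean)
    state$ls <- state$ls + min(0.05, 10 / t) * ((acc * 1) - 0.234)
    state
  }

  var_logpost <- function(p, gs_or_null, M) {
    lp <- sum(dnorm(p[vi], priors$logvar_location, priors$logvar_scale, log = TRUE))
    ll <- if (!is.null(gs_or_null)) biom_loglik_groups(p, gs_or_null)
          else biom_loglik_family(p, st, M)
    ll + lp
  }

  collapsed <- !irt && !has_miss
  gs <- if (collapsed) make_group_stats(st, M) else NULL

  n_iter <- mcmc$n_adapt + mcmc$n_burnin + mcmc$n_keep
  warm <- mcmc$n_adapt + mcmc$n_burnin
  out <- matrix(NA_real_, keep_rows, length(free) + 2L)
  colnames(out) <- c(free, "pi_mz", "pi_dz")
  row <- 0L
  acc_var <- 0; acc_theta <- 0

  for (t in seq_len(n_iter)) {
    adapting <- t <= warm

    # 1. latent traits (IRT)
    if (irt) {
      mo <- pair_moments(p, M, obs$r)
      condv <- mo$v - mo$cc^2 / mo$v
      sdc <- sqrt(condv)
      for (j in 1:2) {
        other <- theta[, 3 - j]
        condm <- mo$m + (mo$cc / mo$v) * (other - mo$m)
        cur <- theta[, j]
        prop <- cur + step[, j] * rnorm(n)
        ill_prop <- itemll(prop, Y0[[j]], W[[j]])
        logr <- ill_prop - ill[, j] +
          dnorm(prop, condm, sdc, log = TRUE) - dnorm(cur, condm, sdc, log = TRUE)
        acc <- log(runif(n)) < logr
        theta[acc, j] <- prop[acc]
        ill[acc, j] <- ill_prop[acc]
        if (adapting) {
          g <- min(0.25, 2 / sqrt(t))
          step[, j] <- pmin(pmax(step[, j] * exp(g * (acc - 0.44)), 1e-3), 10)
        }
        if (t > warm) acc_theta <- acc_theta + mean(acc)
      }
      st$x1 <- theta[, 1]; st$x2 <- theta[, 2]
    }

    # 2a. variance coefficients: joint adaptive Metropolis (centered)
    if (d > 0) {
      prop <- p
      prop[vi] <- am_propose(am, p[vi])
      lp_cur <- var_logpost(p, gs, M)
      lp_prop <- var_logpost(prop, gs, M)
      acc <- log(runif(1)) < (lp_prop - lp_cur)
      if (acc) p <- prop
      if (t > warm) acc_var <- acc_var + acc
      if (adapting) am <- am_learn(am, p[vi], acc, t)
    }

    # 2b. non-centered companion move (IRT): rescale theta with the
    # coefficients, accept on item likelihood + prior
    if (irt && d > 0) {
      mo <- pair_moments(p, M, obs$r)
      l11 <- sqrt(mo$v)
      l21 <- mo$cc / l11
      l22 <- sqrt(pmax(mo$v - l21^2, 1e-12))
      z1 <- (theta[, 1] - mo$m) / l11
      z2 <- (theta[, 2] - mo$m - l21 * z1) / l22
      prop <- p
      prop[vi] <- am_propose(am_nc, p[vi])
      pr <- sum(dnorm(prop[vi], priors$logvar_location, priors$logvar_scale,
                      log = TRUE)) -
            sum(dnorm(p[vi], priors$logvar_location, priors$logvar_scale,
                      log = TRUE))
      mo2 <- pair_moments(prop, M, obs$r)
      if (all(is.finite(mo2$v)) && all(mo2$v > 0) &&
          all(mo2$v^2 > mo2$cc^2)) {
        m11 <- sqrt(mo2$v)
        m21 <- mo2$cc / m11
        m22 <- sqrt(pmax(mo2$v - m21^2, 1e-12))
        th1 <- mo2$m + m11 * z1
        th2 <- mo2$m + m21 * z1 + m22 * z2
        ill1 <- itemll(th1, Y0[[1]], W[[1]])
        ill2 <- itemll(th2, Y0[[2]], W[[2]])
        logr <- pr + sum(ill1) - sum(ill[, 1]) + sum(ill2) - sum(ill[, 2])
        acc <- log(runif(1)) < logr
        if (acc) {
          p <- prop
          theta[, 1] <- th1
          theta[, 2] <- th2
          ill[, 1] <- ill1
          ill[, 2] <- ill2
          st$x1 <- th1
          st$x2 <- th2
        }
        if (adapting) am_nc <- am_learn(am_nc, p[vi], acc, t)
      } else if (adapting) {
        am_nc <- am_learn(am_nc, p[vi], FALSE, t)
      }
    }

    # 3. mean parameters: exact Gibbs
    p <- draw_mean_params(p, st, M, priors, free_mean)

    # 4. missing moderators and pi
    if (has_miss) {
      mo0 <- pair_moments(p, rep(0, length(miss)), obs$r[miss])
      mo1 <- pair_moments(p, rep(1, length(miss)), obs$r[miss])
      ll0 <- ll1 <- numeric(length(miss))
      pb <- match(miss, st$pair_idx); inp <- !is.na(pb)
      if (any(inp)) {
        i <- miss[inp]
        ll0[inp] <- pair_ll_vec(st$x1[i], st$x2[i], mo0$m[inp], mo0$v[inp], mo0$cc[inp])
        ll1[inp] <- pair_ll_vec(st$x1[i], st$x2[i], mo1$m[inp], mo1$v[inp], mo1$cc[inp])
      }
      sb <- match(miss, st$single_idx); ins <- !is.na(sb)
      if (any(ins)) {
        xv <- st$single_val[sb[ins]]
        ll0[ins] <- dnorm(xv, mo0$m[ins], sqrt(mo0$v[ins]), log = TRUE)
        ll1[ins] <- dnorm(xv, mo1$m[ins], sqrt(mo1$v[ins]), log = TRUE)
      }
      piv <- ifelse(mz_idx[miss], pi_mz, pi_dz)
      pr1 <- plogis(qlogis(piv) + ll1 - ll0)
      M[miss] <- rbinom(length(miss), 1L, pr1)
    }
    if (n_mz > 0) pi_mz <- rbeta(1, priors$pi_mz[1] + sum(M[mz_idx]),
                                 priors$pi_mz[2] + n_mz - sum(M[mz_idx]))
    if (n_dz > 0) pi_dz <- rbeta(1, priors$pi_dz[1] + sum(M[!mz_idx]),
                                 priors$pi_dz[2] + n_dz - sum(M[!mz_idx]))

    # 5. record
    if (t > warm && (t - warm) %% mcmc$thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(p[match(free, pn)], pi_mz, pi_dz)
    }
  }

  list(draws = out[seq_len(row), , drop = FALSE],
       accept = c(var_block = if (d > 0) acc_var / mcmc$n_keep else NA_real_,
                  theta = if (irt) acc_theta / (2 * mcmc$n_keep) else NA_real_))
}

pair_ll_vec <- function(x1, x2, m, v, cc) {
  dt <- v * v - cc * cc
  d1 <- x1 - m; d2 <- x2 - m
  -log(2 * pi) - 0.5 * log(dt) -
    0.5 * (v * (d1 * d1 + d2 * d2) - 2 * cc * d1 * d2) / dt
}

run_acem_mcmc <- function(obs, priors, mcmc, fixed = NULL) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_config"))
  fixed <- validate_fixed(fixed)
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max, mcmc$n_chains)
  keep_rows <- mcmc$n_keep %/% mcmc$thin
  chains <- purrr::map(seq_len(mcmc$n_chains), function(ch) {
    res <- run_acem_chain(obs, priors, mcmc, fixed, chain_seeds[ch], keep_rows)
    draws <- tibble::as_tibble(res$draws)
    draws$chain <- ch
    draws$iteration <- seq_len(nrow(draws))
    list(draws = draws, accept = res$accept)
  })
  draws <- dplyr::bind_rows(purrr::map(chains, "draws"))
  draws <- tidyr::pivot_longer(draws, cols = -c("chain", "iteration"),
                               names_to = "parameter", values_to = "value")
  draws <- dplyr::arrange(draws, .data$chain, .data$parameter, .data$iteration)
  list(draws = draws,
       accept = purrr::map(chains, "accept"))
}

validate_fixed <- function(fixed) {
  if (is.null(fixed) || length(fixed) == 0) return(numeric(0))
  fixed <- unlist(fixed)
  bad <- setdiff(names(fixed), acem_par_names())
  if (length(bad)) {
    abort(paste0("Unknown fixed parameter(s): ", paste(bad, collapse = ", ")))
  }
  stopifnot(all(is.finite(fixed)))
  fixed
}
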