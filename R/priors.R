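#' Prior specification
#'
#' Weakly informative priors: Normal(`mean_location`, `mean_scale`^2) on the
#' phenotypic mean `mu` and moderator main effect `beta1m`;
#' Normal(`logvar_location`, `logvar_scale`^2) on the six log-variance
#' intercepts and slopes (weakly informative on the log scale, which also
#' keeps `exp()` from overflowing); independent Beta hyperpriors on the
#' moderator probabilities `pi_mz` and `pi_dz` used when imputing missing
#' moderator values.
#'
#' @param mean_location,mean_scale Normal prior for `mu` and `beta1m`
#'   (scale > 0).
#' @param logvar_location,logvar_scale Normal prior for `beta0a`, `beta1a`,
#'   `beta0c`, `beta1c`, `beta0e`, `beta1e` (scale > 0).
#' @param pi_mz,pi_dz Length-2 positive Beta shape parameters for the MZ and
#'   DZ moderator probabilities (default Beta(1, 1), i.e. uniform).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean_location = 0, mean_scale = 10,
                       logvar_location = 0, logvar_scale = 2,
                       pi_mz = c(1, 1), pi_dz = c(1, 1)) {
  stopifnot(is.finite(mean_location), mean_scale > 0,
            is.finite(logvar_location), logvar_scale > 0,
            length(pi_mz) == 2, all(pi_mz > 0),
            length(pi_dz) == 2, all(pi_dz > 0))
  structure(list(mean_location = mean_location, mean_scale = mean_scale,
                 logvar_location = logvar_location, logvar_scale = logvar_scale,
                 pi_mz = as.numeric(pi_mz), pi_dz = as.numeric(pi_dz)),
            class = "prior_spec")
}

#' MCMC run configuration
#'
#' Defaults follow the reference analysis protocol (5,000 adaptation,
#' 50,000 burn-in, 25,000 kept iterations from one chain). Adaptation and
#' burn-in are both discarded; proposal tuning happens only during those
#' phases so the kept draws come from a fixed kernel. Simulation-suite and
#' test presets use far shorter chains; convergence should be checked with
#' [convergence_report()] rather than assumed from length.
#'
#' @param n_adapt Proposal-adaptation iterations (discarded; >= 0).
#' @param n_burnin Burn-in iterations (discarded; >= 0).
#' @param n_keep Kept iterations per chain (>= 1).
#' @param n_chains Number of independent chains.
#' @param thin Thinning interval for kept iterations.
#' @param seed Integer seed; fully determines the run.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_adapt = 5000, n_burnin = 50000, n_keep = 25000,
                        n_chains = 1, thin = 1, seed = 1L) {
  stopifnot(n_adapt >= 0, n_burnin >= 0, n_keep >= 1, n_chains >= 1, thin >= 1)
  structure(list(n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_keep = as.integer(n_keep),
                 n_chains = as.integer(n_chains),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}
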