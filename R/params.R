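#' ACE x M model parameters
#'
#' Bundles the structural parameters of the moderated twin ACE model: the
#' phenotypic mean `mu`, the moderator main effect `beta1m`, and an
#' intercept/slope pair per variance component moderating the log variance,
#' e.g. \eqn{\sigma^2_A(M) = \exp(\beta_{0a} + \beta_{1a} M)}. Because the
#' moderation acts on the log variance, every implied variance is strictly
#' positive and the map from coefficients to variances is one-to-one — unlike
#' path-moderation parametrizations (see [purcell_equivalent_solutions()]).
#'
#' @param mu Phenotypic mean on the latent-trait scale.
#' @param beta1m Main effect of the moderator on the mean.
#' @param beta0a,beta1a Log-variance intercept and slope for the additive
#'   genetic (A) component.
#' @param beta0c,beta1c Intercept and slope for the common environment (C).
#' @param beta0e,beta1e Intercept and slope for the unique environment (E).
#'
#' @return An object of class `acem_params` (a named list of eight finite
#'   numbers).
#' @examples
#' p <- acem_params(beta0a = log(0.25), beta0c = log(0.25), beta0e = log(0.5),
#'                  beta1m = 0.7)
#' heritability(p)
#' @export
acem_params <- function(mu = 0, beta1m = 0,
                        beta0a = 0, beta1a = 0,
                        beta0c = 0, beta1c = 0,
                        beta0e = 0, beta1e = 0) {
  p <- list(mu = mu, beta1m = beta1m,
            beta0a = beta0a, beta1a = beta1a,
            beta0c = beta0c, beta1c = beta1c,
            beta0e = beta0e, beta1e = beta1e)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("acem_params fields must be single finite numbers: ",
                 paste(bad, collapse = ", ")))
  }
  structure(lapply(p, as.numeric), class = "acem_params")
}

#' @export
print.acem_params <- function(x, ...) {
  cat("<acem_params>\n")
  cat(sprintf("  mean:      mu = %.4g, beta1m = %.4g\n", x$mu, x$beta1m))
  cat(sprintf("  A: exp(%.4g + %.4g M)\n", x$beta0a, x$beta1a))
  cat(sprintf("  C: exp(%.4g + %.4g M)\n", x$beta0c, x$beta1c))
  cat(sprintf("  E: exp(%.4g + %.4g M)\n", x$beta0e, x$beta1e))
  invisible(x)
}

#' @export
as.data.frame.acem_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

structural_par_names <- function() {
  c("mu", "beta1m", "beta0a", "beta1a", "beta0c", "beta1c", "beta0e", "beta1e")
}

as_acem_params <- function(x) {
  if (inherits(x, "acem_params")) return(x)
  do.call(acem_params, as.list(x)[structural_par_names()])
}

#' Log-linear variance moderation
#'
#' Variance of a component as a function of a moderator value under log-linear
#' moderation: `exp(beta0 + beta1 * m)`. The intercept `beta0` is the log
#' variance at `m = 0`; `beta1` is the interaction (moderation) effect.
#'
#' @param beta0,beta1 Log-variance intercept and slope.
#' @param m Moderator value(s); recycled against `beta0`/`beta1`.
#' @return Strictly positive variance(s).
#' @examples
#' log_linear_variance(log(0.25), 0, m = 1) # constant 0.25
#' @export
log_linear_variance <- function(beta0, beta1, m) {
  if (!all(is.finite(beta0)) || !all(is.finite(beta1)) || !all(is.finite(m))) {
    abort("log_linear_variance() requires finite inputs.")
  }
  v <- exp(beta0 + beta1 * m)
  stopifnot(all(v > 0))
  v
}

component_variances <- function(params, m) {
  list(a = log_linear_variance(params$beta0a, params$beta1a, m),
       c = log_linear_variance(params$beta0c, params$beta1c, m),
       e = log_linear_variance(params$beta0e, params$beta1e, m))
}

#' Twin-pair mean and covariance implied by the ACE x M model
#'
#' The marginal distribution of a twin pair's latent traits, after
#' integrating out the familial effects, is bivariate normal. Both means are
#' `mu + beta1m * m`; both variances are \eqn{\sigma^2_A(m) + \sigma^2_C(m) +
#' \sigma^2_E(m)}; the cross-covariance is \eqn{\sigma^2_A(m) + \sigma^2_C(m)}
#' for MZ pairs and \eqn{0.5\,\sigma^2_A(m) + \sigma^2_C(m)} for DZ pairs,
#' reflecting the genetic correlation of 1 versus 0.5.
#'
#' @param params An [acem_params()] object.
#' @param m Moderator value (single finite number).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A list with `mean` (length-2 vector) and `sigma` (2 x 2 matrix).
#' @examples
#' p <- acem_params(beta0a = log(0.25), beta0c = log(0.25), beta0e = log(0.5))
#' twin_covariance(p, m = 0, zygosity = "DZ")$sigma
#' @export
twin_covariance <- function(params, m, zygosity = c("MZ", "DZ")) {
  params <- as_acem_params(params)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) {
    abort("`m` must be a single finite number.")
  }
  if (!is.character(zygosity) || !all(zygosity %in% c("MZ", "DZ"))) {
    abort("`zygosity` must be \"MZ\" or \"DZ\".")
  }
  zygosity <- match.arg(zygosity)
  s2 <- component_variances(params, m)
  r <- if (zygosity == "MZ") 1 else 0.5
  v <- s2$a + s2$c + s2$e
  cv <- r * s2$a + s2$c
  mu <- rep(params$mu + params$beta1m * m, 2)
  sigma <- matrix(c(v, cv, cv, v), 2, 2)
  list(mean = mu, sigma = sigma)
}

#' Heritability at the moderator reference level
#'
#' Proportion of phenotypic variance attributable to additive genetic
#' influences at `m = 0`:
#' \eqn{h^2 = \exp(\beta_{0a}) / (\exp(\beta_{0a}) + \exp(\beta_{0c}) +
#' \exp(\beta_{0e}))}.
#'
#' @inheritParams twin_covariance
#' @return A proportion in (0, 1).
#' @export
heritability <- function(params) {
  params <- as_acem_params(params)
  s2 <- component_variances(params, 0)
  s2$a / (s2$a + s2$c + s2$e)
}

#' Phenotypic variance explained by a binary moderator
#'
#' For a Bernoulli(`p`) family-level moderator with main effect `beta1m`, the
#' mean shift contributes variance \eqn{\beta_{1m}^2 p (1 - p)} on top of the
#' phenotypic variance \eqn{\sigma^2_P} of the ACE components (evaluated at
#' the intercepts, i.e. the zero-interaction case). The explained proportion
#' is \eqn{\beta_{1m}^2 p(1-p) / (\beta_{1m}^2 p(1-p) + \sigma^2_P)}. Used to
#' calibrate simulation scenarios (~11% with `beta1m = 0.7`, `p = 0.5`,
#' \eqn{\sigma^2_P = 1}).
#'
#' @inheritParams twin_covariance
#' @param p Bernoulli probability of the moderator, strictly inside (0, 1).
#' @return A proportion in [0, 1).
#' @export
moderator_variance_explained <- function(params, p) {
  params <- as_acem_params(params)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    abort("`p` must be a single number strictly between 0 and 1.")
  }
  s2 <- component_variances(params, 0)
  s2p <- s2$a + s2$c + s2$e
  vm <- params$beta1m^2 * p * (1 - p)
  vm / (vm + s2p)
}
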