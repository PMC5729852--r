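#' Variance under path moderation
#'
#' In the path-moderation parametrization of moderated twin models, a
#' component's loading is `b0 + b1 * m` and the implied variance is its
#' square, `(b0 + b1 * m)^2`. The square makes the sign of the coefficients
#' unidentifiable, which is why the log-linear parametrization of
#' [log_linear_variance()] is preferred.
#'
#' @param b0 Path intercept.
#' @param b1 Path moderation slope.
#' @param m Moderator value(s).
#' @return Nonnegative variance(s).
#' @examples
#' purcell_variance(0.5, 0, 1) == purcell_variance(-0.5, 0, 1)
#' @export
purcell_variance <- function(b0, b1, m) {
  if (!all(is.finite(b0)) || !all(is.finite(b1)) || !all(is.finite(m))) {
    abort("purcell_variance() requires finite inputs.")
  }
  (b0 + b1 * m)^2
}

#' Equivalent path-moderation solutions
#'
#' Enumerates all `(b0, b1)` pairs whose squared-path variance function
#' `(b0 + b1 * m)^2` agrees with the input pair at every supplied moderator
#' level. For a binary moderator there are generically four such pairs (the
#' signs of `|b0|` and `|b0 + b1|` may be flipped independently), so the
#' likelihood has multiple equal maxima and the parametrization is not
#' identified. The log-linear parametrization has a singleton orbit: the map
#' `(beta0, beta1) -> (V(0), V(1))` is injective.
#'
#' With a single distinct level the orbit is an infinite family; only the two
#' global sign flips are returned in that case. With three or more distinct
#' levels only sign vectors that remain collinear survive (generically just
#' the global flip).
#'
#' @param b0,b1 The reference path coefficients.
#' @param levels Moderator levels observed in the data (default binary 0/1).
#' @param tol Numerical tolerance for verifying variance equality.
#' @return A tibble with columns `b0`, `b1`, one row per equivalent solution
#'   (the input pair included).
#' @examples
#' purcell_equivalent_solutions(1, 0.5)
#' @export
purcell_equivalent_solutions <- function(b0, b1, levels = c(0, 1), tol = 1e-8) {
  stopifnot(is.finite(b0), is.finite(b1), length(levels) >= 1, all(is.finite(levels)))
  lv <- sort(unique(levels))
  k <- length(lv)
  loadings <- b0 + b1 * lv

  if (k == 1L) {
    cand <- unique(data.frame(b0 = c(b0, -b0), b1 = c(b1, -b1)))
  } else {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    X <- cbind(1, lv)
    sols <- apply(signs, 1L, function(s) {
      y <- s * loadings
      beta <- stats::lm.fit(X, y)$coefficients
      fit <- X %*% beta
      if (max(abs(fit - y)) > tol * (1 + max(abs(y)))) return(c(NA_real_, NA_real_))
      beta
    })
    sols <- t(sols)
    sols <- sols[stats::complete.cases(sols), , drop = FALSE]
    cand <- unique(data.frame(b0 = round(sols[, 1], 12), b1 = round(sols[, 2], 12)))
  }

  ok <- vapply(seq_len(nrow(cand)), function(i) {
    max(abs(purcell_variance(cand$b0[i], cand$b1[i], lv) -
              purcell_variance(b0, b1, lv))) <= tol * (1 + max(loadings^2))
  }, logical(1))
  tibble::as_tibble(cand[ok, , drop = FALSE])
}
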