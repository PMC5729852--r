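#' Construct an item bank
#'
#' An item bank records, per dichotomous item, its difficulty `b_k` (the
#' trait level at which the endorsement probability is 50%) and a fixed,
#' known discrimination `a_k` (1 for the pure Rasch model; other positive
#' constants give the one-parameter logistic model with imputed
#' discriminations).
#'
#' @param difficulty Numeric vector of item difficulties (finite).
#' @param discrimination Positive discrimination(s), recycled to the number
#'   of items. Default 1 (Rasch).
#' @param item_id Optional unique item identifiers; defaults to
#'   `item_1 ... item_K`.
#' @return A tibble with columns `item_id`, `difficulty`, `discrimination`.
#' @examples
#' item_bank(c(-1, 0, 1))
#' @export
item_bank <- function(difficulty, discrimination = 1, item_id = NULL) {
  if (!is.numeric(difficulty) || length(difficulty) < 1 || !all(is.finite(difficulty))) {
    abort("`difficulty` must be a non-empty vector of finite numbers.")
  }
  k <- length(difficulty)
  discrimination <- rep_len(discrimination, k)
  if (!all(is.finite(discrimination)) || any(discrimination <= 0)) {
    abort("`discrimination` values must be finite and strictly positive.")
  }
  if (is.null(item_id)) item_id <- sprintf("item_%d", seq_len(k))
  if (anyDuplicated(item_id)) abort("`item_id` values must be unique.")
  tibble::tibble(item_id = as.character(item_id),
                 difficulty = as.numeric(difficulty),
                 discrimination = as.numeric(discrimination))
}

validate_item_bank <- function(bank) {
  if (!is.data.frame(bank) ||
      !all(c("item_id", "difficulty", "discrimination") %in% names(bank))) {
    abort("An item bank needs columns item_id, difficulty, discrimination.")
  }
  item_bank(bank$difficulty, bank$discrimination, bank$item_id)
}

#' Draw item difficulties for a simulated bank
#'
#' Difficulties are drawn independently from Normal(`mean`, `sd`);
#' discriminations are fixed at 1 (Rasch). A positive mean yields mostly hard
#' items and a floor effect in sum scores; a negative mean mostly easy items
#' and a ceiling effect.
#'
#' @param n_items Number of items (>= 1).
#' @param mean,sd Normal parameters of the difficulty distribution; `sd > 0`.
#' @return An [item_bank()] tibble.
#' @export
draw_item_difficulties <- function(n_items, mean = 1, sd = 1) {
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd <= 0) {
    abort("`sd` must be a single positive number.")
  }
  stopifnot(n_items >= 1)
  item_bank(rnorm(n_items, mean, sd))
}

#' Rasch / fixed-discrimination response probability
#'
#' Probability of a correct (1) response as a logistic function of the
#' distance between the latent trait and the item difficulty:
#' \eqn{P(Y = 1) = \mathrm{logistic}(a_k (\theta - b_k))}. With `a_k = 1`
#' this is the Rasch model; the probability is 0.5 at `theta = b_k` and
#' monotone increasing in `theta`.
#'
#' @param theta Latent trait value(s), finite.
#' @param difficulty Item difficulty `b_k`.
#' @param discrimination Fixed positive discrimination `a_k` (default 1).
#' @return Probabilities in (0, 1), recycled over the inputs.
#' @examples
#' irt_probability(0, difficulty = 1) # 1 / (1 + e)
#' @export
irt_probability <- function(theta, difficulty, discrimination = 1) {
  if (!all(is.finite(theta))) abort("`theta` must be finite.")
  if (!all(is.finite(difficulty))) abort("`difficulty` must be finite.")
  if (!all(is.finite(discrimination)) || any(discrimination <= 0)) {
    abort("`discrimination` must be finite and strictly positive.")
  }
  plogis(discrimination * (theta - difficulty))
}
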