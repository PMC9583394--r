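# Logistic psychometric functions: evaluation and the inverse at a
# target proportion correct (the sweet point).

#' Logistic sigmoid with midpoint alpha and slope beta
#'
#' @param x Stimulus magnitude (vectorized).
#' @param alpha Midpoint: the magnitude at which the function is 0.5.
#' @param beta Slope parameter (> 0); larger is steeper.
#' @return Probability in (0, 1): `1 / (1 + exp(beta * (alpha - x)))`.
#' @examples
#' logistic_fun(0.05, alpha = 0.05, beta = 100)   # 0.5 at the midpoint
#' @export
logistic_fun <- function(x, alpha, beta) {
  stopifnot(all(beta > 0))
  1 / (1 + exp(beta * (alpha - x)))
}

#' A candidate psychometric function (hypothesis)
#'
#' The maximum likelihood procedure maintains a set of hypotheses that
#' share slope `beta` and chance level `gamma` but differ in midpoint
#' `alpha`. In a 2AFC task the chance level is 50%.
#'
#' @param alpha Midpoint of the underlying logistic.
#' @param beta Slope (> 0).
#' @param gamma Chance (guessing) level, in \[0, 1).
#' @return An object of class `psych_hypothesis`.
#' @export
psych_hypothesis <- function(alpha, beta = 100, gamma = 0.5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma < 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "psych_hypothesis")
}

#' @export
format.psych_hypothesis <- function(x, ...) {
  sprintf("psi(alpha=%g, beta=%g, gamma=%g)", x$alpha, x$beta, x$gamma)
}

#' @export
print.psych_hypothesis <- function(x, ...) {
  cat("<psychometric hypothesis>", format(x), "\n")
  invisible(x)
}

#' Psychometric function: probability correct at stimulus magnitude x
#'
#' `psi(x) = gamma + (1 - gamma) * logistic(x; alpha, beta)`. The floor
#' is the chance level `gamma` and the ceiling is 1; no lapse term is
#' carried by the hypotheses (attentional lapses are modeled only in the
#' virtual observer).
#'
#' @param x Stimulus magnitude (vectorized).
#' @param hyp A `psych_hypothesis`.
#' @return Probability in \[gamma, 1).
#' @examples
#' h <- psych_hypothesis(alpha = 0.05)
#' psi(0.05, h)     # 0.75: halfway between chance and ceiling
#' psi(-1, h)       # ~0.5: the 2AFC floor
#' @export
psi <- function(x, hyp) {
  stopifnot(inherits(hyp, "psych_hypothesis"))
  hyp$gamma + (1 - hyp$gamma) * logistic_fun(x, hyp$alpha, hyp$beta)
}

#' Inverse psychometric function (sweet-point computation)
#'
#' Solves `psi(x) = p_target` for the stimulus magnitude:
#' `x = alpha - (1/beta) * log((1 - gamma)/(p_target - gamma) - 1)`.
#' Defined for `gamma < p_target < 1`. At `p_target = 0.809` with
#' `gamma = 0.5` this is the 2AFC sweet point, the placement that
#' minimizes the variability of the threshold estimate.
#'
#' @param p_target Target proportion correct, in (gamma, 1).
#' @param hyp A `psych_hypothesis`.
#' @return Stimulus magnitude x with `psi(x, hyp) == p_target`.
#' @examples
#' h <- psych_hypothesis(alpha = 0.05)
#' inverse_psi(0.809, h)          # 0.0548...
#' psi(inverse_psi(0.809, h), h)  # 0.809, round trip
#' @export
inverse_psi <- function(p_target, hyp) {
  stopifnot(inherits(hyp, "psych_hypothesis"),
            is.numeric(p_target), length(p_target) == 1L)
  if (!(p_target > hyp$gamma && p_target < 1)) {
    stop("p_target must lie strictly between gamma (", hyp$gamma,
         ") and 1, got ", format(p_target), call. = FALSE)
  }
  hyp$alpha - (1 / hyp$beta) * log((1 - hyp$gamma) / (p_target - hyp$gamma) - 1)
}
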