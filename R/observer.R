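# A parameterized virtual listener for closed-loop simulation: answers
# 2AFC trials stochastically from a known psychometric function.

#' Virtual 2AFC observer
#'
#' Simulates a listener whose probability of a correct answer at
#' stimulus offset delta is
#' `gamma + (1 - gamma - lapse) * logistic(delta; true_alpha, true_beta)`.
#' With `lapse = 0` this is exactly the psychometric function [psi()];
#' a positive lapse lowers the ceiling below 1 (attentional lapses make
#' the observer guess on a fraction of trials, symmetrically). Answers
#' depend only on the offset, not on presentation order.
#'
#' The observer carries its own reproducible random stream: the same
#' seed always yields the same response sequence.
#'
#' @param true_alpha Midpoint of the observer's logistic.
#' @param true_beta Slope of the observer's logistic (> 0).
#' @param gamma Chance level, in \[0, 1).
#' @param lapse Lapse rate, in \[0, 0.1\]; `gamma + lapse < 1`.
#' @param seed Integer seed of the observer's response stream.
#' @return An object of class `virtual_observer`.
#' @examples
#' obs <- virtual_observer(true_alpha = 0.03, seed = 42)
#' respond(obs, 0.1)    # almost surely TRUE: far above threshold
#' @export
virtual_observer <- function(true_alpha, true_beta = 100, gamma = 0.5,
                             lapse = 0, seed = 1L) {
  stopifnot(is.numeric(true_alpha), length(true_alpha) == 1L, true_alpha > 0,
            is.numeric(true_beta), true_beta > 0,
            gamma >= 0, gamma < 1, lapse >= 0, lapse <= 0.1)
  if (gamma + lapse >= 1) stop("gamma + lapse must be < 1", call. = FALSE)
  obs <- new.env(parent = emptyenv())
  obs$true_alpha <- true_alpha
  obs$true_beta <- true_beta
  obs$gamma <- gamma
  obs$lapse <- lapse
  obs$seed <- as.integer(seed)
  obs$rng <- local_rng(seed)
  class(obs) <- "virtual_observer"
  obs
}

#' @export
print.virtual_observer <- function(x, ...) {
  cat(sprintf(
    "<virtual observer> alpha=%g beta=%g gamma=%g lapse=%g seed=%d\n",
    x$true_alpha, x$true_beta, x$gamma, x$lapse, x$seed))
  invisible(x)
}

#' Probability that the observer answers correctly at a given offset
#'
#' @param observer A `virtual_observer`.
#' @param delta Stimulus offset (>= 0; vectorized).
#' @return Probability of a correct answer.
#' @export
response_probability <- function(observer, delta) {
  stopifnot(inherits(observer, "virtual_observer"))
  observer$gamma + (1 - observer$gamma - observer$lapse) *
    logistic_fun(delta, observer$true_alpha, observer$true_beta)
}

#' Draw one 2AFC judgment from the observer
#'
#' @param observer A `virtual_observer`.
#' @param delta Stimulus offset (>= 0), the magnitude separating the
#'   variable from the standard.
#' @return Logical: `TRUE` if the simulated answer is correct.
#' @export
respond <- function(observer, delta) {
  stopifnot(inherits(observer, "virtual_observer"),
            is.numeric(delta), length(delta) == 1L, delta >= 0)
  observer$rng$draw() < response_probability(observer, delta)
}

#' Wrap an observer as a track responder
#'
#' Adapts a [virtual_observer()] to the
#' `responder(delta, standard, variable, order)` interface expected by
#' [run_track()] and [run_session()]. The observer ignores the
#' coordinates and presentation order; its judgment depends only on the
#' offset magnitude.
#'
#' @param observer A `virtual_observer`.
#' @return A responder function.
#' @export
observer_responder <- function(observer) {
  stopifnot(inherits(observer, "virtual_observer"))
  function(delta, standard, variable, order) respond(observer, delta)
}

#' The observer's true sweet point
#'
#' The stimulus offset at which the observer's lapse-free psychometric
#' function reaches `p_target` — the quantity the sweet-point JND
#' readout of a track estimates.
#'
#' @param observer A `virtual_observer`.
#' @param p_target Target proportion correct (default 0.809).
#' @return Stimulus offset.
#' @export
true_sweet_point <- function(observer, p_target = 0.809) {
  stopifnot(inherits(observer, "virtual_observer"))
  inverse_psi(p_target, psych_hypothesis(observer$true_alpha,
                                         observer$true_beta,
                                         observer$gamma))
}
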