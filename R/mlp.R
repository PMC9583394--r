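# The adaptive maximum-likelihood track: hypothesis grid, per-trial
# likelihood update, sweet-point stimulus selection, and JND readout.

#' Standardized conventions for the maximum likelihood procedure
#'
#' Defaults are the proposed standard for evaluating two-dimensional
#' sonification designs: chance level 50% (2AFC), logistic slope 100,
#' 100 hypotheses with midpoints 0.001 to 0.1 (step 0.001), stimulus
#' placement at the 80.9% sweet point, 12 trials per track, first
#' stimulus at offset 0.07 (a clearly audible difference).
#'
#' @param gamma Chance level, in \[0, 1).
#' @param beta Shared logistic slope (> 0).
#' @param alpha_min,alpha_max Range of hypothesis midpoints; also the
#'   range of presentable stimulus offsets.
#' @param n_hypotheses Number of hypotheses (midpoints linearly spaced
#'   over \[alpha_min, alpha_max\], endpoints included).
#' @param p_target Sweet-point proportion correct, in (gamma, 1).
#' @param n_trials Trials per track.
#' @param initial_delta Stimulus offset of the first trial.
#' @param grid_step Quantization step of presentable offsets.
#' @return An object of class `mlp_conventions`.
#' @export
mlp_conventions <- function(gamma = 0.5, beta = 100,
                            alpha_min = 0.001, alpha_max = 0.1,
                            n_hypotheses = 100, p_target = 0.809,
                            n_trials = 12, initial_delta = 0.07,
                            grid_step = 0.001) {
  stopifnot(gamma >= 0, gamma < 1, beta > 0,
            alpha_min > 0, alpha_max > alpha_min,
            p_target > gamma, p_target < 1,
            n_trials >= 1, grid_step > 0,
            initial_delta >= alpha_min, initial_delta <= alpha_max)
  if (n_hypotheses < 2) {
    stop("n_hypotheses must be at least 2", call. = FALSE)
  }
  structure(list(gamma = gamma, beta = beta,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 n_hypotheses = as.integer(n_hypotheses),
                 p_target = p_target, n_trials = as.integer(n_trials),
                 initial_delta = initial_delta, grid_step = grid_step),
            class = "mlp_conventions")
}

#' Hypothesis midpoint grid
#'
#' Midpoints alpha spread linearly over the complete range in which the
#' JND is assumed to lie; all hypotheses share beta and gamma. Under the
#' defaults this yields alpha = 0.001, 0.002, ..., 0.1.
#'
#' @param conventions An `mlp_conventions`.
#' @return Numeric vector of midpoints, length `n_hypotheses`, strictly
#'   increasing with constant step.
#' @export
hypothesis_grid <- function(conventions) {
  stopifnot(inherits(conventions, "mlp_conventions"))
  seq(conventions$alpha_min, conventions$alpha_max,
      length.out = conventions$n_hypotheses)
}

#' Start a new MLP track
#'
#' A track measures one JND: one standard, one direction, one adaptive
#' run of `n_trials` 2AFC trials. The track carries one log-likelihood
#' accumulator per hypothesis (natural log; the argmax is invariant to
#' the log base).
#'
#' @param standard A `standard_point`.
#' @param direction A `direction_spec` or direction label.
#' @param conventions An `mlp_conventions`.
#' @param seed Optional integer recorded in the track (used by
#'   [run_track()] for presentation-order randomization).
#' @return An object of class `mlp_track`.
#' @export
new_track <- function(standard, direction, conventions = mlp_conventions(),
                      seed = NA_integer_) {
  stopifnot(inherits(standard, "standard_point"),
            inherits(conventions, "mlp_conventions"))
  if (!inherits(direction, "direction_spec")) direction <- direction_spec(direction)
  alphas <- hypothesis_grid(conventions)
  # per-trial likelihood terms for every on-grid stimulus, precomputed:
  # rows = stimulus grid (alpha_min..alpha_max by grid_step), cols = hypotheses
  grid <- seq(conventions$alpha_min, conventions$alpha_max,
              by = conventions$grid_step)
  p <- conventions$gamma + (1 - conventions$gamma) /
    (1 + exp(conventions$beta * outer(grid, alphas, function(d, a) a - d)))
  structure(list(
    standard = standard,
    direction = direction,
    conventions = conventions,
    alphas = alphas,
    log_likelihoods = numeric(length(alphas)),
    deltas = numeric(0),
    orders = character(0),
    corrects = logical(0),
    stim_grid = grid,
    log_p = log(p),
    log_q = log1p(-p),
    seed = seed
  ), class = "mlp_track")
}

#' Trial history of a track
#'
#' @param track An `mlp_track`.
#' @return A data frame with one row per completed trial: `n` (1-based
#'   index), `delta`, `presentation_order`, `correct`.
#' @export
track_history <- function(track) {
  stopifnot(inherits(track, "mlp_track"))
  data.frame(n = seq_along(track$deltas), delta = track$deltas,
             presentation_order = track$orders, correct = track$corrects,
             stringsAsFactors = FALSE)
}

n_trials_done <- function(track) length(track$deltas)

#' @export
print.mlp_track <- function(x, ...) {
  cat("<MLP track> ", format(x$standard), ", direction ", x$direction$label,
      ": ", n_trials_done(x), "/", x$conventions$n_trials, " trials\n", sep = "")
  if (n_trials_done(x)) {
    b <- best_hypothesis(x)
    cat("  best hypothesis alpha =", format(b$alpha), "\n")
  }
  invisible(x)
}

# psi of every hypothesis at one stimulus offset, vectorized over the grid
psi_grid <- function(track, delta) {
  cv <- track$conventions
  cv$gamma + (1 - cv$gamma) / (1 + exp(cv$beta * (track$alphas - delta)))
}

#' Record one trial and update the likelihoods
#'
#' Adds `log(psi_j(delta))` to hypothesis j's accumulator when the
#' answer was correct and `log(1 - psi_j(delta))` when it was wrong, for
#' every hypothesis j — the per-trial term of the running log-likelihood
#' sum. The incremental accumulators always equal a from-scratch
#' recomputation over the full history.
#'
#' @param track An `mlp_track`.
#' @param delta Presented stimulus offset (a grid value).
#' @param correct Logical: was the participant's answer correct?
#' @param presentation_order `"standard_first"` or `"variable_first"`.
#' @return The updated `mlp_track`.
#' @export
record_trial <- function(track, delta, correct,
                         presentation_order = "standard_first") {
  stopifnot(inherits(track, "mlp_track"),
            is.numeric(delta), length(delta) == 1L,
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  if (!presentation_order %in% c("standard_first", "variable_first")) {
    stop("presentation_order must be 'standard_first' or 'variable_first'",
         call. = FALSE)
  }
  if (n_trials_done(track) >= track$conventions$n_trials) {
    stop("track already holds its full complement of ",
         track$conventions$n_trials, " trials", call. = FALSE)
  }
  # on-grid stimuli use the precomputed likelihood terms
  i <- round((delta - track$conventions$alpha_min) / track$conventions$grid_step) + 1
  if (i >= 1 && i <= length(track$stim_grid) &&
      abs(track$stim_grid[i] - delta) < 1e-9) {
    term <- if (correct) track$log_p[i, ] else track$log_q[i, ]
  } else {
    p <- psi_grid(track, delta)
    term <- if (correct) log(p) else log1p(-p)
  }
  track$log_likelihoods <- track$log_likelihoods + term
  track$deltas <- c(track$deltas, delta)
  track$orders <- c(track$orders, presentation_order)
  track$corrects <- c(track$corrects, correct)
  track
}

#' Most likely hypothesis of a track
#'
#' The hypothesis with the highest accumulated likelihood best
#' approximates the participant's psychometric function. Ties (e.g. the
#' empty track, where all accumulators are zero) break toward the
#' smallest midpoint.
#'
#' @param track An `mlp_track`.
#' @return A `psych_hypothesis`.
#' @export
best_hypothesis <- function(track) {
  stopifnot(inherits(track, "mlp_track"))
  j <- which.max(track$log_likelihoods)  # first max = smallest alpha
  psych_hypothesis(track$alphas[j], track$conventions$beta,
                   track$conventions$gamma)
}

# round half-up to the nearest multiple of step
round_to_grid <- function(x, step) {
  floor(x / step + 0.5) * step
}

#' Offset of the next stimulus
#'
#' The first trial uses `initial_delta` (a clearly audible difference).
#' Every later trial is placed at the sweet point of the current best
#' hypothesis — the inverse psychometric function at `p_target` — so
#' that most trials land near the JND. The result is rounded half-up to
#' the stimulus grid and clamped to \[alpha_min, alpha_max\].
#'
#' @param track An `mlp_track`.
#' @param unrounded If `TRUE`, return the raw sweet point before grid
#'   quantization and clamping (the first trial still returns
#'   `initial_delta`).
#' @return Stimulus offset for the next trial.
#' @export
select_next_stimulus <- function(track, unrounded = FALSE) {
  stopifnot(inherits(track, "mlp_track"))
  cv <- track$conventions
  if (n_trials_done(track) == 0L) return(cv$initial_delta)
  sweet <- inverse_psi(cv$p_target, best_hypothesis(track))
  if (unrounded) return(sweet)
  min(cv$alpha_max, max(cv$alpha_min, round_to_grid(sweet, cv$grid_step)))
}

#' JND readout of a completed track
#'
#' Two conventions are offered. `"sweet_point"` (default) reports the
#' inverse psychometric function of the best hypothesis at `p_target`,
#' clamped to the grid range. `"midpoint"` reports the best hypothesis's
#' midpoint alpha itself; only under this convention is the grid floor
#' 0.001 the smallest reportable JND.
#'
#' @param track A completed `mlp_track`.
#' @param mode `"sweet_point"` or `"midpoint"`.
#' @return The JND estimate (stimulus magnitude).
#' @export
jnd_estimate <- function(track, mode = c("sweet_point", "midpoint")) {
  stopifnot(inherits(track, "mlp_track"))
  mode <- match.arg(mode)
  if (n_trials_done(track) < track$conventions$n_trials) {
    stop("track is incomplete: ", n_trials_done(track), " of ",
         track$conventions$n_trials, " trials", call. = FALSE)
  }
  best <- best_hypothesis(track)
  if (mode == "midpoint") return(best$alpha)
  cv <- track$conventions
  min(cv$alpha_max, max(cv$alpha_min, inverse_psi(cv$p_target, best)))
}

#' Run one full adaptive track against a responder
#'
#' Executes exactly `n_trials` trials: select the stimulus, present the
#' (standard, variable) pair in a random order, record the response,
#' update the likelihoods. The responder is called as
#' `responder(delta, standard_coordinate, variable_coordinate, order)`
#' and must return `TRUE` (correct) or `FALSE` (wrong); see
#' [observer_responder()] for the simulated case. If the responder
#' errors, the partial track is preserved in the error's `track` field.
#'
#' @param standard A `standard_point`.
#' @param direction A `direction_spec` or label.
#' @param responder Function mapping a presented pair to a judgment.
#' @param conventions An `mlp_conventions`.
#' @param seed Integer seed for presentation-order randomization.
#' @param mode JND readout mode, passed to [jnd_estimate()].
#' @return A list with elements `track` (the final `mlp_track`) and
#'   `jnd` (the readout).
#' @export
run_track <- function(standard, direction, responder,
                      conventions = mlp_conventions(), seed = 1L,
                      mode = c("sweet_point", "midpoint")) {
  stopifnot(is.function(responder))
  mode <- match.arg(mode)
  track <- new_track(standard, direction, conventions, seed = seed)
  rng <- local_rng(seed)
  order_draws <- rng$draw(conventions$n_trials)
  for (i in seq_len(conventions$n_trials)) {
    delta <- select_next_stimulus(track)
    order <- if (order_draws[i] < 0.5) "standard_first" else "variable_first"
    variable <- variable_coordinate(standard, direction, delta)
    correct <- tryCatch(
      isTRUE(responder(delta, standard$coordinate, variable, order)),
      error = function(e) {
        stop(structure(class = c("track_aborted", "error", "condition"),
                       list(message = paste0("responder failed at trial ", i,
                                             ": ", conditionMessage(e)),
                            call = sys.call(-1), track = track)))
      })
    track <- record_trial(track, delta, correct, order)
  }
  list(track = track, jnd = jnd_estimate(track, mode))
}

# A private, reproducible uniform stream backed by R's own RNG.
# The stream keeps its own copy of .Random.seed and swaps it in and out
# around each draw, so tracks and observers never disturb (and are never
# disturbed by) the caller's RNG state.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  st <- new.env(parent = emptyenv())
  swap_in <- function(state) {
    prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    prev
  }
  swap_out <- function(prev) {
    st$state <- get(".Random.seed", envir = globalenv())
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
  }
  st$state <- NULL
  st$draw <- function(n = 1L) {
    prev <- swap_in(st$state)
    out <- stats::runif(n)
    swap_out(prev)
    out
  }
  st
}
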