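# Independent oracles and fixture builders used across the suite.

# From-scratch log-likelihood recomputation (plain double loop over the
# full history), deliberately independent of the track's incremental
# accumulators. `base` lets the argmax be checked under different log
# bases.
loglik_scratch <- function(track, base = exp(1)) {
  cv <- track$conventions
  h <- track_history(track)
  vapply(track$alphas, function(a) {
    s <- 0
    for (i in seq_len(nrow(h))) {
      p <- cv$gamma + (1 - cv$gamma) / (1 + exp(cv$beta * (a - h$delta[i])))
      s <- s + if (h$correct[i]) log(p, base) else log(1 - p, base)
    }
    s
  }, numeric(1))
}

# literal four-case interference classification, written straight from
# the case rule (independent of interference())
classify_interference_literal <- function(jnd_x, jnd_y, jnd_diag) {
  jnd_min <- min(jnd_x, jnd_y)
  jnd_max <- max(jnd_x, jnd_y)
  T_s <- 0.5 * log10(jnd_max / jnd_min)
  d_s <- 0.5 * log10(jnd_diag / jnd_min)
  if (d_s < 0) "positive"
  else if (d_s == 0) "none"
  else if (d_s <= T_s) "usual"
  else "negative"
}

# a track filled with random on-grid trials and random responses
random_track <- function(seed, n_trials = 12,
                         conventions = mlp_conventions(n_trials = n_trials)) {
  set.seed(seed)
  tr <- new_track(standard_point("I"), "plus_x", conventions, seed = seed)
  grid <- seq(conventions$alpha_min, conventions$alpha_max,
              by = conventions$grid_step)
  for (i in seq_len(n_trials)) {
    tr <- record_trial(tr, sample(grid, 1), runif(1) < 0.6,
                       sample(c("standard_first", "variable_first"), 1))
  }
  tr
}

# a completed simulated track against a lapse-free observer
simulated_track <- function(seed, true_alpha = 0.03, n_trials = 12) {
  obs <- virtual_observer(true_alpha, seed = seed * 31 + 7)
  run_track(standard_point("I"), "plus_x", observer_responder(obs),
            mlp_conventions(n_trials = n_trials), seed = seed)
}

constant_responder <- function(answer) {
  function(delta, standard, variable, order) answer
}
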