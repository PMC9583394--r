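test_that("the default hypothesis grid is 0.001..0.1 in steps of 0.001", {
  g <- hypothesis_grid(mlp_conventions())
  expect_length(g, 100)
  expect_equal(g, seq(0.001, 0.1, by = 0.001))
  expect_true(all(diff(g) > 0))
  expect_equal(diff(range(diff(g))), 0, tolerance = 1e-12)  # constant step
  g2 <- hypothesis_grid(mlp_conventions(n_hypotheses = 2))
  expect_equal(g2, c(0.001, 0.1))
  expect_error(mlp_conventions(n_hypotheses = 1), "at least 2")
})

test_that("a single correct trial contributes log psi to every accumulator", {
  tr <- new_track(standard_point("I"), "plus_x")
  # hypothesis alpha = 0.05: its sweet point rounds to 0.055 on the grid
  delta <- 0.055
  tr <- record_trial(tr, delta, correct = TRUE)
  h <- psych_hypothesis(0.05, 100, 0.5)
  j <- which(abs(tr$alphas - 0.05) < 1e-12)
  expect_equal(tr$log_likelihoods[j], log(psi(delta, h)), tolerance = 1e-12)
  # in base-10 terms the hypothesis whose psi is ~0.809 scores ~ -0.092
  expect_equal(tr$log_likelihoods[j] / log(10), log10(psi(delta, h)))
})

test_that("all-correct histories favor the smallest midpoint, all-wrong the largest", {
  tr_c <- new_track(standard_point("I"), "plus_x")
  tr_w <- tr_c
  set.seed(404)
  for (d in sample(seq(0.001, 0.1, 0.001), 12)) {
    tr_c <- record_trial(tr_c, d, TRUE)
    tr_w <- record_trial(tr_w, d, FALSE)
  }
  expect_equal(best_hypothesis(tr_c)$alpha, 0.001)
  expect_equal(best_hypothesis(tr_w)$alpha, 0.1)
})

test_that("the empty track ties all hypotheses and breaks toward the smallest", {
  tr <- new_track(standard_point("I"), "plus_x")
  expect_equal(tr$log_likelihoods, numeric(100))
  expect_equal(best_hypothesis(tr)$alpha, 0.001)
})

test_that("incremental accumulators equal a from-scratch recomputation", {
  for (seed in c(1, 2, 3, 17, 99)) {
    tr <- random_track(seed)
    expect_equal(tr$log_likelihoods, loglik_scratch(tr), tolerance = 1e-10)
  }
})

test_that("the likelihood argmax is invariant to the log base", {
  for (seed in 1:20) {
    tr <- random_track(seed)
    expect_equal(which.max(loglik_scratch(tr, base = 10)),
                 which.max(loglik_scratch(tr, base = exp(1))))
    expect_equal(best_hypothesis(tr)$alpha,
                 tr$alphas[which.max(loglik_scratch(tr, base = 10))])
  }
})

test_that("a correct trial never raises the argmax midpoint, a wrong one never lowers it", {
  set.seed(505)
  grid <- seq(0.001, 0.1, 0.001)
  for (i in 1:40) {
    tr <- random_track(i, n_trials = sample(3:10, 1),
                       conventions = mlp_conventions(n_trials = 20))
    a0 <- best_hypothesis(tr)$alpha
    d <- sample(grid, 1)
    expect_lte(best_hypothesis(record_trial(tr, d, TRUE))$alpha, a0)
    expect_gte(best_hypothesis(record_trial(tr, d, FALSE))$alpha, a0)
  }
})

test_that("stimulus selection starts audible, then tracks the sweet point on the grid", {
  tr <- new_track(standard_point("I"), "plus_x")
  expect_equal(select_next_stimulus(tr), 0.07)   # first trial: clearly audible
  # force the best hypothesis to alpha = 0.05
  tr$log_likelihoods[which(abs(tr$alphas - 0.05) < 1e-12)] <- 1
  tr$deltas <- 0.07; tr$orders <- "standard_first"; tr$corrects <- TRUE
  expect_equal(select_next_stimulus(tr, unrounded = TRUE), 0.0548107,
               tolerance = 1e-5)
  expect_equal(select_next_stimulus(tr), 0.055)  # rounded to the grid
  # a ceiling hypothesis clamps: its sweet point exceeds alpha_max
  tr$log_likelihoods[] <- 0
  tr$log_likelihoods[100] <- 1
  expect_gt(select_next_stimulus(tr, unrounded = TRUE), 0.1)
  expect_equal(select_next_stimulus(tr), 0.1)
})

test_that("the JND readout offers the sweet-point and midpoint conventions", {
  res <- simulated_track(12)
  tr <- res$track
  best <- best_hypothesis(tr)
  expect_equal(jnd_estimate(tr, "midpoint"), best$alpha)
  expect_equal(jnd_estimate(tr, "sweet_point"),
               min(0.1, max(0.001, inverse_psi(0.809, best))))
  incomplete <- new_track(standard_point("I"), "plus_x")
  expect_error(jnd_estimate(incomplete), "incomplete")
})

test_that("run_track executes exactly n_trials and hits the grid edges for constant responders", {
  res <- run_track(standard_point("I"), "plus_x", constant_responder(TRUE),
                   mode = "midpoint")
  expect_equal(nrow(track_history(res$track)), 12)
  expect_equal(res$jnd, 0.001)   # grid floor
  res <- run_track(standard_point("I"), "plus_x", constant_responder(FALSE),
                   mode = "midpoint")
  expect_equal(res$jnd, 0.1)     # grid ceiling
  expect_true(all(track_history(res$track)$delta >= 0.001 &
                  track_history(res$track)$delta <= 0.1))
})

test_that("a failing responder aborts the track but preserves the partial log", {
  flaky <- local({
    k <- 0
    function(delta, standard, variable, order) {
      k <<- k + 1
      if (k >= 4) stop("participant walked away")
      TRUE
    }
  })
  err <- tryCatch(
    run_track(standard_point("I"), "plus_x", flaky),
    track_aborted = function(e) e)
  expect_s3_class(err, "track_aborted")
  expect_match(conditionMessage(err), "trial 4")
  expect_equal(nrow(track_history(err$track)), 3)
})

test_that("overfilling a track is refused", {
  tr <- new_track(standard_point("I"), "plus_x", mlp_conventions(n_trials = 1))
  tr <- record_trial(tr, 0.07, TRUE)
  expect_error(record_trial(tr, 0.07, TRUE), "full complement")
})
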