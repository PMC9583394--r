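# small conventions keep session tests fast where trial counts don't matter
fast_conv <- mlp_conventions(n_trials = 3)

test_that("a full session runs 5 directions per configured quadrant", {
  cfg <- session_config(mode = "full", seed = 11, conventions = fast_conv)
  expect_length(session_tracks(cfg), 20)
  log <- run_session(cfg, virtual_observer(0.03, seed = 1))
  expect_length(log$results, 20)
  df <- session_jnd_table(log)
  expect_equal(nrow(df), 20)
  expect_equal(sort(unique(df$direction)),
               sort(c("plus_x", "minus_x", "plus_y", "minus_y", "diagonal")))
  expect_equal(table(df$quadrant)[["III"]], 5)
  cfg2 <- session_config(quadrants = c("I", "IV"), conventions = fast_conv)
  expect_length(session_tracks(cfg2), 10)
})

test_that("a light session runs one plus-direction track per admissible tick", {
  cfg <- session_config(mode = "light", tick_spacing = 0.1, seed = 3,
                        conventions = fast_conv)
  expect_length(session_tracks(cfg), 36)
  cfg1 <- session_config(mode = "light", tick_spacing = 0.5, quadrants = "I",
                         conventions = fast_conv)
  trks <- session_tracks(cfg1)
  expect_length(trks, 2)
  expect_true(all(vapply(trks, function(t) grepl("^plus", t$direction$label),
                         logical(1))))
})

test_that("simulated sessions replay identically from config and seed", {
  run_once <- function() {
    cfg <- session_config(seed = 21, quadrants = c("I", "II"),
                          conventions = fast_conv)
    run_session(cfg, virtual_observer(0.02, seed = 99))
  }
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_session_log(run_once(), p1)
  write_session_log(run_once(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("session logs round-trip through JSON and rescore identically", {
  cfg <- session_config(seed = 5, conventions = mlp_conventions(n_trials = 4))
  log <- run_session(cfg, virtual_observer(0.03, seed = 2))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "log.json")
  write_session_log(log, p)
  expect_true(file.exists(paste0(p, ".trials.csv")))
  back <- read_session_log(p)
  expect_equal(session_jnd_table(back), session_jnd_table(log))
  r1 <- score_session(log); r2 <- score_session(back)
  expect_equal(r1$resolution, r2$resolution)
  expect_equal(r1$hysteresis, r2$hysteresis)
  expect_equal(r1$interference, r2$interference)
  # rebuilt accumulators must equal the originals (likelihoods are replayed)
  expect_equal(back$results[[1]]$track$log_likelihoods,
               log$results[[1]]$track$log_likelihoods, tolerance = 1e-12)
})

test_that("scoring a full session yields the three report tables", {
  sim <- simulate_session(list(true_alpha = 0.03, seed = 8),
                          seed = 13, conventions = mlp_conventions(n_trials = 6))
  rep <- sim$report
  expect_s3_class(rep, "score_report")
  expect_equal(dim(rep$resolution), c(2, 4))
  expect_true(all(rep$interference$quality %in%
                  c("positive", "none", "usual", "negative")))
  expect_error(score_session(structure(list(config = sim$log$config,
                                            results = list()),
                                       class = "session_log")),
               "empty")
})

test_that("scoring a light session yields per-axis-polarity linearity verdicts", {
  cfg <- session_config(mode = "light", tick_spacing = 0.2, seed = 4,
                        conventions = fast_conv)
  log <- run_session(cfg, virtual_observer(0.02, seed = 31))
  out <- score_session(log, tolerance = 200)  # a wide band: verdict shape only
  expect_setequal(names(out), c("plus_x", "minus_x", "plus_y", "minus_y"))
  expect_length(out$plus_x$jnds, 4)           # ticks 0.2, 0.4, 0.6, 0.8
  expect_true(all(vapply(out, function(o) is.logical(o$pass), logical(1))))
})

test_that("track order is a seeded permutation with no systematically first track", {
  conv1 <- mlp_conventions(n_trials = 1, n_hypotheses = 2)
  firsts <- integer(0)
  for (seed in 1:120) {
    cfg <- session_config(seed = seed, conventions = conv1)
    log <- run_session(cfg, constant_responder(TRUE))
    expect_setequal(log$order, 1:20)
    firsts <- c(firsts, log$order[1])
  }
  tab <- table(factor(firsts, levels = 1:20))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("interleaved sessions give the same bookkeeping as sequential ones", {
  cfg <- session_config(seed = 9, quadrants = "I", interleave = TRUE,
                        conventions = mlp_conventions(n_trials = 5))
  log <- run_session(cfg, virtual_observer(0.04, seed = 12))
  expect_length(log$results, 5)
  for (r in log$results) expect_equal(nrow(track_history(r$track)), 5)
  expect_s3_class(score_session(log), "score_report")
})

test_that("session configuration reads from YAML", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "mode: full",
    "quadrants: [I, II]",
    "seed: 77",
    "readout_mode: midpoint",
    "conventions:",
    "  n_trials: 6",
    "normalization:",
    "  temperature: {target: 39, min: 35, max: 42}",
    "observer: {true_alpha: 0.02, seed: 3}"
  ), p)
  cfg <- read_session_config(p)
  expect_equal(cfg$quadrants, c("I", "II"))
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$conventions$n_trials, 6L)
  expect_equal(cfg$readout_mode, "midpoint")
  expect_equal(normalize_value(40.5, cfg$normalization$temperature), 0.5)
  expect_equal(attr(cfg, "observer_params")$true_alpha, 0.02)
})
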