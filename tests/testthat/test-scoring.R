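test_that("perceptual resolution is the reciprocal JND", {
  q <- quadrant_jnds("I", plus_x = 0.001, minus_x = 0.002,
                     plus_y = 0.1, minus_y = 0.05, diagonal = 0.01)
  r <- resolution(q)
  expect_equal(r$steps_x, 1000)   # the finest measurable resolution
  expect_equal(r$steps_y, 10)     # the coarsest
  q2 <- quadrant_jnds("I", 0.02, 0.02, 0.02, 0.02, 0.02)
  expect_equal(resolution(q2)$steps_x, 50)
  expect_error(quadrant_jnds("I", -0.01, 0.02, 0.02, 0.02, 0.02), "positive")
})

test_that("steps are strictly decreasing in the JND", {
  jnds <- seq(0.001, 0.1, by = 0.001)
  steps <- 1 / jnds
  expect_true(all(diff(steps) < 0))
})

test_that("hysteresis is the half log-ratio with its documented extremes", {
  expect_equal(hysteresis(0.1, 0.001), 1)    # toward-origin JND at ceiling
  expect_equal(hysteresis(0.001, 0.1), -1)
  expect_equal(hysteresis(0.02, 0.02), 0)    # no hysteresis
  expect_equal(hysteresis(0.02, 0.01), 0.5 * log10(2))   # 0.15051
  expect_error(hysteresis(0, 0.01), "positive")
  expect_error(hysteresis(0.01, -1), "positive")
})

test_that("hysteresis is antisymmetric and bounded on the default grid", {
  set.seed(606)
  a <- runif(10000, 0.001, 0.1)
  b <- runif(10000, 0.001, 0.1)
  h <- hysteresis(a, b)
  expect_equal(h, -hysteresis(b, a), tolerance = 1e-12)
  expect_true(all(h >= -1 & h <= 1))
})

test_that("interference reproduces the worked cases", {
  mk <- function(x, y, d) quadrant_jnds("I", plus_x = x, minus_x = x,
                                        plus_y = y, minus_y = y, diagonal = d)
  z <- interference(mk(0.01, 0.04, 0.01))      # diagonal equals jnd_min
  expect_equal(z$delta, 0)
  expect_equal(z$quality, "none")
  z <- interference(mk(0.01, 0.04, 0.02))
  expect_equal(z$threshold, 0.30103, tolerance = 1e-5)
  expect_equal(z$delta, 0.150515, tolerance = 1e-5)
  expect_equal(z$quality, "usual")
  z <- interference(mk(0.01, 0.01, 0.05))      # equal dims, harder diagonal
  expect_equal(z$threshold, 0)
  expect_equal(z$delta, 0.349485, tolerance = 1e-5)
  expect_equal(z$quality, "negative")
  z <- interference(mk(0.1, 0.1, 0.001))       # joint changes much easier
  expect_equal(z$delta, -1)
  expect_equal(z$quality, "positive")
})

test_that("interference scores stay in bounds and match the literal classification", {
  set.seed(707)
  x <- runif(10000, 0.001, 0.1)
  y <- runif(10000, 0.001, 0.1)
  d <- runif(10000, 0.001, 0.1)
  zs <- lapply(seq_along(x), function(i)
    interference(quadrant_jnds("I", x[i], x[i], y[i], y[i], d[i])))
  thr <- vapply(zs, `[[`, numeric(1), "threshold")
  del <- vapply(zs, `[[`, numeric(1), "delta")
  qual <- vapply(zs, `[[`, character(1), "quality")
  expect_true(all(thr >= 0 & thr <= 1))
  expect_true(all(del >= -1 & del <= 1))
  literal <- mapply(classify_interference_literal, x, y, d)
  expect_identical(qual, unname(literal))
})

test_that("the epsilon tolerance widens the no-interference band", {
  mk <- function(d) quadrant_jnds("I", 0.01, 0.01, 0.02, 0.02, d)
  z <- interference(mk(0.0101), epsilon = 0.01)
  expect_equal(z$quality, "none")
  expect_equal(interference(mk(0.0101), epsilon = 0)$quality, "usual")
})

test_that("the linearity check compares tick JNDs by their max/min ratio", {
  chk <- linearity_check(c(0.02, 0.02, 0.02))
  expect_true(chk$pass)
  expect_equal(chk$ratio, 1)
  chk <- linearity_check(c(0.01, 0.02), tolerance = 1.5)
  expect_false(chk$pass)    # ratio 2 exceeds the tolerance
  expect_equal(chk$ratio, 2)
  expect_error(linearity_check(0.01), "two or more")
})

test_that("the report tables take the standardized shapes", {
  qs <- lapply(c("I", "II", "III", "IV"), function(id)
    quadrant_jnds(id, 0.01, 0.02, 0.03, 0.04, 0.02))
  rep <- build_report(qs)
  expect_equal(dim(rep$resolution), c(2, 4))
  expect_equal(rownames(rep$resolution), c("x", "y"))
  expect_equal(colnames(rep$resolution), c("I", "II", "III", "IV"))
  expect_equal(dim(rep$hysteresis), c(2, 4))
  expect_equal(nrow(rep$interference), 4)
  expect_true(all(c("delta", "quality") %in% colnames(rep$interference)))
  expect_equal(rep$hysteresis["x", "I"], 0.5 * log10(2))
  # ratio-scale design: quadrant I only
  rep1 <- build_report(qs[1])
  expect_equal(dim(rep1$resolution), c(2, 1))
  expect_equal(nrow(rep1$interference), 1)
})

test_that("reports export to CSV and Markdown", {
  dir <- withr::local_tempdir()
  qs <- lapply(c("I", "II"), function(id)
    quadrant_jnds(id, 0.01, 0.02, 0.03, 0.04, 0.02))
  rep <- build_report(qs)
  paths <- export_report_csv(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1], row.names = 1)
  expect_equal(as.matrix(back), as.matrix(rep$resolution))
  md <- file.path(dir, "report.md")
  export_report_markdown(rep, md)
  txt <- readLines(md)
  expect_true(any(grepl("Perceptual interference", txt)))
  expect_true(any(grepl("\\| x \\|", txt)))
})
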