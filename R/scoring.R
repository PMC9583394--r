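# Perceptual scores derived from the five JNDs per quadrant:
# resolution (steps per dimension), hysteresis (log-ratio of the toward-
# vs away-from-origin JNDs), and perceptual interference (diagonal vs
# single-dimension JNDs).

#' The five JNDs measured at one standard
#'
#' Each standard yields five JNDs: along x toward and away from the
#' origin, along y toward and away from the origin, and along the
#' positive diagonal.
#'
#' @param quadrant A `quadrant_spec` or quadrant id.
#' @param plus_x,minus_x,plus_y,minus_y,diagonal JND estimates
#'   (stimulus magnitudes, > 0).
#' @param readout_mode How the JNDs were read out (`"sweet_point"` or
#'   `"midpoint"`); metadata only.
#' @return An object of class `quadrant_jnds`.
#' @export
quadrant_jnds <- function(quadrant, plus_x, minus_x, plus_y, minus_y,
                          diagonal, readout_mode = "sweet_point") {
  if (!inherits(quadrant, "quadrant_spec")) quadrant <- quadrant_spec(quadrant)
  vals <- c(plus_x = plus_x, minus_x = minus_x, plus_y = plus_y,
            minus_y = minus_y, diagonal = diagonal)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all five JNDs must be positive and finite", call. = FALSE)
  }
  structure(list(quadrant = quadrant, jnd = as.list(vals),
                 readout_mode = readout_mode),
            class = "quadrant_jnds")
}

#' Perceptual resolution of one quadrant
#'
#' The resolution of each dimension is described by the JND when
#' increasing the absolute value of that dimension; its reciprocal is
#' the number of distinguishable steps along the unit axis. A JND of
#' 0.001 (the grid floor) means 1000 distinguishable steps; 0.1 (the
#' ceiling) means only 10.
#'
#' @param q A `quadrant_jnds`.
#' @return A list: `jnd_plus_x`, `jnd_plus_y`, `steps_x`, `steps_y`.
#' @export
resolution <- function(q) {
  stopifnot(inherits(q, "quadrant_jnds"))
  list(jnd_plus_x = q$jnd$plus_x, jnd_plus_y = q$jnd$plus_y,
       steps_x = 1 / q$jnd$plus_x, steps_y = 1 / q$jnd$plus_y)
}

#' Hysteresis score of one dimension
#'
#' `h = 0.5 * log10(jnd_minus / jnd_plus)`, the log-ratio of the JND
#' toward the origin over the JND away from it. With JNDs confined to
#' \[0.001, 0.1\] the score lies in \[-1, 1\]. Positive values mean
#' larger steps are needed to be audible when approaching the origin;
#' zero means no hysteresis.
#'
#' @param jnd_minus JND toward the origin (> 0).
#' @param jnd_plus JND away from the origin (> 0).
#' @return The hysteresis score (vectorized over its inputs).
#' @examples
#' hysteresis(0.1, 0.001)   # 1: the extreme positive case
#' hysteresis(0.02, 0.02)   # 0: no hysteresis
#' @export
hysteresis <- function(jnd_minus, jnd_plus) {
  if (any(!is.finite(jnd_minus)) || any(!is.finite(jnd_plus)) ||
      any(jnd_minus <= 0) || any(jnd_plus <= 0)) {
    stop("JNDs must be positive and finite", call. = FALSE)
  }
  0.5 * log10(jnd_minus / jnd_plus)
}

#' Perceptual interference of one quadrant
#'
#' From the two away-from-origin JNDs, `jnd_min` and `jnd_max` are the
#' smaller and larger one; their log-ratio `T = 0.5*log10(max/min)` (in
#' \[0, 1\] on the default grid) is the threshold separating usual from
#' negative interference. The degree of interference is
#' `delta = 0.5*log10(jnd_diagonal / jnd_min)` (in \[-1, 1\]), and the
#' qualitative class is: positive interference if `delta < 0` (joint
#' changes are easier to detect than the best single dimension), none if
#' `delta = 0` (orthogonal dimensions), usual if `0 < delta <= T`
#' (the diagonal lies between the single-dimension JNDs), negative if
#' `delta > T` (the diagonal is harder than the worse dimension).
#'
#' Exact equality `delta == 0` has measure zero in floating point, so an
#' optional tolerance `epsilon` widens the "none" band to
#' `|delta| <= epsilon`; the default 0 applies the classification
#' literally.
#'
#' @param q A `quadrant_jnds` (only `plus_x`, `plus_y`, `diagonal` are
#'   used).
#' @param epsilon Half-width of the "no interference" band. Default 0.
#' @return A list: `jnd_min`, `jnd_max`, `threshold` (T), `delta`, and
#'   `quality` (one of `"positive"`, `"none"`, `"usual"`, `"negative"`).
#' @export
interference <- function(q, epsilon = 0) {
  stopifnot(inherits(q, "quadrant_jnds"), epsilon >= 0)
  jnd_min <- min(q$jnd$plus_x, q$jnd$plus_y)
  jnd_max <- max(q$jnd$plus_x, q$jnd$plus_y)
  threshold <- 0.5 * log10(jnd_max / jnd_min)
  delta <- 0.5 * log10(q$jnd$diagonal / jnd_min)
  quality <-
    if (delta < -epsilon) "positive"
    else if (abs(delta) <= epsilon) "none"
    else if (delta <= threshold) "usual"
    else "negative"
  list(jnd_min = jnd_min, jnd_max = jnd_max, threshold = threshold,
       delta = delta, quality = quality)
}

#' Axis linearity check for the "light" experiment
#'
#' A perceptually linear parameter mapping yields the same
#' away-from-origin JND at every tick mark of an axis polarity. The
#' check reports the max/min ratio of the measured JNDs and passes iff
#' it does not exceed the tolerance; a failed check means the parameter
#' mapping function needs adjustment before the full evaluation.
#'
#' @param jnds Numeric vector of JNDs, one per tick (>= 2 ticks),
#'   optionally named by tick position.
#' @param tolerance Largest acceptable max/min JND ratio. Default 1.5.
#' @return A list: `ratio`, `pass`, `jnd_min`, `jnd_max`, `tolerance`.
#' @export
linearity_check <- function(jnds, tolerance = 1.5) {
  stopifnot(is.numeric(jnds), tolerance >= 1)
  if (length(jnds) < 2) {
    stop("linearity check needs JNDs at two or more ticks", call. = FALSE)
  }
  if (any(!is.finite(jnds)) || any(jnds <= 0)) {
    stop("JNDs must be positive and finite", call. = FALSE)
  }
  ratio <- max(jnds) / min(jnds)
  list(ratio = ratio, pass = ratio <= tolerance,
       jnd_min = min(jnds), jnd_max = max(jnds), tolerance = tolerance)
}

#' Assemble the standardized score report
#'
#' Builds the three report tables from the per-quadrant JNDs:
#' resolution (rows x/y, one column per quadrant), hysteresis (same
#' shape), and interference (one row per quadrant with T, delta, and the
#' qualitative class Q). Quadrants outside the configured mask appear as
#' `NA` columns/rows, never imputed.
#'
#' @param quadrants A list of `quadrant_jnds` (any subset of the four).
#' @param epsilon Tolerance for the interference classification.
#' @return An object of class `score_report` with elements `resolution`,
#'   `steps`, `hysteresis`, `interference` (data frames) and metadata
#'   (`readout_mode`, `quadrant_mask`).
#' @export
build_report <- function(quadrants, epsilon = 0) {
  stopifnot(is.list(quadrants), length(quadrants) >= 1)
  if (inherits(quadrants, "quadrant_jnds")) quadrants <- list(quadrants)
  ids <- vapply(quadrants, function(q) q$quadrant$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate quadrants in report input", call. = FALSE)
  cols <- QUADRANT_IDS
  grab <- function(fun) {
    m <- matrix(NA_real_, 2, length(cols), dimnames = list(c("x", "y"), cols))
    for (i in seq_along(quadrants)) m[, ids[i]] <- fun(quadrants[[i]])
    as.data.frame(m[, cols %in% ids, drop = FALSE])
  }
  res <- grab(function(q) c(q$jnd$plus_x, q$jnd$plus_y))
  steps <- grab(function(q) c(1 / q$jnd$plus_x, 1 / q$jnd$plus_y))
  hys <- grab(function(q) c(hysteresis(q$jnd$minus_x, q$jnd$plus_x),
                            hysteresis(q$jnd$minus_y, q$jnd$plus_y)))
  intf <- data.frame(row.names = ids,
                     threshold = rep(NA_real_, length(ids)),
                     delta = rep(NA_real_, length(ids)),
                     quality = rep(NA_character_, length(ids)))
  for (i in seq_along(quadrants)) {
    z <- interference(quadrants[[i]], epsilon)
    intf[ids[i], "threshold"] <- z$threshold
    intf[ids[i], "delta"] <- z$delta
    intf[ids[i], "quality"] <- z$quality
  }
  modes <- unique(vapply(quadrants, function(q) q$readout_mode, character(1)))
  structure(list(resolution = res, steps = steps, hysteresis = hys,
                 interference = intf,
                 readout_mode = paste(modes, collapse = ","),
                 quadrant_mask = ids, epsilon = epsilon),
            class = "score_report")
}

#' @export
print.score_report <- function(x, digits = 4, ...) {
  cat("Perceptual evaluation report (JND readout:", x$readout_mode, ")\n\n")
  cat("Perceptual resolution (JND away from the origin):\n")
  print(round(x$resolution, digits))
  cat("\nDistinguishable steps (1/JND):\n")
  print(round(x$steps, 1))
  cat("\nHysteresis h:\n")
  print(round(x$hysteresis, digits))
  cat("\nPerceptual interference:\n")
  print(cbind(round(x$interference[, c("threshold", "delta")], digits),
              Q = x$interference$quality))
  invisible(x)
}

#' Export a score report
#'
#' `export_report_csv()` writes one CSV per table
#' (`resolution.csv`, `hysteresis.csv`, `interference.csv`) into a
#' directory; `export_report_markdown()` writes the three tables as
#' Markdown.
#'
#' @param report A `score_report`.
#' @param dir Output directory for the CSV files.
#' @return Invisibly, the paths written.
#' @export
export_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "score_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("resolution.csv", "hysteresis.csv",
                            "interference.csv"))
  utils::write.csv(report$resolution, paths[1])
  utils::write.csv(report$hysteresis, paths[2])
  utils::write.csv(report$interference, paths[3])
  invisible(paths)
}

md_table <- function(df, corner = "") {
  hdr <- paste0("| ", corner, " | ", paste(colnames(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df) + 1), collapse = "|"), "|")
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = 4, format = "g") else v
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", rownames(df)[i], " | ",
           paste(vapply(df[i, , drop = FALSE], fmt, character(1)),
                 collapse = " | "), " |")
  }, character(1))
  paste(c(hdr, sep, rows), collapse = "\n")
}

#' @rdname export_report_csv
#' @param path Output path of the Markdown file.
#' @export
export_report_markdown <- function(report, path) {
  stopifnot(inherits(report, "score_report"))
  txt <- paste0(
    "## Perceptual resolution\n\n", md_table(report$resolution), "\n\n",
    "## Hysteresis\n\n", md_table(report$hysteresis), "\n\n",
    "## Perceptual interference\n\n",
    md_table(report$interference[, c("delta", "quality")], corner = "S"), "\n\n",
    "JND readout: ", report$readout_mode, "\n")
  writeLines(txt, path)
  invisible(path)
}
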