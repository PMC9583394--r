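# Variable-coordinate grids and sound-pair rendering: signal hygiene
# (onset/offset ramps, equal pause, shared peak normalization) around a
# user-supplied sonifier.

#' Timing and format of the test sounds
#'
#' Test sounds last 3 to 5 s, followed by a pause of equal length; the
#' pause sits between the two sounds of a 2AFC pair. Onsets carry a
#' short raised-cosine ramp to avoid clicks; offsets a long, gradual
#' fade-out so listeners cannot compare the pair by its final
#' modulation phase.
#'
#' @param duration Sound duration in seconds, in \[3, 5\]. Default 4.
#' @param ramp_onset Onset ramp duration in seconds. Default 0.05.
#' @param ramp_offset Offset ramp duration in seconds. Default 0.5.
#' @param sample_rate Sampling rate in Hz. Default 44100.
#' @return An object of class `stimulus_spec`; the pause equals
#'   `duration`.
#' @export
stimulus_spec <- function(duration = 4, ramp_onset = 0.05,
                          ramp_offset = 0.5, sample_rate = 44100) {
  stopifnot(duration >= 3, duration <= 5,
            ramp_onset > 0, ramp_offset > 0,
            sample_rate > 0)
  if (ramp_onset >= duration / 2 || ramp_offset >= duration / 2) {
    stop("ramps must each be shorter than half the sound duration",
         call. = FALSE)
  }
  structure(list(duration = duration, pause = duration,
                 ramp_onset = ramp_onset, ramp_offset = ramp_offset,
                 sample_rate = as.integer(sample_rate)),
            class = "stimulus_spec")
}

#' Variable stimulus grid of one track
#'
#' One coordinate per presentable offset: alpha from `alpha_min` to
#' `alpha_max` in steps of `grid_step` (100 coordinates under the
#' defaults), ordered by alpha. The grid coincides with the hypothesis
#' midpoint grid, so every selectable stimulus has a pre-renderable
#' sound.
#'
#' @param standard A `standard_point`.
#' @param direction A `direction_spec` or label.
#' @param conventions An `mlp_conventions`.
#' @return A list of `mapping_coordinate`s with the offsets attached as
#'   the `"alphas"` attribute.
#' @export
variable_grid <- function(standard, direction, conventions = mlp_conventions()) {
  alphas <- seq(conventions$alpha_min, conventions$alpha_max,
                by = conventions$grid_step)
  coords <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    coords[[i]] <- tryCatch(
      variable_coordinate(standard, direction, alphas[i]),
      error = function(e) stop("variable grid leaves the mapping space at ",
                               "alpha = ", format(alphas[i]), ": ",
                               conditionMessage(e), call. = FALSE))
  }
  attr(coords, "alphas") <- alphas
  coords
}

# raised-cosine onset and offset ramps; first and last samples are 0
apply_ramps <- function(samples, spec) {
  n <- length(samples)
  n_on <- max(2L, round(spec$ramp_onset * spec$sample_rate))
  n_off <- max(2L, round(spec$ramp_offset * spec$sample_rate))
  stopifnot(n_on + n_off <= n)
  on <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = n_on))
  off <- rev(0.5 - 0.5 * cos(pi * seq(0, 1, length.out = n_off)))
  samples[seq_len(n_on)] <- samples[seq_len(n_on)] * on
  samples[(n - n_off + 1L):n] <- samples[(n - n_off + 1L):n] * off
  samples
}

check_sonifier_output <- function(samples, spec) {
  n_expected <- round(spec$duration * spec$sample_rate)
  if (!is.numeric(samples) || length(samples) != n_expected) {
    stop("sonifier contract violated: expected a numeric buffer of ",
         n_expected, " samples, got ", length(samples), call. = FALSE)
  }
  samples
}

#' Render one 2AFC sound pair
#'
#' Renders the standard and the variable through the sonifier, applies
#' the onset/offset ramps, normalizes both buffers by their joint peak
#' (so relative level is preserved), and assembles them in the requested
#' order with a silent pause of equal length between the two sounds.
#'
#' @param standard,variable `mapping_coordinate`s.
#' @param sonifier Function `(coordinate, duration, sample_rate)` to a
#'   numeric sample buffer. Must be deterministic and start its
#'   modulators at a fixed phase, so standard and variable begin at the
#'   same point of the modulation cycle.
#' @param spec A `stimulus_spec`.
#' @param order `"standard_first"` or `"variable_first"`.
#' @return A list of class `stimulus_pair`: `first`, `second` (ramped,
#'   normalized buffers), `sequence` (first + pause + second), `order`,
#'   and `spec`.
#' @export
render_pair <- function(standard, variable, sonifier,
                        spec = stimulus_spec(),
                        order = c("standard_first", "variable_first")) {
  stopifnot(inherits(standard, "mapping_coordinate"),
            inherits(variable, "mapping_coordinate"),
            is.function(sonifier), inherits(spec, "stimulus_spec"))
  order <- match.arg(order)
  s <- check_sonifier_output(sonifier(standard, spec$duration, spec$sample_rate), spec)
  v <- check_sonifier_output(sonifier(variable, spec$duration, spec$sample_rate), spec)
  s <- apply_ramps(s, spec)
  v <- apply_ramps(v, spec)
  peak <- max(abs(c(s, v)), 1e-12)
  s <- s / peak * 0.9
  v <- v / peak * 0.9
  pause <- numeric(round(spec$pause * spec$sample_rate))
  pair <- if (order == "standard_first") list(first = s, second = v)
          else list(first = v, second = s)
  structure(c(pair, list(sequence = c(pair$first, pause, pair$second),
                         order = order, spec = spec)),
            class = "stimulus_pair")
}

#' Reference sonifier (for tests and demonstrations)
#'
#' A simple deterministic two-dimensional parameter mapping used to
#' exercise the toolkit: x maps linearly to the logarithm of a sine
#' carrier's frequency (220 Hz at x = -1 to 880 Hz at x = +1) and y maps
#' linearly to the rate of a sinusoidal amplitude modulation (2 Hz at
#' y = -1 to 10 Hz at y = +1, depth 0.5). The modulator starts at a
#' fixed phase, so paired sounds begin at the same point of the
#' modulation cycle. Real evaluations plug in the sonification under
#' test instead.
#'
#' @param coordinate A `mapping_coordinate`.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric sample buffer in \[-1, 1\].
#' @export
reference_sonifier <- function(coordinate, duration, sample_rate) {
  stopifnot(inherits(coordinate, "mapping_coordinate"))
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  freq <- 440 * 2^coordinate$x          # log-frequency mapping of x
  am_rate <- 6 + 4 * coordinate$y       # AM-rate mapping of y
  env <- 1 - 0.5 * (0.5 - 0.5 * cos(2 * pi * am_rate * t))  # starts at 1
  sin(2 * pi * freq * t) * env
}

#' Demonstration stimuli for participant familiarization
#'
#' Before the experiment, participants hear: the reference coordinate
#' (0.6, 0.6); (0.601, 0.6), a probably inaudible difference;
#' (0.7, 0.6), a probably clearly audible difference; and a coordinate
#' at a configurable offset near the conductor's personal JND.
#'
#' @param sonifier Sonifier function (see [render_pair()]).
#' @param spec A `stimulus_spec`.
#' @param personal_jnd Offset of the fourth demonstration. Default 0.01.
#' @return A named list of four labeled, ramped buffers with the
#'   coordinates and offsets attached as attributes.
#' @export
demo_stimuli <- function(sonifier, spec = stimulus_spec(), personal_jnd = 0.01) {
  base <- mapping_coordinate(0.6, 0.6)
  coords <- list(
    reference                = base,
    probably_inaudible       = mapping_coordinate(0.601, 0.6),
    probably_clearly_audible = mapping_coordinate(0.7, 0.6),
    personal_jnd             = mapping_coordinate(0.6 + personal_jnd, 0.6)
  )
  out <- lapply(coords, function(co) {
    apply_ramps(check_sonifier_output(
      sonifier(co, spec$duration, spec$sample_rate), spec), spec)
  })
  attr(out, "coordinates") <- coords
  attr(out, "offsets") <- c(0, 0.001, 0.1, personal_jnd)
  out
}

#' Pre-render a track's variable grid to WAV files
#'
#' Writes the standard plus all 100 variables of one standard/direction
#' combination as mono PCM WAV, named
#' `<quadrant>_<direction>_<alpha>.wav` (the standard as
#' `<quadrant>_standard.wav`).
#'
#' @param standard A `standard_point`.
#' @param direction A `direction_spec` or label.
#' @param sonifier Sonifier function.
#' @param dir Output directory (created if needed).
#' @param conventions An `mlp_conventions`.
#' @param spec A `stimulus_spec`.
#' @return Invisibly, the vector of file paths written.
#' @export
render_grid_wavs <- function(standard, direction, sonifier, dir,
                             conventions = mlp_conventions(),
                             spec = stimulus_spec()) {
  if (!inherits(direction, "direction_spec")) direction <- direction_spec(direction)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coords <- variable_grid(standard, direction, conventions)
  alphas <- attr(coords, "alphas")
  prep <- function(co) {
    s <- apply_ramps(check_sonifier_output(
      sonifier(co, spec$duration, spec$sample_rate), spec), spec)
    s / max(abs(s), 1e-12) * 0.9
  }
  qid <- standard$quadrant$id
  paths <- file.path(dir, sprintf("%s_%s_%.3f.wav", qid,
                                  direction$label, alphas))
  std_path <- file.path(dir, sprintf("%s_standard.wav", qid))
  write_wav(prep(standard$coordinate), std_path, spec$sample_rate)
  for (i in seq_along(coords)) {
    write_wav(prep(coords[[i]]), paths[i], spec$sample_rate)
  }
  invisible(c(std_path, paths))
}
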