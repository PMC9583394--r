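# Session orchestration: enumerate the tracks of a full or light
# evaluation, run them in a seeded order against a responder, log every
# trial, and turn a finished session into the standardized report.

#' Configuration of an evaluation session
#'
#' A *full* session measures five JNDs (plus/minus x, plus/minus y,
#' diagonal) at the center standard of every quadrant in the mask: with
#' all four quadrants, 20 tracks of 12 trials each. A *light* session —
#' the design-stage aid — measures only the away-from-origin JND at
#' every axis tick mark covered by the mask, to verify perceptual
#' linearity of the parameter mapping.
#'
#' @param mode `"full"` or `"light"`.
#' @param quadrants Quadrant mask: subset of `c("I","II","III","IV")`.
#' @param conventions An `mlp_conventions`.
#' @param stimulus A `stimulus_spec` (used when rendering audio).
#' @param tick_spacing Light-mode tick spacing. Default 0.1.
#' @param seed Integer master seed; drives track order, per-track
#'   presentation order, and the simulated observer (if its seed is
#'   unset).
#' @param readout_mode JND readout, `"sweet_point"` or `"midpoint"`.
#' @param interleave If `TRUE`, trials of different tracks are
#'   interleaved (round-robin) rather than run track-by-track.
#' @param normalization Optional named list of `normalization_spec`s
#'   (one per raw input variable); carried as metadata.
#' @return An object of class `session_config`.
#' @export
session_config <- function(mode = c("full", "light"),
                           quadrants = c("I", "II", "III", "IV"),
                           conventions = mlp_conventions(),
                           stimulus = stimulus_spec(),
                           tick_spacing = 0.1,
                           seed = 1L,
                           readout_mode = c("sweet_point", "midpoint"),
                           interleave = FALSE,
                           normalization = NULL) {
  mode <- match.arg(mode)
  quadrants <- match.arg(quadrants, QUADRANT_IDS, several.ok = TRUE)
  readout_mode <- match.arg(readout_mode)
  stopifnot(inherits(conventions, "mlp_conventions"),
            inherits(stimulus, "stimulus_spec"),
            is.numeric(seed), length(seed) == 1L)
  structure(list(mode = mode, quadrants = quadrants,
                 conventions = conventions, stimulus = stimulus,
                 tick_spacing = tick_spacing, seed = as.integer(seed),
                 readout_mode = readout_mode,
                 interleave = isTRUE(interleave),
                 normalization = normalization),
            class = "session_config")
}

#' Read a session configuration from YAML or JSON
#'
#' Recognized keys: `mode`, `quadrants`, `seed`, `tick_spacing`,
#' `readout_mode`, `interleave`, `conventions` (any field of
#' [mlp_conventions()]), `stimulus` (any field of [stimulus_spec()]),
#' `normalization` (per-variable `target`/`min`/`max`), and `observer`
#' (fields of [virtual_observer()], returned as the `observer`
#' attribute).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `session_config`; if the file defines an observer, it is
#'   attached as `attr(config, "observer_params")`.
#' @export
read_session_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  conv <- do.call(mlp_conventions, as.list(raw$conventions %||% list()))
  stim <- do.call(stimulus_spec, as.list(raw$stimulus %||% list()))
  norm <- NULL
  if (!is.null(raw$normalization)) {
    norm <- lapply(raw$normalization, function(v) {
      normalization_spec(v$target, v$min, v$max)
    })
  }
  cfg <- session_config(
    mode = raw$mode %||% "full",
    quadrants = raw$quadrants %||% c("I", "II", "III", "IV"),
    conventions = conv, stimulus = stim,
    tick_spacing = raw$tick_spacing %||% 0.1,
    seed = raw$seed %||% 1L,
    readout_mode = raw$readout_mode %||% "sweet_point",
    interleave = raw$interleave %||% FALSE,
    normalization = norm)
  if (!is.null(raw$observer)) attr(cfg, "observer_params") <- raw$observer
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the tracks of a session
#'
#' @param config A `session_config`.
#' @return A list of track descriptors, each with `standard`,
#'   `direction`, and a human-readable `label`.
#' @export
session_tracks <- function(config) {
  stopifnot(inherits(config, "session_config"))
  out <- list()
  if (config$mode == "full") {
    for (qid in config$quadrants) {
      std <- standard_point(qid)
      for (d in DIRECTION_LABELS) {
        out[[length(out) + 1L]] <- list(
          standard = std, direction = direction_spec(d),
          label = paste0("S_", qid, ":", d))
      }
    }
  } else {
    stds <- light_standards(config$tick_spacing, config$quadrants,
                            alpha_max = config$conventions$alpha_max)
    for (std in stds) {
      d <- if (std$axis == "x") "plus_x" else "plus_y"
      tick <- std$coordinate[[std$axis]]
      out[[length(out) + 1L]] <- list(
        standard = std, direction = direction_spec(d),
        label = sprintf("tick_%s_%+g:%s", std$axis, tick, d))
    }
  }
  out
}

#' Run an evaluation session
#'
#' Executes every track of the configured design in a seeded random
#' order. The responder is either a function
#' `(delta, standard, variable, order) -> logical` — e.g.
#' [observer_responder()] for closed-loop simulation, or an interactive
#' callback that plays the rendered pair and collects the judgment — or
#' a [virtual_observer()], which is wrapped automatically (its response
#' stream is re-seeded from the session seed so a session replays
#' exactly).
#'
#' @param config A `session_config`.
#' @param responder Responder function or `virtual_observer`.
#' @return An object of class `session_log`: the config, the seeded
#'   track order, and per-track results (`track`, `jnd`, `label`).
#' @export
run_session <- function(config, responder) {
  stopifnot(inherits(config, "session_config"))
  descriptors <- session_tracks(config)
  n <- length(descriptors)
  if (!n) stop("session has no tracks under this configuration", call. = FALSE)
  rng <- local_rng(config$seed)
  order_idx <- order(rng$draw(n))               # seeded permutation
  track_seeds <- floor(rng$draw(n) * 2147483646) + 1
  if (inherits(responder, "virtual_observer")) {
    responder <- observer_responder(
      virtual_observer(responder$true_alpha, responder$true_beta,
                       responder$gamma, responder$lapse,
                       seed = bitwXor(config$seed, 1164413355L)))
  }
  stopifnot(is.function(responder))
  results <- vector("list", n)
  if (!config$interleave) {
    for (k in seq_len(n)) {
      i <- order_idx[k]
      d <- descriptors[[i]]
      res <- run_track(d$standard, d$direction, responder,
                       config$conventions, seed = track_seeds[i],
                       mode = config$readout_mode)
      results[[i]] <- c(res, list(label = d$label))
    }
  } else {
    # round-robin: one trial per track per sweep, in the seeded order
    tracks <- lapply(seq_len(n), function(i) {
      d <- descriptors[[i]]
      new_track(d$standard, d$direction, config$conventions,
                seed = track_seeds[i])
    })
    rngs <- lapply(track_seeds, local_rng)
    for (t in seq_len(config$conventions$n_trials)) {
      for (k in seq_len(n)) {
        i <- order_idx[k]
        tr <- tracks[[i]]
        delta <- select_next_stimulus(tr)
        ord <- if (rngs[[i]]$draw() < 0.5) "standard_first" else "variable_first"
        variable <- variable_coordinate(tr$standard, tr$direction, delta)
        correct <- isTRUE(responder(delta, tr$standard$coordinate, variable, ord))
        tracks[[i]] <- record_trial(tr, delta, correct, ord)
      }
    }
    for (i in seq_len(n)) {
      results[[i]] <- list(track = tracks[[i]],
                           jnd = jnd_estimate(tracks[[i]], config$readout_mode),
                           label = descriptors[[i]]$label)
    }
  }
  structure(list(config = config, order = order_idx, results = results),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session log> mode=", x$config$mode, ", ",
      length(x$results), " tracks, seed=", x$config$seed, "\n", sep = "")
  df <- session_jnd_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-track JND table of a session
#'
#' @param log A `session_log`.
#' @return A data frame with one row per track: `label`, `quadrant`,
#'   `direction`, `jnd`.
#' @export
session_jnd_table <- function(log) {
  stopifnot(inherits(log, "session_log"))
  do.call(rbind, lapply(log$results, function(r) {
    data.frame(label = r$label,
               quadrant = r$track$standard$quadrant$id,
               direction = r$track$direction$label,
               jnd = r$jnd, stringsAsFactors = FALSE)
  }))
}

#' Score a finished session
#'
#' Full mode: assembles the five JNDs of every configured quadrant and
#' builds the standardized report tables. Light mode: groups the
#' per-tick JNDs by axis polarity and runs the linearity check on each.
#'
#' @param log A `session_log`.
#' @param epsilon Interference classification tolerance (full mode).
#' @param tolerance Max/min JND ratio tolerance (light mode).
#' @return Full mode: a `score_report`. Light mode: a named list of
#'   [linearity_check()] results (one per axis polarity) with the
#'   per-tick JNDs attached.
#' @export
score_session <- function(log, epsilon = 0, tolerance = 1.5) {
  stopifnot(inherits(log, "session_log"))
  if (!length(log$results) || any(vapply(log$results, is.null, logical(1)))) {
    stop("session log is empty or incomplete", call. = FALSE)
  }
  df <- session_jnd_table(log)
  if (log$config$mode == "full") {
    qs <- lapply(log$config$quadrants, function(qid) {
      sub <- df[df$quadrant == qid, ]
      need <- DIRECTION_LABELS
      missing <- setdiff(need, sub$direction)
      if (length(missing)) {
        stop("quadrant ", qid, " is missing tracks: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      pick <- function(d) sub$jnd[sub$direction == d][1]
      quadrant_jnds(qid, pick("plus_x"), pick("minus_x"),
                    pick("plus_y"), pick("minus_y"), pick("diagonal"),
                    readout_mode = log$config$readout_mode)
    })
    build_report(qs, epsilon = epsilon)
  } else {
    polarity <- vapply(log$results, function(r) {
      std <- r$track$standard
      tick <- std$coordinate[[std$axis]]
      paste0(if (tick >= 0) "plus_" else "minus_", std$axis)
    }, character(1))
    out <- lapply(split(seq_along(polarity), polarity), function(idx) {
      jnds <- df$jnd[idx]
      names(jnds) <- df$label[idx]
      chk <- linearity_check(jnds, tolerance)
      chk$jnds <- jnds
      chk
    })
    out
  }
}

#' Write and read session logs
#'
#' `write_session_log()` serializes a session as JSON (config echo,
#' track order, per-track trial records and JND) and, alongside, one
#' CSV of all trials (`<path>.trials.csv`) with columns track label,
#' quadrant, direction, trial number, delta, presentation order,
#' correct. `read_session_log()` restores the JSON into the structures
#' [score_session()] accepts; a simulated session replayed from its
#' config and seed reproduces the log exactly.
#'
#' @param log A `session_log`.
#' @param path Output path of the JSON log.
#' @return Invisibly, `path`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  cfg <- log$config
  ser <- list(
    config = list(mode = cfg$mode, quadrants = cfg$quadrants,
                  conventions = unclass(cfg$conventions),
                  tick_spacing = cfg$tick_spacing, seed = cfg$seed,
                  readout_mode = cfg$readout_mode,
                  interleave = cfg$interleave),
    order = log$order,
    tracks = lapply(log$results, function(r) {
      std <- r$track$standard
      list(label = r$label, quadrant = std$quadrant$id,
           axis = std$axis,
           standard = c(std$coordinate$x, std$coordinate$y),
           direction = r$track$direction$label,
           seed = r$track$seed, jnd = r$jnd,
           trials = track_history(r$track))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  trials <- do.call(rbind, lapply(log$results, function(r) {
    cbind(data.frame(label = r$label,
                     quadrant = r$track$standard$quadrant$id,
                     direction = r$track$direction$label,
                     stringsAsFactors = FALSE),
          track_history(r$track))
  }))
  utils::write.csv(trials, paste0(path, ".trials.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @return `read_session_log()`: a `session_log`.
#' @export
read_session_log <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  conv <- do.call(mlp_conventions, as.list(ser$config$conventions))
  cfg <- session_config(mode = ser$config$mode,
                        quadrants = ser$config$quadrants,
                        conventions = conv,
                        tick_spacing = ser$config$tick_spacing,
                        seed = ser$config$seed,
                        readout_mode = ser$config$readout_mode,
                        interleave = isTRUE(ser$config$interleave))
  n <- nrow(ser$tracks)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    row <- ser$tracks[i, ]
    axis <- row$axis
    quad <- quadrant_spec(row$quadrant)
    coord <- mapping_coordinate(row$standard[[1]][1], row$standard[[1]][2])
    std <- standard_point(quad, coord,
                          axis = if (is.na(axis)) NA_character_ else axis)
    tr <- new_track(std, row$direction, conv, seed = row$seed)
    h <- row$trials[[1]]
    for (k in seq_len(nrow(h))) {
      tr <- record_trial(tr, h$delta[k], h$correct[k], h$presentation_order[k])
    }
    results[[i]] <- list(track = tr, jnd = row$jnd, label = row$label)
  }
  structure(list(config = cfg, order = ser$order, results = results),
            class = "session_log")
}

#' Simulate a complete evaluation session
#'
#' Convenience wrapper: builds the config, wraps the observer, runs the
#' session, and scores it.
#'
#' @param observer A `virtual_observer` (or parameters for one, as a
#'   list).
#' @param ... Passed to [session_config()].
#' @return A list with `log` (the `session_log`) and `report` (the
#'   score; see [score_session()]).
#' @export
simulate_session <- function(observer, ...) {
  if (is.list(observer) && !inherits(observer, "virtual_observer")) {
    observer <- do.call(virtual_observer, observer)
  }
  cfg <- session_config(...)
  log <- run_session(cfg, observer)
  list(log = log, report = score_session(log))
}
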