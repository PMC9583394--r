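# The normalized two-dimensional mapping space: quadrants, standards,
# directions, and the piecewise-linear normalization of raw input data.

QUADRANT_IDS <- c("I", "II", "III", "IV")
QUADRANT_SIGNS <- list(
  I   = c(x =  1, y =  1),
  II  = c(x = -1, y =  1),
  III = c(x = -1, y = -1),
  IV  = c(x =  1, y = -1)
)
DIRECTION_LABELS <- c("plus_x", "minus_x", "plus_y", "minus_y", "diagonal")

#' A point in the normalized mapping space
#'
#' The mapping space has two linear dimensions, each normalized to
#' \[-1, 1\]. All stimuli of the experiment live in this space.
#'
#' @param x,y Coordinates, each within \[-1, 1\].
#' @return An object of class `mapping_coordinate` (a named list with
#'   elements `x` and `y`).
#' @examples
#' mapping_coordinate(0.5, 0.5)
#' @export
mapping_coordinate <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (!is.finite(x) || !is.finite(y) || abs(x) > 1 || abs(y) > 1) {
    stop("mapping coordinates must lie within [-1, 1]^2, got (",
         format(x), ", ", format(y), ")", call. = FALSE)
  }
  structure(list(x = x, y = y), class = "mapping_coordinate")
}

#' @export
format.mapping_coordinate <- function(x, ...) {
  sprintf("(%g, %g)", x$x, x$y)
}

#' @export
print.mapping_coordinate <- function(x, ...) {
  cat("<mapping coordinate>", format(x), "\n")
  invisible(x)
}

#' Quadrant of the mapping space
#'
#' The space is divided into four quadrants named I to IV, with the
#' conventional sign pattern I (+,+), II (-,+), III (-,-), IV (+,-).
#'
#' @param id One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return An object of class `quadrant_spec` with elements `id`,
#'   `sign_x`, `sign_y`.
#' @export
quadrant_spec <- function(id) {
  id <- match.arg(as.character(id), QUADRANT_IDS)
  s <- QUADRANT_SIGNS[[id]]
  structure(list(id = id, sign_x = unname(s["x"]), sign_y = unname(s["y"])),
            class = "quadrant_spec")
}

#' Standard (reference) point of a quadrant
#'
#' In the full experiment each quadrant holds one standard at its
#' center, (±0.5, ±0.5). Variable stimuli are offset from the standard
#' along one of five directions. In the "light" design-stage variant the
#' standards instead sit on axis tick marks (see [light_standards()]).
#'
#' @param quadrant A `quadrant_spec` or a quadrant id string.
#' @param coordinate Optional `mapping_coordinate`; defaults to the
#'   quadrant center (sign_x * 0.5, sign_y * 0.5).
#' @param axis For axis (light-mode) standards, `"x"` or `"y"`; `NA` for
#'   quadrant-center standards.
#' @return An object of class `standard_point`.
#' @examples
#' standard_point("I")            # (0.5, 0.5)
#' standard_point("III")          # (-0.5, -0.5)
#' @export
standard_point <- function(quadrant, coordinate = NULL, axis = NA_character_) {
  if (!inherits(quadrant, "quadrant_spec")) quadrant <- quadrant_spec(quadrant)
  if (is.null(coordinate)) {
    coordinate <- mapping_coordinate(quadrant$sign_x * 0.5, quadrant$sign_y * 0.5)
  }
  stopifnot(inherits(coordinate, "mapping_coordinate"))
  if (!is.na(axis)) axis <- match.arg(axis, c("x", "y"))
  # the standard's coordinate must carry the quadrant's signs (0 allowed
  # for the off-axis component of light-mode standards)
  if (coordinate$x * quadrant$sign_x < 0 || coordinate$y * quadrant$sign_y < 0) {
    stop("standard coordinate ", format(coordinate),
         " contradicts the signs of quadrant ", quadrant$id, call. = FALSE)
  }
  structure(list(quadrant = quadrant, coordinate = coordinate, axis = axis),
            class = "standard_point")
}

#' @export
format.standard_point <- function(x, ...) {
  lab <- if (is.na(x$axis)) paste0("S_", x$quadrant$id) else
    paste0("tick ", x$axis, "=", format(x$coordinate[[x$axis]]))
  paste0(lab, " at ", format(x$coordinate))
}

#' @export
print.standard_point <- function(x, ...) {
  cat("<standard>", format(x), "\n")
  invisible(x)
}

#' The five test directions
#'
#' From every standard, the experiment probes five motions: along the
#' positive or negative x-direction, the positive or negative
#' y-direction, and the positive diagonal. "Positive" means increasing
#' the absolute value of the component (moving away from the coordinate
#' origin); "negative" means decreasing it (approaching the origin). The
#' diagonal increases both absolute values equally.
#'
#' @param label One of `"plus_x"`, `"minus_x"`, `"plus_y"`, `"minus_y"`,
#'   `"diagonal"`.
#' @return An object of class `direction_spec`.
#' @export
direction_spec <- function(label) {
  label <- match.arg(label, DIRECTION_LABELS)
  structure(list(label = label), class = "direction_spec")
}

#' Piecewise-linear normalization of raw input data
#'
#' Raw sensor or application data are mapped into the normalized space
#' relative to a target value: the target maps to 0, the lower bound to
#' -1, the upper bound to +1, linearly in between and clamped outside.
#' The two branches may have different slopes, so the transfer function
#' is piecewise linear.
#'
#' @param target Raw-unit target value (maps to 0).
#' @param lower_bound Raw-unit lower bound (maps to -1).
#' @param upper_bound Raw-unit upper bound (maps to +1).
#' @return An object of class `normalization_spec`.
#' @examples
#' # hot-tub temperature: target 39 degC, acceptable 35..42 degC
#' sp <- normalization_spec(target = 39, lower_bound = 35, upper_bound = 42)
#' normalize_value(c(34, 37, 39, 40.5, 43), sp)
#' @export
normalization_spec <- function(target, lower_bound, upper_bound) {
  stopifnot(is.numeric(target), is.numeric(lower_bound), is.numeric(upper_bound))
  if (!(lower_bound < target && target < upper_bound)) {
    stop("normalization bounds must satisfy lower_bound < target < upper_bound",
         call. = FALSE)
  }
  structure(list(target = target, lower_bound = lower_bound,
                 upper_bound = upper_bound),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param raw Numeric vector of raw values.
#' @param spec A `normalization_spec`.
#' @return `normalize_value()`: numeric vector in \[-1, 1\].
#' @export
normalize_value <- function(raw, spec) {
  stopifnot(inherits(spec, "normalization_spec"), is.numeric(raw))
  up <- (raw - spec$target) / (spec$upper_bound - spec$target)
  dn <- (raw - spec$target) / (spec$target - spec$lower_bound)
  out <- ifelse(raw > spec$target, up, dn)
  pmin(1, pmax(-1, out))
}

#' Variable coordinate at offset alpha from a standard
#'
#' Applies a signed offset `alpha` to the standard along a direction.
#' Offsets act on the absolute value of the component: `plus_*` moves
#' away from the coordinate origin, `minus_*` toward it, and the signs
#' are those of the standard's quadrant. For quadrant I this reduces to
#' the plain arithmetic (0.5 + alpha, 0.5) etc.
#'
#' @param standard A `standard_point`.
#' @param direction A `direction_spec` or direction label.
#' @param alpha Offset magnitude (dimensionless, >= 0).
#' @return A `mapping_coordinate`.
#' @examples
#' variable_coordinate(standard_point("I"), "plus_x", 0.07)   # (0.57, 0.5)
#' variable_coordinate(standard_point("II"), "plus_x", 0.01)  # (-0.51, 0.5)
#' @export
variable_coordinate <- function(standard, direction, alpha) {
  stopifnot(inherits(standard, "standard_point"),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  if (!inherits(direction, "direction_spec")) direction <- direction_spec(direction)
  sx <- standard$quadrant$sign_x
  sy <- standard$quadrant$sign_y
  ax <- abs(standard$coordinate$x)
  ay <- abs(standard$coordinate$y)
  lab <- direction$label
  nx <- switch(lab,
    plus_x  = sx * (ax + alpha),
    minus_x = sx * (ax - alpha),
    diagonal = sx * (ax + alpha),
    sx * ax)
  ny <- switch(lab,
    plus_y  = sy * (ay + alpha),
    minus_y = sy * (ay - alpha),
    diagonal = sy * (ay + alpha),
    sy * ay)
  if (abs(nx) > 1 || abs(ny) > 1 ||
      (lab == "minus_x" && ax - alpha < 0) || (lab == "minus_y" && ay - alpha < 0)) {
    stop("offset alpha = ", format(alpha), " pushes the variable outside the ",
         "mapping space from standard ", format(standard), " along ", lab,
         call. = FALSE)
  }
  mapping_coordinate(nx, ny)
}

#' Axis standards for the "light" design-stage experiment
#'
#' During sonification design, perceptual linearity of each axis is
#' checked by measuring the away-from-origin JND at standards that
#' equally sample the axes — the tick marks of the mapping space. Ticks
#' whose alpha grid would leave the space (|tick| + alpha_max > 1) are
#' excluded. Which axis polarities are sampled follows the quadrant
#' mask: +x from quadrants I/IV, -x from II/III, +y from I/II, -y from
#' III/IV.
#'
#' @param tick_spacing Spacing of the tick marks, in (0, 1). Default 0.1.
#' @param quadrants Character vector of quadrant ids to sample
#'   (the quadrant mask). Default all four.
#' @param alpha_max Largest stimulus offset the tick must accommodate;
#'   default 0.1 (the default hypothesis-grid ceiling).
#' @return A list of `standard_point` objects, each tagged with its axis
#'   and carrying the polarity through its quadrant signs.
#' @examples
#' length(light_standards(0.1))                      # 36: 9 ticks x 2 axes x 2 polarities
#' length(light_standards(0.5, quadrants = "I"))     # 2: (0.5, 0) and (0, 0.5)
#' @export
light_standards <- function(tick_spacing = 0.1,
                            quadrants = QUADRANT_IDS,
                            alpha_max = 0.1) {
  stopifnot(is.numeric(tick_spacing), length(tick_spacing) == 1L)
  if (!(tick_spacing > 0 && tick_spacing < 1)) {
    stop("tick_spacing must lie in (0, 1)", call. = FALSE)
  }
  quadrants <- match.arg(quadrants, QUADRANT_IDS, several.ok = TRUE)
  limit <- 1 - alpha_max + 1e-12
  ks <- seq_len(floor(limit / tick_spacing))
  if (!length(ks)) return(list())
  pol <- list(
    list(axis = "x", sign = +1, quad = "I"),
    list(axis = "x", sign = -1, quad = "II"),
    list(axis = "y", sign = +1, quad = "I"),
    list(axis = "y", sign = -1, quad = "IV")
  )
  want <- function(axis, sign) {
    qs <- QUADRANT_SIGNS[quadrants]
    any(vapply(qs, function(s) s[[axis]] == sign, logical(1)))
  }
  out <- list()
  for (p in pol) {
    if (!want(p$axis, p$sign)) next
    # quadrant tag chosen so its sign along the axis matches the polarity
    quad <- if (p$axis == "x") (if (p$sign > 0) "I" else "II")
            else (if (p$sign > 0) "I" else "IV")
    for (k in ks) {
      v <- p$sign * k * tick_spacing
      coord <- if (p$axis == "x") mapping_coordinate(v, 0) else mapping_coordinate(0, v)
      out[[length(out) + 1L]] <- standard_point(quad, coord, axis = p$axis)
    }
  }
  out
}
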