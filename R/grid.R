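#' Construct a microperimetry stimulus grid
#'
#' A grid is the geometric layout of the test points projected on the
#' retina: each point has an eccentricity (degrees from fixation) and an
#' angle (degrees counter-clockwise from the horizontal meridian).
#' Cartesian coordinates are derived as `x = ecc * cos(angle)`,
#' `y = ecc * sin(angle)`; a point at eccentricity 0 sits exactly on
#' fixation whatever its nominal angle.
#'
#' @param name Identifier string for the grid.
#' @param eccentricity Numeric vector of eccentricities in degrees
#'   (non-negative), one per point.
#' @param angle Numeric vector of angles in degrees, recycled against
#'   `eccentricity`; reduced modulo 360.
#'
#' @return An object of class `mp_grid`: a list with elements `name` and
#'   `points`, the latter a tibble with columns `point_index` (0-based,
#'   contiguous), `eccentricity`, `angle`, `x`, `y`.
#' @seealso [grid_study33()], [grid_norm61()], [read_grid()]
#' @export
#' @examples
#' g <- mp_grid("ring4", eccentricity = rep(4, 4), angle = c(0, 90, 180, 270))
#' g$points
mp_grid <- function(name, eccentricity, angle) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  eccentricity <- as.numeric(eccentricity)
  angle <- as.numeric(rep_len(angle, length(eccentricity))) %% 360
  if (length(eccentricity) == 0L) {
    stop("a grid needs at least one point", call. = FALSE)
  }
  if (any(!is.finite(eccentricity)) || any(eccentricity < 0)) {
    stop("eccentricities must be finite and non-negative", call. = FALSE)
  }
  rad <- angle * pi / 180
  pts <- tibble::tibble(
    point_index = seq_along(eccentricity) - 1L,
    eccentricity = eccentricity,
    angle = angle,
    x = ifelse(eccentricity == 0, 0, eccentricity * cos(rad)),
    y = ifelse(eccentricity == 0, 0, eccentricity * sin(rad))
  )
  structure(list(name = name, points = pts), class = "mp_grid")
}

#' @export
print.mp_grid <- function(x, ...) {
  cat(sprintf(
    "<mp_grid '%s': %d points, eccentricities {%s} deg>\n",
    x$name, nrow(x$points),
    paste(sort(unique(x$points$eccentricity)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of points in a grid
#' @param grid An [mp_grid()].
#' @return Integer point count.
#' @export
n_points <- function(grid) {
  stopifnot(inherits(grid, "mp_grid"))
  nrow(grid$points)
}

ring <- function(eccentricity, n, start = 0) {
  list(
    eccentricity = rep(eccentricity, n),
    angle = start + seq(0, 360 - 360 / n, by = 360 / n)
  )
}

#' The 33-point study grid
#'
#' One fixation point plus four rings of 8 points at eccentricities 1, 3,
#' 5 and 7 degrees, spanning the central 14 degrees of the macula. Only
#' the eccentricities of this layout are fixed by the study design; the
#' angular placement (8 points per ring at 45-degree spacing starting on
#' the horizontal meridian) is this package's convention — none of the
#' downstream statistics depend on it, since the normative model is
#' location-independent.
#'
#' @return An [mp_grid()] named `"study33"` with 33 points.
#' @export
#' @examples
#' table(grid_study33()$points$eccentricity)
grid_study33 <- function() {
  rings <- lapply(c(1, 3, 5, 7), ring, n = 8)
  mp_grid(
    "study33",
    eccentricity = c(0, unlist(lapply(rings, `[[`, "eccentricity"))),
    angle = c(0, unlist(lapply(rings, `[[`, "angle")))
  )
}

#' Alias mirroring the pipeline vocabulary
#' @rdname grid_study33
#' @export
build_study_grid <- grid_study33

#' The 61-point normative-database grid
#'
#' The layout used to derive the device's internal normative database:
#' 61 points covering the central ten degrees (eccentricities 0 through
#' 5 degrees). One fixation point plus five rings of 12 points at
#' 30-degree spacing is the package's angular convention consistent with
#' the printed point count.
#'
#' @return An [mp_grid()] named `"norm61"` with 61 points.
#' @export
grid_norm61 <- function() {
  rings <- lapply(1:5, ring, n = 12)
  mp_grid(
    "norm61",
    eccentricity = c(0, unlist(lapply(rings, `[[`, "eccentricity"))),
    angle = c(0, unlist(lapply(rings, `[[`, "angle")))
  )
}

#' Read a grid definition from a plain-text config file
#'
#' The file is YAML with a `name` field and a `points` list of
#' `{eccentricity, angle}` pairs, e.g.
#'
#' ```yaml
#' name: custom5
#' points:
#'   - {eccentricity: 0, angle: 0}
#'   - {eccentricity: 2, angle: 0}
#'   - {eccentricity: 2, angle: 90}
#'   - {eccentricity: 2, angle: 180}
#'   - {eccentricity: 2, angle: 270}
#' ```
#'
#' @param path Path to the YAML grid definition.
#' @return An [mp_grid()].
#' @export
read_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$points)) {
    stop("grid config must have 'name' and 'points' fields: ", path,
         call. = FALSE)
  }
  ecc <- vapply(cfg$points, function(p) as.numeric(p$eccentricity), numeric(1))
  ang <- vapply(cfg$points, function(p) as.numeric(p$angle), numeric(1))
  mp_grid(cfg$name, ecc, ang)
}
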