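#' Continuous (finely gridded) beam profile
#'
#' A relative dose profile sampled on a uniform position grid, normalized so
#' the central-axis value (position 0 mm) is 1.0 when the grid contains 0.
#'
#' @param positions_mm Uniformly spaced positions in mm.
#' @param values Relative dose values (finite, non-negative).
#' @param geometry Optional [beam_geometry()].
#' @param normalize Renormalize to 1.0 at 0 mm (default `TRUE` when the
#'   grid covers 0).
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(positions_mm, values, geometry = NULL,
                         normalize = TRUE) {
  stopifnot(length(positions_mm) == length(values), length(values) >= 2L,
            all(is.finite(positions_mm)), all(is.finite(values)))
  steps <- diff(positions_mm)
  if (any(steps <= 0)) stop("positions_mm must be strictly increasing")
  if (max(steps) - min(steps) > 1e-9)
    stop("beam_profile requires a uniform grid (spacing varies by > 1e-9 mm)")
  step <- steps[1]
  if (normalize && min(positions_mm) <= 0 && max(positions_mm) >= 0) {
    v0 <- approx(positions_mm, values, xout = 0)$y
    if (!is.finite(v0) || v0 <= 0) stop("cannot normalize: value at 0 mm is ", v0)
    values <- values / v0
  }
  structure(
    list(positions_mm = positions_mm, values = values,
         geometry = geometry, grid_step_mm = step),
    class = "beam_profile"
  )
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("<beam_profile> %d points, [%g, %g] mm, step %g mm\n",
              length(x$values), min(x$positions_mm), max(x$positions_mm),
              x$grid_step_mm))
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}

#' @export
plot.beam_profile <- function(x, ..., xlab = "Position (mm)",
                              ylab = "Relative dose", type = "l") {
  graphics::plot(x$positions_mm, x$values, type = type,
                 xlab = xlab, ylab = ylab, ...)
}

#' Evaluate a profile at arbitrary positions by linear interpolation
#'
#' @param profile A [beam_profile()].
#' @param positions_mm Query positions, all inside the profile support.
#' @return Interpolated values.
#' @export
profile_at <- function(profile, positions_mm) {
  stopifnot(inherits(profile, "beam_profile"))
  if (any(positions_mm < min(profile$positions_mm) - 1e-9) ||
      any(positions_mm > max(profile$positions_mm) + 1e-9))
    stop("query positions outside profile support")
  approx(profile$positions_mm, profile$values, xout = positions_mm,
         rule = 2)$y
}

#' Discrete chamber-array measurement
#'
#' Readings of a detector array at its detector positions, normalized so the
#' reading nearest the central axis is 1.0.
#'
#' @param positions_mm Detector coordinates (strictly increasing).
#' @param readings Non-negative relative readings, same length.
#' @param geometry Optional [beam_geometry()].
#' @param noise_seed Integer seed used when the readings were perturbed, or
#'   `NULL` for noise-free data.
#' @return An object of class `discrete_measurement`.
#' @export
discrete_measurement <- function(positions_mm, readings, geometry = NULL,
                                 noise_seed = NULL) {
  stopifnot(length(positions_mm) == length(readings),
            all(is.finite(readings)), all(readings >= 0))
  if (any(diff(positions_mm) <= 0))
    stop("positions_mm must be strictly increasing")
  structure(
    list(positions_mm = positions_mm, readings = readings,
         geometry = geometry, noise_seed = noise_seed),
    class = "discrete_measurement"
  )
}

#' @export
print.discrete_measurement <- function(x, ...) {
  cat(sprintf("<discrete_measurement> %d detectors, [%g, %g] mm\n",
              length(x$readings), min(x$positions_mm), max(x$positions_mm)))
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}
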