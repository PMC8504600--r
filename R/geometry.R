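#' Beam measurement geometry
#'
#' Describes one profile measurement: a square field of nominal side
#' `field_size_cm` (defined at the 100 cm isocenter plane), measured at
#' effective depth `depth_cm` with the array surface at `ssd_cm` from the
#' source, along either the in-plane or cross-plane axis.  On the modelled
#' machine the in-plane field edge is collimated by jaws and is sharper than
#' the MLC-defined cross-plane edge.
#'
#' @param field_size_cm Nominal square field side in cm (2-10 cm studied).
#' @param depth_cm Effective measurement depth in cm.
#' @param plane `"in"` (in-plane) or `"cross"` (cross-plane).
#' @param ssd_cm Source-to-surface distance in cm (default 90).
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry(10, 10, "in")
#' field_half_width_mm(g)  # 50 mm scaled by (90 + 10)/100 = 50 mm
#' @export
beam_geometry <- function(field_size_cm, depth_cm, plane = c("in", "cross"),
                          ssd_cm = 90) {
  plane <- match.arg(plane)
  stopifnot(is.numeric(field_size_cm), length(field_size_cm) == 1L,
            field_size_cm > 0, is.numeric(depth_cm), depth_cm > 0,
            ssd_cm > 0)
  structure(
    list(field_size_cm = field_size_cm, depth_cm = depth_cm,
         plane = plane, ssd_cm = ssd_cm),
    class = "beam_geometry"
  )
}

#' Geometric field half-width at the measurement plane
#'
#' The nominal field is defined at the isocenter (100 cm); the edge position
#' at the measurement plane follows beam divergence,
#' `(field_size_cm * 10 / 2) * (ssd_cm + depth_cm) / 100` mm.
#'
#' @param geometry A [beam_geometry()].
#' @return Half-width in mm.
#' @export
field_half_width_mm <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  (geometry$field_size_cm * 10 / 2) *
    (geometry$ssd_cm + geometry$depth_cm) / 100
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> %g x %g cm2, depth %g cm, %s-plane, SSD %g cm\n",
              x$field_size_cm, x$field_size_cm, x$depth_cm, x$plane, x$ssd_cm))
  invisible(x)
}

#' Detector array axis specification
#'
#' The modelled chamber array has 65 detectors at 5 mm pitch spanning
#' -160..160 mm on the Y axis and 63 on the X axis (the +/-5 mm positions
#' are absent for mechanical reasons).  Each chamber averages dose over a
#' finite aperture along the scan direction (2.9 mm for this device), the
#' source of the volume averaging effect.  By convention in-plane profiles
#' are measured on the Y axis and cross-plane profiles on the X axis.
#'
#' @param axis `"Y"` (65 detectors) or `"X"` (63 detectors, +/-5 mm absent).
#' @param pitch_mm Detector spacing in mm.
#' @param aperture_mm Volume-averaging aperture along the scan direction, mm.
#' @return An object of class `detector_array_spec` with a `positions_mm`
#'   field of detector coordinates.
#' @examples
#' length(detector_array_spec("Y")$positions_mm)  # 65
#' length(detector_array_spec("X")$positions_mm)  # 63
#' @export
detector_array_spec <- function(axis = c("Y", "X"), pitch_mm = 5,
                                aperture_mm = 2.9) {
  axis <- match.arg(axis)
  stopifnot(pitch_mm > 0, aperture_mm >= 0)
  positions <- seq(-160, 160, by = pitch_mm)
  if (axis == "X") positions <- positions[!positions %in% c(-5, 5)]
  structure(
    list(axis = axis, pitch_mm = pitch_mm, aperture_mm = aperture_mm,
         positions_mm = positions),
    class = "detector_array_spec"
  )
}

#' Array axis conventionally used for a scan plane
#'
#' In-plane profiles are read from the Y axis detectors, cross-plane
#' profiles from the X axis detectors.
#'
#' @param plane `"in"` or `"cross"`.
#' @param ... Passed to [detector_array_spec()].
#' @return A `detector_array_spec`.
#' @export
axis_for_plane <- function(plane = c("in", "cross"), ...) {
  plane <- match.arg(plane)
  detector_array_spec(axis = if (plane == "in") "Y" else "X", ...)
}
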