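#' Mean squared error between two value sequences
#'
#' @param predicted Numeric vector.
#' @param reference Numeric vector of the same length.
#' @return `mean((predicted - reference)^2)`.
#' @export
mse <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference differ in length")
  if (length(predicted) < 1L) stop("empty input")
  mean((predicted - reference)^2)
}

#' Penumbra analysis of a beam profile
#'
#' Locates the 20/50/80% crossings of each field edge and reports the
#' 80-20% penumbra width per side.  The profile is first centered at the
#' midpoint of its two 50% crossings (making the metric robust to small
#' setup offsets); thresholds are fractions of the central-axis value;
#' crossings are located by linear interpolation between bracketing grid
#' points, searching outward from the center.
#'
#' @param profile A [beam_profile()] with both edges inside the grid.
#' @return An object of class `penumbra_report`: `left_width_mm`,
#'   `right_width_mm`, `mean_width_mm`, and a `crossings` data frame of
#'   (side, level, position_mm) in centered coordinates.
#' @examples
#' g <- beam_geometry(10, 10, "in")
#' penumbra(truth_profile(g))$mean_width_mm
#' @export
penumbra <- function(profile) {
  stopifnot(inherits(profile, "beam_profile"))
  x <- profile$positions_mm
  v <- profile$values
  cax <- approx(x, v, xout = 0)$y
  if (!is.finite(cax) || cax <= 0) stop("invalid central-axis value")
  c50 <- c(left  = outward_crossing(x, v, 0.5 * cax, 0, "left"),
           right = outward_crossing(x, v, 0.5 * cax, 0, "right"))
  center <- mean(c50)
  cax <- approx(x, v, xout = center)$y
  cross <- expand.grid(side = c("left", "right"), level = c(0.2, 0.5, 0.8),
                       stringsAsFactors = FALSE)
  cross$position_mm <- mapply(function(side, level) {
    outward_crossing(x, v, level * cax, center, side) - center
  }, cross$side, cross$level)
  pos <- function(side, level)
    cross$position_mm[cross$side == side & cross$level == level]
  left_w  <- pos("left", 0.8) - pos("left", 0.2)
  right_w <- pos("right", 0.2) - pos("right", 0.8)
  if (left_w <= 0 || right_w <= 0)
    stop("degenerate penumbra: 20% crossing not outside 80% crossing")
  structure(
    list(left_width_mm = left_w, right_width_mm = right_w,
         mean_width_mm = (left_w + right_w) / 2, crossings = cross),
    class = "penumbra_report"
  )
}

# first position, scanning outward from `center` toward the given side,
# where the profile drops below `threshold` (linear interpolation between
# the bracketing grid points)
outward_crossing <- function(x, v, threshold, center, side) {
  i0 <- which.min(abs(x - center))
  idx <- if (side == "left") rev(seq_len(i0)) else seq(i0, length(x))
  below <- which(v[idx] < threshold)
  if (length(below) == 0L || below[1] == 1L)
    stop(sprintf("profile never crosses %.3g on the %s side", threshold, side))
  j <- below[1]
  i_in  <- idx[j - 1L]   # last point at or above threshold
  i_out <- idx[j]        # first point below
  frac <- (v[i_in] - threshold) / (v[i_in] - v[i_out])
  x[i_in] + frac * (x[i_out] - x[i_in])
}

#' @export
print.penumbra_report <- function(x, ...) {
  cat(sprintf("<penumbra_report> left %.3f mm, right %.3f mm, mean %.3f mm\n",
              x$left_width_mm, x$right_width_mm, x$mean_width_mm))
  invisible(x)
}

#' Penumbra width difference
#'
#' Signed difference `W_o - W_r` of mean 80-20% penumbra widths between a
#' reconstructed and a reference profile.  Positive values mean the
#' reconstruction is still broader than the reference; smaller |PWD| means
#' better agreement in the high-gradient region.
#'
#' @param reconstructed A [penumbra()] report of the profile under test.
#' @param reference A [penumbra()] report of the reference profile.
#' @return Signed PWD in mm.
#' @export
pwd <- function(reconstructed, reference) {
  stopifnot(inherits(reconstructed, "penumbra_report"),
            inherits(reference, "penumbra_report"))
  reconstructed$mean_width_mm - reference$mean_width_mm
}

#' Summarize signed PWDs over a geometry set
#'
#' @param pwds Numeric vector of signed PWDs in mm.
#' @return Data frame with `mean_pwd_mm`, `sd_pwd_mm`, `mean_abs_pwd_mm`,
#'   `max_abs_pwd_mm`, `n`.
#' @export
pwd_summary <- function(pwds) {
  data.frame(mean_pwd_mm = mean(pwds),
             sd_pwd_mm = if (length(pwds) > 1L) sd(pwds) else 0,
             mean_abs_pwd_mm = mean(abs(pwds)),
             max_abs_pwd_mm = max(abs(pwds)),
             n = length(pwds))
}

#' 1-D gamma analysis
#'
#' Global-normalization gamma index between an evaluated and a reference
#' profile.  For each reference point with value at or above the low-dose
#' threshold, the evaluated curve (resampled at `search_step_mm`) is
#' searched within `search_window_dta * dta_mm` for the minimum of
#' `sqrt((dose diff / (dose_pct% of max reference))^2 + (dx / dta_mm)^2)`;
#' a point passes when gamma <= 1.
#'
#' The minimum is taken exactly over the piecewise-linear interpolant of
#' the resampled evaluated curve (point-to-segment distance in criterion
#' units), not just at the resampled points, so steep-gradient regions do
#' not suffer search-grid artifacts.
#'
#' @param evaluated A [beam_profile()] under test.
#' @param reference A [beam_profile()] serving as reference.
#' @param dose_pct Dose criterion as percent of the reference maximum
#'   (global normalization), default 1.
#' @param dta_mm Distance-to-agreement criterion in mm, default 1.
#' @param low_dose_threshold_pct Reference points below this percent of the
#'   reference maximum are not evaluated, default 10.
#' @param search_step_mm Resampling step of the evaluated curve for the
#'   minimum search, default 0.1 mm.
#' @param search_window_dta Half search window in units of `dta_mm`,
#'   default 3.
#' @return An object of class `gamma_report`: per-point `gamma` values,
#'   evaluated `positions_mm`, `pass_rate` in percent, and the criteria.
#' @export
gamma_1d <- function(evaluated, reference, dose_pct = 1, dta_mm = 1,
                     low_dose_threshold_pct = 10, search_step_mm = 0.1,
                     search_window_dta = 3) {
  stopifnot(inherits(evaluated, "beam_profile"),
            inherits(reference, "beam_profile"),
            dose_pct > 0, dta_mm > 0)
  ref_max <- max(reference$values)
  thr <- low_dose_threshold_pct / 100 * ref_max
  keep <- reference$values >= thr
  if (!any(keep)) stop("no reference points above the low-dose threshold")
  xr <- reference$positions_mm[keep]
  dr <- reference$values[keep]
  dose_tol <- dose_pct / 100 * ref_max
  # fine resampling of the evaluated curve for the distance search
  xe <- seq(min(evaluated$positions_mm), max(evaluated$positions_mm),
            by = search_step_mm)
  de <- approx(evaluated$positions_mm, evaluated$values, xout = xe)$y
  half <- search_window_dta * dta_mm
  # criterion-unit coordinates: u along position, v along dose
  ue <- xe / dta_mm
  ve <- de / dose_tol
  gam <- vapply(seq_along(xr), function(i) {
    lo <- max(findInterval(xr[i] - half, xe), 1L)
    hi <- min(findInterval(xr[i] + half + 1e-12, xe) + 1L, length(xe))
    if (hi <= lo) return(Inf)
    j <- lo:(hi - 1L)
    # exact distance from (xr, dr) to each segment of the evaluated polyline
    p1u <- ue[j] - xr[i] / dta_mm
    p1v <- ve[j] - dr[i] / dose_tol
    du <- ue[j + 1L] - ue[j]
    dv <- ve[j + 1L] - ve[j]
    t <- pmin(pmax(-(p1u * du + p1v * dv) / (du^2 + dv^2), 0), 1)
    sqrt(min((p1u + t * du)^2 + (p1v + t * dv)^2))
  }, numeric(1))
  structure(
    list(gamma = gam, positions_mm = xr,
         pass_rate = 100 * mean(gam <= 1 + 1e-9),
         criteria = list(dose_pct = dose_pct, dta_mm = dta_mm,
                         low_dose_threshold_pct = low_dose_threshold_pct,
                         search_step_mm = search_step_mm,
                         search_window_dta = search_window_dta)),
    class = "gamma_report"
  )
}

#' @export
print.gamma_report <- function(x, ...) {
  cat(sprintf(
    "<gamma_report> %d points, %g%%/%g mm: pass rate %.1f%%, max gamma %.3f\n",
    length(x$gamma), x$criteria$dose_pct, x$criteria$dta_mm,
    x$pass_rate, max(x$gamma)))
  invisible(x)
}
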