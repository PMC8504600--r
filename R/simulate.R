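#' Truth model parameters for the synthetic beam generator
#'
#' The synthetic ground truth is an analytic model of a flattened 6 MV
#' profile: an erf-edge field shape (Gaussian penumbra of scale
#' `edge_sigma_mm`) modulated by flattening-filter horns near the field edge
#' and an out-of-field transmission tail.  Edge sharpness depends on the
#' collimating element, so `edge_sigma_mm` is a per-(plane, depth) map; the
#' jaw-defined in-plane edge is sharper than the MLC-defined cross-plane
#' edge at every depth.
#'
#' @param edge_sigma_mm Named list `$in` / `$cross`, each a named numeric
#'   vector keyed by depth in cm (names as `format(depth)`), giving the
#'   Gaussian edge scale in mm.
#' @param horn_amplitude Named numeric vector keyed by depth: relative horn
#'   height (0-0.1).  Horns fade with depth on a filter-flattened beam.
#' @param horn_width_frac Horn Gaussian width as a fraction of the field
#'   half-width.
#' @param tail_level Out-of-field transmission fraction (0-0.05).
#' @return An object of class `truth_model_params`.
#' @seealso [default_truth_params()], [calibrate_defaults()]
#' @export
truth_model_params <- function(edge_sigma_mm, horn_amplitude,
                               horn_width_frac = 0.15, tail_level = 0.015) {
  stopifnot(is.list(edge_sigma_mm),
            all(c("in", "cross") %in% names(edge_sigma_mm)),
            all(unlist(edge_sigma_mm) > 0),
            all(horn_amplitude >= 0), all(horn_amplitude <= 0.1),
            tail_level >= 0, tail_level <= 0.05, horn_width_frac > 0)
  structure(
    list(edge_sigma_mm = edge_sigma_mm, horn_amplitude = horn_amplitude,
         horn_width_frac = horn_width_frac, tail_level = tail_level),
    class = "truth_model_params"
  )
}

#' Shipped truth-model defaults
#'
#' Edge scales were fixed once by [calibrate_defaults()]: for each
#' (plane, depth) the scale is the one whose simulated array measurement,
#' after 2.9 mm volume averaging, 5 mm sampling and Makima upsampling,
#' reproduces the target penumbra broadening of
#' [default_calibration_targets()] averaged over the seven studied field
#' sizes.  Horn amplitudes are small and fade with depth (the beam is
#' flattened at 10 cm); the tail is a typical transmission level.
#'
#' @return A `truth_model_params` object.
#' @export
default_truth_params <- function() {
  truth_model_params(
    edge_sigma_mm = list(
      "in"    = c("1.5" = 0.6463, "5" = 0.7516, "10" = 1.4301),
      "cross" = c("1.5" = 1.7413, "5" = 2.0718, "10" = 2.2184)
    ),
    horn_amplitude = c("1.5" = 0.03, "5" = 0.015, "10" = 0),
    horn_width_frac = 0.15,
    tail_level = 0.015
  )
}

depth_key <- function(depth_cm) format(depth_cm, trim = TRUE)

edge_sigma_for <- function(params, plane, depth_cm) {
  sig_map <- params$edge_sigma_mm[[plane]]
  key <- depth_key(depth_cm)
  if (is.null(sig_map) || !key %in% names(sig_map) || is.na(sig_map[[key]]))
    stop(sprintf("no edge_sigma_mm entry for plane '%s' at depth %s cm",
                 plane, key))
  sig_map[[key]]
}

horn_amplitude_for <- function(params, depth_cm) {
  key <- depth_key(depth_cm)
  if (!key %in% names(params$horn_amplitude) ||
      is.na(params$horn_amplitude[[key]]))
    stop(sprintf("no horn_amplitude entry for depth %s cm", key))
  params$horn_amplitude[[key]]
}

#' Default fine evaluation grid
#'
#' 0.1 mm spacing over -170..170 mm: much finer than both the 2.9 mm
#' averaging aperture and the narrowest penumbra, and wide enough that a
#' half-aperture margin survives convolution outside the 320 mm detector
#' span.
#'
#' @return Numeric vector of positions in mm.
#' @export
fine_grid <- function() seq(-170, 170, by = 0.1)

#' Analytic ground-truth beam profile
#'
#' Builds the synthetic reference profile
#' `D(x) = [S(x; -e, sigma) - S(x; +e, sigma)] * H(x) + tail`,
#' where `S(x; e, sigma) = pnorm((x - e)/sigma)` is the erf edge, `e` the
#' divergence-scaled field half-width, and `H` adds symmetric Gaussian
#' horns of relative height `horn_amplitude` just inside each edge.  The
#' result is renormalized to 1.0 on the central axis.
#'
#' @param geometry A [beam_geometry()].
#' @param params A [truth_model_params()]; default [default_truth_params()].
#' @param grid Uniform position grid in mm, covering at least -170..170 mm.
#' @return A [beam_profile()].
#' @examples
#' p <- truth_profile(beam_geometry(10, 10, "in"))
#' p$values[p$positions_mm == 0]  # 1
#' @export
truth_profile <- function(geometry, params = default_truth_params(),
                          grid = fine_grid()) {
  stopifnot(inherits(geometry, "beam_geometry"))
  if (min(grid) > -170 || max(grid) < 170)
    stop("grid must cover at least [-170, 170] mm")
  sigma <- edge_sigma_for(params, geometry$plane, geometry$depth_cm)
  horn  <- horn_amplitude_for(params, geometry$depth_cm)
  e  <- field_half_width_mm(geometry)
  hw <- params$horn_width_frac * e
  edge <- pnorm((grid + e) / sigma) - pnorm((grid - e) / sigma)
  H <- 1 + horn * (exp(-(grid - (e - hw))^2 / (2 * hw^2)) +
                   exp(-(grid + (e - hw))^2 / (2 * hw^2)))
  d <- edge * H + params$tail_level
  beam_profile(grid, d, geometry = geometry, normalize = TRUE)
}

#' Volume averaging by a rectangular aperture
#'
#' Convolves a profile with a unit-area rectangular kernel of width
#' `aperture_mm`, the 1-D model of a chamber averaging dose over its extent
#' along the scan direction.  The convolution is the exact mean of the
#' piecewise-linear interpolant over each `[x - a/2, x + a/2]` window
#' (trapezoidal quadrature on the grid), so flat regions are invariant.
#' The output grid is trimmed to positions where the full window fits.
#'
#' @param profile A [beam_profile()] with grid step `<= aperture_mm / 4`.
#' @param aperture_mm Kernel width in mm; 0 returns the input unchanged.
#' @return A [beam_profile()] (not renormalized: a flat central axis keeps
#'   its value under a unit-area kernel).
#' @export
volume_average <- function(profile, aperture_mm = 2.9) {
  stopifnot(inherits(profile, "beam_profile"), aperture_mm >= 0)
  if (aperture_mm == 0) return(profile)
  x <- profile$positions_mm
  y <- profile$values
  h <- profile$grid_step_mm
  if (h > aperture_mm / 4 + 1e-12)
    stop("profile grid step must be <= aperture_mm / 4")
  if (aperture_mm >= max(x) - min(x))
    stop("aperture wider than profile support")
  # cumulative integral of the piecewise-linear interpolant (piecewise
  # quadratic; evaluated exactly at off-grid points)
  cumint <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * h))
  eval_cumint <- function(t) {
    i <- pmin(pmax(findInterval(t, x), 1L), length(x) - 1L)
    dt <- t - x[i]
    slope <- (y[i + 1L] - y[i]) / h
    cumint[i] + y[i] * dt + 0.5 * slope * dt^2
  }
  half <- aperture_mm / 2
  keep <- x - half >= min(x) - 1e-9 & x + half <= max(x) + 1e-9
  xo <- x[keep]
  avg <- (eval_cumint(pmin(xo + half, max(x))) -
          eval_cumint(pmax(xo - half, min(x)))) / aperture_mm
  beam_profile(xo, avg, geometry = profile$geometry, normalize = FALSE)
}

#' Simulate a chamber-array acquisition
#'
#' Samples a (typically volume-averaged) profile at the array's detector
#' positions, optionally with a lateral setup offset and multiplicative
#' Gaussian reading noise, and normalizes so the reading nearest the
#' central axis is 1.0.
#'
#' @param profile A [beam_profile()] covering all shifted detector positions.
#' @param spec A [detector_array_spec()].
#' @param setup_offset_mm Lateral setup error in mm, |offset| <= 2.5.
#' @param noise_sd Standard deviation of multiplicative reading noise
#'   (fraction; 0 = noise-free).
#' @param seed Integer seed for the noise draw (required when
#'   `noise_sd > 0` for reproducibility).
#' @return A [discrete_measurement()].
#' @export
sample_array <- function(profile, spec, setup_offset_mm = 0, noise_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(profile, "beam_profile"),
            inherits(spec, "detector_array_spec"),
            abs(setup_offset_mm) <= 2.5, noise_sd >= 0)
  pos <- spec$positions_mm
  readings <- profile_at(profile, pos + setup_offset_mm)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    eps <- withr::with_seed(seed, rnorm(length(readings), sd = noise_sd))
    readings <- readings * (1 + eps)
  }
  central <- which.min(abs(pos))
  if (readings[central] <= 0) stop("non-positive central reading")
  readings <- pmax(readings / readings[central], 0)
  discrete_measurement(pos, readings, geometry = profile$geometry,
                       noise_seed = if (noise_sd > 0) seed else NULL)
}

#' Dataset generation configuration
#'
#' @param fields_cm Field sizes in cm.
#' @param depths_cm Depths in cm.
#' @param planes Scan planes to generate.
#' @param replicates Number of noise replicates (measurement repeats).
#' @param noise_sd Multiplicative reading noise per replicate (0 = none).
#' @param setup_offset_mm Lateral setup offset applied to every acquisition.
#' @param aperture_mm Volume-averaging aperture.
#' @param seed Base seed; per-acquisition seeds are derived from it.
#' @param params Truth model parameters.
#' @param grid Fine evaluation grid for the truth profiles.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(fields_cm = c(2, 3, 4, 5, 6, 8, 10),
                           depths_cm = c(1.5, 5, 10),
                           planes = c("in", "cross"),
                           replicates = 1, noise_sd = 0,
                           setup_offset_mm = 0, aperture_mm = 2.9,
                           seed = 1L, params = default_truth_params(),
                           grid = fine_grid()) {
  stopifnot(all(planes %in% c("in", "cross")), replicates >= 1)
  structure(
    list(fields_cm = fields_cm, depths_cm = depths_cm, planes = planes,
         replicates = replicates, noise_sd = noise_sd,
         setup_offset_mm = setup_offset_mm, aperture_mm = aperture_mm,
         seed = as.integer(seed), params = params, grid = grid),
    class = "dataset_config"
  )
}

#' Generate a paired truth/measurement dataset
#'
#' Runs the forward chain (analytic truth, volume averaging, array
#' sampling) for every geometry in the configuration.  The default emits 7
#' fields x 3 depths x 2 planes = 42 geometry pairs per replicate,
#' deterministically for a given seed.
#'
#' @param config A [dataset_config()].
#' @param out_dir Optional directory: when given, truth and measurement CSV
#'   files plus a `manifest.csv` index are written there.
#' @return A list of entries, each with `$geometry`, `$truth` (fine-grid
#'   [beam_profile()]), `$measurement` ([discrete_measurement()]), and
#'   `$replicate`.
#' @export
generate_dataset <- function(config = dataset_config(), out_dir = NULL) {
  stopifnot(inherits(config, "dataset_config"))
  entries <- list()
  manifest <- list()
  idx <- 0L
  for (rep_i in seq_len(config$replicates)) {
    for (plane in config$planes) {
      spec <- axis_for_plane(plane, aperture_mm = config$aperture_mm)
      for (depth in config$depths_cm) {
        for (field in config$fields_cm) {
          idx <- idx + 1L
          geom <- beam_geometry(field, depth, plane)
          truth <- truth_profile(geom, config$params, config$grid)
          blurred <- volume_average(truth, config$aperture_mm)
          acq_seed <- (config$seed + 7919L * idx) %% 2147483647L
          meas <- sample_array(blurred, spec,
                               setup_offset_mm = config$setup_offset_mm,
                               noise_sd = config$noise_sd, seed = acq_seed)
          entries[[idx]] <- list(geometry = geom, truth = truth,
                                 measurement = meas, replicate = rep_i)
          manifest[[idx]] <- data.frame(
            index = idx, plane = plane, field_cm = field, depth_cm = depth,
            replicate = rep_i,
            seed = if (config$noise_sd > 0) acq_seed else NA_integer_)
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    man <- do.call(rbind, manifest)
    man$truth_file <- sprintf("truth_%03d.csv", man$index)
    man$measurement_file <- sprintf("meas_%03d.csv", man$index)
    for (i in seq_along(entries)) {
      write_profile(entries[[i]]$truth, file.path(out_dir, man$truth_file[i]))
      write_profile(entries[[i]]$measurement,
                    file.path(out_dir, man$measurement_file[i]))
    }
    write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  entries
}

#' Calibrate edge scales against penumbra-broadening targets
#'
#' Fixes the truth model's `edge_sigma_mm` so the simulator reproduces a
#' stated array-measurement penumbra degradation.  For each (plane, depth)
#' a scalar search over the edge scale finds the value whose forward chain
#' (truth, 2.9 mm volume averaging, 5 mm array sampling, Makima upsampling)
#' gives a mean penumbra width difference versus truth, over the field
#' sizes, equal to the target within `tol_mm`.  This is a development-time
#' procedure: its output is shipped as [default_truth_params()].
#'
#' @param targets Data frame with columns `plane`, `depth_cm`,
#'   `target_pwd_mm`; default [default_calibration_targets()].
#' @param params Starting truth parameters (horns/tail are kept).
#' @param fields_cm Field sizes averaged over.
#' @param aperture_mm Averaging aperture.
#' @param grid_step_mm Makima upsampling step.
#' @param sigma_range Search bracket for the edge scale, mm.
#' @param tol_mm Required agreement of mean PWD with the target.
#' @return A `truth_model_params` with calibrated `edge_sigma_mm`.
#' @export
calibrate_defaults <- function(targets = default_calibration_targets(),
                               params = default_truth_params(),
                               fields_cm = c(2, 3, 4, 5, 6, 8, 10),
                               aperture_mm = 2.9, grid_step_mm = 0.5,
                               sigma_range = c(0.5, 6), tol_mm = 0.05) {
  stopifnot(all(c("plane", "depth_cm", "target_pwd_mm") %in% names(targets)))
  out <- params
  for (r in seq_len(nrow(targets))) {
    plane <- targets$plane[r]
    depth <- targets$depth_cm[r]
    target <- targets$target_pwd_mm[r]
    objective <- function(sigma) {
      p <- params
      p$edge_sigma_mm[[plane]][[depth_key(depth)]] <- sigma
      forward_chain_mean_pwd(p, plane, depth, fields_cm, aperture_mm,
                             grid_step_mm) - target
    }
    lo <- objective(sigma_range[1])
    hi <- objective(sigma_range[2])
    if (abs(lo - hi) < 1e-6)
      stop(sprintf(
        "flat calibration objective for plane '%s' depth %s (degenerate chain)",
        plane, depth_key(depth)))
    if (sign(lo) == sign(hi))
      stop(sprintf(
        paste0("no edge scale in [%g, %g] mm reaches target %.2f mm for ",
               "plane '%s' depth %s (objective %.3f at %g mm, %.3f at %g mm)"),
        sigma_range[1], sigma_range[2], target, plane, depth_key(depth),
        lo, sigma_range[1], hi, sigma_range[2]))
    root <- uniroot(objective, sigma_range, tol = 1e-3)
    if (abs(root$f.root) > tol_mm)
      stop(sprintf("calibration for plane '%s' depth %s off target by %.3f mm",
                   plane, depth_key(depth), root$f.root))
    out$edge_sigma_mm[[plane]][[depth_key(depth)]] <- root$root
  }
  out
}

#' Penumbra-broadening calibration targets
#'
#' Mean Makima-upsampled array-measurement penumbra width differences, per
#' plane and depth, that the shipped simulator defaults reproduce:
#' in-plane 1.6/1.8/2.4 mm and cross-plane 1.2/1.2/1.6 mm at depths
#' 1.5/5/10 cm, characteristic of a jaw- (in-plane) and MLC- (cross-plane)
#' collimated flattened 6 MV beam measured with this array.
#'
#' @return Data frame with columns `plane`, `depth_cm`, `target_pwd_mm`.
#' @export
default_calibration_targets <- function() {
  data.frame(
    plane = rep(c("in", "cross"), each = 3),
    depth_cm = rep(c(1.5, 5, 10), 2),
    target_pwd_mm = c(1.6, 1.8, 2.4, 1.2, 1.2, 1.6)
  )
}

# Mean signed PWD of the Makima-upsampled array measurement versus truth,
# averaged over field sizes, for one (plane, depth).
forward_chain_mean_pwd <- function(params, plane, depth_cm, fields_cm,
                                   aperture_mm, grid_step_mm) {
  spec <- axis_for_plane(plane, aperture_mm = aperture_mm)
  pwds <- vapply(fields_cm, function(field) {
    geom <- beam_geometry(field, depth_cm, plane)
    truth <- truth_profile(geom, params)
    meas <- sample_array(volume_average(truth, aperture_mm), spec)
    upsampled <- makima_resample(meas, grid_step_mm)
    ref <- resample_profile(truth, upsampled$positions_mm)
    pwd(penumbra(upsampled), penumbra(ref))
  }, numeric(1))
  mean(pwds)
}
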