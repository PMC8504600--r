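test_that("truth profile is normalized, erf-edged, and horn-configurable", {
  params <- flat_params(sigma_in = 2)
  g <- beam_geometry(10, 5, "in")
  p <- truth_profile(g, params)
  expect_equal(p$values[p$positions_mm == 0], 1.0)
  # horn-free, tail-free edge midpoint reads one half of the CAX value
  e <- field_half_width_mm(g)
  expect_equal(profile_at(p, e), 0.5, tolerance = 1e-6)
  expect_equal(profile_at(p, -e), 0.5, tolerance = 1e-6)
  # closed form: 80-20 width of an erf edge is 2 * qnorm(0.8) * sigma
  pen <- penumbra(p)
  expect_equal(pen$mean_width_mm, 2 * qnorm(0.8) * 2, tolerance = 0.01)
  expect_equal(pen$left_width_mm, pen$right_width_mm, tolerance = 1e-6)
  # horns raise the near-edge region above the central axis
  horned <- truth_profile(g, default_truth_params())
  expect_gt(max(horned$values), 1.0)
  expect_error(truth_profile(beam_geometry(10, 25, "in")), "depth 25")
  expect_error(truth_profile(g, params, grid = seq(-50, 50, 0.1)), "-170")
})

test_that("volume averaging preserves flat regions and is identity at zero aperture", {
  x <- seq(-20, 20, 0.1)
  flat <- beam_profile(x, rep(1, length(x)), normalize = FALSE)
  out <- volume_average(flat, 2.9)
  expect_equal(out$values, rep(1, length(out$values)), tolerance = 1e-12)
  p <- erf_edge_profile(1.5)
  expect_identical(volume_average(p, 0), p)
  expect_error(volume_average(beam_profile(x, rep(1, length(x))), 41),
               "support")
  expect_error(volume_average(erf_edge_profile(1.5, step = 1), 2.9),
               "grid step")
})

test_that("rectangular averaging broadens an erf edge by the quadrature rule", {
  sigma <- 1.5
  a <- 2.9
  p <- erf_edge_double(sigma, step = 0.05)
  w0 <- penumbra(p)$mean_width_mm
  expect_equal(w0, 2 * qnorm(0.8) * sigma, tolerance = 0.005)
  wa <- penumbra(volume_average(p, a))$mean_width_mm
  # effective scale of erf (x) rect: sqrt(sigma^2 + a^2 / 12)
  expect_equal(wa, 2 * qnorm(0.8) * sqrt(sigma^2 + a^2 / 12),
               tolerance = 0.02 * wa)
  # independent oracle: direct quadrature of the convolution integral on a
  # rising erf edge
  single <- erf_edge_profile(sigma, step = 0.01, span = 15)
  direct <- vapply(c(-2.2, -0.7, 0.4, 1.9), function(x0) {
    u <- seq(x0 - a / 2, x0 + a / 2, length.out = 4001)
    v <- pnorm(u / sigma)
    sum((v[-1] + v[-length(v)]) / 2 * diff(u)) / a
  }, numeric(1))
  expect_equal(profile_at(volume_average(single, a), c(-2.2, -0.7, 0.4, 1.9)),
               direct, tolerance = 1e-5)
})

test_that("volume averaging never raises the maximum nor sharpens the penumbra", {
  params <- default_truth_params()
  for (plane in c("in", "cross")) {
    for (depth in c(1.5, 5, 10)) {
      for (field in c(2, 5, 10)) {
        p <- truth_profile(beam_geometry(field, depth, plane), params)
        b <- volume_average(p, 2.9)
        expect_lte(max(b$values), max(p$values) + 1e-12)
        expect_gte(penumbra(b)$mean_width_mm,
                   penumbra(p)$mean_width_mm - 1e-9)
      }
    }
  }
})

test_that("array sampling matches the device layout and is seeded", {
  p <- volume_average(truth_profile(beam_geometry(10, 5, "in")), 2.9)
  my <- sample_array(p, detector_array_spec("Y"))
  expect_length(my$readings, 65)
  expect_equal(my$positions_mm, seq(-160, 160, 5))
  expect_equal(my$readings[my$positions_mm == 0], 1.0)
  mx <- sample_array(p, detector_array_spec("X"))
  expect_length(mx$readings, 63)
  expect_false(any(mx$positions_mm %in% c(-5, 5)))
  # noise-free sampling equals the averaged profile at the detectors
  expect_equal(my$readings, profile_at(p, my$positions_mm) /
                 profile_at(p, 0), tolerance = 1e-12)
  n1 <- sample_array(p, detector_array_spec("Y"), noise_sd = 0.01, seed = 42)
  n2 <- sample_array(p, detector_array_spec("Y"), noise_sd = 0.01, seed = 42)
  n3 <- sample_array(p, detector_array_spec("Y"), noise_sd = 0.01, seed = 43)
  expect_identical(n1$readings, n2$readings)
  expect_false(identical(n1$readings, n3$readings))
  expect_error(sample_array(p, detector_array_spec("Y"),
                            setup_offset_mm = 5), "setup_offset")
  narrow <- beam_profile(seq(-50, 50, 0.1), rep(1, 1001))
  expect_error(sample_array(narrow, detector_array_spec("Y")), "support")
})

test_that("dataset generation emits the configured geometry grid deterministically", {
  d <- generate_dataset(dataset_config(seed = 7))
  expect_length(d, 42)
  planes <- vapply(d, function(e) e$geometry$plane, character(1))
  expect_equal(sum(planes == "in"), 21)
  counts <- vapply(d, function(e) length(e$measurement$readings), integer(1))
  expect_true(all(counts[planes == "in"] == 65))
  expect_true(all(counts[planes == "cross"] == 63))
  d2 <- generate_dataset(dataset_config(fields_cm = c(2, 4, 6, 10), seed = 7))
  expect_length(d2, 24)
  d3 <- generate_dataset(dataset_config(fields_cm = c(2, 10),
                                        replicates = 3, noise_sd = 0.005,
                                        seed = 7))
  expect_length(d3, 36)
  seeds <- vapply(d3, function(e) e$measurement$noise_seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # full reproducibility for a fixed config
  d4 <- generate_dataset(dataset_config(fields_cm = c(2, 10),
                                        replicates = 3, noise_sd = 0.005,
                                        seed = 7))
  expect_identical(lapply(d3, `[[`, "measurement"),
                   lapply(d4, `[[`, "measurement"))
})

test_that("makima-only penumbra error vanishes for fine pitch and no averaging", {
  params <- flat_params(sigma_in = 2)
  g <- beam_geometry(10, 5, "in")
  truth <- truth_profile(g, params)
  fine_spec <- detector_array_spec("Y", pitch_mm = 0.5, aperture_mm = 0)
  meas <- sample_array(truth, fine_spec)
  up <- makima_resample(meas, 0.5)
  ref <- resample_profile(truth, up$positions_mm)
  expect_lt(abs(pwd(penumbra(up), penumbra(ref))), 0.05)
})

test_that("edge-scale calibration reaches its target and fails cleanly otherwise", {
  tgt <- data.frame(plane = "in", depth_cm = 10, target_pwd_mm = 2.4)
  cal <- calibrate_defaults(tgt)
  achieved <- profilerestore:::forward_chain_mean_pwd(
    cal, "in", 10, c(2, 3, 4, 5, 6, 8, 10), 2.9, 0.5)
  expect_equal(achieved, 2.4, tolerance = 0.05)
  # shipped defaults respect the collimation ordering at every depth
  ship <- default_truth_params()
  for (d in c("1.5", "5", "10"))
    expect_lt(ship$edge_sigma_mm[["in"]][[d]],
              ship$edge_sigma_mm[["cross"]][[d]])
  # an unreachable target (mean PWD is strictly positive here) must error
  bad <- data.frame(plane = "in", depth_cm = 10, target_pwd_mm = 0)
  expect_error(calibrate_defaults(bad), "no edge scale")
})
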