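test_that("mse matches hand arithmetic and a naive loop", {
  expect_equal(mse(c(1, 4), c(1, 2)), 2.0)
  expect_equal(mse(1:5, 1:5), 0.0)
  o <- withr::with_seed(1, rnorm(50))
  p <- withr::with_seed(2, rnorm(50))
  acc <- 0
  for (i in seq_along(o)) acc <- acc + (o[i] - p[i])^2
  expect_equal(mse(o, p), acc / 50, tolerance = 1e-15)
  expect_error(mse(1:3, 1:4), "length")
})

test_that("penumbra of a linear ramp spans 60% of the ramp run", {
  # trapezoid: 10 mm linear ramps up at -30..-20 and down at 20..30
  x <- seq(-40, 40, 0.1)
  v <- pmin(pmax((x + 30) / 10, 0), 1) * pmin(pmax((30 - x) / 10, 0), 1)
  p <- beam_profile(x, v, normalize = FALSE)
  pen <- penumbra(p)
  expect_equal(pen$left_width_mm, 6.0, tolerance = 1e-9)
  expect_equal(pen$right_width_mm, 6.0, tolerance = 1e-9)
})

test_that("penumbra of an erf edge follows the Gaussian quantile closed form", {
  params <- flat_params(sigma_in = 2)
  p <- truth_profile(beam_geometry(10, 5, "in"), params)
  pen <- penumbra(p)
  expect_equal(pen$mean_width_mm, 2 * qnorm(0.8) * 2, tolerance = 0.01)
  expect_equal(pen$left_width_mm, pen$right_width_mm, tolerance = 1e-6)
  # crossing positions are invariant under uniform rescaling of the values
  p2 <- beam_profile(p$positions_mm, p$values * 3.7, normalize = FALSE)
  expect_equal(penumbra(p2)$crossings$position_mm, pen$crossings$position_mm,
               tolerance = 1e-9)
  # a profile that never falls below 20% cannot be analyzed
  x <- seq(-40, 40, 0.1)
  expect_error(penumbra(beam_profile(x, 0.6 + 0.4 * exp(-x^2 / 200),
                                     normalize = FALSE)),
               "never crosses")
})

test_that("penumbra centering absorbs small setup offsets", {
  params <- flat_params(sigma_in = 2)
  p <- truth_profile(beam_geometry(6, 5, "in"), params)
  shifted <- beam_profile(p$positions_mm + 1.5, p$values, normalize = FALSE)
  expect_equal(penumbra(shifted)$mean_width_mm, penumbra(p)$mean_width_mm,
               tolerance = 1e-3)
})

test_that("pwd is the signed difference of mean widths", {
  p1 <- penumbra(erf_edge_double(2.0))
  p2 <- penumbra(erf_edge_double(3.188))  # widths 3.366 vs 5.366
  expect_equal(pwd(p1, p1), 0.0)
  expect_equal(pwd(p2, p1), 2.0, tolerance = 0.01)
  # blurring with a wider kernel never decreases PWD versus the same truth
  truth <- truth_profile(beam_geometry(10, 5, "in"), flat_params(2))
  widths <- vapply(c(0, 2, 4), function(a) {
    b <- if (a == 0) truth else volume_average(truth, a)
    pwd(penumbra(b), penumbra(truth))
  }, numeric(1))
  expect_true(all(diff(widths) > -1e-9))
  s <- pwd_summary(c(-0.2, 0.4, 0.1))
  expect_equal(s$mean_pwd_mm, 0.1, tolerance = 1e-12)
  expect_equal(s$mean_abs_pwd_mm, 7 / 30, tolerance = 1e-12)
  expect_equal(s$max_abs_pwd_mm, 0.4)
})

test_that("gamma is zero for identical profiles and 1.0 at the dose boundary", {
  p <- truth_profile(beam_geometry(6, 5, "in"), flat_params(2))
  p <- resample_profile(p, seq(-100, 100, 0.5))
  g <- gamma_1d(p, p)
  expect_equal(max(g$gamma), 0.0)
  expect_equal(g$pass_rate, 100)
  x <- seq(-50, 50, 0.5)
  flat1 <- beam_profile(x, rep(1, length(x)), normalize = FALSE)
  flat2 <- beam_profile(x, rep(1.01, length(x)), normalize = FALSE)
  g2 <- gamma_1d(flat2, flat1)
  expect_equal(unique(round(g2$gamma, 9)), 1.0)
  expect_equal(g2$pass_rate, 100)  # boundary counts as a pass
})

test_that("gamma of a 1 mm shifted edge peaks at one criterion unit", {
  x <- seq(-30, 30, 0.5)
  ref <- beam_profile(x, pnorm(x / 2), normalize = FALSE)
  ev <- beam_profile(x, pnorm((x - 1) / 2), normalize = FALSE)
  g <- gamma_1d(ev, ref)
  expect_equal(max(g$gamma), 1.0, tolerance = 0.02)
})

test_that("gamma agrees with a brute-force fine-grid oracle", {
  x <- seq(-40, 40, 0.5)
  ref <- beam_profile(x, pnorm((x + 20) / 2) - pnorm((x - 20) / 2) + 0.01,
                      normalize = FALSE)
  ev <- beam_profile(x, pnorm((x + 20.4) / 1.8) - pnorm((x - 19.8) / 2.2) +
                       0.012, normalize = FALSE)
  g <- gamma_1d(ev, ref)
  oracle <- gamma_bruteforce(ev, ref)
  expect_equal(g$gamma, oracle, tolerance = 0.02)
  # scaling: doubling both tolerances halves every gamma value
  g2 <- gamma_1d(ev, ref, dose_pct = 2, dta_mm = 2,
                 search_window_dta = 6)
  expect_equal(g2$gamma, g$gamma / 2, tolerance = 0.02)
})
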