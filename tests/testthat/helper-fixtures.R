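# shared fixtures, all built in code

# horn-free, tail-free parameters with a single edge scale everywhere
flat_params <- function(sigma_in = 2, sigma_cross = 3) {
  truth_model_params(
    edge_sigma_mm = list(
      "in"    = c("1.5" = sigma_in, "5" = sigma_in, "10" = sigma_in),
      "cross" = c("1.5" = sigma_cross, "5" = sigma_cross, "10" = sigma_cross)
    ),
    horn_amplitude = c("1.5" = 0, "5" = 0, "10" = 0),
    tail_level = 0
  )
}

# analytic erf edge rising at x = 0 with scale sigma, on its own grid
erf_edge_profile <- function(sigma, step = 0.05, span = 40) {
  x <- seq(-span, span, by = step)
  beam_profile(x, pnorm(x / sigma), normalize = FALSE)
}

# symmetric two-edged erf field with edges at +/-20 mm
erf_edge_double <- function(sigma, step = 0.1, span = 60) {
  x <- seq(-span, span, by = step)
  beam_profile(x, pnorm((x + 20) / sigma) - pnorm((x - 20) / sigma),
               normalize = FALSE)
}

# random small teacher network for trainer recovery tests
random_teacher <- function(L, N, seed) {
  withr::with_seed(seed, {
    ann_model(matrix(rnorm(L * N, sd = 0.6), L, N),
              rnorm(N, sd = 0.3), rnorm(N, sd = 0.8), rnorm(1, sd = 0.2),
              grid_step_mm = 0.5)
  })
}

# pair set whose targets come from a frozen teacher evaluated on random
# smooth-ish windows
teacher_pairs <- function(teacher, n, seed) {
  L <- teacher$L_sw
  inputs <- withr::with_seed(seed, {
    base <- matrix(runif(n * L), n, L)
    t(apply(base, 1L, function(r) stats::filter(r, rep(1 / 3, 3),
                                                circular = TRUE)))
  })
  structure(list(inputs = inputs,
                 targets = ann_forward(teacher, inputs),
                 window_mm = (L - 1) * 0.5, grid_step_mm = 0.5,
                 partition = NULL),
            class = "data_pair_set")
}

# naive double-loop forward pass, the independent oracle for ann_forward
forward_bruteforce <- function(model, s) {
  out <- model$b_out
  for (k in seq_len(model$N_hn)) {
    z <- model$b_hidden[k]
    for (j in seq_len(model$L_sw)) z <- z + model$w_hidden[j, k] * s[j]
    out <- out + model$w_out[k] * tanh(z)
  }
  out
}

# brute-force fine-grid gamma oracle (independent of gamma_1d internals)
gamma_bruteforce <- function(evaluated, reference, dose_pct = 1, dta_mm = 1,
                             threshold_pct = 10, step = 0.01) {
  ref_max <- max(reference$values)
  keep <- reference$values >= threshold_pct / 100 * ref_max
  xe <- seq(min(evaluated$positions_mm), max(evaluated$positions_mm),
            by = step)
  de <- approx(evaluated$positions_mm, evaluated$values, xout = xe)$y
  dd <- dose_pct / 100 * ref_max
  vapply(which(keep), function(i) {
    xr <- reference$positions_mm[i]
    dr <- reference$values[i]
    sqrt(min(((de - dr) / dd)^2 + ((xe - xr) / dta_mm)^2))
  }, numeric(1))
}

run_scipy_makima <- function(x, y, xq) {
  payload <- jsonlite::toJSON(list(x = x, y = y, xq = xq), digits = NA)
  script <- paste(
    "import sys, json",
    "from scipy.interpolate import Akima1DInterpolator",
    "d = json.load(sys.stdin)",
    "f = Akima1DInterpolator(d['x'], d['y'], method='makima')",
    "print(json.dumps([float(v) for v in f(d['xq'])]))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = payload,
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(out[length(out)])
}

scipy_available <- function() {
  nzchar(Sys.which("python")) &&
    identical(tryCatch(
      system2("python", c("-c", shQuote("import scipy")), stdout = FALSE,
              stderr = FALSE),
      error = function(e) 1L), 0L)
}
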