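#' Three-layer sliding-window network model
#'
#' The correction network maps a fixed-length window of the Makima-upsampled
#' measurement to the volume-averaging-free value at the window center:
#' `O = w_out' tanh(W_hidden' s + b_hidden) + b_out`, with a
#' tangent-sigmoid hidden layer and a linear single-node output layer.
#'
#' @param w_hidden `L_sw x N_hn` input-to-hidden weight matrix.
#' @param b_hidden Length-`N_hn` hidden biases.
#' @param w_out Length-`N_hn` hidden-to-output weights.
#' @param b_out Scalar output bias.
#' @param grid_step_mm Grid spacing (mm) the window taps assume.
#' @return An object of class `ann_model` with `L_sw` (window length in
#'   taps, odd) and `N_hn` (hidden nodes) fields.
#' @export
ann_model <- function(w_hidden, b_hidden, w_out, b_out, grid_step_mm = 0.5) {
  w_hidden <- as.matrix(w_hidden)
  stopifnot(all(is.finite(w_hidden)), all(is.finite(b_hidden)),
            all(is.finite(w_out)), is.finite(b_out),
            length(b_hidden) == ncol(w_hidden),
            length(w_out) == ncol(w_hidden))
  if (nrow(w_hidden) %% 2L == 0L)
    stop("window length L_sw must be odd (the window needs a center tap)")
  structure(
    list(L_sw = nrow(w_hidden), N_hn = ncol(w_hidden),
         w_hidden = w_hidden, b_hidden = as.numeric(b_hidden),
         w_out = as.numeric(w_out), b_out = as.numeric(b_out),
         grid_step_mm = grid_step_mm),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model> window %d taps (%.1f mm), %d hidden nodes, %d parameters\n",
    x$L_sw, (x$L_sw - 1) * x$grid_step_mm, x$N_hn, ann_n_params(x)))
  invisible(x)
}

ann_n_params <- function(model) {
  model$L_sw * model$N_hn + 2L * model$N_hn + 1L
}

# hidden-layer activations for a windows matrix (n x L_sw)
ann_hidden <- function(model, windows) {
  tanh(sweep(windows %*% model$w_hidden, 2L, model$b_hidden, "+"))
}

#' Network forward pass
#'
#' @param model An [ann_model()].
#' @param windows A length-`L_sw` vector (one window) or an `n x L_sw`
#'   matrix of windows.
#' @return Scalar output, or a length-`n` vector for a matrix input.
#' @examples
#' m <- ann_model(matrix(1), 0, 2, 0.5)
#' ann_forward(m, 1)  # 2 * tanh(1) + 0.5
#' @export
ann_forward <- function(model, windows) {
  stopifnot(inherits(model, "ann_model"))
  if (is.null(dim(windows))) {
    if (length(windows) != model$L_sw)
      stop(sprintf("window has %d taps; model expects %d",
                   length(windows), model$L_sw))
    windows <- matrix(windows, nrow = 1L)
  }
  if (ncol(windows) != model$L_sw)
    stop(sprintf("windows have %d taps; model expects %d",
                 ncol(windows), model$L_sw))
  drop(ann_hidden(model, windows) %*% model$w_out + model$b_out)
}

#' Extract sliding-window training pairs from a profile pair
#'
#' Slides a `window_mm`-long window over the (upsampled) input profile one
#' grid point at a time; each position where the full window fits yields
#' one pair: the window values as input and the reference value at the
#' window center as target.
#'
#' @param input_profile Makima-upsampled measurement ([beam_profile()]).
#' @param reference_profile Reference profile on the identical grid.
#' @param window_mm Window length in mm (default 15; must span an odd
#'   number of grid points).
#' @return An object of class `data_pair_set`: `inputs` (`n x L_sw`
#'   matrix), `targets`, `window_mm`, `grid_step_mm`, and a `partition`
#'   slot (`NULL` until [partition_pairs()]).
#' @export
extract_pairs <- function(input_profile, reference_profile, window_mm = 15) {
  stopifnot(inherits(input_profile, "beam_profile"),
            inherits(reference_profile, "beam_profile"))
  if (length(input_profile$positions_mm) !=
        length(reference_profile$positions_mm) ||
      max(abs(input_profile$positions_mm -
                reference_profile$positions_mm)) > 1e-9)
    stop("input and reference profiles must share an identical grid")
  step <- input_profile$grid_step_mm
  L <- as.integer(round(window_mm / step)) + 1L
  if (abs(window_mm / step - round(window_mm / step)) > 1e-9 || L %% 2L == 0L)
    stop("window_mm must span an odd number of grid points")
  n <- length(input_profile$values)
  if (n < L) stop("profile shorter than the window")
  # embed() returns windows with reversed tap order; restore natural order
  inputs <- embed(input_profile$values, L)[, L:1, drop = FALSE]
  half <- (L - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  structure(
    list(inputs = inputs, targets = reference_profile$values[centers],
         window_mm = window_mm, grid_step_mm = step, partition = NULL),
    class = "data_pair_set"
  )
}

#' Concatenate data pair sets
#'
#' @param ... `data_pair_set` objects (or a single list of them) sharing
#'   window and grid settings.
#' @return A single `data_pair_set`.
#' @export
combine_pairs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "data_pair_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "data_pair_set")))
  w <- unique(vapply(sets, `[[`, numeric(1), "window_mm"))
  g <- unique(vapply(sets, `[[`, numeric(1), "grid_step_mm"))
  if (length(w) != 1L || length(g) != 1L)
    stop("pair sets disagree on window or grid settings")
  structure(
    list(inputs = do.call(rbind, lapply(sets, `[[`, "inputs")),
         targets = unlist(lapply(sets, `[[`, "targets")),
         window_mm = w, grid_step_mm = g, partition = NULL),
    class = "data_pair_set"
  )
}

#' Randomly partition pairs into train/validation/test
#'
#' Uniform-random assignment over pairs (seeded), not contiguous blocks,
#' so every profile region appears in every partition.
#'
#' @param pairs A `data_pair_set`.
#' @param split Fractions for train/validation/test; must sum to 1.
#' @param seed Integer seed.
#' @return The pair set with a `partition` factor
#'   (`train`/`validation`/`test`).
#' @export
partition_pairs <- function(pairs, split = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(pairs, "data_pair_set"), length(split) == 3L,
            abs(sum(split) - 1) < 1e-9)
  n <- length(pairs$targets)
  n_train <- round(split[1] * n)
  n_val <- round(split[2] * n)
  labels <- rep(c("train", "validation", "test"),
                c(n_train, n_val, n - n_train - n_val))
  perm <- withr::with_seed(seed, sample.int(n))
  pairs$partition <- factor(labels[perm],
                            levels = c("train", "validation", "test"))
  pairs
}

#' @export
print.data_pair_set <- function(x, ...) {
  cat(sprintf("<data_pair_set> %d pairs, window %g mm (%d taps)\n",
              length(x$targets), x$window_mm, ncol(x$inputs)))
  if (!is.null(x$partition)) print(table(x$partition))
  invisible(x)
}

#' Training configuration
#'
#' Hyperparameters of the Levenberg-Marquardt batch trainer and the
#' restart/sweep protocol.  An epoch is one accepted LM update over the
#' full training partition.
#'
#' @param epochs Maximum accepted LM updates per restart (default 400).
#' @param restarts Random re-initializations per architecture (default 10).
#' @param split Train/validation/test fractions (default 0.70/0.15/0.15).
#' @param window_mm Sliding-window length in mm (default 15).
#' @param seed Base seed; restart and partition seeds derive from it.
#' @param mu0,mu_raise,mu_lower,mu_max LM damping: initial value, factor on
#'   a rejected step, factor on an accepted step, and the ceiling at which
#'   a restart stops.
#' @param patience Consecutive validation-MSE failures before early stop.
#' @param grad_tol Infinity-norm gradient tolerance for convergence.
#' @param sweep_range Hidden-node counts for [sweep_hidden_nodes()].
#' @param verbose Print per-epoch traces.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 400L, restarts = 10L,
                            split = c(0.70, 0.15, 0.15), window_mm = 15,
                            seed = 1L, mu0 = 1e-3, mu_raise = 10,
                            mu_lower = 0.1, mu_max = 1e10, patience = 6L,
                            grad_tol = 1e-10, sweep_range = seq(2L, 20L, 2L),
                            verbose = FALSE) {
  stopifnot(epochs >= 1L, restarts >= 1L, abs(sum(split) - 1) < 1e-9,
            mu0 > 0, mu_raise > 1, mu_lower < 1, patience >= 1L)
  structure(
    list(epochs = as.integer(epochs), restarts = as.integer(restarts),
         split = split, window_mm = window_mm, seed = as.integer(seed),
         mu0 = mu0, mu_raise = mu_raise, mu_lower = mu_lower,
         mu_max = mu_max, patience = as.integer(patience),
         grad_tol = grad_tol, sweep_range = as.integer(sweep_range),
         verbose = isTRUE(verbose)),
    class = "training_config"
  )
}

restart_seed <- function(seed, restart) {
  as.integer((as.numeric(seed) + 104729 * restart) %% 2147483647)
}

# theta packing order: vec(w_hidden), b_hidden, w_out, b_out
theta_to_model <- function(theta, L, N, grid_step_mm) {
  ann_model(matrix(theta[1:(L * N)], L, N),
            theta[L * N + 1:N],
            theta[L * N + N + 1:N],
            theta[L * N + 2 * N + 1],
            grid_step_mm = grid_step_mm)
}

model_to_theta <- function(model) {
  c(as.numeric(model$w_hidden), model$b_hidden, model$w_out, model$b_out)
}

# Nguyen-Widrow-style layer initialization: hidden-unit weight vectors are
# random directions of magnitude beta = 0.7 * N^(1/L) with biases spreading
# the tanh active regions across the input range (relative dose ~[0, 1.05],
# center 0.525), so units start partitioning the window space instead of
# all saturating together.
random_init_theta <- function(L, N, seed) {
  withr::with_seed(seed, {
    beta <- 0.7 * N^(1 / L)
    W <- matrix(runif(L * N, -1, 1), L, N)
    W <- sweep(W, 2L, sqrt(colSums(W^2)) / beta, "/")
    spread <- if (N > 1L) seq(-1, 1, length.out = N) else 0
    bh <- beta * spread * sign(W[1L, ]) - colSums(W) * 0.525
    c(as.numeric(W), bh, rnorm(N, sd = 1 / sqrt(N)), 0)
  })
}

# residuals r = O - P and analytic Jacobian dO/dtheta for one theta
lm_residual_jacobian <- function(theta, S, targets, L, N) {
  W <- matrix(theta[1:(L * N)], L, N)
  bh <- theta[L * N + 1:N]
  wo <- theta[L * N + N + 1:N]
  bo <- theta[L * N + 2 * N + 1]
  A <- tanh(sweep(S %*% W, 2L, bh, "+"))
  r <- drop(A %*% wo) + bo - targets
  G <- (1 - A^2) * matrix(wo, nrow(S), N, byrow = TRUE)  # dO/d(pre-activation)
  J <- matrix(0, nrow(S), length(theta))
  for (k in seq_len(N))
    J[, (k - 1L) * L + 1:L] <- S * G[, k]
  J[, L * N + 1:N] <- G
  J[, L * N + N + 1:N] <- A
  J[, L * N + 2 * N + 1] <- 1
  list(r = r, J = J)
}

lm_sse <- function(theta, S, targets, L, N) {
  W <- matrix(theta[1:(L * N)], L, N)
  A <- tanh(sweep(S %*% W, 2L, theta[L * N + 1:N], "+"))
  r <- drop(A %*% theta[L * N + N + 1:N]) + theta[L * N + 2 * N + 1] - targets
  sum(r^2)
}

# one LM restart; returns theta (best by validation MSE), history, stop reason
lm_run <- function(theta, S_train, t_train, S_val, t_val, L, N, config) {
  mu <- config$mu0
  sse <- lm_sse(theta, S_train, t_train, L, N)
  n_train <- length(t_train)
  best_val <- lm_sse(theta, S_val, t_val, L, N) / length(t_val)
  best_theta <- theta
  val_fail <- 0L
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric(), mu = numeric())
  reason <- "max epochs"
  for (epoch in seq_len(config$epochs)) {
    rj <- lm_residual_jacobian(theta, S_train, t_train, L, N)
    g <- crossprod(rj$J, rj$r)
    if (max(abs(g)) < config$grad_tol) { reason <- "gradient tolerance"; break }
    H <- crossprod(rj$J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch({
        R <- chol(H + diag(mu, length(theta)))
        backsolve(R, forwardsolve(t(R), g))
      }, error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta - drop(step)
        sse_new <- lm_sse(cand, S_train, t_train, L, N)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- cand
          sse <- sse_new
          mu <- max(mu * config$mu_lower, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * config$mu_raise
        if (mu > config$mu_max) break
      }
    }
    if (!accepted) { reason <- "damping ceiling"; break }
    val_mse <- lm_sse(theta, S_val, t_val, L, N) / length(t_val)
    history <- rbind(history, data.frame(
      epoch = epoch, train_mse = sse / n_train, val_mse = val_mse, mu = mu))
    if (config$verbose)
      message(sprintf("  epoch %3d: train %.3e  val %.3e  mu %.1e",
                      epoch, sse / n_train, val_mse, mu))
    if (val_mse < best_val) {
      best_val <- val_mse
      best_theta <- theta
      val_fail <- 0L
    } else {
      val_fail <- val_fail + 1L
      if (val_fail >= config$patience) { reason <- "validation patience"; break }
    }
  }
  list(theta = best_theta, val_mse = best_val, history = history,
       reason = reason)
}

#' Train the correction network with Levenberg-Marquardt backpropagation
#'
#' Batch damped Gauss-Newton minimization of the training-partition MSE
#' with the analytic Jacobian of the per-pair residuals: each epoch solves
#' `(J'J + mu I) step = J'r`, lowering the damping `mu` on accepted steps
#' and raising it on rejected ones.  Training stops at the epoch limit, on
#' `patience` consecutive validation failures, at the gradient tolerance,
#' or at the damping ceiling.  The run is repeated from `restarts` random
#' initializations (seeds derived from the config seed) and the model with
#' the lowest validation MSE is returned.
#'
#' @param pairs A [extract_pairs()]/[combine_pairs()] pair set; partitioned
#'   with the config split and seed if not already.
#' @param n_hidden Hidden node count.
#' @param config A [training_config()].
#' @return An `ann_fit` list: `$model` ([ann_model()]), `$mse` (train /
#'   validation / test MSE of the selected model), `$restarts` (per-restart
#'   validation MSE and stop reason), `$history` (per-epoch trace of the
#'   selected restart), `$n_hidden`, `$selected_restart`.
#' @export
train_lm <- function(pairs, n_hidden, config = training_config()) {
  stopifnot(inherits(pairs, "data_pair_set"), n_hidden >= 1L,
            inherits(config, "training_config"))
  if (is.null(pairs$partition))
    pairs <- partition_pairs(pairs, config$split, config$seed)
  L <- ncol(pairs$inputs)
  N <- as.integer(n_hidden)
  n_params <- L * N + 2L * N + 1L
  tr <- pairs$partition == "train"
  va <- pairs$partition == "validation"
  te <- pairs$partition == "test"
  if (sum(tr) < 10L * n_params)
    warning(sprintf("only %d training pairs for %d parameters (< 10x)",
                    sum(tr), n_params))
  S_train <- pairs$inputs[tr, , drop = FALSE]
  t_train <- pairs$targets[tr]
  S_val <- pairs$inputs[va, , drop = FALSE]
  t_val <- pairs$targets[va]
  runs <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    theta0 <- random_init_theta(L, N, restart_seed(config$seed, r))
    runs[[r]] <- lm_run(theta0, S_train, t_train, S_val, t_val, L, N, config)
    if (config$verbose)
      message(sprintf("restart %d/%d: val MSE %.3e (%s)", r, config$restarts,
                      runs[[r]]$val_mse, runs[[r]]$reason))
  }
  val_mses <- vapply(runs, `[[`, numeric(1), "val_mse")
  if (all(!is.finite(val_mses))) stop("all training restarts diverged")
  best <- which.min(val_mses)
  model <- theta_to_model(runs[[best]]$theta, L, N, pairs$grid_step_mm)
  theta <- runs[[best]]$theta
  mse_of <- function(mask)
    if (any(mask)) lm_sse(theta, pairs$inputs[mask, , drop = FALSE],
                          pairs$targets[mask], L, N) / sum(mask) else NA_real_
  structure(
    list(model = model,
         mse = c(train = mse_of(tr), validation = mse_of(va),
                 test = mse_of(te)),
         restarts = data.frame(restart = seq_len(config$restarts),
                               val_mse = val_mses,
                               reason = vapply(runs, `[[`, character(1),
                                               "reason")),
         history = runs[[best]]$history,
         n_hidden = N, selected_restart = best),
    class = "ann_fit"
  )
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf(
    "<ann_fit> %d hidden nodes; MSE train %.3e / val %.3e / test %.3e (restart %d)\n",
    x$n_hidden, x$mse["train"], x$mse["validation"], x$mse["test"],
    x$selected_restart))
  invisible(x)
}

#' Hidden-node parametric sweep
#'
#' Trains the network for each hidden-node count in the sweep range
#' (each with the configured number of random restarts) and records the
#' minimum validation MSE per count.  Returns the recorded curve and the
#' model with the overall lowest validation MSE.
#'
#' @param pairs A `data_pair_set`.
#' @param config A [training_config()]; `config$sweep_range` gives the
#'   hidden-node counts (default 2, 4, ..., 20).
#' @return A list: `$curve` (data frame of `n_hidden`, `train_mse`,
#'   `val_mse`), `$best_fit` (the selected [train_lm()] fit), and
#'   `$best_n_hidden`.
#' @export
sweep_hidden_nodes <- function(pairs, config = training_config()) {
  stopifnot(inherits(pairs, "data_pair_set"))
  if (is.null(pairs$partition))
    pairs <- partition_pairs(pairs, config$split, config$seed)
  fits <- lapply(config$sweep_range, function(N) train_lm(pairs, N, config))
  curve <- data.frame(
    n_hidden = config$sweep_range,
    train_mse = vapply(fits, function(f) unname(f$mse["train"]), numeric(1)),
    val_mse = vapply(fits, function(f) unname(f$mse["validation"]),
                     numeric(1)))
  best <- which.min(curve$val_mse)
  list(curve = curve, best_fit = fits[[best]],
       best_n_hidden = config$sweep_range[best])
}

#' Reconstruct a volume-averaging-free profile
#'
#' Slides the model window one grid point at a time over the upsampled
#' measurement, emitting the network output at each window center.  The
#' half-window margins at each end, where the full window does not fit,
#' copy the input values; the result is renormalized to 1.0 at 0 mm.
#'
#' @param model An [ann_model()] (or an `ann_fit` from [train_lm()]).
#' @param profile A [beam_profile()] on the model's grid step.
#' @return A [beam_profile()] of the same length.
#' @export
reconstruct_profile <- function(model, profile) {
  if (inherits(model, "ann_fit")) model <- model$model
  stopifnot(inherits(model, "ann_model"), inherits(profile, "beam_profile"))
  if (abs(profile$grid_step_mm - model$grid_step_mm) > 1e-9)
    stop(sprintf("profile grid step %g mm does not match model step %g mm",
                 profile$grid_step_mm, model$grid_step_mm))
  v <- profile$values
  n <- length(v)
  L <- model$L_sw
  if (n < L) stop("profile shorter than the model window")
  windows <- embed(v, L)[, L:1, drop = FALSE]
  half <- (L - 1L) %/% 2L
  out <- v
  out[(half + 1L):(n - half)] <- ann_forward(model, windows)
  beam_profile(profile$positions_mm, out, geometry = profile$geometry,
               normalize = TRUE)
}

#' Save / load a trained network as JSON
#'
#' The document stores the architecture, grid step, weight matrices
#' (row-major), and optional training metadata.
#'
#' @param model An [ann_model()] or `ann_fit`.
#' @param path Output file.
#' @param metadata Optional named list stored alongside the weights.
#' @return `save_ann` returns `path` invisibly; `load_ann` an [ann_model()].
#' @export
save_ann <- function(model, path, metadata = NULL) {
  fit_meta <- NULL
  if (inherits(model, "ann_fit")) {
    fit_meta <- list(mse = as.list(model$mse),
                     selected_restart = model$selected_restart)
    model <- model$model
  }
  doc <- list(
    format = "profilerestore-ann-1",
    L_sw = model$L_sw, N_hn = model$N_hn,
    grid_step_mm = model$grid_step_mm,
    w_hidden = as.numeric(t(model$w_hidden)),  # row-major
    b_hidden = model$b_hidden, w_out = model$w_out, b_out = model$b_out,
    training = fit_meta, metadata = metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "profilerestore-ann-1")
    stop("not a profilerestore ANN model file: ", path)
  ann_model(matrix(doc$w_hidden, doc$L_sw, doc$N_hn, byrow = TRUE),
            doc$b_hidden, doc$w_out, doc$b_out,
            grid_step_mm = doc$grid_step_mm)
}
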