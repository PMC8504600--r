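test_that("forward pass reproduces hand-computed and degenerate cases", {
  m <- ann_model(matrix(1), 0, 2, 0.5)
  expect_equal(ann_forward(m, 1), 2 * tanh(1) + 0.5, tolerance = 1e-12)
  expect_equal(ann_forward(m, 1), 2.02319, tolerance = 1e-5)
  zero <- ann_model(matrix(0, 5, 3), rep(0, 3), rep(0, 3), 0)
  expect_equal(ann_forward(zero, rep(2, 5)), 0.0)
  collapsed <- ann_model(matrix(rnorm(15), 5, 3), rnorm(3), rep(0, 3), 0.37)
  expect_equal(ann_forward(collapsed, rnorm(5)), 0.37)
  expect_error(ann_forward(m, c(1, 2)), "taps")
  expect_error(ann_model(matrix(0, 4, 2), rep(0, 2), rep(0, 2), 0), "odd")
})

test_that("forward pass matches a naive double-loop oracle on random models", {
  for (seed in 1:10) {
    dims <- withr::with_seed(seed, c(L = sample(c(3, 7, 31), 1),
                                     N = sample(1:20, 1)))
    teacher <- random_teacher(dims["L"], dims["N"], seed)
    s <- withr::with_seed(seed + 100, runif(dims["L"], 0, 1.05))
    expect_equal(ann_forward(teacher, s), forward_bruteforce(teacher, s),
                 tolerance = 1e-12)
  }
})

test_that("pair extraction yields one pair per full-window center", {
  x <- seq(-160, 160, 0.5)
  input <- beam_profile(x, pnorm((x + 40) / 3) - pnorm((x - 40) / 3) + 0.01)
  ref <- beam_profile(x, pnorm((x + 40) / 2) - pnorm((x - 40) / 2) + 0.01)
  pairs <- extract_pairs(input, ref, 15)
  expect_equal(ncol(pairs$inputs), 31)
  expect_equal(nrow(pairs$inputs), 641 - 31 + 1)
  # window rows are contiguous slices, targets are reference centers
  expect_equal(pairs$inputs[1, ], input$values[1:31])
  expect_equal(pairs$inputs[10, ], input$values[10:40])
  expect_equal(pairs$targets[10], ref$values[10 + 15])
  ident <- extract_pairs(input, input, 15)
  expect_equal(ident$targets, ident$inputs[, 16])
  other <- beam_profile(seq(-160, 160, 1), rep(1, 321))
  expect_error(extract_pairs(input, other, 15), "identical grid")
  expect_error(extract_pairs(input, ref, 15.5), "odd")
})

test_that("pair partitioning matches the configured fractions", {
  x <- seq(-160, 160, 0.5)
  input <- beam_profile(x, pnorm((x + 40) / 3) - pnorm((x - 40) / 3) + 0.01)
  pairs <- partition_pairs(extract_pairs(input, input, 15), seed = 3)
  tab <- table(pairs$partition)
  expect_equal(as.integer(tab["train"]), round(0.70 * 611))
  expect_equal(as.integer(tab["validation"]), round(0.15 * 611))
  expect_identical(partition_pairs(extract_pairs(input, input, 15),
                                   seed = 3)$partition, pairs$partition)
  both <- combine_pairs(extract_pairs(input, input, 15),
                        extract_pairs(input, input, 15))
  expect_equal(length(both$targets), 2 * 611)
})

test_that("a constant target is absorbed by the output bias", {
  inputs <- withr::with_seed(1, matrix(runif(200 * 5), 200, 5))
  pairs <- structure(list(inputs = inputs, targets = rep(0.7, 200),
                          window_mm = 2, grid_step_mm = 0.5,
                          partition = NULL), class = "data_pair_set")
  fit <- suppressWarnings(
    train_lm(pairs, 2, training_config(epochs = 50, restarts = 1, seed = 4)))
  pred <- ann_forward(fit$model, inputs)
  expect_lt(max(abs(pred - 0.7)), 1e-6)
})

test_that("the trainer recovers a teacher network to near machine loss", {
  # noise-free teacher-student recovery, five random teachers
  for (seed in 1:5) {
    teacher <- random_teacher(5, 4, seed)
    pairs <- teacher_pairs(teacher, 600, seed + 50)
    fit <- suppressWarnings(
      train_lm(pairs, 4, training_config(epochs = 250, restarts = 3,
                                         seed = seed, patience = 250)))
    expect_lt(fit$mse[["train"]], 1e-8)
  }
})

test_that("training loss never increases over accepted steps and is seeded", {
  teacher <- random_teacher(5, 4, 99)
  pairs <- teacher_pairs(teacher, 400, 7)
  cfg <- training_config(epochs = 60, restarts = 2, seed = 21)
  fit1 <- suppressWarnings(train_lm(pairs, 4, cfg))
  expect_true(all(diff(fit1$history$train_mse) <= 1e-15))
  fit2 <- suppressWarnings(train_lm(pairs, 4, cfg))
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$w_hidden, fit2$model$w_hidden)
  fit3 <- suppressWarnings(
    train_lm(pairs, 4, training_config(epochs = 60, restarts = 2, seed = 22)))
  expect_false(identical(fit1$model$w_hidden, fit3$model$w_hidden))
})

test_that("hidden-node sweep records one entry per count and is deterministic", {
  teacher <- random_teacher(5, 3, 11)
  pairs <- teacher_pairs(teacher, 400, 13)
  cfg <- training_config(epochs = 30, restarts = 1, seed = 2,
                         sweep_range = c(2L, 4L))
  sw1 <- suppressWarnings(sweep_hidden_nodes(pairs, cfg))
  expect_equal(sw1$curve$n_hidden, c(2L, 4L))
  expect_equal(nrow(sw1$curve), 2L)
  sw2 <- suppressWarnings(sweep_hidden_nodes(pairs, cfg))
  expect_identical(sw1$curve, sw2$curve)
  expect_true(sw1$best_n_hidden %in% c(2L, 4L))
})

test_that("reconstruction slides the window, copies margins, renormalizes", {
  x <- seq(-160, 160, 0.5)
  input <- beam_profile(x, pnorm((x + 40) / 3) - pnorm((x - 40) / 3) + 0.01)
  # identity-trained model: input profile is its own reference
  pairs <- extract_pairs(input, input, 15)
  fit <- suppressWarnings(
    train_lm(pairs, 4, training_config(epochs = 150, restarts = 2, seed = 8,
                                       patience = 150)))
  rec <- reconstruct_profile(fit, input)
  # margins copy the input up to the final renormalization at 0 mm
  scale <- rec$values[1] / input$values[1]
  expect_equal(rec$values[1:15], input$values[1:15] * scale,
               tolerance = 1e-12)
  expect_equal(rec$values[627:641], input$values[627:641] * scale,
               tolerance = 1e-12)
  expect_equal(scale, 1, tolerance = 1e-3)
  expect_lt(max(abs(rec$values - input$values)), 1e-3)
  wrong <- beam_profile(seq(-160, 160, 1), rep(1, 321))
  expect_error(reconstruct_profile(fit$model, wrong), "grid step")
})

test_that("model JSON serialization round-trips", {
  teacher <- random_teacher(7, 3, 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_ann(teacher, path, metadata = list(note = "fixture"))
  back <- load_ann(path)
  expect_equal(back$w_hidden, teacher$w_hidden)
  expect_equal(back$b_hidden, teacher$b_hidden)
  expect_equal(back$w_out, teacher$w_out)
  expect_equal(back$b_out, teacher$b_out)
  expect_equal(back$grid_step_mm, teacher$grid_step_mm)
  s <- withr::with_seed(1, runif(7))
  expect_equal(ann_forward(back, s), ann_forward(teacher, s),
               tolerance = 1e-12)
})
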