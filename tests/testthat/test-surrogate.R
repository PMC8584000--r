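# Surrogate MLP: architecture, dataset splitting, training dynamics,
# prediction determinism and metrics.

test_that("architecture widths and validation match the design", {
  arch <- surrogate_architecture()
  expect_equal(arch$input_dim, 2232L)
  expect_equal(arch$hidden1, 1024L)
  expect_equal(arch$hidden2, 528L)
  expect_equal(arch$output, 1L)
  expect_true(arch$input_batch_norm)
  expect_equal(arch$dropout_rate, 0.3)
  expect_error(surrogate_architecture(hidden1 = 0), "hidden1")
  expect_error(surrogate_architecture(dropout_rate = 1), "dropout")

  model <- build_surrogate(arch, rng_seed = 1)
  expect_equal(dim(model$params$W1), c(2232L, 1024L))
  expect_equal(dim(model$params$W2), c(1024L, 528L))
  expect_equal(dim(model$params$W3), c(528L, 1L))

  # forward pass shape contract: k rows in, k scalars out
  X <- matrix(rnorm(5 * 2232), 5)
  expect_length(dockgen:::mlp_forward(model, X), 5L)
})

test_that("split_dataset is exhaustive, disjoint and seed-reproducible", {
  X <- matrix(rnorm(100 * 4), 100)
  y <- rnorm(100)
  cfg <- training_config(train_fraction = 0.8, rng_seed = 5)
  sp <- split_dataset(X, y, cfg)
  expect_length(sp$train_idx, 80L)
  expect_length(sp$test_idx, 20L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  sp2 <- split_dataset(X, y, cfg)
  expect_identical(sp$train_idx, sp2$train_idx)

  expect_error(training_config(train_fraction = 1.0), "train_fraction")
  expect_error(split_dataset(X[1, , drop = FALSE], y[1]), "at least 2")
})

test_that("training fits a degenerate constant target and logs history", {
  arch <- surrogate_architecture(input_dim = 20, hidden1 = 16, hidden2 = 8,
                                 dropout_rate = 0)
  model <- build_surrogate(arch, rng_seed = 2)
  X <- matrix(rnorm(120 * 20), 120)
  y <- rep(-5, 120)
  cfg <- training_config(epochs = 200, batch_size = 32,
                         learning_rate = 0.01, rng_seed = 3)
  fit <- train_surrogate(model, X, y, cfg)
  expect_length(fit$training_history, 200L)
  expect_lt(fit$training_history[200], fit$training_history[1])
  expect_true(all(abs(predict_surrogate(fit, X) - (-5)) < 0.5))
})

test_that("prediction requires training and is bit-stable", {
  arch <- surrogate_architecture(input_dim = 10, hidden1 = 8, hidden2 = 4)
  model <- build_surrogate(arch, rng_seed = 1)
  X <- matrix(rnorm(30), 3)
  expect_error(predict_surrogate(model, X), "not been trained")
  fit <- train_surrogate(model, matrix(rnorm(200), 20), rnorm(20),
                         training_config(epochs = 2, batch_size = 10,
                                         rng_seed = 1))
  p1 <- predict_surrogate(fit, X)
  p2 <- predict_surrogate(fit, X)
  expect_identical(p1, p2)
  # duplicate rows get identical predictions
  Xd <- rbind(X[1, ], X[1, ])
  pd <- predict_surrogate(fit, Xd)
  expect_equal(pd[1], pd[2])
  expect_error(train_surrogate(model, matrix(0, 2, 7), c(1, 2)), "columns")
})

test_that("regression metrics follow their definitions", {
  truth <- c(-8, -6, -4, -2)
  m <- evaluate_regression(truth, truth)
  expect_equal(m$pearson_r, 1.0)
  expect_equal(m$mse, 0.0)
  expect_equal(evaluate_regression(-truth, truth)$pearson_r, -1.0)
  shifted <- evaluate_regression(truth + 1, truth)
  expect_equal(shifted$pearson_r, 1.0)
  expect_equal(shifted$mse, 1.0)
  expect_error(evaluate_regression(c(1, 2), c(3, 3)), "constant")
})

test_that("checkpoints round-trip predictions exactly", {
  arch <- surrogate_architecture(input_dim = 12, hidden1 = 8, hidden2 = 4)
  fit <- train_surrogate(build_surrogate(arch, rng_seed = 4),
                         matrix(rnorm(240), 20), rnorm(20),
                         training_config(epochs = 3, batch_size = 10,
                                         rng_seed = 4))
  path <- tempfile(fileext = ".rds")
  save_surrogate(fit, path)
  back <- load_surrogate(path)
  X <- matrix(rnorm(36), 3)
  expect_identical(predict_surrogate(fit, X), predict_surrogate(back, X))
  unlink(path)
})
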