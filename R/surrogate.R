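# Docking-energy surrogate: a multilayer perceptron regressor
# 2232 -> 1024 -> 528 -> 1 with ELU activations, batch normalization of
# the input vector, dropout after each hidden activation, Adam updates
# and mean-squared-error loss. Implemented directly in R matrix algebra
# (BLAS-backed); evaluation mode is deterministic.

#' Surrogate network architecture
#'
#' @param input_dim feature-vector length (2232).
#' @param hidden1,hidden2 hidden-layer widths (1024 and 528).
#' @param dropout_rate dropout probability after each hidden activation.
#' @return a `dg_surrogate_arch` list.
#' @export
surrogate_architecture <- function(input_dim = 2232L, hidden1 = 1024L,
                                   hidden2 = 528L, dropout_rate = 0.3) {
  stopifnot(input_dim > 0L, hidden1 > 0L, hidden2 > 0L)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  structure(
    list(input_dim = as.integer(input_dim), hidden1 = as.integer(hidden1),
         hidden2 = as.integer(hidden2), output = 1L,
         activation = "ELU", input_batch_norm = TRUE,
         dropout_rate = dropout_rate),
    class = "dg_surrogate_arch"
  )
}

#' Surrogate training configuration
#'
#' @param epochs number of passes over the training data.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param train_fraction fraction of samples used for training in
#'   [split_dataset()]; the rest is held out.
#' @param rng_seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param weight_decay decoupled L2 weight decay applied to the dense
#'   weight matrices (not biases or batch-norm parameters). At desk-scale
#'   sample sizes the 2.3M-parameter network memorizes fingerprint bits
#'   without it; see the methods vignette.
#' @return a `dg_training_config` list.
#' @export
training_config <- function(epochs = 200L, learning_rate = 0.001,
                            batch_size = 256L, train_fraction = 0.8,
                            rng_seed = 1L, weight_decay = 1e-4) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            weight_decay >= 0)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         train_fraction = train_fraction, rng_seed = as.integer(rng_seed),
         weight_decay = weight_decay),
    class = "dg_training_config"
  )
}

#' Build an (untrained) surrogate model
#'
#' Initializes weights (He-scaled normal) under the given seed. The model
#' must be passed through [train_surrogate()] before [predict_surrogate()]
#' accepts it.
#'
#' @param arch a [surrogate_architecture()].
#' @param rng_seed seed for weight initialization.
#' @return a `dg_surrogate` model object.
#' @export
build_surrogate <- function(arch = surrogate_architecture(), rng_seed = 0L) {
  stopifnot(inherits(arch, "dg_surrogate_arch"))
  p <- with_seed(rng_seed, {
    list(
      gamma = rep(1, arch$input_dim), beta = rep(0, arch$input_dim),
      W1 = matrix(rnorm(arch$input_dim * arch$hidden1,
                        sd = sqrt(2 / arch$input_dim)),
                  arch$input_dim, arch$hidden1),
      b1 = rep(0, arch$hidden1),
      W2 = matrix(rnorm(arch$hidden1 * arch$hidden2,
                        sd = sqrt(2 / arch$hidden1)),
                  arch$hidden1, arch$hidden2),
      b2 = rep(0, arch$hidden2),
      W3 = matrix(rnorm(arch$hidden2, sd = sqrt(2 / arch$hidden2)),
                  arch$hidden2, 1L),
      b3 = 0
    )
  })
  structure(
    list(architecture = arch, params = p,
         running_mean = rep(0, arch$input_dim),
         running_var = rep(1, arch$input_dim),
         trained = FALSE, training_history = numeric(0)),
    class = "dg_surrogate"
  )
}

#' @export
print.dg_surrogate <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<surrogate MLP %d-%d-%d-1, ELU, dropout %.2f, %s>\n",
              a$input_dim, a$hidden1, a$hidden2, a$dropout_rate,
              if (x$trained) sprintf("trained %d epochs",
                                     length(x$training_history))
              else "untrained"))
  invisible(x)
}

elu <- function(z) ifelse(z > 0, z, exp(z) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(z))

# normalization scale from stored feature variances; features with zero
# training variance (e.g. fingerprint bits never seen in training) carry
# no information and are zeroed rather than amplified by 1/sqrt(eps)
norm_scale <- function(rvar) {
  ifelse(rvar < 1e-8, 0, 1 / sqrt(rvar + 1e-5))
}

# forward pass in evaluation mode (running batch-norm statistics, no
# dropout); deterministic.
mlp_forward <- function(model, X) {
  stopifnot(is.matrix(X), ncol(X) == model$architecture$input_dim)
  p <- model$params
  xn <- sweep(sweep(X, 2L, model$running_mean), 2L,
              norm_scale(model$running_var), "*")
  h0 <- sweep(sweep(xn, 2L, p$gamma, "*"), 2L, p$beta, "+")
  a1 <- elu(sweep(h0 %*% p$W1, 2L, p$b1, "+"))
  a2 <- elu(sweep(a1 %*% p$W2, 2L, p$b2, "+"))
  drop(a2 %*% p$W3 + p$b3)
}

#' Split a labeled dataset into train and test sets
#'
#' Seeded shuffle, disjoint and exhaustive at `cfg$train_fraction`.
#'
#' @param X feature matrix (rows are samples).
#' @param y label vector, `length(y) == nrow(X)`.
#' @param cfg a [training_config()].
#' @return list with `x_train`, `y_train`, `x_test`, `y_test`,
#'   `train_idx`, `test_idx`.
#' @export
split_dataset <- function(X, y, cfg = training_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples to split")
  n_train <- floor(n * cfg$train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop("train_fraction ", cfg$train_fraction, " leaves an empty set for n = ", n)
  }
  idx <- with_seed(cfg$rng_seed, sample.int(n))
  train_idx <- sort(idx[seq_len(n_train)])
  test_idx <- sort(idx[(n_train + 1L):n])
  list(x_train = X[train_idx, , drop = FALSE], y_train = y[train_idx],
       x_test = X[test_idx, , drop = FALSE], y_test = y[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Train the surrogate on labeled feature vectors
#'
#' Minibatch Adam on mean-squared error for `cfg$epochs` epochs. The
#' per-epoch mean training loss is recorded in `training_history`.
#'
#' @param model a [build_surrogate()] model.
#' @param X feature matrix (n x input_dim).
#' @param y docking energies (kcal/mol), length n.
#' @param cfg a [training_config()].
#' @return the trained model.
#' @export
train_surrogate <- function(model, X, y, cfg = training_config()) {
  stopifnot(inherits(model, "dg_surrogate"))
  arch <- model$architecture
  if (!is.matrix(X) || ncol(X) != arch$input_dim) {
    stop("X must be a matrix with ", arch$input_dim, " columns")
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  p <- model$params
  mstate <- lapply(p, function(w) w * 0)
  vstate <- lapply(p, function(w) w * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  wd <- if (is.null(cfg$weight_decay)) 0 else cfg$weight_decay
  drop_p <- arch$dropout_rate
  # input normalization statistics: computed once over the training set
  # (per-batch statistics amplify rare fingerprint bits inconsistently
  # from batch to batch; dataset statistics keep the normalized features
  # identical in training and evaluation mode)
  rmean <- colMeans(X)
  rvar <- apply(X, 2L, stats::var) * (nrow(X) - 1) / nrow(X)
  inv_sd_all <- norm_scale(rvar)
  n <- nrow(X)
  history <- numeric(cfg$epochs)
  t_step <- 0L

  with_seed(cfg$rng_seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        B <- length(idx)
        xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        xn <- sweep(sweep(xb, 2L, rmean), 2L, inv_sd_all, "*")
        h0 <- sweep(sweep(xn, 2L, p$gamma, "*"), 2L, p$beta, "+")
        z1 <- sweep(h0 %*% p$W1, 2L, p$b1, "+"); a1 <- elu(z1)
        if (drop_p > 0) {
          m1 <- matrix(runif(B * arch$hidden1) >= drop_p, B) / (1 - drop_p)
          d1 <- a1 * m1
        } else d1 <- a1
        z2 <- sweep(d1 %*% p$W2, 2L, p$b2, "+"); a2 <- elu(z2)
        if (drop_p > 0) {
          m2 <- matrix(runif(B * arch$hidden2) >= drop_p, B) / (1 - drop_p)
          d2 <- a2 * m2
        } else d2 <- a2
        pred <- drop(d2 %*% p$W3 + p$b3)
        err <- pred - yb
        epoch_loss <- epoch_loss + sum(err^2)
        # backward
        dpred <- matrix(2 * err / B, ncol = 1L)
        gW3 <- crossprod(d2, dpred); gb3 <- sum(dpred)
        dd2 <- dpred %*% t(p$W3)
        if (drop_p > 0) dd2 <- dd2 * m2
        dz2 <- dd2 * elu_grad(z2)
        gW2 <- crossprod(d1, dz2); gb2 <- colSums(dz2)
        dd1 <- dz2 %*% t(p$W2)
        if (drop_p > 0) dd1 <- dd1 * m1
        dz1 <- dd1 * elu_grad(z1)
        gW1 <- crossprod(h0, dz1); gb1 <- colSums(dz1)
        dh0 <- dz1 %*% t(p$W1)
        ggamma <- colSums(dh0 * xn); gbeta <- colSums(dh0)
        grads <- list(gamma = ggamma, beta = gbeta, W1 = gW1, b1 = gb1,
                      W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
        # Adam update
        t_step <- t_step + 1L
        bc1 <- 1 - b1m^t_step; bc2 <- 1 - b2m^t_step
        for (nm in names(p)) {
          g <- grads[[nm]]
          mstate[[nm]] <- b1m * mstate[[nm]] + (1 - b1m) * g
          vstate[[nm]] <- b2m * vstate[[nm]] + (1 - b2m) * g^2
          p[[nm]] <- p[[nm]] -
            lr * (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + eps)
          # decoupled weight decay on the dense weights only
          if (wd > 0 && nm %in% c("W1", "W2", "W3")) {
            p[[nm]] <- p[[nm]] * (1 - lr * wd)
          }
        }
      }
      history[epoch] <- epoch_loss / n
    }
  })
  model$params <- p
  model$running_mean <- rmean
  model$running_var <- rvar
  model$trained <- TRUE
  model$training_history <- history
  model
}

#' Predict docking energies with a trained surrogate
#'
#' Evaluation mode: dropout disabled, batch normalization uses running
#' statistics; identical input always gives identical output.
#'
#' @param model a trained surrogate.
#' @param X feature matrix (n x input_dim).
#' @return numeric vector of predicted energies (kcal/mol), length n.
#' @export
predict_surrogate <- function(model, X) {
  stopifnot(inherits(model, "dg_surrogate"))
  if (!model$trained) stop("surrogate model has not been trained")
  mlp_forward(model, X)
}

#' @export
predict.dg_surrogate <- function(object, newdata, ...) {
  predict_surrogate(object, newdata)
}

#' Regression metrics for predicted vs true energies
#'
#' @param pred predicted values.
#' @param truth true values (must not be constant).
#' @return list with `pearson_r` and `mse`.
#' @export
evaluate_regression <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2L) stop("need at least 2 observations")
  if (stats::sd(truth) == 0) {
    stop("truth vector is constant; Pearson correlation undefined")
  }
  list(pearson_r = stats::cor(pred, truth), mse = mean((pred - truth)^2))
}

#' Save / load a surrogate checkpoint
#'
#' The checkpoint carries the architecture, weights, batch-norm running
#' statistics and a feature-layout stamp so later sessions reproduce
#' predictions exactly.
#'
#' @param model a trained or untrained surrogate.
#' @param path checkpoint file path.
#' @return `save_surrogate` returns `path` invisibly; `load_surrogate`
#'   returns the model.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "dg_surrogate"))
  obj <- list(
    format = "dockgen-surrogate-1",
    package_version = as.character(utils::packageVersion("dockgen")),
    feature_dim = model$architecture$input_dim,
    model = model
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dockgen-surrogate-1")) {
    stop("not a surrogate checkpoint: ", path)
  }
  obj$model
}
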