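#' Training configuration for the mortality network
#'
#' The remaining-lifespan regressor is a multilayer perceptron with two
#' hidden layers of 70 rectified-linear nodes and a single affine output,
#' trained with minibatch Adam on mean-absolute-error loss. The number of
#' passes over the training data follows the batch-count convention (one
#' "epoch" per batch, see [n_training_passes()]) unless overridden.
#'
#' @param hidden Hidden layer widths (default `c(70, 70)`).
#' @param batch_size Minibatch size (default 32).
#' @param lr Initial Adam learning rate (default 0.001).
#' @param passes Number of passes over the training data; `NULL` (default)
#'   means `n_training_passes(n_train, batch_size)`.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(70, 70), batch_size = 32, lr = 0.001,
                       passes = NULL, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1), batch_size >= 1, lr > 0)
  structure(list(hidden = hidden, batch_size = batch_size, lr = lr,
                 passes = passes, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "mlp_config")
}

# internal: uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
# for both weights and biases
init_layers <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    fan_in <- sizes[i]
    bound <- 1 / sqrt(fan_in)
    list(w = matrix(stats::runif(fan_in * sizes[i + 1], -bound, bound),
                    fan_in, sizes[i + 1]),
         b = stats::runif(sizes[i + 1], -bound, bound))
  })
}

# internal: forward pass; returns activations per layer (ReLU on hidden,
# affine output)
mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$w, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
  }
  acts
}

#' Train the remaining-lifespan MLP
#'
#' Inputs are z-score normalized with statistics computed from the training
#' data only, except columns listed in `exempt` (the strain encodings, rank
#' code and timepoint index, which are already on meaningful categorical
#' scales). Training is seeded and bit-reproducible: the same seed, data and
#' configuration give identical weights.
#'
#' @param x Numeric matrix of training features (named columns).
#' @param y Numeric vector of weeks until death.
#' @param config An [mlp_config()].
#' @param seed Integer seed for initialization and batch shuffling.
#' @param exempt Column names excluded from z-normalization.
#' @return Object of class `mlp_model`: layers, normalization statistics,
#'   feature names, training config.
#' @export
train_mlp <- function(x, y, config = mlp_config(), seed = 1,
                      exempt = character(0)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) stop("empty training set")
  stopifnot(length(y) == n, !is.null(colnames(x)))
  set.seed(as.integer(seed))

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  ex <- colnames(x) %in% exempt
  center[ex] <- 0
  scale[ex] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")

  layers <- init_layers(c(ncol(x), config$hidden, 1))
  passes <- if (is.null(config$passes)) {
    n_training_passes(n, config$batch_size)
  } else {
    config$passes
  }

  # Adam state
  mom <- lapply(layers, function(l) list(mw = l$w * 0, vw = l$w * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  step <- 0
  for (pass in seq_len(passes)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      xb <- xs[idx, , drop = FALSE]
      yb <- y[idx]
      acts <- mlp_forward(layers, xb)
      pred <- acts[[length(acts)]][, 1]
      # MAE loss gradient
      delta <- matrix(sign(pred - yb) / length(yb), ncol = 1)
      step <- step + 1
      for (i in rev(seq_along(layers))) {
        gw <- crossprod(acts[[i]], delta)
        gb <- colSums(delta)
        if (i > 1) {
          delta <- (delta %*% t(layers[[i]]$w)) * (acts[[i]] > 0)
        }
        m <- mom[[i]]
        m$mw <- config$beta1 * m$mw + (1 - config$beta1) * gw
        m$vw <- config$beta2 * m$vw + (1 - config$beta2) * gw^2
        m$mb <- config$beta1 * m$mb + (1 - config$beta1) * gb
        m$vb <- config$beta2 * m$vb + (1 - config$beta2) * gb^2
        mom[[i]] <- m
        corr1 <- 1 - config$beta1^step
        corr2 <- 1 - config$beta2^step
        layers[[i]]$w <- layers[[i]]$w -
          config$lr * (m$mw / corr1) / (sqrt(m$vw / corr2) + config$eps)
        layers[[i]]$b <- layers[[i]]$b -
          config$lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + config$eps)
      }
    }
  }
  structure(list(layers = layers, center = center, scale = scale,
                 features = colnames(x), config = config,
                 passes = passes, seed = as.integer(seed)),
            class = "mlp_model")
}

#' Predict weeks until death with a trained MLP
#'
#' @param object An `mlp_model`.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  acts <- mlp_forward(object$layers, xs)
  acts[[length(acts)]][, 1]
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %s -> 1 (%d passes, batch %d, lr %g)\n",
              paste(c(length(x$features), x$config$hidden), collapse = " -> "),
              x$passes, x$config$batch_size, x$config$lr))
  invisible(x)
}
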