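#' Back-propagation network configuration
#'
#' Architecture and optimizer settings for the suitability classifier: a
#' feed-forward network with logistic hidden units and a sigmoid output,
#' trained on mean cross-entropy by full-batch gradient descent with
#' momentum. The small default capacity (one hidden layer of 16 units)
#' reflects the small-sample regime this screen operates in, where a
#' ~160-entry library cannot support deep architectures.
#'
#' @param hidden Integer vector of hidden-layer sizes (default one layer of
#'   16).
#' @param learn_rate Learning rate (> 0, default 0.05).
#' @param momentum Momentum coefficient (default 0.9).
#' @param batch_size Mini-batch size for stochastic gradient descent
#'   (default 16); batches are reshuffled every epoch under the training
#'   seed, so runs are reproducible.
#' @param epochs Training epochs (>= 0, default 2000).
#' @param patience Early-stop patience: training stops once the monitored
#'   loss (validation loss when a validation set is given, else training
#'   loss) has not improved for this many epochs; the best snapshot is
#'   returned. Default 100.
#' @param val_fraction Fraction of the training data carved out (seeded,
#'   stratified) as a validation set monitored for early stopping when no
#'   explicit validation set is passed. Default 0 (monitor training loss).
#' @param threshold Decision threshold on the output probability (default
#'   0.5).
#' @param seed Integer seed for weight initialization.
#' @return A `bp_config` list.
#' @export
bp_config <- function(hidden = 16L, learn_rate = 0.05, momentum = 0.9,
                      batch_size = 16L, epochs = 2000L, patience = 100L,
                      val_fraction = 0, threshold = 0.5, seed = 1L) {
  assert_that(learn_rate > 0 && momentum >= 0,
              "rates must be positive", class = "coformerscout_argument_error")
  assert_that(is_count(epochs), "epochs must be a non-negative integer",
              class = "coformerscout_argument_error")
  assert_that(is_count(batch_size) && batch_size >= 1,
              "batch_size must be >= 1",
              class = "coformerscout_argument_error")
  assert_that(val_fraction >= 0 && val_fraction < 1,
              "val_fraction must lie in [0, 1)",
              class = "coformerscout_argument_error")
  structure(list(hidden = as.integer(hidden), activation = "logistic",
                 learn_rate = learn_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction,
                 threshold = threshold, seed = as.integer(seed)),
            class = "bp_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Initialize network weights
#'
#' Glorot-uniform initialization for a fully connected network.
#'
#' @param layer_sizes Integer vector `c(p, hidden..., 1)` of layer widths.
#' @param seed Integer seed.
#' @return List with `W` (list of weight matrices, in-features x
#'   out-features) and `b` (list of bias vectors).
#' @export
bp_init <- function(layer_sizes, seed = 1L) {
  withr::with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(layer_sizes) - 1)) {
      fan_in <- layer_sizes[l]; fan_out <- layer_sizes[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[l]] <- rep(0, fan_out)
    }
    list(W = W, b = b)
  })
}

bp_forward <- function(weights, x) {
  a <- list(x)
  n_layers <- length(weights$W)
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% weights$W[[l]] +
      matrix(weights$b[[l]], nrow(a[[l]]), length(weights$b[[l]]),
             byrow = TRUE)
    a[[l + 1]] <- logistic(z)
  }
  a
}

#' Loss and analytic gradient of the network
#'
#' Mean binary cross-entropy of the network output against 0/1 targets and
#' its exact gradient with respect to every weight and bias, computed by
#' error back-propagation. Exposed so the gradient can be verified against
#' finite differences.
#'
#' @param weights A weight list as produced by [bp_init()].
#' @param x Numeric input matrix (rows = samples).
#' @param y Binary targets (0/1).
#' @return List with `loss` (scalar) and `grad` (same shape as `weights`).
#' @export
bp_loss_grad <- function(weights, x, y) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  a <- bp_forward(weights, x)
  p <- pmin(pmax(a[[length(a)]], 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  n_layers <- length(weights$W)
  gW <- vector("list", n_layers); gb <- vector("list", n_layers)
  # output delta for sigmoid + cross-entropy
  delta <- (a[[n_layers + 1]] - y) / n
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- t(a[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(weights$W[[l]])) * a[[l]] * (1 - a[[l]])
    }
  }
  list(loss = loss, grad = list(W = gW, b = gb))
}

#' Train the back-propagation suitability classifier
#'
#' Full-batch gradient descent with momentum on mean cross-entropy. The
#' loss is recorded every epoch; when the monitored loss (validation loss
#' if `x_val` is given, else training loss) stops improving for
#' `config$patience` epochs, training halts and the best snapshot seen is
#' returned.
#'
#' @param x A `feature_matrix` from [featurize_library()] (its stored
#'   normalization is kept on the model for prediction-time reuse), or an
#'   already-normalized numeric matrix.
#' @param y Binary labels (0/1), one per row.
#' @param config A [bp_config()].
#' @param x_val,y_val Optional validation set monitored for early stopping.
#' @return A `bp_model`: weights, config, normalization parameters, loss
#'   trace and the epoch of the returned snapshot.
#' @examples
#' lib <- generate_library(generator_config(n = 100, noise = 0, seed = 2))
#' fm <- featurize_library(lib)
#' fit <- train_bp(fm, lib$label, bp_config(epochs = 200, seed = 2))
#' glance(fit)
#' @export
train_bp <- function(x, y, config = bp_config(), x_val = NULL, y_val = NULL) {
  if (inherits(x, "feature_matrix")) {
    xm <- x$x
    scaling <- list(spec = x$spec, center = x$center, scale = x$scale,
                    k = x$k, encode_seed = x$encode_seed)
  } else {
    xm <- as.matrix(x)
    scaling <- list(spec = colnames(xm),
                    center = rep(0, ncol(xm)), scale = rep(1, ncol(xm)),
                    k = NA_integer_, encode_seed = NA_integer_)
  }
  y <- as.numeric(y)
  assert_that(!anyNA(xm) && all(is.finite(xm)),
              "x contains missing or non-finite values",
              class = "coformerscout_data_error")
  assert_that(all(y %in% c(0, 1)) && length(y) == nrow(xm),
              "y must be binary 0/1 with one entry per row of x",
              class = "coformerscout_data_error")
  if (inherits(x_val, "feature_matrix")) x_val <- x_val$x
  if (is.null(x_val) && config$val_fraction > 0 && nrow(xm) >= 10) {
    # stratified seeded carve-out, monitored only (never used for updates)
    hold <- withr::with_seed(config$seed + 2L, {
      unlist(lapply(split(seq_along(y), y), function(idx) {
        sample(idx, max(1L, round(length(idx) * config$val_fraction)))
      }), use.names = FALSE)
    })
    x_val <- xm[hold, , drop = FALSE]
    y_val <- y[hold]
    xm <- xm[-hold, , drop = FALSE]
    y <- y[-hold]
  }
  layers <- c(ncol(xm), config$hidden, 1L)
  weights <- bp_init(layers, config$seed)
  velocity <- list(W = lapply(weights$W, function(w) w * 0),
                   b = lapply(weights$b, function(b) b * 0))
  trace <- numeric(0)
  monitor <- numeric(0)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  stall <- 0L
  n <- nrow(xm)
  full_loss <- function(w, xx, yy) {
    p <- bp_forward(w, xx)
    p <- pmin(pmax(p[[length(p)]], 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  withr::with_seed(config$seed + 1L, for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      lg <- bp_loss_grad(weights, xm[idx, , drop = FALSE], y[idx])
      for (l in seq_along(weights$W)) {
        velocity$W[[l]] <- config$momentum * velocity$W[[l]] -
          config$learn_rate * lg$grad$W[[l]]
        velocity$b[[l]] <- config$momentum * velocity$b[[l]] -
          config$learn_rate * lg$grad$b[[l]]
        weights$W[[l]] <- weights$W[[l]] + velocity$W[[l]]
        weights$b[[l]] <- weights$b[[l]] + velocity$b[[l]]
      }
    }
    loss <- full_loss(weights, xm, y)
    if (!is.finite(loss)) {
      abort("training diverged (non-finite loss)",
            class = "coformerscout_training_error",
            trace = trace)
    }
    trace[epoch] <- loss
    mon <- if (is.null(x_val)) loss else {
      full_loss(weights, as.matrix(x_val), y_val)
    }
    monitor[epoch] <- mon
    if (mon < best$loss - 1e-12) {
      best <- list(loss = mon, weights = weights, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  })
  final <- if (config$epochs == 0) {
    list(loss = NA_real_, weights = weights, epoch = 0L)
  } else best
  structure(list(weights = final$weights, config = config,
                 scaling = scaling, layers = layers,
                 loss_trace = trace, monitor_trace = monitor,
                 best_epoch = final$epoch),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> layers %s, %d epoch(s) run, snapshot at epoch %d\n",
              paste(x$layers, collapse = "-"), length(x$loss_trace),
              x$best_epoch))
  invisible(x)
}

# Resolve prediction inputs to the model's normalized feature space.
model_input <- function(object, x) {
  if (inherits(x, "feature_matrix")) {
    assert_that(identical(colnames(x$x), names(object$scaling$center)) ||
                  ncol(x$x) == object$layers[1],
                "feature columns do not match the training spec",
                class = "coformerscout_schema_error")
    raw <- x$x_raw
  } else {
    raw <- as.matrix(x)
    assert_that(ncol(raw) == object$layers[1],
                "feature columns do not match the training spec",
                class = "coformerscout_schema_error")
  }
  sc <- object$scaling
  safe <- ifelse(is.na(sc$scale) | sc$scale == 0, 1, sc$scale)
  out <- sweep(sweep(raw, 2, sc$center), 2, safe, "/")
  out[, sc$scale == 0 | is.na(sc$scale)] <- 0
  out
}

#' Predict suitability probabilities and labels
#'
#' @param object A trained `bp_model`.
#' @param x A `feature_matrix` built with the same feature spec, or a raw
#'   descriptor matrix on the original scale (the model's stored
#'   normalization is applied).
#' @param ... Unused.
#' @return A tibble with columns `prob` (output probability in \[0, 1\]) and
#'   `label` (1 when `prob >= threshold`).
#' @export
predict.bp_model <- function(object, x, ...) {
  xm <- model_input(object, x)
  a <- bp_forward(object$weights, xm)
  prob <- as.numeric(a[[length(a)]])
  tibble(prob = prob,
         label = as.integer(prob >= object$config$threshold))
}

#' Confusion matrix for binary suitability predictions
#'
#' @param predicted Predicted 0/1 labels.
#' @param actual True 0/1 labels.
#' @return A `confusion_matrix` with counts `tp`, `fp`, `fn`, `tn`
#'   (positive class = 1).
#' @examples
#' # a 39-entry evaluation with 34 agreements
#' cm <- confusion_matrix(c(rep(1, 20), rep(0, 14), rep(1, 3), rep(0, 2)),
#'                        c(rep(1, 20), rep(0, 14), rep(0, 3), rep(1, 2)))
#' glance(cm)$accuracy # 87.2
#' @export
confusion_matrix <- function(predicted, actual) {
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  assert_that(length(predicted) == length(actual) && length(actual) > 0,
              "predicted and actual must be equal-length and non-empty",
              class = "coformerscout_argument_error")
  assert_that(all(predicted %in% c(0L, 1L)) && all(actual %in% c(0L, 1L)),
              "labels must be 0/1", class = "coformerscout_argument_error")
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 fp = sum(predicted == 1 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1),
                 tn = sum(predicted == 0 & actual == 0)),
            class = "confusion_matrix")
}

#' Evaluate a model on a labeled test set
#'
#' @param model A trained `bp_model`.
#' @param x Test features (see [predict.bp_model()]).
#' @param y True 0/1 labels.
#' @return A [confusion_matrix()].
#' @export
evaluate_bp <- function(model, x, y) {
  y <- as.integer(y)
  assert_that(length(y) > 0, "empty test set",
              class = "coformerscout_argument_error")
  pred <- predict(model, x)
  confusion_matrix(pred$label, y)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  g <- glance(x)
  cat("<confusion_matrix>\n")
  cat(sprintf("            actual 1  actual 0\n"))
  cat(sprintf("  pred 1   %8d  %8d\n", x$tp, x$fp))
  cat(sprintf("  pred 0   %8d  %8d\n", x$fn, x$tn))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              g$accuracy, g$sensitivity, g$specificity))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn))
}

#' @describeIn confusion_matrix One-row summary with `accuracy`,
#'   `sensitivity` and `specificity` in percent, reported to one decimal
#'   (half-up, matching how such accuracies are conventionally printed).
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @export
glance.confusion_matrix <- function(x, ...) {
  n <- x$tp + x$fp + x$fn + x$tn
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = n,
         accuracy = pct(x$tp + x$tn, n),
         sensitivity = pct(x$tp, x$tp + x$fn),
         specificity = pct(x$tn, x$tn + x$fp))
}

#' @export
tidy.bp_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights$W), function(l) {
    tibble(layer = l,
           n_weights = length(x$weights$W[[l]]) + length(x$weights$b[[l]]),
           weight_norm = sqrt(sum(x$weights$W[[l]]^2) +
                                sum(x$weights$b[[l]]^2)))
  })
}

#' @export
glance.bp_model <- function(x, ...) {
  tibble(epochs_run = length(x$loss_trace),
         best_epoch = x$best_epoch,
         final_loss = if (length(x$loss_trace)) {
           x$loss_trace[length(x$loss_trace)]
         } else NA_real_,
         best_monitored_loss = if (length(x$monitor_trace)) {
           min(x$monitor_trace)
         } else NA_real_)
}

#' @export
autoplot.bp_model <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trace),
               loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble(predicted = factor(c(1, 1, 0, 0), levels = c(1, 0)),
               actual = factor(c(1, 0, 1, 0), levels = c(0, 1)),
               count = c(object$tp, object$fp, object$fn, object$tn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "#9ecae1", high = "#08306b") +
    ggplot2::theme_minimal()
}
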