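test_that("backpropagated gradients match central finite differences", {
  for (s in 1:3) {
    w <- bp_init(c(3, 4, 1), seed = s)
    withr::with_seed(100 + s, {
      x <- matrix(rnorm(30), 10, 3)
      y <- sample(0:1, 10, replace = TRUE)
    })
    expect_lt(grad_rel_error(w, x, y), 1e-5)
  }
})

test_that("an untrained model predicts near one half", {
  withr::with_seed(1, x <- matrix(rnorm(60), 20, 3))
  m <- train_bp(x, rep(c(0, 1), 10), bp_config(epochs = 0, seed = 5))
  p <- predict(m, x)$prob
  expect_true(all(p > 0.1 & p < 0.9))
  expect_lt(abs(mean(p) - 0.5), 0.2)
})

test_that("separable data is fit perfectly within 500 epochs", {
  hits <- vapply(1:3, function(s) {
    d <- generate_separable_data(n = 200, seed = s)
    expect_true(perceptron_separates(d$x, d$y))
    m <- train_bp(d$x, d$y,
                  bp_config(epochs = 500, patience = 500, seed = s))
    mean(predict(m, d$x)$label == d$y)
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("prediction identities hold", {
  m <- train_bp(matrix(rnorm(40), 20, 2), rep(c(0, 1), 10),
                bp_config(epochs = 5, seed = 1))
  # zero weights force probability exactly one half
  m0 <- m
  m0$weights$W <- lapply(m0$weights$W, function(w) w * 0)
  m0$weights$b <- lapply(m0$weights$b, function(b) b * 0)
  withr::with_seed(2, xs <- matrix(rnorm(200), 100, 2))
  expect_identical(unique(predict(m0, xs)$prob), 0.5)
  # codomain and threshold consistency
  pr <- predict(m, xs)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_identical(pr$label, as.integer(pr$prob >= 0.5))
  expect_identical(pr$label,
                   as.integer(apply(cbind(1 - pr$prob, pr$prob), 1,
                                    which.max) - 1L))
  expect_error(predict(m, xs[, 1, drop = FALSE]),
               class = "coformerscout_schema_error")
})

test_that("training rejects bad inputs and returns the best snapshot", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(train_bp(rbind(x, c(NA, 1)), rep(0:1, length.out = 21)),
               class = "coformerscout_data_error")
  expect_error(train_bp(x, rep(2, 20)), class = "coformerscout_data_error")
  d <- generate_separable_data(n = 60, seed = 4)
  m <- train_bp(d$x, d$y, bp_config(epochs = 300, patience = 40, seed = 4))
  expect_equal(min(m$monitor_trace), m$monitor_trace[m$best_epoch])
  expect_lte(m$best_epoch, length(m$loss_trace))
})

test_that("confusion matrices count every test record exactly once", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(5:60, 1)
      pred <- sample(0:1, n, replace = TRUE)
      act <- sample(0:1, n, replace = TRUE)
    })
    cm <- confusion_matrix(pred, act)
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, n)
    expect_identical(cm$tp + cm$fn, sum(act == 1))
  }
  cm <- confusion_matrix(rep(1, 10), rep(1, 10))
  expect_identical(glance(cm)$accuracy, 100)
  expect_error(evaluate_bp(structure(list(), class = "bp_model"),
                           matrix(0, 0, 2), integer(0)),
               class = "coformerscout_argument_error")
})

test_that("label-shuffled data yields chance-level test accuracy", {
  accs <- vapply(1:20, function(s) {
    lib <- random_library(120, seed = 500 + s)
    shuffled <- withr::with_seed(s, sample(lib$label))
    sp <- split_library(lib, 90, seed = s, stratified = FALSE)
    tr_idx <- lib$id %in% sp$train_ids
    fm <- featurize_library(lib)
    m <- train_bp(fm$x[tr_idx, ], shuffled[tr_idx],
                  bp_config(hidden = 8, epochs = 150, patience = 150,
                            seed = s))
    mean(predict(m, fm$x[!tr_idx, ])$label == shuffled[!tr_idx])
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("models survive a JSON round-trip", {
  lib <- random_library(60, seed = 21)
  fm <- featurize_library(lib)
  m <- train_bp(fm, lib$label, bp_config(epochs = 50, seed = 21))
  f <- withr::local_tempfile(fileext = ".json")
  write_bp_model(m, f)
  m2 <- read_bp_model(f)
  expect_equal(predict(m2, fm), predict(m, fm))
})
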