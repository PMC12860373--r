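# Independent oracles used to pin expected values. Each is a deliberately
# naive, separate implementation of the quantity it checks.

# Mass-balance Franz-cell simulator: analyte mass enters the receiver at a
# random rate per interval; each sampling measures the concentration,
# removes an aliquot S and replaces it with fresh medium. Returns the
# measured concentration series and the true cumulative mass permeated per
# area, tracked by explicit bookkeeping.
simulate_franz <- function(n_samples, receiver_volume, area, aliquot,
                           seed = 1) {
  withr::with_seed(seed, {
    dm <- runif(n_samples, 0, 50)           # mass entering per interval (ug)
    conc <- numeric(n_samples)
    mass_in_receiver <- 0
    for (i in seq_len(n_samples)) {
      mass_in_receiver <- mass_in_receiver + dm[i]
      conc[i] <- mass_in_receiver / receiver_volume
      mass_in_receiver <- mass_in_receiver - conc[i] * aliquot
    }
    list(data = tibble::tibble(time_h = 2 * seq_len(n_samples),
                               conc_ug_ml = conc),
         truth_q = cumsum(dm) / area)
  })
}

# Best single-split Gini gain per feature, by exhaustive threshold scan.
gini_gain_per_feature <- function(x, y) {
  gini <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab)
    2 * p * (1 - p)
  }
  parent <- gini(y)
  apply(x, 2, function(v) {
    cuts <- sort(unique(v))
    if (length(cuts) < 2) return(0)
    thr <- (cuts[-1] + cuts[-length(cuts)]) / 2
    max(vapply(thr, function(t) {
      l <- y[v <= t]; r <- y[v > t]
      parent - (length(l) * gini(l) + length(r) * gini(r)) / length(y)
    }, numeric(1)))
  })
}

# Pocket perceptron: returns TRUE if it finds a perfect linear separator.
perceptron_separates <- function(x, y, max_iter = 5000) {
  x1 <- cbind(1, x)
  w <- rep(0, ncol(x1))
  yy <- ifelse(y == 1, 1, -1)
  for (it in seq_len(max_iter)) {
    pred <- sign(x1 %*% w)
    wrong <- which(pred != yy)
    if (!length(wrong)) return(TRUE)
    i <- wrong[1]
    w <- w + yy[i] * x1[i, ]
  }
  FALSE
}

# Central finite-difference gradient of the network loss.
fd_gradient <- function(weights, x, y, eps = 1e-6) {
  num <- weights
  for (part in c("W", "b")) {
    for (l in seq_along(weights[[part]])) {
      g <- weights[[part]][[l]]
      for (j in seq_along(g)) {
        wp <- weights; wp[[part]][[l]][j] <- wp[[part]][[l]][j] + eps
        wm <- weights; wm[[part]][[l]][j] <- wm[[part]][[l]][j] - eps
        g[j] <- (bp_loss_grad(wp, x, y)$loss -
                   bp_loss_grad(wm, x, y)$loss) / (2 * eps)
      }
      num[[part]][[l]] <- g
    }
  }
  num
}

# Relative error between analytic and finite-difference gradients, as the
# standard norm ratio ||g_an - g_fd|| / (||g_an|| + ||g_fd||).
grad_rel_error <- function(weights, x, y) {
  an <- bp_loss_grad(weights, x, y)$grad
  fd <- fd_gradient(weights, x, y)
  av <- unlist(an); fv <- unlist(fd)
  sqrt(sum((av - fv)^2)) / (sqrt(sum(av^2)) + sqrt(sum(fv^2)))
}

# Exhaustive-search oracle over a candidate pool, mirroring run_ga's
# returned-best rule: highest-fitness feasible candidate when any exists.
exhaustive_best_id <- function(pool, model, constraints) {
  feats <- model$scaling$spec
  raw <- as.matrix(tibble::as_tibble(pool)[, feats])
  f <- ga_fitness(raw, model, constraints)
  viol <- constraint_violation(raw, constraints)
  feas <- viol == 0
  if (any(feas)) pool$id[which(feas)[which.max(f[feas])]]
  else pool$id[which.max(f)]
}

random_library <- function(n, seed) {
  generate_library(generator_config(n = n, seed = seed))
}

# One shared classifier for the GA tests (memoized: training it once is
# enough for every search test).
.model_cache <- new.env(parent = emptyenv())
trained_model <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.model_cache[[key]])) {
    lib <- random_library(159, seed = seed)
    .model_cache[[key]] <- train_bp(featurize_library(lib), lib$label,
                                    bp_config(epochs = 600, seed = seed))
  }
  .model_cache[[key]]
}
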