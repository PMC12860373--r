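#' Random-forest configuration
#'
#' Hyperparameters for the feature-importance ranking stage. Defaults are
#' the conventional classification settings: 100 trees, unlimited depth,
#' `floor(sqrt(p))` candidate features per split, bootstrap resampling.
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth via node-size limit; `NULL` grows
#'   trees fully.
#' @param mtry Features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param bootstrap Sample with replacement per tree.
#' @param seed Integer seed pinning the forest.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 100L, max_depth = NULL, mtry = NULL,
                      bootstrap = TRUE, seed = 1L) {
  assert_that(is_count(n_trees) && n_trees >= 1, "n_trees must be >= 1",
              class = "coformerscout_argument_error")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 mtry = mtry, bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Rank features by random-forest importance
#'
#' Fits a classification random forest to the binary suitability labels and
#' returns mean-decrease-impurity (Gini) importances, normalized to sum to
#' one and sorted in descending order. Ties are broken by input column
#' order. Deterministic under the configured seed.
#'
#' @param x A `feature_matrix` (from [featurize_library()]) or numeric
#'   matrix.
#' @param y Binary labels (0/1), one per row of `x`.
#' @param config An [rf_config()].
#' @return A `feature_importance` tibble with columns `feature` and
#'   `importance`.
#' @examples
#' lib <- generate_library(generator_config(n = 100, seed = 5))
#' fm <- featurize_library(lib)
#' rank_features_rf(fm, lib$label, rf_config(seed = 5))
#' @export
rank_features_rf <- function(x, y, config = rf_config()) {
  xm <- if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
  y <- as.integer(y)
  assert_that(!anyNA(xm) && !anyNA(y), "missing values are not allowed",
              class = "coformerscout_validation_error")
  assert_that(length(unique(y)) >= 2,
              "labels contain a single class; importance is undefined",
              class = "coformerscout_degenerate_label_error")
  p <- ncol(xm)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  nodesize <- 1L
  maxnodes <- if (!is.null(config$max_depth)) 2L^config$max_depth else NULL
  fit <- withr::with_seed(config$seed,
    randomForest::randomForest(
      x = xm, y = factor(y, levels = c(0, 1)),
      ntree = config$n_trees, mtry = mtry, replace = config$bootstrap,
      nodesize = nodesize, maxnodes = maxnodes, importance = FALSE
    )
  )
  imp <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  imp_norm <- if (total > 0) imp / total else rep(1 / p, p)
  ord <- order(-imp_norm, seq_len(p))   # descending, ties by column order
  out <- tibble(feature = colnames(xm)[ord],
                importance = unname(imp_norm[ord]))
  structure(new_tibble(out, nrow = nrow(out),
                       class = "feature_importance",
                       config = config),
            class = c("feature_importance", class(tibble())))
}

#' @export
tidy.feature_importance <- function(x, ...) as_tibble(x)

#' Select the top-ranked features
#'
#' @param importance A `feature_importance` ranking.
#' @param k How many features to keep (`k <=` number of features).
#' @return Character vector of the first `k` feature names in importance
#'   order.
#' @export
select_top_features <- function(importance, k) {
  assert_that(is_count(k) && k <= nrow(importance),
              paste0("k must be an integer in [0, ", nrow(importance), "]"),
              class = "coformerscout_argument_error")
  head(importance$feature, k)
}

#' @export
autoplot.feature_importance <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                   y = .data$feature)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "normalized importance (mean decrease in impurity)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
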