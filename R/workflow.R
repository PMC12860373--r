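#' Persist a trained model as JSON
#'
#' Stores the weight matrices, bias vectors, normalization parameters and
#' training configuration in a plain JSON document.
#'
#' @param model A `bp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bp_model <- function(model, path) {
  doc <- list(
    layers = model$layers,
    weights = lapply(model$weights$W, function(w) unclass(w)),
    biases = model$weights$b,
    scaling = list(spec = model$scaling$spec,
                   center = as.list(model$scaling$center),
                   scale = as.list(model$scaling$scale),
                   k = model$scaling$k,
                   encode_seed = model$scaling$encode_seed),
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    loss_trace = model$loss_trace
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a model written by [write_bp_model()]
#' @param path Path to the JSON document.
#' @return A `bp_model`.
#' @export
read_bp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(doc$weights, function(w) as.matrix(w))
  b <- doc$biases
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  if (!is.list(b)) b <- list(b)
  cfg <- do.call(bp_config, doc$config[c("hidden", "learn_rate", "momentum",
                                         "epochs", "patience", "threshold",
                                         "seed")])
  structure(list(
    weights = list(W = W, b = b),
    config = cfg,
    scaling = list(spec = doc$scaling$spec,
                   center = setNames(unlist(doc$scaling$center),
                                     names(doc$scaling$center)),
                   scale = setNames(unlist(doc$scaling$scale),
                                    names(doc$scaling$scale)),
                   k = doc$scaling$k, encode_seed = doc$scaling$encode_seed),
    layers = doc$layers,
    loss_trace = doc$loss_trace,
    monitor_trace = doc$loss_trace,
    best_epoch = doc$best_epoch
  ), class = "bp_model")
}

#' Workflow configuration
#'
#' One config object drives the whole screen: load or generate a library,
#' featurize, rank features, split, train, evaluate and run the GA screen.
#' A single global `seed` is fanned out deterministically to every stage
#' (each stage's seed is derived from the global seed and the stage name),
#' so one number reproduces the entire run; nested configs passed
#' explicitly keep their own seeds.
#'
#' @param library_path Optional CSV path of an existing labeled library;
#'   when `NULL` the library is generated from `generator`.
#' @param generator A [generator_config()] (its seed is overridden by the
#'   fanned-out global seed unless `library_path` is set).
#' @param rank_features Features ranked by the random forest.
#' @param model_features Features the classifier is trained on (descriptor
#'   subset, so the trained model can drive the GA in either mode).
#' @param train_size,stratified Split parameters (see [split_library()]).
#' @param rf,bp,ga Stage configurations.
#' @param constraints A [constraint_set()] for the search.
#' @param pool_path Optional CSV path of a candidate pool; when `NULL` a
#'   pool of `pool_size` candidates is generated.
#' @param pool_size Generated pool size (default 1000).
#' @param ga_mode `"discrete"` or `"continuous"`.
#' @param seed Global seed.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(library_path = NULL,
                            generator = generator_config(),
                            rank_features = c("mw", "hbd", "tpsa",
                                              "tyr_inhib", "smiles_enc"),
                            model_features = c("mw", "hbd", "tpsa",
                                               "tyr_inhib"),
                            train_size = 120L, stratified = TRUE,
                            rf = rf_config(),
                            bp = bp_config(val_fraction = 0.2),
                            ga = ga_config(),
                            constraints = default_constraints(),
                            pool_path = NULL, pool_size = 1000L,
                            ga_mode = "discrete", seed = 1L) {
  structure(list(library_path = library_path, generator = generator,
                 rank_features = rank_features,
                 model_features = model_features,
                 train_size = as.integer(train_size),
                 stratified = isTRUE(stratified),
                 rf = rf, bp = bp, ga = ga, constraints = constraints,
                 pool_path = pool_path, pool_size = as.integer(pool_size),
                 ga_mode = ga_mode, seed = as.integer(seed)),
            class = "workflow_config")
}

workflow_stamp <- function(cfg) {
  list(config_hash = str_hash(paste(deparse(unclass(cfg)), collapse = "")),
       seed = cfg$seed)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full screening workflow
#'
#' Executes the stages in order — library, featurization, random-forest
#' importance ranking, train/test split, classifier training,
#' confusion-matrix evaluation, GA candidate search — writing one artifact
#' per stage into `out_dir` (each stamped with the config hash and global
#' seed) plus a human-readable `summary.txt`. Re-running with an identical
#' config reproduces identical artifacts. A failing stage aborts with the
#' stage name; artifacts of completed stages are preserved.
#'
#' @param cfg A [workflow_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and artifact `paths`.
#' @examples
#' \donttest{
#' cfg <- workflow_config(generator = generator_config(n = 80),
#'                        train_size = 60, pool_size = 100,
#'                        bp = bp_config(epochs = 200),
#'                        ga = ga_config(generations = 20), seed = 42)
#' res <- run_workflow(cfg, tempfile("screen"))
#' glance(res$confusion)
#' }
#' @export
run_workflow <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- workflow_stamp(cfg)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("workflow stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "coformerscout_stage_error", parent = e)
    })
  }

  lib <- stage("library", {
    if (!is.null(cfg$library_path)) {
      read_coformer_library(cfg$library_path)
    } else {
      gen <- cfg$generator
      gen$seed <- fan_seed(cfg$seed, "generate")
      generate_library(gen)
    }
  })
  paths$library <- file.path(out_dir, "library.csv")
  write_coformer_library(lib, paths$library)

  fm_all <- stage("featurize", {
    featurize_library(lib, cfg$rank_features,
                      encode_seed = fan_seed(cfg$seed, "encode") %% 100000L)
  })
  paths$features <- file.path(out_dir, "features.csv")
  readr::write_csv(tidy(fm_all), paths$features, progress = FALSE)

  importance <- stage("rank_features", {
    rf <- cfg$rf
    rf$seed <- fan_seed(cfg$seed, "rf")
    rank_features_rf(fm_all, lib$label, rf)
  })
  paths$importance <- file.path(out_dir, "importance.json")
  write_stage_json(c(stamp, list(importance = as_tibble(importance))),
                   paths$importance)

  split <- stage("split", {
    split_library(lib, cfg$train_size,
                  seed = fan_seed(cfg$seed, "split"),
                  stratified = cfg$stratified)
  })
  paths$split <- file.path(out_dir, "split.json")
  write_stage_json(c(stamp, list(
    train_size = length(split$train_ids),
    test_size = length(split$test_ids),
    stratified = split$stratified,
    train_ids = split$train_ids, test_ids = split$test_ids
  )), paths$split)

  model <- stage("train", {
    train_lib <- split_records(lib, split, "train")
    fm_train <- featurize_library(train_lib, cfg$model_features)
    bp <- cfg$bp
    bp$seed <- fan_seed(cfg$seed, "bp")
    train_bp(fm_train, train_lib$label, bp)
  })
  paths$model <- file.path(out_dir, "model.json")
  write_bp_model(model, paths$model)

  confusion <- stage("evaluate", {
    test_lib <- split_records(lib, split, "test")
    fm_test <- featurize_library(test_lib, cfg$model_features,
                                 scaling = NULL)
    evaluate_bp(model, fm_test, test_lib$label)
  })
  paths$confusion <- file.path(out_dir, "confusion.json")
  write_stage_json(c(stamp, as.list(glance(confusion))), paths$confusion)

  ga_res <- stage("screen", {
    pool <- if (!is.null(cfg$pool_path)) {
      read_coformer_library(cfg$pool_path)
    } else {
      gen <- cfg$generator
      gen$seed <- fan_seed(cfg$seed, "pool")
      generate_candidate_pool(gen, size = cfg$pool_size)
    }
    ga <- cfg$ga
    ga$seed <- fan_seed(cfg$seed, "ga")
    res <- run_ga(model, cfg$constraints, pool, ga, mode = cfg$ga_mode)
    res$pool_metadata <- library_metadata(pool)
    res
  })
  paths$ga_report <- file.path(out_dir, "ga_report.json")
  write_stage_json(c(stamp, list(
    mode = ga_res$mode,
    best_candidate = as.list(ga_res$best_candidate),
    best_fitness = ga_res$best$fitness,
    convergence_generation = if (is.na(ga_res$convergence)) NULL else
      ga_res$convergence,
    trace = ga_res$trace[, c("generation", "best", "mean")]
  )), paths$ga_report)

  g <- glance(confusion)
  paths$summary <- file.path(out_dir, "summary.txt")
  writeLines(c(
    sprintf("coformerscout workflow (seed %d, config hash %.0f)",
            cfg$seed, stamp$config_hash),
    sprintf("library: %d records (%d suitable)", nrow(lib),
            sum(lib$label == 1L, na.rm = TRUE)),
    sprintf("split: %d train / %d test", length(split$train_ids),
            length(split$test_ids)),
    sprintf("top feature: %s (importance %.3f)", importance$feature[1],
            importance$importance[1]),
    sprintf("test accuracy: %.1f%% (sens %.1f%%, spec %.1f%%)",
            g$accuracy, g$sensitivity, g$specificity),
    sprintf("GA best candidate: %s (fitness %.4f%s)",
            ga_res$best_candidate$id, ga_res$best$fitness,
            if (is.na(ga_res$convergence)) "" else
              sprintf(", converged at generation %d", ga_res$convergence))
  ), paths$summary)

  invisible(list(library = lib, features = fm_all,
                 importance = importance, split = split, model = model,
                 confusion = confusion, ga = ga_res, paths = paths))
}
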