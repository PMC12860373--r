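#' Genetic-algorithm configuration
#'
#' Settings for the elitist genetic-algorithm search that inverts the
#' trained classifier: tournament selection (size 3), crossover and
#' per-gene mutation at the configured rates, with the best individuals
#' carried unchanged into each generation so best-ever fitness is
#' non-decreasing. The 100-generation default is the search budget; the
#' plateau detector (see [detect_convergence()]) reports where the run
#' actually converged.
#'
#' @param pop_size Population size (>= 2, default 50).
#' @param crossover_rate Probability a selected pair is recombined
#'   (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param generations Search budget (default 100).
#' @param elitism Number of elites copied unchanged (default 2, must be
#'   < `pop_size`).
#' @param conv_window,conv_tol Plateau window (generations) and fitness
#'   tolerance used by [detect_convergence()].
#' @param unique_genotypes Diversity policy for discrete pools: a child
#'   that decodes to a candidate already scored earlier in the run (or
#'   duplicated within its generation) is replaced by a fresh uniform
#'   random chromosome, one resampling pass per generation; elites are
#'   exempt. On a finite pool this stops the search from re-scoring clones
#'   of the incumbent and spends the fixed evaluation budget on unseen
#'   candidates instead. Default `TRUE`; ignored in continuous mode,
#'   where exact duplicates have probability zero.
#' @param seed Integer seed; identical config + seed reproduces the run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 50L, crossover_rate = 0.8,
                      mutation_rate = 0.1, generations = 100L,
                      elitism = 2L, conv_window = 10L, conv_tol = 1e-4,
                      unique_genotypes = TRUE, seed = 1L) {
  assert_that(pop_size >= 2, "pop_size must be >= 2",
              class = "coformerscout_argument_error")
  assert_that(crossover_rate >= 0 && crossover_rate <= 1 &&
                mutation_rate >= 0 && mutation_rate <= 1,
              "rates must lie in [0, 1]",
              class = "coformerscout_argument_error")
  assert_that(elitism >= 0 && elitism < pop_size,
              "elitism must be < pop_size",
              class = "coformerscout_argument_error")
  structure(list(pop_size = as.integer(pop_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 conv_window = as.integer(conv_window),
                 conv_tol = conv_tol,
                 unique_genotypes = isTRUE(unique_genotypes),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Descriptor box constraints for the search
#'
#' Per-descriptor box bounds plus a penalty weight. Violations are
#' normalized by each bound's span (one-sided bounds use a unit span), so a
#' chromosome breaching one bound by the bound's full span loses exactly
#' `penalty_weight` fitness units.
#'
#' @param lower,upper Named numeric vectors of bounds over the model's
#'   descriptor features (use `-Inf`/`Inf` for open sides). Names must
#'   match feature names.
#' @param penalty_weight Penalty multiplier lambda (>= 0, default 1).
#' @return A `constraint_set`.
#' @examples
#' constraint_set(lower = c(mw = 75, hbd = 1, tpsa = 20, tyr_inhib = 0.5),
#'                upper = c(mw = 250, hbd = 4, tpsa = 90, tyr_inhib = 1))
#' @export
constraint_set <- function(lower, upper, penalty_weight = 1) {
  stopifnot(identical(names(lower), names(upper)))
  assert_that(all(lower <= upper), "every lower bound must be <= upper",
              class = "coformerscout_argument_error")
  assert_that(penalty_weight >= 0, "penalty_weight must be >= 0",
              class = "coformerscout_argument_error")
  structure(list(lower = lower, upper = upper,
                 penalty_weight = penalty_weight),
            class = "constraint_set")
}

#' Summed normalized constraint violations
#'
#' For each row, sums over all bounds the amount by which the value falls
#' outside the box, normalized by the bound's span (unit span for one-sided
#' bounds). Feasible rows score exactly zero.
#'
#' @param x_raw Matrix of raw descriptor rows with named columns.
#' @param constraints A [constraint_set()].
#' @return Numeric vector of violations, one per row.
#' @export
constraint_violation <- function(x_raw, constraints) {
  x_raw <- as.matrix(x_raw)
  feats <- names(constraints$lower)
  idx <- match(feats, colnames(x_raw))
  assert_that(!anyNA(idx), "constraint features missing from the matrix",
              class = "coformerscout_schema_error")
  span <- constraints$upper - constraints$lower
  span[!is.finite(span) | span == 0] <- 1
  viol <- numeric(nrow(x_raw))
  for (j in seq_along(feats)) {
    v <- x_raw[, idx[j]]
    below <- pmax(constraints$lower[[j]] - v, 0)
    above <- pmax(v - constraints$upper[[j]], 0)
    viol <- viol + (below + above) / span[[j]]
  }
  unname(viol)
}

#' Fitness of candidate descriptor vectors
#'
#' The search objective: predicted suitability probability minus
#' `penalty_weight` times the summed normalized constraint violations.
#' Feasible candidates score exactly their predicted probability.
#'
#' @param x_raw Matrix of raw descriptor vectors (columns named after the
#'   model's feature spec).
#' @param model A trained [train_bp()] model.
#' @param constraints A [constraint_set()], or `NULL` for no penalty.
#' @return Numeric fitness vector, one per row.
#' @export
ga_fitness <- function(x_raw, model, constraints = NULL) {
  prob <- predict(model, as.matrix(x_raw))$prob
  if (is.null(constraints)) return(prob)
  prob - constraints$penalty_weight * constraint_violation(x_raw, constraints)
}

# --- engine ----------------------------------------------------------------

#' Run the elitist genetic-algorithm engine
#'
#' Mode `"continuous"` searches a box in descriptor space: chromosomes are
#' descriptor vectors, recombined by blend (BLX-0.5) crossover and mutated
#' per-gene with Gaussian noise (sd = 10% of the gene's span), then
#' repaired onto the box. Mode `"discrete"` searches a candidate pool:
#' chromosomes are fixed-length bit-strings decoding to a pool index (so
#' one-point crossover and per-gene bit-flip mutation act on bits).
#'
#' The trace records, for generation 0 (initial population) through the
#' final generation, the best-ever fitness (non-decreasing by elitism), the
#' population mean and the best-ever chromosome.
#'
#' @param fitness A function. Continuous mode: takes a matrix of gene rows,
#'   returns one fitness per row. Discrete mode: takes a vector of pool
#'   indices, returns one fitness per index.
#' @param mode `"continuous"` or `"discrete"`.
#' @param lower,upper Box bounds (continuous mode).
#' @param pool_size Number of candidates (discrete mode).
#' @param config A [ga_config()].
#' @param feasible Optional function with the same signature as `fitness`
#'   returning `TRUE` for constraint-satisfying individuals. When any
#'   feasible individual is ever evaluated, the returned best is the best
#'   feasible one.
#' @param init Optional matrix of initial chromosomes (rows; bit rows in
#'   discrete mode), recycled or truncated to the population size. By
#'   default the initial population is drawn uniformly.
#' @return A `ga_result` with `best` (genes/index + fitness), `trace`
#'   (a tibble) and `convergence` (generation index or `NA`).
#' @export
ga_optimize <- function(fitness, mode = c("continuous", "discrete"),
                        lower = NULL, upper = NULL, pool_size = NULL,
                        config = ga_config(), feasible = NULL,
                        init = NULL) {
  mode <- match.arg(mode)
  if (mode == "continuous") {
    stopifnot(!is.null(lower), !is.null(upper), length(lower) == length(upper))
    d <- length(lower)
    span <- upper - lower
  } else {
    assert_that(!is.null(pool_size) && pool_size >= 1,
                "discrete mode needs a non-empty pool",
                class = "coformerscout_argument_error")
    n_bits <- max(1L, ceiling(log2(pool_size)))
    decode <- function(bits) {
      idx <- as.integer(bits %*% 2^(seq_len(n_bits) - 1))
      (idx %% pool_size) + 1L
    }
  }
  pop_n <- config$pop_size
  eval_fit <- function(genes) {
    if (mode == "continuous") fitness(genes) else fitness(decode(genes))
  }
  eval_feas <- function(genes) {
    if (is.null(feasible)) return(rep(TRUE, nrow(genes)))
    if (mode == "continuous") feasible(genes) else feasible(decode(genes))
  }
  seen <- if (mode == "discrete") rep(FALSE, pool_size) else NULL
  dedup <- function(genes, protect = 0L) {
    # one resampling pass: rows decoding to an already-scored candidate or
    # duplicated within the generation get a fresh uniform chromosome
    # (residual collisions are accepted; elites are protected)
    if (mode != "discrete" || !isTRUE(config$unique_genotypes)) return(genes)
    idx <- decode(genes)
    dup <- duplicated(idx) | seen[idx]
    if (protect > 0L) dup[seq_len(protect)] <- FALSE
    if (any(dup)) {
      genes[dup, ] <- matrix(sample(0:1, sum(dup) * n_bits, replace = TRUE),
                             nrow = sum(dup))
    }
    genes
  }
  mark_seen <- function(genes) {
    if (mode == "discrete") seen[decode(genes)] <<- TRUE
  }
  withr::with_seed(config$seed, {
    genes <- if (!is.null(init)) {
      init <- as.matrix(init)
      init[rep_len(seq_len(nrow(init)), pop_n), , drop = FALSE]
    } else if (mode == "continuous") {
      matrix(runif(pop_n * d, rep(lower, each = pop_n),
                   rep(upper, each = pop_n)), nrow = pop_n)
    } else {
      dedup(matrix(sample(0:1, pop_n * n_bits, replace = TRUE),
                   nrow = pop_n))
    }
    mark_seen(genes)
    fit <- eval_fit(genes)
    feas <- eval_feas(genes)
    best_i <- which.max(fit)
    best_ever <- list(genes = genes[best_i, ], fitness = fit[best_i])
    best_feas <- if (any(feas)) {
      fi <- which(feas)[which.max(fit[feas])]
      list(genes = genes[fi, ], fitness = fit[fi], feasible = TRUE)
    } else NULL
    trace_best <- best_ever$fitness
    trace_mean <- mean(fit)
    trace_genes <- list(best_ever$genes)
    tournament <- function() {
      cand <- sample.int(pop_n, 3L, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    for (gen in seq_len(config$generations)) {
      new_genes <- genes
      elite_idx <- order(-fit)[seq_len(config$elitism)]
      if (config$elitism > 0) {
        new_genes[seq_len(config$elitism), ] <- genes[elite_idx, ]
      }
      slot <- config$elitism + 1L
      while (slot <= pop_n) {
        p1 <- genes[tournament(), ]
        p2 <- genes[tournament(), ]
        if (runif(1) < config$crossover_rate) {
          if (mode == "continuous") {
            lo <- pmin(p1, p2); hi <- pmax(p1, p2); w <- hi - lo
            c1 <- runif(d, lo - 0.5 * w, hi + 0.5 * w)
            c2 <- runif(d, lo - 0.5 * w, hi + 0.5 * w)
          } else {
            cut <- sample.int(n_bits, 1L)
            c1 <- c(p1[seq_len(cut)], p2[-seq_len(cut)])[seq_len(n_bits)]
            c2 <- c(p2[seq_len(cut)], p1[-seq_len(cut)])[seq_len(n_bits)]
          }
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (slot > pop_n) break
          if (mode == "continuous") {
            hit <- runif(d) < config$mutation_rate
            if (any(hit)) {
              child[hit] <- child[hit] +
                rnorm(sum(hit), 0, 0.1 * span[hit])
            }
            child <- pmin(pmax(child, lower), upper)
          } else {
            hit <- runif(n_bits) < config$mutation_rate
            child[hit] <- 1 - child[hit]
          }
          new_genes[slot, ] <- child
          slot <- slot + 1L
        }
      }
      genes <- dedup(new_genes, protect = config$elitism)
      mark_seen(genes)
      fit <- eval_fit(genes)
      feas <- eval_feas(genes)
      gi <- which.max(fit)
      if (fit[gi] > best_ever$fitness) {
        best_ever <- list(genes = genes[gi, ], fitness = fit[gi])
      }
      if (any(feas)) {
        fi <- which(feas)[which.max(fit[feas])]
        if (is.null(best_feas) || fit[fi] > best_feas$fitness) {
          best_feas <- list(genes = genes[fi, ], fitness = fit[fi],
                            feasible = TRUE)
        }
      }
      trace_best <- c(trace_best, best_ever$fitness)
      trace_mean <- c(trace_mean, mean(fit))
      trace_genes <- c(trace_genes, list(best_ever$genes))
    }
    trace <- tibble(generation = seq_along(trace_best) - 1L,
                    best = trace_best, mean = trace_mean,
                    chromosome = trace_genes)
    returned <- best_feas %||% c(best_ever, list(feasible = FALSE))
    out <- list(best = returned, best_overall = best_ever,
                trace = trace, mode = mode, config = config)
    if (mode == "discrete") {
      out$best$index <- decode(matrix(out$best$genes, nrow = 1))
      out$best_overall$index <- decode(matrix(out$best_overall$genes,
                                              nrow = 1))
    }
    out$convergence <- detect_convergence(trace,
                                          window = config$conv_window,
                                          tol = config$conv_tol)
    structure(out, class = "ga_result")
  })
}

#' Screen candidates with the trained classifier and a genetic algorithm
#'
#' The inverse-design stage: maximizes [ga_fitness()] (suitability
#' probability minus constraint penalty) either directly over a discrete
#' candidate pool, or over the continuous descriptor box spanned by the
#' constraints, in which case the continuous optimum is mapped to the
#' nearest real pool candidate with [map_to_candidate()].
#'
#' @param model A trained [train_bp()] model (descriptor-only feature
#'   spec).
#' @param constraints A [constraint_set()] over the model's features.
#' @param pool A `coformer_library` of candidates (required for
#'   `mode = "discrete"`, optional in continuous mode).
#' @param config A [ga_config()].
#' @param mode `"discrete"` (default when a pool is given) or
#'   `"continuous"`.
#' @return A `ga_result`; when a pool is given it additionally carries
#'   `best_candidate`, the winning `coformer_library` record.
#' @examples
#' lib <- generate_library(generator_config(n = 159, seed = 4))
#' fm <- featurize_library(lib)
#' model <- train_bp(fm, lib$label, bp_config(epochs = 300, seed = 4))
#' pool <- generate_candidate_pool(generator_config(seed = 4), size = 200)
#' res <- run_ga(model, default_constraints(), pool,
#'               ga_config(generations = 30, seed = 4))
#' res$best_candidate$id
#' @export
run_ga <- function(model, constraints, pool = NULL, config = ga_config(),
                   mode = NULL) {
  feats <- model$scaling$spec
  assert_that(all(feats %in% c("mw", "hbd", "tpsa", "tyr_inhib")),
              "run_ga requires a descriptor-only model feature spec",
              class = "coformerscout_schema_error")
  mode <- mode %||% if (is.null(pool)) "continuous" else "discrete"
  if (!is.null(pool)) {
    validate_coformer_library(pool)
    assert_that(nrow(pool) > 0, "candidate pool is empty",
                class = "coformerscout_argument_error")
    pool_raw <- as.matrix(as_tibble(pool)[, feats])
  }
  if (mode == "discrete") {
    assert_that(!is.null(pool), "discrete mode requires a candidate pool",
                class = "coformerscout_argument_error")
    fit_all <- ga_fitness(pool_raw, model, constraints)
    feas_all <- constraint_violation(pool_raw, constraints) == 0
    res <- ga_optimize(function(idx) fit_all[idx], mode = "discrete",
                       pool_size = nrow(pool), config = config,
                       feasible = function(idx) feas_all[idx])
    res$best_candidate <- as_tibble(pool)[res$best$index, ]
  } else {
    lower <- constraints$lower[feats]
    upper <- constraints$upper[feats]
    assert_that(all(is.finite(lower)) && all(is.finite(upper)),
                "continuous mode requires finite bounds on every feature",
                class = "coformerscout_argument_error")
    fit_fn <- function(genes) {
      colnames(genes) <- feats
      ga_fitness(genes, model, constraints)
    }
    res <- ga_optimize(fit_fn, mode = "continuous", lower = lower,
                       upper = upper, config = config,
                       feasible = function(genes) {
                         colnames(genes) <- feats
                         constraint_violation(genes, constraints) == 0
                       })
    names(res$best$genes) <- feats
    if (!is.null(pool)) {
      res$best_candidate <- map_to_candidate(res$best$genes, pool, model)
    }
  }
  res$model_features <- feats
  res
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %s mode, %d generations, best fitness %.4f",
              x$mode, max(x$trace$generation), x$best$fitness))
  if (!is.na(x$convergence)) {
    cat(sprintf(", converged at generation %d", x$convergence))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) x$trace[, c("generation", "best", "mean")]

#' @export
glance.ga_result <- function(x, ...) {
  tibble(mode = x$mode, generations = max(x$trace$generation),
         best_fitness = x$best$fitness, feasible = isTRUE(x$best$feasible),
         convergence_generation = x$convergence)
}

#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                        y = .data$fitness,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness") +
    ggplot2::theme_minimal()
  if (!is.na(object$convergence)) {
    p <- p + ggplot2::geom_vline(xintercept = object$convergence,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Detect the convergence generation of a fitness trace
#'
#' Returns the first generation `g` such that the best fitness varies by at
#' most `tol` over the `window` generations starting at `g`, i.e. the start
#' of the first plateau; `NA` if the trace never plateaus. Generation 0 is
#' the initial population.
#'
#' @param trace A `ga_result` or its trace tibble (column `best`).
#' @param window Plateau length in generations.
#' @param tol Maximum best-fitness variation within the plateau.
#' @return Integer generation index, or `NA` if no plateau is found.
#' @export
detect_convergence <- function(trace, window = 10L, tol = 1e-4) {
  if (inherits(trace, "ga_result")) trace <- trace$trace
  best <- trace$best
  n <- length(best)
  assert_that(n >= 1, "trace is empty",
              class = "coformerscout_argument_error")
  assert_that(window <= n, "window exceeds trace length",
              class = "coformerscout_argument_error")
  for (g in seq_len(n - window + 1)) {
    w <- best[g:(g + window - 1)]
    if (max(w) - min(w) <= tol) return(trace$generation[g])
  }
  NA_integer_
}

#' Map a continuous descriptor optimum to a real candidate
#'
#' Finds the pool record nearest to a descriptor vector by Euclidean
#' distance in the model's normalized feature space; ties are broken by the
#' lexicographically smallest id. This names a real molecule for a
#' continuous-search optimum.
#'
#' @param vector Named raw descriptor vector in the model's feature order.
#' @param pool A non-empty `coformer_library` with those descriptors.
#' @param model The trained model whose stored normalization defines the
#'   feature space.
#' @return The nearest record as a one-row tibble.
#' @export
map_to_candidate <- function(vector, pool, model) {
  validate_coformer_library(pool)
  assert_that(nrow(pool) > 0, "candidate pool is empty",
              class = "coformerscout_argument_error")
  feats <- model$scaling$spec
  pool_raw <- as.matrix(as_tibble(pool)[, feats])
  q <- matrix(as.numeric(vector[feats]), nrow = 1,
              dimnames = list(NULL, feats))
  pn <- model_input(model, pool_raw)
  qn <- model_input(model, q)
  dist2 <- rowSums(sweep(pn, 2, as.numeric(qn))^2)
  ord <- order(dist2, pool$id)
  as_tibble(pool)[ord[1], ]
}
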