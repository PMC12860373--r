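test_that("fitness is probability minus the normalized penalty", {
  model <- trained_model()
  cons <- default_constraints()
  feats <- c("mw", "hbd", "tpsa", "tyr_inhib")
  inside <- matrix(c(150, 2, 60, 0.8), 1, dimnames = list(NULL, feats))
  expect_identical(ga_fitness(inside, model, cons),
                   predict(model, inside)$prob)
  # breach one bound by its full span: fitness drops by exactly lambda
  outside <- inside
  outside[, "mw"] <- 250 + (250 - 75)
  expect_equal(ga_fitness(outside, model, cons),
               predict(model, outside)$prob - 1)
  # lambda = 0 switches the penalty off entirely
  cons0 <- default_constraints(penalty_weight = 0)
  withr::with_seed(3, rand <- matrix(
    c(runif(100, 0, 500), sample(0:8, 100, TRUE), runif(100, 0, 200),
      runif(100)), 100, dimnames = list(NULL, feats)))
  expect_identical(ga_fitness(rand, model, cons0),
                   predict(model, rand)$prob)
})

test_that("elitism preserves a planted optimum under frozen operators", {
  pool_size <- 16L
  fit_lookup <- c(5, seq_len(pool_size - 1))  # candidate 1 is the optimum
  cfg <- ga_config(pop_size = 8, crossover_rate = 0, mutation_rate = 0,
                   generations = 20, unique_genotypes = FALSE, seed = 2)
  init <- matrix(0L, 8, 4)   # all chromosomes decode to index 1
  res <- ga_optimize(function(i) fit_lookup[i], mode = "discrete",
                     pool_size = pool_size, config = cfg, init = init)
  expect_identical(res$best$index, 1L)
  expect_true(all(res$trace$best == 5))
})

test_that("best-ever fitness is non-decreasing for every seed", {
  model <- trained_model()
  cons <- default_constraints()
  for (s in 1:5) {
    pool <- generate_candidate_pool(generator_config(seed = s), 200)
    res <- run_ga(model, cons, pool, ga_config(generations = 40, seed = s))
    expect_false(is.unsorted(res$trace$best))
  }
})

test_that("the discrete search matches exhaustive search on small pools", {
  model <- trained_model()
  cons <- default_constraints()
  hits <- vapply(1:5, function(s) {
    pool <- generate_candidate_pool(generator_config(seed = s), 300)
    res <- run_ga(model, cons, pool, ga_config(seed = s))
    res$best_candidate$id == exhaustive_best_id(pool, model, cons)
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("identical config and seed reproduce the trace exactly", {
  model <- trained_model()
  cons <- default_constraints()
  pool <- generate_candidate_pool(generator_config(seed = 9), 150)
  a <- run_ga(model, cons, pool, ga_config(generations = 25, seed = 12))
  b <- run_ga(model, cons, pool, ga_config(generations = 25, seed = 12))
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_candidate, b$best_candidate)
})

test_that("continuous search recovers a concave quadratic argmax", {
  argmax <- c(0.3, -0.5, 0.7)
  for (s in 1:3) {
    res <- ga_optimize(function(g) -colSums((t(g) - argmax)^2),
                       mode = "continuous",
                       lower = rep(-1, 3), upper = rep(1, 3),
                       config = ga_config(seed = s))
    expect_true(all(abs(res$best$genes - argmax) <= 0.05 * 2))
  }
})

test_that("convergence detection finds the first plateau", {
  flat <- tibble::tibble(generation = 0:30, best = rep(1, 31))
  expect_identical(detect_convergence(flat, window = 10), 0L)
  rising <- tibble::tibble(generation = 0:30, best = seq(0, 3, 0.1))
  expect_identical(detect_convergence(rising, window = 10, tol = 1e-4),
                   NA_integer_)
  mixed <- tibble::tibble(generation = 0:99,
                          best = c(seq_len(60) / 10, rep(6.1, 40)))
  expect_identical(detect_convergence(mixed, window = 10, tol = 1e-4), 60L)
  expect_error(detect_convergence(flat, window = 40),
               class = "coformerscout_argument_error")
})

test_that("continuous optima map to the nearest real candidate", {
  model <- trained_model()
  pool <- generate_candidate_pool(generator_config(seed = 4), 500)
  feats <- c("mw", "hbd", "tpsa", "tyr_inhib")
  raw <- as.matrix(tibble::as_tibble(pool)[, feats])
  # a pool record's own descriptors map to that record
  expect_identical(map_to_candidate(raw[57, ], pool, model)$id, pool$id[57])
  # agreement with a brute-force nearest-neighbour scan
  pn <- coformerscout:::model_input(model, raw)
  withr::with_seed(8, queries <- sample.int(nrow(pool), 50))
  for (q in queries) {
    jitter <- raw[q, ] * (1 + 1e-4)
    got <- map_to_candidate(jitter, pool, model)$id
    qn <- coformerscout:::model_input(model, matrix(jitter, 1,
                                                    dimnames = list(NULL, feats)))
    d2 <- rowSums(sweep(pn, 2, as.numeric(qn))^2)
    expect_identical(got, pool$id[order(d2, pool$id)[1]])
  }
  # exact ties break toward the lexicographically smaller id
  two <- coformer_library(tibble::tibble(
    id = c("b", "a"), smiles = "C", mw = c(100, 100), hbd = c(2, 2),
    tpsa = c(50, 50), tyr_inhib = c(0.5, 0.5)))
  expect_identical(map_to_candidate(c(mw = 100, hbd = 2, tpsa = 50,
                                      tyr_inhib = 0.5), two, model)$id, "a")
})

test_that("empty pools and bad configs are rejected", {
  model <- trained_model()
  expect_error(run_ga(model, default_constraints(), pool = NULL,
                      config = ga_config(), mode = "discrete"),
               class = "coformerscout_argument_error")
  expect_error(ga_config(pop_size = 1), class = "coformerscout_argument_error")
  expect_error(ga_config(elitism = 50), class = "coformerscout_argument_error")
  expect_error(constraint_set(lower = c(mw = 10), upper = c(mw = 5)),
               class = "coformerscout_argument_error")
})
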