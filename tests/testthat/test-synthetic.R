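test_that("with zero noise every label equals the planted rule", {
  cfg <- generator_config(n = 200, noise = 0, seed = 31)
  lib <- generate_library(cfg)
  truth <- planted_rule(lib, cfg$rule)
  expect_identical(lib$label, truth$label)
})

test_that("the empirical flip rate matches the configured noise", {
  cfg <- generator_config(n = 5000, noise = 0.1, seed = 17)
  lib <- generate_library(cfg)
  truth <- planted_rule(lib, cfg$rule)
  flip <- mean(lib$label != truth$label)
  expect_lte(abs(flip - 0.1), 0.01)
})

test_that("the rule uses closed bounds and fails single violations", {
  rule <- planted_rule_spec()
  boundary <- tibble::tibble(mw = rule$mw_cap, hbd = rule$hbd_range[1],
                             tpsa = rule$tpsa_range[2],
                             tyr_inhib = rule$tyr_min)
  expect_identical(planted_rule(boundary, rule)$label, 1L)
  for (bad in list(c("mw", rule$mw_cap + 1),
                   c("hbd", rule$hbd_range[2] + 1),
                   c("tpsa", rule$tpsa_range[1] - 1),
                   c("tyr_inhib", rule$tyr_min - 0.01))) {
    rec <- boundary
    rec[[bad[1]]] <- as.numeric(bad[2])
    expect_identical(planted_rule(rec, rule)$label, 0L)
  }
  expect_error(planted_rule(tibble::tibble(mw = 1, hbd = 1, tpsa = NA,
                                           tyr_inhib = 1), rule),
               class = "coformerscout_data_error")
})

test_that("rule scores order candidates like a by-hand margin computation", {
  rule <- planted_rule_spec()
  lib <- random_library(100, seed = 23)
  score <- planted_rule(lib, rule)$score
  by_hand <- vapply(seq_len(nrow(lib)), function(i) {
    min(lib$hbd[i] - rule$hbd_range[1], rule$hbd_range[2] - lib$hbd[i]) /
      (diff(rule$hbd_range) + 2) +
      min(lib$tpsa[i] - rule$tpsa_range[1],
          rule$tpsa_range[2] - lib$tpsa[i]) / 150 +
      (rule$mw_cap - lib$mw[i]) / 325 +
      (lib$tyr_inhib[i] - rule$tyr_min)
  }, numeric(1))
  expect_equal(order(score), order(by_hand))
  expect_equal(score, by_hand, tolerance = 1e-12)
})

test_that("candidate pools contain a unique planted optimum", {
  for (s in 1:3) {
    cfg <- generator_config(seed = s)
    pool <- generate_candidate_pool(cfg, 500)
    expect_identical(nrow(pool), 500L)
    expect_true(all(is.na(pool$label)))
    sc <- planted_rule(pool, cfg$rule)$score
    opt_id <- library_metadata(pool)$optimum_id
    expect_identical(pool$id[which.max(sc)], opt_id)
    # strict margin: nobody else comes within the configured gap
    expect_gte(max(sc) - max(sc[pool$id != opt_id]), cfg$optimum_margin)
  }
  one <- generate_candidate_pool(generator_config(seed = 5), 1)
  expect_identical(nrow(one), 1L)
  expect_equal(one$mw, 157.21)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_library(generator_config(n = 50, seed = 77))
  b <- generate_library(generator_config(n = 50, seed = 77))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  pa <- generate_candidate_pool(generator_config(seed = 77), 100)
  pb <- generate_candidate_pool(generator_config(seed = 77), 100)
  expect_identical(tibble::as_tibble(pa), tibble::as_tibble(pb))
})

test_that("the planted rule is learnable from noiseless libraries", {
  accs <- vapply(1:10, function(s) {
    lib <- generate_library(generator_config(n = 1000, noise = 0, seed = s))
    sp <- split_library(lib, 750, seed = s)
    tr <- split_records(lib, sp, "train")
    te <- split_records(lib, sp, "test")
    m <- train_bp(featurize_library(tr), tr$label,
                  bp_config(epochs = 800, patience = 200, seed = s))
    mean(predict(m, featurize_library(te))$label == te$label)
  }, numeric(1))
  expect_gte(sum(accs >= 0.95), 9L)
})
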