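test_that("CSV round-trip preserves libraries exactly", {
  for (s in 1:20) {
    lib <- random_library(n = sample(3:30, 1), seed = s)
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_coformer_library(lib, f1)
    back <- read_coformer_library(f1)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(lib),
                 ignore_attr = TRUE)
    write_coformer_library(back, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("header-only files give an empty library", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles,mw,hbd,tpsa,tyr_inhib,label", f)
  lib <- read_coformer_library(f)
  expect_s3_class(lib, "coformer_library")
  expect_identical(nrow(lib), 0L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_coformer_library(lib, out)
  expect_length(readLines(out), 1L)
})

test_that("malformed rows and columns are rejected with diagnostics", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,label", "a,CCO,1", "b,CO,2"), f)
  expect_error(read_coformer_library(f), "row",
               class = "coformerscout_validation_error")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,label", "CCO,1"), f2)
  expect_error(read_coformer_library(f2), "id",
               class = "coformerscout_format_error")
  expect_error(
    coformer_library(tibble::tibble(id = c("a", "a"),
                                    smiles = c("C", "C"))),
    "duplicate id", class = "coformerscout_validation_error")
  expect_error(
    coformer_library(tibble::tibble(id = "a", smiles = "C", hbd = 1.5)),
    "hbd", class = "coformerscout_validation_error")
  expect_error(
    coformer_library(tibble::tibble(id = "a", smiles = "C",
                                    tyr_inhib = 1.2)),
    "tyr_inhib", class = "coformerscout_validation_error")
})

test_that("a 159-record library splits into 120 train and 39 test", {
  lib <- random_library(159, seed = 11)
  sp <- split_library(lib, train_size = 120, seed = 5)
  expect_length(sp$train_ids, 120L)
  expect_length(sp$test_ids, 39L)
})

test_that("splits partition the library for any size", {
  lib <- random_library(40, seed = 2)
  for (k in c(0L, 1L, 17L, 40L)) {
    for (strat in c(TRUE, FALSE)) {
      sp <- split_library(lib, k, seed = 9, stratified = strat)
      expect_length(sp$train_ids, k)
      expect_length(sp$test_ids, 40L - k)
      expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
      expect_setequal(c(sp$train_ids, sp$test_ids), lib$id)
    }
  }
  expect_error(split_library(lib, 41), class = "coformerscout_argument_error")
})

test_that("splits are seed-deterministic and seed-sensitive", {
  lib <- random_library(60, seed = 3)
  a <- split_library(lib, 45, seed = 7)
  b <- split_library(lib, 45, seed = 7)
  expect_identical(a$train_ids, b$train_ids)
  distinct <- unique(lapply(1:10, function(s) {
    split_library(lib, 45, seed = s)$train_ids
  }))
  expect_gt(length(distinct), 5L)
})

test_that("stratified splits preserve class proportions", {
  lib <- random_library(200, seed = 8)
  k <- 150L
  sp <- split_library(lib, k, seed = 4, stratified = TRUE)
  train <- split_records(lib, sp, "train")
  lib_frac <- mean(lib$label)
  expect_lte(abs(mean(train$label) - lib_frac), 1 / k + 1e-12)
  # unlabeled records cannot be stratified
  pool <- generate_candidate_pool(generator_config(seed = 1), 10)
  expect_error(split_library(pool, 5, stratified = TRUE),
               class = "coformerscout_validation_error")
})
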