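test_that("single-sample permeation reproduces the hand-worked value", {
  out <- cumulative_permeation(
    tibble::tibble(time_h = 2, conc_ug_ml = 2),
    receiver_volume = 6, area = 1.77
  )
  expect_equal(out$q_s, 2 * 6 / 1.77)          # 6.78 ug/cm^2
  zero <- cumulative_permeation(
    tibble::tibble(time_h = c(2, 4, 6), conc_ug_ml = c(0, 0, 0)),
    receiver_volume = 6, area = 1.77
  )
  expect_identical(zero$q_s, c(0, 0, 0))
})

test_that("the correction term recovers a mass-balance simulator's truth", {
  for (s in 1:20) {
    withr::with_seed(s, {
      v <- runif(1, 4, 12); a <- runif(1, 0.5, 4)
      sal <- runif(1, 0.2, min(2, v))
      n <- sample(4:15, 1)
    })
    sim <- simulate_franz(n, v, a, sal, seed = s)
    q <- cumulative_permeation(sim$data, v, a, sal)$q_s
    expect_equal(q, sim$truth_q, tolerance = 1e-12)
    expect_false(is.unsorted(q))
  }
})

test_that("permeation is exactly scale-equivariant in the diffusion area", {
  sim <- simulate_franz(8, 6, 1.77, 1, seed = 3)
  q1 <- cumulative_permeation(sim$data, 6, 1.77, 1)$q_s
  q2 <- cumulative_permeation(sim$data, 6, 1.77 / 2, 1)$q_s
  expect_identical(q2, q1 * 2)
})

test_that("invalid experiments are rejected with the offending field", {
  good <- tibble::tibble(time_h = c(2, 4), conc_ug_ml = c(1, 2))
  expect_error(cumulative_permeation(good[c(2, 1), ], 6, 1.77),
               "increasing", class = "coformerscout_validation_error")
  expect_error(cumulative_permeation(
    tibble::tibble(time_h = 2, conc_ug_ml = -1), 6, 1.77),
    "non-negative", class = "coformerscout_validation_error")
  expect_error(cumulative_permeation(good, -6, 1.77),
               "receiver_volume", class = "coformerscout_validation_error")
  expect_error(cumulative_permeation(good, 6, 1.77, aliquot_volume = 7),
               "aliquot", class = "coformerscout_validation_error")
})

test_that("viability identities and the worked mid-case hold", {
  expect_equal(viability(1.0, 1.0, 0.1), 100)
  expect_equal(viability(0.1, 1.0, 0.1), 0)
  expect_equal(viability(0.6, 1.0, 0.1), 100 * 0.5 / 0.9)  # 55.6%
  expect_warning(viability(1.2, 1.0, 0.1), "unclipped")
  expect_error(viability(0.5, 0.1, 0.1),
               class = "coformerscout_assay_error")
})

test_that("IC estimation hits exact points and interpolates in log space", {
  dr <- tibble::tibble(concentration = c(0.01, 0.1, 1),
                       viability = c(90, 60, 40))
  expect_identical(estimate_ic(dr, 10), 0.01)     # exact boundary hit
  expect_equal(estimate_ic(dr, 50), 10^(-1 + 0.5), tolerance = 1e-12)
  expect_equal(estimate_ic(dr, 50, interpolation = "linear"),
               0.1 + 0.5 * 0.9, tolerance = 1e-12)
  exact <- tibble::tibble(concentration = c(0.1, 1), viability = c(50, 20))
  expect_identical(estimate_ic(exact, 50), 0.1)
  expect_error(estimate_ic(tibble::tibble(concentration = c(0.1, 1),
                                          viability = c(95, 92)), 50),
               class = "coformerscout_not_estimable_error")
  expect_error(estimate_ic(dr[c(2, 1, 3), ], 50),
               class = "coformerscout_validation_error")
})

test_that("IC10 never exceeds IC50 on strictly decreasing curves", {
  for (s in 1:10) {
    withr::with_seed(s, {
      conc <- 10^seq(-3, 1, length.out = 8)
      viab <- sort(runif(8, 5, 98), decreasing = TRUE)
    })
    dr <- tibble::tibble(concentration = conc, viability = viab)
    ic10 <- tryCatch(estimate_ic(dr, 10), error = function(e) NA)
    ic50 <- tryCatch(estimate_ic(dr, 50), error = function(e) NA)
    if (!is.na(ic10) && !is.na(ic50)) expect_lte(ic10, ic50)
  }
})
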