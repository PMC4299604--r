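test_that("gate_output matches direct evaluation, clamps at y_max, and scales as a power law", {
  g <- gate_response(y_max = 1000, k = 100, b = 1)
  expect_identical(gate_output(g, 0), 1000)
  expect_equal(gate_output(g, 10), 10)
  expect_equal(fold_repression(g, 10), 100)
  expect_identical(fold_repression(g, 0), 1)
  # doubling x multiplies output by 2^-b in the unclamped region
  g2 <- gate_response(1040, 5000, 0.7)
  xs <- log_spaced(10, 1e4, 20)
  expect_equal(gate_output(g2, 2 * xs) / gate_output(g2, xs),
               rep(2^-0.7, 20), tolerance = 1e-12)
})

test_that("gate_output is monotone non-increasing and bounded by (0, y_max] over random parameters", {
  withr::with_seed(31, {
    for (i in 1:50) {
      g <- gate_response(runif(1, 10, 2000), runif(1, 1, 1e5), runif(1, 0, 1.5))
      xs <- sort(c(0, log_spaced(1e-3, 1e6, 60)))
      y <- gate_output(g, xs)
      expect_true(all(diff(y) <= 1e-12))
      expect_true(all(y > 0 & y <= g$y_max + 1e-12))
      expect_true(all(diff(fold_repression(g, xs)) >= -1e-12))
    }
  })
})

test_that("power-law fits recover noiseless parameters to machine precision", {
  truth <- gate_response(1040, 100, 0.8)
  d <- synth_gate_data(truth, log_spaced(1, 1000, 24), noise_sigma = 0, seed = 1)
  f <- suppressWarnings(fit_power_law(d, y_max = 1040))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "b"], 0.8,
               tolerance = 1e-9)
  expect_equal(f$gate$k, 100, tolerance = 1e-6)
  expect_gt(f$r.squared, 1 - 1e-12)

  # flat data: slope estimate within its own confidence interval of 0
  flat <- tibble::tibble(input = log_spaced(1, 1000, 24),
                         output = 500 * exp(withr::with_seed(2, rnorm(24, 0, 0.05))))
  ff <- fit_power_law(flat, y_max = 5000)
  bb <- ff$coefficients[ff$coefficients$term == "b", ]
  expect_lt(abs(bb$estimate), 2.1 * bb$std.error)
})

test_that("saturated points are excluded and preconditions enforced", {
  truth <- gate_response(1000, 800, 0.9)
  x <- log_spaced(0.01, 1000, 24)
  d <- synth_gate_data(truth, x, 0, seed = 3)
  f <- suppressWarnings(fit_power_law(d, y_max = 1000))
  expect_identical(f$n_used + f$n_excluded, 24L)
  expect_gt(f$n_excluded, 0)
  expect_equal(f$coefficients$estimate[2], 0.9, tolerance = 1e-9)
  expect_error(fit_power_law(d[1:2, ], 1000), class = "crisprgates_insufficient_data")
  expect_error(fit_power_law(tibble::tibble(input = c(-1, 1, 2), output = c(1, 2, 3)), 10),
               class = "crisprgates_invalid_data")
})

test_that("exponent recovery under multiplicative noise is nearly unbiased (simulation)", {
  # scaled-down version of the 1,000-replicate study in the acceptance suite
  b_true <- 0.7
  truth <- gate_response(1040, 400, b_true)
  est <- withr::with_seed(44, vapply(1:150, function(i) {
    d <- synth_gate_data(truth, log_spaced(1, 1000, 24), 0.1, seed = sample.int(1e7, 1))
    fit_power_law(d, 1040)$coefficients$estimate[2]
  }, numeric(1)))
  expect_lt(abs(mean(est) - b_true), 0.02)
  expect_lt(sd(est), 0.06)
})

test_that("Hill fits recover exact parameters, evaluate correctly, and flag saturated designs", {
  m <- inducer_model(10, 1000, 0.1, 1.5)
  doses <- inducer_doses()
  ara <- doses$dose[doses$inducer == "arabinose" & doses$assay == "graded_circuit"]
  expect_identical(length(ara), 11L)
  d <- tibble::tibble(concentration = ara, output = inducer_to_activity(m, ara))
  f <- fit_hill(d)
  expect_equal(f$model$K, 0.1, tolerance = 1e-6)
  expect_equal(f$model$n, 1.5, tolerance = 1e-6)
  expect_equal(f$model$y_min, 10, tolerance = 1e-4)
  expect_equal(f$model$y_max, 1000, tolerance = 1e-6)
  expect_false(f$ill_conditioned)

  expect_identical(inducer_to_activity(m, 0), 10)
  expect_equal(inducer_to_activity(m, 0.1), (10 + 1000) / 2)
  act <- inducer_to_activity(m, sort(ara))
  expect_true(all(diff(act) > 0))

  # saturating-only doses: K unidentifiable
  sat <- tibble::tibble(concentration = c(50, 100, 200, 400, 800),
                        output = inducer_to_activity(m, c(50, 100, 200, 400, 800)) *
                          exp(withr::with_seed(8, rnorm(5, 0, 0.02))))
  fs <- fit_hill(sat)
  expect_true(fs$ill_conditioned)
  expect_error(fit_hill(d[1:3, ]), class = "crisprgates_insufficient_data")
})

test_that("noisy Hill recovery at the 11-dose ladder (simulation-calibrated tolerance)", {
  m <- inducer_model(20, 800, 0.05, 1.2)
  ara <- inducer_doses() |>
    dplyr::filter(inducer == "arabinose", assay == "graded_circuit") |>
    dplyr::pull(dose)
  Ks <- withr::with_seed(55, vapply(1:100, function(i) {
    d <- tibble::tibble(concentration = ara,
                        output = inducer_to_activity(m, ara) * exp(rnorm(11, 0, 0.05)))
    fit_hill(d)$model$K
  }, numeric(1)))
  expect_lt(abs(median(Ks) - 0.05) / 0.05, 0.15)
})

test_that("tidy and glance return the broom-shaped summaries", {
  d <- synth_gate_data(gate_response(1040, 100, 0.8), log_spaced(1, 1000, 24), 0.05, 9)
  f <- fit_power_law(d, 1040)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_identical(td$term, c("k", "b"))
  gl <- glance(f)
  expect_named(gl, c("r.squared", "sigma", "nobs", "n_excluded", "y_max"))
})
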