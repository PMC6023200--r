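test_that("the 4PL curve has the defining midpoint and asymptotes", {
  expect_equal(four_pl(0.4, 0, 100, 0.4, 1), 50)
  expect_equal(four_pl(1e-9, 5, 95, 0.4, 1), 5, tolerance = 1e-6)
  expect_equal(four_pl(1e9, 5, 95, 0.4, 2), 95, tolerance = 1e-6)
})

test_that("noiseless series are recovered essentially exactly", {
  doses <- dose_series_3fold(100, 10)
  for (hill in c(0.5, 1, 2)) {
    for (ec50 in c(0.05, 0.4, 5, 40)) {
      ds <- generate_dose_series(ec50, hill, top = 100, bottom = 0,
                                 doses = doses, noise_sd = 0)
      fit <- fit_4pl(ds$dose, ds$response)
      expect_true(fit$converged)
      expect_equal(fit$censoring, "none")
      expect_equal(fit$ec50, ec50, tolerance = 0.01)
      expect_equal(fit$hill, hill, tolerance = 0.02)
      expect_lt(fit$residual_sd, 1e-4)
    }
  }
})

test_that("falling (inhibition) curves fit with detected orientation", {
  doses <- dose_series_3fold(100, 10)
  ds <- generate_dose_series(ec50 = 8, hill = 1.5, top = 5, bottom = 100,
                             doses = doses, noise_sd = 0)
  fit <- fit_4pl(ds$dose, ds$response)
  expect_equal(fit$direction, "decreasing")
  expect_equal(fit$ec50, 8, tolerance = 0.01)
  expect_lte(fit$bottom, fit$top)
})

test_that("flat or non-informative series are censored, never silent numbers", {
  doses <- dose_series_3fold(100, 10)
  fit <- fit_4pl(doses, rep(50, 10))
  expect_false(fit$converged)
  expect_equal(fit$censoring, "low_span")
  expect_true(is.na(fit$ec50))

  # midpoint beyond the tested range is flagged
  ds <- generate_dose_series(ec50 = 5000, hill = 1, top = 100, bottom = 0,
                             doses = doses, noise_sd = 2, seed = 2)
  fit2 <- fit_4pl(ds$dose, ds$response, control_range = 10)
  if (fit2$converged && !is.na(fit2$ec50) && fit2$ec50 > 100)
    expect_equal(fit2$censoring, "above_top_dose")

  expect_error(fit_4pl(c(1, 3, 9), c(1, 2, 3)), "4 distinct")
  expect_error(fit_4pl(c(-1, 1, 3, 9), c(1, 2, 3, 4)), "positive")
})

test_that("noisy series recover EC50 within tolerance (median over seeds)", {
  doses <- dose_series_3fold(100, 10)
  errs <- vapply(1:200, function(s) {
    ds <- generate_dose_series(ec50 = 3, hill = 1, top = 100, bottom = 0,
                               doses = doses, noise_sd = 5,
                               replicates = 3, seed = s)
    fit <- fit_4pl(ds$dose, ds$response)
    abs(fit$ec50 - 3) / 3
  }, numeric(1))
  expect_lt(median(errs), 0.10)

  # single noisy replicate set at the stated seed stays within 25%
  ds <- generate_dose_series(ec50 = 0.4, hill = 1, top = 100, bottom = 0,
                             doses = dose_series_3fold(10, 10),
                             noise_sd = 5, replicates = 3, seed = 7)
  fit <- fit_4pl(ds$dose, ds$response)
  expect_equal(fit$ec50, 0.4, tolerance = 0.25)
})

test_that("run-to-run EC50 spread stays within the 3-fold criterion", {
  doses <- dose_series_3fold(10, 10)
  ec50s <- vapply(1:6, function(run) {
    ds <- generate_dose_series(ec50 = 0.45, hill = 1.2, top = 100,
                               bottom = 0, doses = doses, noise_sd = 5,
                               replicates = 2, seed = 1000 + run)
    fit_4pl(ds$dose, ds$response)$ec50
  }, numeric(1))
  expect_lt(max(ec50s) / min(ec50s), 3)
})

test_that("activation normalisation maps the control window to 0-100", {
  cs <- control_summary(c(2.4, 2.6), c(0.9, 1.1))
  expect_equal(normalize_activation(1.0, cs), 0)
  expect_equal(normalize_activation(2.5, cs), 100)
  expect_equal(normalize_activation(1.75, cs), 50)
  degenerate <- control_summary(c(1, 1), c(1, 1))
  expect_error(normalize_activation(1.2, degenerate), "degenerate")
})

test_that("percent growth normalises by the vehicle-control mean", {
  expect_equal(percent_growth(500, c(400, 600)), 100)
  expect_equal(percent_growth(0, c(400, 600)), 0)
  expect_equal(percent_growth(250, c(400, 600)), 50)
  expect_error(percent_growth(100, numeric(0)), "required")
  expect_error(percent_growth(100, c(0, 0)), "positive")
})

test_that("cytotoxicity fitting recovers IC50 and censors beyond the top dose", {
  doses <- dose_series_3fold(100, 10)
  growth <- four_pl(doses, bottom = 100, top = 2, ec50 = 12, hill = 1.3)
  ct <- fit_cytotox(rep(doses, 2), rep(growth, 2))
  expect_false(ct$censored)
  expect_equal(ct$ic50, 12, tolerance = 0.02)

  # barely toxic compound: curve hardly moves, IC50 reported as > top dose
  growth_flat <- four_pl(doses, bottom = 100, top = 92, ec50 = 90, hill = 1)
  ct2 <- fit_cytotox(doses, growth_flat)
  expect_true(ct2$censored)
  expect_equal(ct2$ic50, 100)
})

test_that("selectivity reproduces printed indices and classes", {
  s <- selectivity(3.8, 28)
  expect_equal(s$si, 7.4)
  expect_equal(s$class, "good")
  s2 <- selectivity(2.6, 86)
  expect_equal(s2$si, 33)
  s3 <- selectivity(5, 5)
  expect_equal(s3$si, 1.0)
  expect_equal(s3$class, "none")

  # censored cytotoxicity gives a flagged lower bound
  s4 <- selectivity(10, 100, ic50_censored = TRUE)
  expect_true(s4$si_censored)
  expect_equal(s4$si, 10)
  expect_equal(s4$class, "good")

  # censored EC50 is unclassifiable
  s5 <- selectivity(NA_real_, 50, ec50_censored = TRUE)
  expect_true(is.na(s5$class))

  expect_equal(classify_si(c(6, 5, 2, 1.99)),
               c("good", "some", "some", "none"))
})
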