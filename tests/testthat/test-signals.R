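exposures <- c(10, 20, 50, 100, 200)

test_that("an exactly linear series recovers its slope with r2 = 1", {
  sig <- make_series(exposures, 0.1 * exposures)
  fit <- fit_exposure_slopes(sig)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$value, log2(100 * 0.1), tolerance = 1e-12)
})

test_that("a constant series gets slope 0 and r2 reported as 0", {
  sig <- make_series(exposures, rep(3.7, 5))
  fit <- fit_exposure_slopes(sig)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r2, 0)
  expect_true(is.na(fit$value))
})

test_that("slope and r2 match the lm oracle under both models", {
  y <- c(1.1, 2.0, 5.2, 9.8, 20.3)
  for (model in c("with_intercept", "through_origin")) {
    fit <- fit_exposure_slopes(make_series(exposures, y), model = model)
    ref <- lm_oracle(exposures, y, intercept = model == "with_intercept")
    expect_equal(fit$slope, ref$slope, tolerance = 1e-10)
    expect_equal(fit$r2, ref$r2, tolerance = 1e-10)
  }
  # randomized series, both models, many cases
  set.seed(42)
  for (i in 1:25) {
    y <- runif(1, 0.01, 0.5) * exposures + rnorm(5, 0, 2)
    for (model in c("with_intercept", "through_origin")) {
      fit <- fit_exposure_slopes(make_series(exposures, y), model = model)
      ref <- lm_oracle(exposures, y, intercept = model == "with_intercept")
      expect_equal(fit$slope, ref$slope, tolerance = 1e-10)
      expect_equal(fit$r2, ref$r2, tolerance = 1e-10)
    }
  }
})

test_that("reduce_to_value is log2(100 x slope) with missing for slope <= 0", {
  expect_equal(reduce_to_value(0.01), 0)
  expect_equal(reduce_to_value(0.1), log2(10), tolerance = 1e-12)
  expect_true(is.na(reduce_to_value(-0.05)))
  expect_true(is.na(reduce_to_value(0)))
})

test_that("scaling signals multiplies the slope and shifts the value by log2(k)", {
  set.seed(1)
  y <- 0.2 * exposures + rnorm(5, 0, 1)
  base <- fit_exposure_slopes(make_series(exposures, y))
  for (k in c(0.5, 2, runif(3, 0.1, 10))) {
    scaled <- fit_exposure_slopes(make_series(exposures, k * y))
    expect_equal(scaled$slope, k * base$slope, tolerance = 1e-10)
    expect_equal(scaled$r2, base$r2, tolerance = 1e-10)
    if (!is.na(base$value)) {
      expect_equal(scaled$value, base$value + log2(k), tolerance = 1e-10)
    }
  }
})

test_that("rescaling exposure units leaves r2 unchanged", {
  set.seed(2)
  y <- 0.3 * exposures + rnorm(5, 0, 2)
  base <- fit_exposure_slopes(make_series(exposures, y))
  for (k in c(0.001, 1000, runif(2, 0.1, 10))) {
    scaled <- fit_exposure_slopes(make_series(k * exposures, y))
    expect_equal(scaled$r2, base$r2, tolerance = 1e-10)
  }
})

test_that("the noiseless generator's slopes are recovered to 1e-10", {
  cfg <- sim_config(n_peptides = 10, n_kinases = 2, noise_sd = 0,
                    peptides_per_kinase = c(3, 5), effect_size = 0, seed = 6)
  sim <- simulate_array_experiment(cfg)
  fits <- fit_exposure_slopes(sim$signals)
  truth <- sim$truth$peptides
  expect_equal(fits$slope,
               truth$base_slope[match(fits$peptide_id, truth$peptide_id)],
               tolerance = 1e-10)
})

test_that("degenerate series are rejected with the spot named", {
  expect_error(
    fit_exposure_slopes(make_series(c(10, 10), c(1, 2), peptide_id = "P009")),
    "P009"
  )
  expect_error(
    fit_exposure_slopes(make_series(exposures, c(1, 2, NA, 4, 5),
                                    peptide_id = "P007")),
    "P007"
  )
  expect_error(fit_exposure_slopes(make_series(c(-10, 20), c(1, 2))),
               "positive")
})

test_that("replicate spots are averaged with a message", {
  sig <- dplyr::bind_rows(
    dplyr::mutate(make_series(exposures, 0.1 * exposures), spot_id = "a"),
    dplyr::mutate(make_series(exposures, 0.3 * exposures), spot_id = "b")
  )
  expect_message(fit <- fit_exposure_slopes(sig), "replicate")
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(nrow(fit), 1)
})

test_that("QC is per-peptide across all samples", {
  # peptide P002 fails in a single sample -> excluded everywhere
  sig <- dplyr::bind_rows(
    make_series(exposures, 0.2 * exposures, "S1", "condition", "P001"),
    make_series(exposures, 0.2 * exposures, "S2", "control", "P001"),
    make_series(exposures, 0.3 * exposures, "S1", "condition", "P002"),
    make_series(exposures, rep(2, 5), "S2", "control", "P002")
  )
  values <- qc_filter(fit_exposure_slopes(sig), r2_min = 0.9)
  expect_identical(qc_passing(values), "P001")
  expect_true(all(!values$qc_pass[values$peptide_id == "P002"]))

  # all exactly linear positive-slope peptides pass at r2_min = 0.9
  cfg <- sim_config(n_peptides = 8, n_kinases = 2, noise_sd = 0,
                    peptides_per_kinase = c(3, 4), seed = 5)
  sim <- simulate_array_experiment(cfg)
  v2 <- qc_filter(fit_exposure_slopes(sim$signals), r2_min = 0.9)
  expect_length(qc_passing(v2), 8)
})

test_that("QC agrees with an independent filter re-implementation", {
  cfg <- sim_config(n_peptides = 40, n_kinases = 5, noise_sd = 0.05,
                    baseline_slope_range = c(0.02, 0.3), seed = 17)
  sim <- simulate_array_experiment(cfg)
  fits <- fit_exposure_slopes(sim$signals)
  values <- qc_filter(fits, r2_min = 0.95, min_slope = 0.01)
  # oracle: plain loop over peptides
  expected <- character()
  for (p in sort(unique(fits$peptide_id))) {
    rows <- fits[fits$peptide_id == p, ]
    ok <- TRUE
    for (i in seq_len(nrow(rows))) {
      if (!(is.finite(rows$r2[i]) && rows$r2[i] >= 0.95 &&
              rows$slope[i] > 0.01 && !is.na(rows$value[i]))) {
        ok <- FALSE
      }
    }
    if (ok) expected <- c(expected, p)
  }
  expect_identical(qc_passing(values), expected)
})
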