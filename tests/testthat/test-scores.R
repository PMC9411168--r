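test_that("group means and unbiased variances are computed per peptide", {
  V <- rbind(c(1, 3, 5, 5), c(2, 2, 2, 2))
  vals <- values_from_matrix(V, c(TRUE, TRUE, FALSE, FALSE))
  st <- peptide_group_stats(vals)
  expect_equal(st$mean_condition[1], 2)
  expect_equal(st$var_condition[1], 2) # two-point variance (1,3)
  expect_equal(st$var_condition[2], 0)
  expect_equal(st$var_control[1], 0)

  # random 4v4 matrix against a plain mean/var oracle
  set.seed(9)
  V <- matrix(rnorm(10 * 8), 10, 8)
  is_cond <- rep(c(TRUE, FALSE), each = 4)
  st <- peptide_group_stats(values_from_matrix(V, is_cond))
  for (i in 1:10) {
    expect_equal(st$mean_condition[i], mean(V[i, 1:4]), tolerance = 1e-12)
    expect_equal(st$var_condition[i], stats::var(V[i, 1:4]),
                 tolerance = 1e-12)
    expect_equal(st$var_control[i], stats::var(V[i, 5:8]),
                 tolerance = 1e-12)
  }
})

test_that("the Mean Kinase Statistic matches Eq-by-term evaluation", {
  # single peptide: (2 - 1) / sqrt(0.5 + 0.5) = 1
  st <- tibble::tibble(peptide_id = "P1", z = (2 - 1) / sqrt(0.5 + 0.5))
  expect_equal(mean_kinase_statistic(st, "P1"), 1)

  # identical groups: statistic is exactly 0 for every kinase
  V <- matrix(rnorm(24), 6, 4)
  V <- cbind(V, V) # condition columns duplicate control columns
  st0 <- peptide_group_stats(
    values_from_matrix(V, rep(c(TRUE, FALSE), each = 4))
  )
  expect_equal(mean_kinase_statistic(st0, st0$peptide_id), 0)

  # 9 random peptides against the term-by-term oracle
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    m1 <- rnorm(n); m2 <- rnorm(n)
    v1 <- runif(n, 0, 2); v2 <- runif(n, 0, 2)
    st <- tibble::tibble(
      peptide_id = sprintf("P%d", seq_len(n)),
      z = ifelse(v1 + v2 > 0, (m1 - m2) / sqrt(v1 + v2), NA_real_)
    )
    expect_equal(mean_kinase_statistic(st, st$peptide_id),
                 mks_oracle(m1, m2, v1, v2), tolerance = 1e-12)
  }
})

test_that("zero-variance peptides are dropped from a kinase's average", {
  st <- tibble::tibble(
    peptide_id = c("P1", "P2"),
    z = c(2, NA_real_) # P2 has summed variance 0
  )
  expect_equal(mean_kinase_statistic(st, c("P1", "P2")), 2)
  expect_true(is.na(mean_kinase_statistic(st, "P2")))
})

test_that("exhaustive significance equals brute-force enumeration", {
  set.seed(21)
  # 3v3: 20 assignments; 4v3: 35 assignments
  for (sizes in list(c(3, 3), c(4, 3))) {
    V <- matrix(rnorm(8 * sum(sizes)), 8, sum(sizes))
    is_cond <- rep(c(TRUE, FALSE), sizes)
    vals <- values_from_matrix(V, is_cond)
    rows <- c(2, 5, 7)
    peptides <- sprintf("P%03d", rows)
    res <- significance_score(vals, peptides, n_perm = 1000, seed = 1)
    expect_true(res$exact)
    expect_equal(res$n_used, choose(sum(sizes), sizes[1]))
    expect_identical(res$p, enum_significance_oracle(V, is_cond, rows))
  }
})

test_that("a constant value matrix gives significance p = 1, score 0", {
  V <- matrix(5, 4, 6)
  vals <- values_from_matrix(V, rep(c(TRUE, FALSE), each = 3))
  res <- significance_score(vals, sprintf("P%03d", 1:2), n_perm = 100,
                            seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$score, 0)
})

test_that("sampled-mode significance is deterministic given a seed and calibrated", {
  set.seed(3)
  V <- matrix(rnorm(12 * 10), 12, 10)
  vals <- values_from_matrix(V, rep(c(TRUE, FALSE), each = 5))
  peptides <- sprintf("P%03d", 1:4)
  a <- significance_score(vals, peptides, n_perm = 50, seed = 77)
  b <- significance_score(vals, peptides, n_perm = 50, seed = 77)
  expect_false(a$exact) # choose(10,5) = 252 > 50
  expect_identical(a$p, b$p)
  expect_gt(a$p, 0) # add-one smoothing: p = 0 impossible
})

test_that("specificity over the whole pool is uninformative (p = 1)", {
  set.seed(5)
  V <- matrix(rnorm(6 * 8), 6, 8)
  vals <- values_from_matrix(V, rep(c(TRUE, FALSE), each = 4))
  res <- specificity_score(vals, sprintf("P%03d", 1:6), n_perm = 200,
                           seed = 2)
  expect_equal(res$p, 1)
})

test_that("specificity detects a kinase-specific shift and ignores a global one", {
  set.seed(6)
  # shift confined to one kinase's peptides -> small p
  V <- matrix(rnorm(40 * 8, sd = 0.3), 40, 8)
  V[1:5, 1:4] <- V[1:5, 1:4] + 2
  vals <- values_from_matrix(V, rep(c(TRUE, FALSE), each = 4))
  res <- specificity_score(vals, sprintf("P%03d", 1:5), n_perm = 500,
                           seed = 3)
  expect_lt(res$p, 0.05)
  # the same shift applied to every peptide -> no specific signal
  Vg <- matrix(rnorm(40 * 8, sd = 0.3), 40, 8)
  Vg[, 1:4] <- Vg[, 1:4] + 2
  valsg <- values_from_matrix(Vg, rep(c(TRUE, FALSE), each = 4))
  resg <- specificity_score(valsg, sprintf("P%03d", 1:5), n_perm = 500,
                            seed = 3)
  expect_gt(resg$p, 0.05)
})

test_that("the Mean Final Score combines scores per the singlicate rule", {
  expect_equal(mean_final_score(0.9, 0.4, singlicate = FALSE), 1.3)
  expect_equal(mean_final_score(0.9, 0.4, singlicate = TRUE), 0.4)
  expect_equal(mean_final_score(0, 0, FALSE), 0)
  expect_error(mean_final_score(-0.1, 0.4, FALSE), "scores")
})

test_that("activated calls are strict on both thresholds and sorted", {
  scores <- tibble::tibble(
    kinase_id = c("A", "B", "C", "D", "E"),
    mks = c(0.5, -0.2, 1.0, 0.3, 0.3),
    mfs = c(0.6, 0.9, 0.5, 1.2, 1.2)
  )
  act <- call_activated(scores)
  # B excluded (negative MKS), C excluded (MFS exactly 0.5)
  expect_identical(act$kinase_id, c("D", "E", "A"))
})

test_that("swapping group labels negates every MKS exactly", {
  cfg <- sim_config(n_peptides = 30, n_kinases = 6, planted_kinases = 2,
                    seed = 19)
  sim <- simulate_array_experiment(cfg)
  values <- qc_filter(fit_exposure_slopes(sim$signals))
  map <- build_kinase_map(sim$candidates, values)
  fwd <- score_kinases(values, map, n_perm = 100, seed = 4)
  rev <- score_kinases(values, map, condition = "control",
                       control = "condition", n_perm = 100, seed = 4)
  f <- dplyr::arrange(tidy(fwd), kinase_id)
  r <- dplyr::arrange(tidy(rev), kinase_id)
  expect_identical(f$mks, -r$mks)
  expect_identical(f$significance_p, r$significance_p) # two-sided
})

test_that("statistics are invariant to adding a constant to every value", {
  cfg <- sim_config(n_peptides = 24, n_kinases = 5, seed = 23)
  sim <- simulate_array_experiment(cfg)
  values <- qc_filter(fit_exposure_slopes(sim$signals))
  map <- build_kinase_map(sim$candidates, values)
  base <- tidy(score_kinases(values, map, n_perm = 100, seed = 9))
  shifted <- values
  shifted$value <- shifted$value + 7
  moved <- tidy(score_kinases(shifted, map, n_perm = 100, seed = 9))
  expect_equal(base$mks, moved$mks, tolerance = 1e-9)
  expect_identical(base$significance_p, moved$significance_p)
  expect_identical(base$specificity_p, moved$specificity_p)
})

test_that("batch scoring reproduces per-kinase calls and is order-independent", {
  cfg <- sim_config(n_peptides = 36, n_kinases = 8, planted_kinases = 2,
                    seed = 29)
  sim <- simulate_array_experiment(cfg)
  values <- qc_filter(fit_exposure_slopes(sim$signals))
  map <- build_kinase_map(sim$candidates, values)
  ks <- score_kinases(values, map, n_perm = 300, seed = 31)
  tab <- tidy(ks)

  # per-kinase public API reproduces the batch specificity stream
  k <- tab$kinase_id[1]
  peps <- map$peptide_id[map$kinase_id == k]
  peps <- peps[peps %in% qc_passing(values)]
  solo <- specificity_score(values, peps, n_perm = 300,
                            seed = kinact:::derive_seed(31, paste0("spec:", k)))
  expect_identical(solo$p, tab$specificity_p[tab$kinase_id == k])

  # shuffling the map rows changes nothing
  ks2 <- score_kinases(values, map[sample(nrow(map)), ], n_perm = 300,
                       seed = 31)
  expect_identical(tab, tidy(ks2))
})

test_that("degenerate groupings are rejected", {
  V <- matrix(rnorm(12), 3, 4)
  vals <- values_from_matrix(V, rep(TRUE, 4))
  expect_error(peptide_group_stats(vals), "degenerate|group")
})

test_that("singlicate designs fall back to specificity-only MFS", {
  set.seed(8)
  V <- matrix(rnorm(20 * 4), 20, 4)
  vals <- values_from_matrix(V, c(TRUE, FALSE, FALSE, FALSE))
  map <- tibble::tibble(kinase_id = "KIN1",
                        peptide_id = sprintf("P%03d", 1:4))
  ks <- score_kinases(vals, map, n_perm = 100, seed = 13)
  expect_true(ks$singlicate)
  tab <- tidy(ks)
  expect_true(is.na(tab$significance_score))
  expect_identical(tab$mfs, tab$specificity_score)
})
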