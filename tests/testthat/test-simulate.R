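test_that("identical configs reproduce the experiment byte for byte", {
  cfg <- sim_config(n_peptides = 24, n_kinases = 6, planted_kinases = 2,
                    seed = 7)
  a <- simulate_array_experiment(cfg)
  b <- simulate_array_experiment(cfg)
  expect_identical(readr::format_tsv(a$signals), readr::format_tsv(b$signals))
  expect_identical(readr::format_tsv(a$candidates),
                   readr::format_tsv(b$candidates))
  expect_identical(a$truth$planted_kinases, b$truth$planted_kinases)

  net1 <- simulate_interaction_network(12, density = 0.3, seed = 5)
  net2 <- simulate_interaction_network(12, density = 0.3, seed = 5)
  expect_identical(net1, net2)

  ph1 <- simulate_phosphosite_table(30, 5, 4, planted_pathways = 1, seed = 9)
  ph2 <- simulate_phosphosite_table(30, 5, 4, planted_pathways = 1, seed = 9)
  expect_identical(readr::format_tsv(ph1$intensities),
                   readr::format_tsv(ph2$intensities))
})

test_that("generators draw from independent streams", {
  cfg <- sim_config(n_peptides = 24, n_kinases = 6, seed = 7)
  map_alone <- simulate_kinase_map(cfg)
  sim <- simulate_array_experiment(cfg)
  # the candidate table inside the experiment is the same object a direct
  # call produces: generating signals does not perturb the map stream
  expect_identical(map_alone, sim$candidates)
})

test_that("a noiseless null experiment is exactly linear and group-symmetric", {
  cfg <- sim_config(n_peptides = 12, n_kinases = 3, group_sizes = c(3, 3),
                    effect_size = 0, noise_sd = 0, seed = 3)
  sim <- simulate_array_experiment(cfg)
  slopes <- sim$truth$peptides$base_slope
  expected <- slopes[match(sim$signals$peptide_id,
                           sim$truth$peptides$peptide_id)] *
    sim$signals$exposure_ms
  expect_equal(sim$signals$signal, expected, tolerance = 1e-12)
  # every sample sees the same series for a given peptide
  per_sample <- tidyr::pivot_wider(
    sim$signals[, c("peptide_id", "exposure_ms", "sample_id", "signal")],
    names_from = "sample_id", values_from = "signal"
  )
  mat <- as.matrix(per_sample[, grep("^S", names(per_sample))])
  expect_true(all(apply(mat, 1, function(r) max(r) - min(r) == 0)))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_peptides = 0), "n_peptides")
  expect_error(sim_config(exposure_times = c(50, 20, 10)), "exposure_times")
  expect_error(sim_config(group_sizes = c(0, 4)), "group_sizes")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(n_peptides = 8, peptides_per_kinase = 9),
               "peptides_per_kinase")
  expect_error(sim_config(planted_kinases = "NOT_A_KINASE"),
               "planted_kinases")
})

test_that("planted kinases shift the reduced value by the stated amount", {
  # Monte-Carlo check of the generative contract: over replicate
  # experiments, the per-peptide condition-minus-control mean value for
  # planted peptides matches effect_size x the per-peptide value SD
  # within 3 standard errors.
  n_rep <- 200
  diffs <- numeric(n_rep)
  shifts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_peptides = 16, n_kinases = 3,
                      peptides_per_kinase = c(4, 4),
                      planted_kinases = "K02", effect_size = 1.5,
                      noise_sd = 0.002, seed = 1000 + r)
    sim <- simulate_array_experiment(cfg)
    values <- fit_exposure_slopes(sim$signals)
    planted <- sim$truth$peptides$peptide_id[sim$truth$peptides$planted]
    pep <- values[values$peptide_id %in% planted, ]
    d <- tapply(pep$value, list(pep$peptide_id, pep$group), mean)
    diffs[r] <- mean(d[, "condition"] - d[, "control"])
    tp <- sim$truth$peptides
    shifts[r] <- mean(1.5 * tp$value_sd[tp$planted])
  }
  err <- diffs - shifts
  se <- stats::sd(err) / sqrt(n_rep)
  expect_lt(abs(mean(err)), 3 * se + 1e-12)
})

test_that("kinase map has the requested shape and guarantees", {
  cfg <- sim_config(n_peptides = 36, n_kinases = 1,
                    peptides_per_kinase = 9, seed = 4)
  map <- simulate_kinase_map(cfg)
  expect_equal(nrow(map), 9)
  expect_equal(unique(map$kinase_id), "K01")
  # in-vitro flag and rank-0 are equivalent
  expect_identical(map$in_vitro, map$rank == 0L)

  cfg2 <- sim_config(n_peptides = 144, n_kinases = 40,
                     planted_kinases = 6, seed = 11)
  map2 <- simulate_kinase_map(cfg2)
  retained <- map2[map2$in_vitro | (map2$score > 300 & map2$rank <= 12), ]
  # every kinase (planted ones in particular) has a retained peptide
  expect_setequal(unique(retained$kinase_id), cfg2$kinase_ids)
  expect_true(all(cfg2$planted_kinases %in% retained$kinase_id))
  # no duplicated (kinase, peptide) pairs
  expect_equal(anyDuplicated(map2[, c("kinase_id", "peptide_id")]), 0L)
})

test_that("interaction networks are connected, simple, and sized as asked", {
  # minimal density on 5 nodes: exactly a spanning tree
  net <- simulate_interaction_network(5, density = 4 / 10, seed = 2)
  expect_equal(nrow(net), 4)
  expect_true(all(net$node_a != net$node_b))

  big <- simulate_interaction_network(30, density = 0.2, seed = 8)
  expect_true(all(big$node_a != big$node_b))
  expect_equal(anyDuplicated(paste(pmin(big$node_a, big$node_b),
                                   pmax(big$node_a, big$node_b))), 0L)
  g <- igraph::graph_from_data_frame(big[, c("node_a", "node_b")],
                                     directed = FALSE)
  expect_true(igraph::is_connected(g))
  # handshake lemma on the constructed edge list
  expect_equal(sum(igraph::degree(g)), 2 * nrow(big))
  expect_error(simulate_interaction_network(30, density = 0.01, seed = 1),
               "density")
})

test_that("phosphosite generator plants pathway-consistent shifts", {
  ph <- simulate_phosphosite_table(60, 8, 5, planted_pathways = "PW02",
                                   seed = 13)
  truth <- ph$truth
  expect_identical(truth$planted_pathways, "PW02")
  # every differential site is catalyzed by a kinase of the planted pathway
  planted_k <- ph$pathways$kinase_id[ph$pathways$pathway_id == "PW02"]
  for (s in truth$differential_sites) {
    expect_true(any(ph$site_kinases$kinase_id[ph$site_kinases$site_id == s]
                    %in% planted_k))
  }
  # planted shift is visible in group means
  ints <- ph$intensities[ph$intensities$site_id %in%
                           truth$differential_sites, ]
  m <- tapply(ints$log_intensity, ints$group, mean)
  expect_gt(m[["condition"]] - m[["control"]], 1)
})

test_that("strong planted phosphosite shifts are nearly always recovered", {
  # Monte-Carlo power of the per-site Welch test at a 3 SD planted shift,
  # 4 vs 4 (raw p at alpha = 0.05; the analytic noncentral-t power at this
  # effect size is about 0.93)
  n_rep <- 100
  recall <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ph <- simulate_phosphosite_table(100, 10, 6, planted_pathways = 2,
                                     seed = 5000 + r, effect_size = 3)
    dp <- differential_phosphosites(ph$intensities, adjust = "none")
    truth <- ph$truth$differential_sites
    recall[r] <- mean(truth %in% dp$increased)
  }
  expect_gt(mean(recall), 0.9)
})
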