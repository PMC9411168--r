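# Independent oracles used to check the implementation by a second route.
# These deliberately use different code paths (stats::lm, stats::var,
# explicit loops) from the package internals.

# OLS slope and r2 via stats::lm
lm_oracle <- function(x, y, intercept = TRUE) {
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  list(slope = unname(stats::coef(fit)[["x"]]),
       r2 = summary(fit)$r.squared)
}

# Term-by-term Mean Kinase Statistic from raw group values
mks_oracle <- function(m1, m2, v1, v2) {
  terms <- c()
  for (i in seq_along(m1)) {
    if (v1[i] + v2[i] > 0) {
      terms <- c(terms, (m1[i] - m2[i]) / sqrt(v1[i] + v2[i]))
    }
  }
  if (length(terms) == 0) return(NA_real_)
  sum(terms) / length(terms)
}

# MKS for a peptide subset of a values matrix (rows = peptides), given a
# logical condition indicator over columns
mks_from_matrix_oracle <- function(V, is_cond, rows) {
  m1 <- apply(V[rows, is_cond, drop = FALSE], 1, mean)
  m2 <- apply(V[rows, !is_cond, drop = FALSE], 1, mean)
  v1 <- apply(V[rows, is_cond, drop = FALSE], 1, stats::var)
  v2 <- apply(V[rows, !is_cond, drop = FALSE], 1, stats::var)
  mks_oracle(m1, m2, v1, v2)
}

# Brute-force exact sample-permutation p-value: enumerate every way to
# choose the condition group, recompute the MKS for the kinase's peptides,
# and count assignments at least as extreme (two-sided)
enum_significance_oracle <- function(V, is_cond, rows) {
  n <- ncol(V)
  n1 <- sum(is_cond)
  tau_obs <- mks_from_matrix_oracle(V, is_cond, rows)
  combos <- utils::combn(n, n1)
  taus <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    ind <- seq_len(n) %in% combos[, j]
    taus[j] <- mks_from_matrix_oracle(V, ind, rows)
  }
  mean(abs(taus) >= abs(tau_obs))
}

# Independent pathway tally: loop over pathways and differential sites
pathway_tally_oracle <- function(sites, site_kinases, pathways) {
  out <- list()
  for (pw in sort(unique(pathways$pathway_id))) {
    members <- unique(pathways$kinase_id[pathways$pathway_id == pw])
    n <- 0
    for (s in unique(sites)) {
      catal <- unique(site_kinases$kinase_id[site_kinases$site_id == s])
      if (any(catal %in% members)) n <- n + 1
    }
    out[[pw]] <- n
  }
  out
}

# Long-format signal tibble from a named list of per-sample signal vectors
make_series <- function(exposures, signal, sample_id = "S1",
                        group = "condition", peptide_id = "P001") {
  tibble::tibble(sample_id = sample_id, group = group,
                 peptide_id = peptide_id, exposure_ms = exposures,
                 signal = signal)
}

# Values tibble (post slope-reduction shape) from a matrix: rows peptides,
# columns samples; `is_cond` marks condition columns
values_from_matrix <- function(V, is_cond,
                               peptides = sprintf("P%03d", seq_len(nrow(V))),
                               samples = sprintf("S%d", seq_len(ncol(V)))) {
  df <- expand.grid(peptide_id = peptides, sample_id = samples,
                    stringsAsFactors = FALSE)
  df$group <- ifelse(is_cond[match(df$sample_id, samples)],
                     "condition", "control")
  df$value <- V[cbind(match(df$peptide_id, peptides),
                      match(df$sample_id, samples))]
  tibble::as_tibble(df[, c("sample_id", "group", "peptide_id", "value")])
}
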