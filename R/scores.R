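# Per-kinase activity statistics.
#
# For kinase K with retained peptides i = 1..n, the Mean Kinase Statistic is
#
#   MKS(K) = (1/n) * sum_i (m_i1 - m_i2) / sqrt(s2_i1 + s2_i2)
#
# where m_ig and s2_ig are the sample mean and unbiased variance of peptide
# i's reduced value in group g (group 1 = condition of interest, group 2 =
# control), so MKS > 0 means higher activity in the condition group. Two
# permutation summaries qualify it:
#
#   * significance — permute the sample labels: how much does MKS depend on
#     the experimental grouping? Exhaustive enumeration replaces sampling
#     whenever the number of distinct label assignments fits in n_perm.
#   * specificity — resample peptide sets of the same size from the whole
#     QC-passing pool with the true labels: how much does MKS depend on the
#     particular peptide-to-kinase mapping?
#
# Scores are -log10(p); the Mean Final Score is specificity alone for
# singlicate designs, otherwise significance + specificity. A kinase is
# called activated when MKS > 0 and MFS > 0.5.

TAU_TOL <- 1e-12 # slack for |tau_perm| >= |tau_obs| so the identity
                 # assignment always counts as at least as extreme

#' Per-peptide group means and variances
#'
#' Computes, for every peptide, the sample mean and unbiased (n - 1
#' denominator) variance of the reduced value in each of the two comparison
#' groups, plus the standardized difference
#' `z = (mean_condition - mean_control) / sqrt(var_condition + var_control)`.
#' A group of size one contributes variance 0 (it carries no spread
#' information); `z` is `NA` where the summed variance is 0.
#'
#' @param values Tibble with columns `sample_id`, `group`, `peptide_id`,
#'   `value` (typically [qc_filter()] output restricted to `qc_pass`).
#' @param condition,control Labels of the two groups in `values$group`;
#'   the sign of every downstream statistic follows this orientation.
#' @return A tibble with one row per peptide: group sizes, means, variances
#'   and `z`.
#' @export
peptide_group_stats <- function(values, condition = "condition",
                                control = "control") {
  vm <- value_matrix(values, condition, control)
  stats_from_matrix(vm$V, vm$is_condition) %>%
    mutate(peptide_id = rownames(vm$V), .before = 1)
}

# Internal: wide peptides x samples matrix plus the group indicator.
value_matrix <- function(values, condition, control) {
  check_columns(values, c("sample_id", "group", "peptide_id", "value"),
                "`values`")
  if ("qc_pass" %in% names(values)) values <- filter(values, .data$qc_pass)
  values <- filter(values, .data$group %in% c(condition, control))
  if (nrow(values) == 0L) abort("no values in the requested groups")
  wide <- values %>%
    select("peptide_id", "sample_id", "value") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  V <- as.matrix(wide[, -1, drop = FALSE])
  rownames(V) <- wide$peptide_id
  grp <- values %>% distinct(.data$sample_id, .data$group)
  is_condition <- grp$group[match(colnames(V), grp$sample_id)] == condition
  if (all(is_condition) || !any(is_condition)) {
    abort(sprintf("degenerate grouping: need >= 1 sample in each of '%s' and '%s'",
                  condition, control))
  }
  list(V = V, is_condition = is_condition)
}

group_var_rows <- function(M) {
  if (ncol(M) == 1L) rep(0, nrow(M)) else row_vars(M)
}

stats_from_matrix <- function(V, is_condition) {
  V1 <- V[, is_condition, drop = FALSE]
  V2 <- V[, !is_condition, drop = FALSE]
  m1 <- unname(rowMeans(V1)); m2 <- unname(rowMeans(V2))
  v1 <- unname(group_var_rows(V1)); v2 <- unname(group_var_rows(V2))
  tibble(
    n_condition = ncol(V1), n_control = ncol(V2),
    mean_condition = m1, mean_control = m2,
    var_condition = v1, var_control = v2,
    z = ifelse(v1 + v2 > 0, (m1 - m2) / sqrt(v1 + v2), NA_real_)
  )
}

# Standardized differences for one label assignment (cond = column indices
# of the condition group); returns the per-peptide z vector.
z_for_assignment <- function(V, cond) {
  s <- stats_from_matrix(V, seq_len(ncol(V)) %in% cond)
  s$z
}

#' Mean Kinase Statistic for one peptide set
#'
#' Averages the standardized per-peptide group differences `z` over the
#' given peptides. Peptides whose summed group variance is 0 (undefined `z`)
#' are dropped from the average; if all are dropped the statistic is `NA`.
#'
#' @param stats Output of [peptide_group_stats()].
#' @param peptides Character vector of retained peptide ids for the kinase.
#' @return A single number (the MKS), or `NA` when no peptide has a defined
#'   standardized difference.
#' @export
#' @examples
#' st <- tibble::tibble(peptide_id = "P1", mean_condition = 2,
#'                      mean_control = 1, var_condition = 0.5,
#'                      var_control = 0.5,
#'                      z = (2 - 1) / sqrt(0.5 + 0.5))
#' mean_kinase_statistic(st, "P1") # 1
mean_kinase_statistic <- function(stats, peptides) {
  check_columns(stats, c("peptide_id", "z"), "`stats`")
  z <- stats$z[match(peptides, stats$peptide_id)]
  z <- z[!is.na(z)]
  if (length(z) == 0L) return(NA_real_)
  mean(z)
}

# Shared permutation-p machinery -------------------------------------------

perm_pvalue <- function(tau_perm, tau_obs, alternative, add_one) {
  if (is.na(tau_obs)) {
    # undefined observed statistic (all peptide terms dropped): no evidence
    # of dependence on the grouping or mapping
    return(1)
  }
  if (alternative == "two_sided") {
    hits <- abs(tau_perm) >= abs(tau_obs) - TAU_TOL
  } else {
    hits <- tau_perm >= tau_obs - TAU_TOL
  }
  n_hit <- sum(hits, na.rm = TRUE)
  n_tot <- length(tau_perm)
  if (add_one) (1 + n_hit) / (n_tot + 1) else n_hit / n_tot
}

# All distinct condition-group assignments as a list of index vectors.
enumerate_assignments <- function(n, n1) {
  asplit(combn(n, n1), 2)
}

#' Permutation significance of a kinase's MKS
#'
#' Shuffles the group labels across all samples, recomputes every peptide's
#' group statistics and the kinase's MKS for each relabeling, and reports
#' how often the permuted statistic is at least as extreme as the observed
#' one. When the number of distinct label assignments is at most `n_perm`,
#' exhaustive enumeration replaces Monte-Carlo sampling and the p-value is
#' the exact proportion (the identity assignment guarantees p >= 1/N);
#' sampled p-values use the add-one correction so p = 0 is impossible. The
#' score is `-log10(p)`.
#'
#' @inheritParams peptide_group_stats
#' @param peptides Retained peptide ids of the kinase.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the kinase's permutation stream.
#' @param alternative `"two_sided"` (default; compares `|MKS|`) or
#'   `"one_sided"` (signed, condition-greater).
#' @return A list with `p`, `score`, `exact` (logical), and `n_used`
#'   (assignments actually evaluated).
#' @export
significance_score <- function(values, peptides, condition = "condition",
                               control = "control", n_perm = 1000, seed = 1,
                               alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  vm <- value_matrix(values, condition, control)
  idx <- match(peptides, rownames(vm$V))
  if (anyNA(idx)) abort("`peptides` not all present in `values`")
  sig_one_kinase(vm$V, vm$is_condition, idx, n_perm, seed, alternative)
}

sig_one_kinase <- function(V, is_condition, idx, n_perm, seed, alternative) {
  n <- length(is_condition)
  n1 <- sum(is_condition)
  obs_cond <- which(is_condition)
  tau_obs <- mean_na(z_for_assignment(V[idx, , drop = FALSE], obs_cond))
  n_assign <- choose(n, n1)
  exact <- n_assign <= n_perm
  Vk <- V[idx, , drop = FALSE]
  if (exact) {
    assigns <- enumerate_assignments(n, n1)
    tau_perm <- vapply(assigns, function(a) {
      mean_na(z_for_assignment(Vk, a))
    }, numeric(1))
    p <- perm_pvalue(tau_perm, tau_obs, alternative, add_one = FALSE)
  } else {
    tau_perm <- with_stream(seed, "significance", {
      vapply(seq_len(n_perm), function(i) {
        mean_na(z_for_assignment(Vk, sample(n, n1)))
      }, numeric(1))
    })
    p <- perm_pvalue(tau_perm, tau_obs, alternative, add_one = TRUE)
  }
  list(p = p, score = -log10(p), exact = exact,
       n_used = if (exact) n_assign else n_perm, tau_obs = tau_obs)
}

mean_na <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0L) NA_real_ else mean(z)
}

#' Permutation specificity of a kinase's MKS
#'
#' Keeps the true group labels and redraws the kinase's peptide set: each
#' permutation samples the same number of peptides uniformly without
#' replacement from the whole QC-passing pool and recomputes the MKS on
#' that random set. A small p means the observed statistic is specific to
#' the kinase's own substrate peptides rather than an array-wide shift.
#' Add-one correction; score is `-log10(p)`.
#'
#' @inheritParams significance_score
#' @return A list with `p`, `score`, and `n_used` (= `n_perm`).
#' @export
specificity_score <- function(values, peptides, condition = "condition",
                              control = "control", n_perm = 1000, seed = 1,
                              alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  vm <- value_matrix(values, condition, control)
  z_pool <- z_for_assignment(vm$V, which(vm$is_condition))
  idx <- match(peptides, rownames(vm$V))
  if (anyNA(idx)) abort("`peptides` not all present in `values`")
  spec_one_kinase(z_pool, idx, n_perm, seed, alternative)
}

spec_one_kinase <- function(z_pool, idx, n_perm, seed, alternative) {
  n <- length(idx)
  pool_n <- length(z_pool)
  if (n > pool_n) abort("kinase has more peptides than the QC-passing pool")
  tau_obs <- mean_na(z_pool[idx])
  tau_perm <- with_stream(seed, "specificity", {
    draws <- matrix(0L, n_perm, n)
    for (i in seq_len(n_perm)) draws[i, ] <- sample.int(pool_n, n)
    zm <- matrix(z_pool[draws], n_perm, n)
    rowMeans(zm, na.rm = TRUE)
  })
  tau_perm[is.nan(tau_perm)] <- NA_real_
  p <- perm_pvalue(tau_perm, tau_obs, alternative, add_one = TRUE)
  list(p = p, score = -log10(p), n_used = n_perm, tau_obs = tau_obs)
}

#' Combine significance and specificity into the Mean Final Score
#'
#' For singlicate designs (any group with a single sample, where sample
#' relabeling carries no information) the MFS is the specificity score
#' alone; otherwise it is the sum of the significance and specificity
#' scores.
#'
#' @param significance,specificity Numeric score vectors (`-log10` scale).
#' @param singlicate Logical (scalar or vector).
#' @return Numeric vector of Mean Final Scores.
#' @export
#' @examples
#' mean_final_score(0.9, 0.4, singlicate = FALSE) # 1.3
#' mean_final_score(0.9, 0.4, singlicate = TRUE)  # 0.4
mean_final_score <- function(significance, specificity, singlicate = FALSE) {
  if (any(stats::na.omit(c(significance, specificity)) < 0)) {
    abort("scores must be >= 0")
  }
  ifelse(singlicate, specificity, significance + specificity)
}

#' Call activated kinases
#'
#' A kinase is activated when its Mean Kinase Statistic is strictly
#' positive (activity higher in the condition group) and its Mean Final
#' Score strictly exceeds 0.5. Both comparisons are strict: MKS = 0 or
#' MFS = 0.5 is not called. The result is sorted by MFS descending, ties by
#' MKS descending, then kinase id.
#'
#' @param scores Tibble with columns `kinase_id`, `mks`, `mfs` (e.g.
#'   `tidy(score_kinases(...))`).
#' @param mks_min_exclusive,mfs_min_exclusive Strict thresholds (defaults 0
#'   and 0.5).
#' @return The activated subset of `scores`, sorted.
#' @export
call_activated <- function(scores, mks_min_exclusive = 0,
                           mfs_min_exclusive = 0.5) {
  check_columns(scores, c("kinase_id", "mks", "mfs"), "`scores`")
  scores %>%
    filter(!is.na(.data$mks), !is.na(.data$mfs),
           .data$mks > mks_min_exclusive, .data$mfs > mfs_min_exclusive) %>%
    arrange(desc(.data$mfs), desc(.data$mks), .data$kinase_id)
}

#' Score every kinase in a peptide-to-kinase map
#'
#' The main entry point of the kinase-statistics stage: computes, for every
#' kinase in `map`, the Mean Kinase Statistic, permutation significance and
#' specificity p-values and scores, the Mean Final Score, and the activated
#' call. Each kinase's permutation stream is seeded from the master seed and
#' the kinase id, so results do not depend on kinase order and per-kinase
#' calls reproduce the batch result exactly. In the exhaustive significance
#' regime the per-assignment standardized differences are computed once and
#' shared across kinases.
#'
#' Peptides with zero summed group variance are dropped from a kinase's
#' average with a message; a kinase losing all its peptides is reported
#' with `NA` statistics. A BH-adjusted significance p is included for
#' information only; it plays no part in the activated call.
#'
#' @inheritParams significance_score
#' @param map Retained peptide-to-kinase map from [build_kinase_map()]
#'   (columns `kinase_id`, `peptide_id`).
#' @param mks_min,mfs_min Strict thresholds for the activated call.
#' @param singlicate Force singlicate handling; default `NULL` auto-detects
#'   (any group of size 1).
#' @return An object of class `kinase_scores`; see [tidy.kinase_scores()].
#' @export
#' @examples
#' sim <- simulate_array_experiment(sim_config(
#'   n_peptides = 36, n_kinases = 8, planted_kinases = 2, seed = 7
#' ))
#' values <- qc_filter(fit_exposure_slopes(sim$signals))
#' map <- build_kinase_map(sim$candidates, values)
#' ks <- score_kinases(values, map, n_perm = 200, seed = 7)
#' head(tidy(ks))
score_kinases <- function(values, map, condition = "condition",
                          control = "control", n_perm = 1000, seed = 1,
                          mks_min = 0, mfs_min = 0.5, singlicate = NULL,
                          alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  check_columns(map, c("kinase_id", "peptide_id"), "`map`")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  vm <- value_matrix(values, condition, control)
  V <- vm$V
  is_condition <- vm$is_condition
  n <- length(is_condition)
  n1 <- sum(is_condition)
  if (is.null(singlicate)) singlicate <- min(n1, n - n1) == 1L

  pool <- rownames(V)
  map <- filter(map, .data$peptide_id %in% pool)
  kinases <- sort(unique(map$kinase_id))
  if (length(kinases) == 0L) abort("no mapped kinase has QC-passing peptides")
  pep_idx <- lapply(setNames(kinases, kinases), function(k) {
    match(map$peptide_id[map$kinase_id == k], pool)
  })

  z_obs <- z_for_assignment(V, which(is_condition))
  n_assign <- choose(n, n1)
  exact <- n_assign <= n_perm

  # exhaustive regime: one peptides x assignments matrix shared by all kinases
  Z <- NULL
  if (exact && !singlicate) {
    assigns <- enumerate_assignments(n, n1)
    Z <- vapply(assigns, function(a) z_for_assignment(V, a),
                numeric(nrow(V)))
    obs_col <- which(vapply(assigns, function(a) {
      identical(sort(a), sort(which(is_condition)))
    }, logical(1)))
  }

  rows <- purrr::map(kinases, function(k) {
    idx <- pep_idx[[k]]
    zk <- z_obs[idx]
    n_dropped <- sum(is.na(zk))
    mks <- mean_na(zk)

    if (singlicate) {
      sig <- list(p = NA_real_, score = NA_real_, exact = FALSE,
                  n_used = NA_integer_)
    } else if (exact) {
      tau_perm <- colMeans(Z[idx, , drop = FALSE], na.rm = TRUE)
      tau_perm[is.nan(tau_perm)] <- NA_real_
      p <- perm_pvalue(tau_perm, tau_perm[obs_col], alternative,
                       add_one = FALSE)
      sig <- list(p = p, score = -log10(p), exact = TRUE, n_used = n_assign)
    } else {
      sig <- sig_one_kinase(V, is_condition, idx, n_perm,
                            derive_seed(seed, paste0("sig:", k)), alternative)
    }

    spc <- spec_one_kinase(z_obs, idx, n_perm,
                           derive_seed(seed, paste0("spec:", k)), alternative)
    mfs <- if (is.na(mks)) NA_real_ else {
      mean_final_score(sig$score, spc$score, singlicate)
    }
    tibble(
      kinase_id = k,
      n_peptides = length(idx) - n_dropped,
      n_dropped = n_dropped,
      mks = mks,
      significance_p = sig$p,
      significance_score = sig$score,
      specificity_p = spc$p,
      specificity_score = spc$score,
      mfs = mfs,
      activated = !is.na(mks) & !is.na(mfs) & mks > mks_min & mfs > mfs_min
    )
  })
  scores <- bind_rows(rows)
  n_zero_var <- sum(scores$n_dropped)
  if (n_zero_var > 0L) {
    inform(sprintf(
      "dropped %d zero-variance peptide term(s) across %d kinase(s)",
      n_zero_var, sum(scores$n_dropped > 0L)
    ))
  }
  scores <- scores %>%
    mutate(significance_q = p.adjust(.data$significance_p, "BH"),
           .after = "significance_score") %>%
    arrange(desc(.data$mfs), desc(.data$mks), .data$kinase_id)

  structure(
    list(
      scores = scores,
      condition = condition, control = control,
      group_sizes = c(n1, n - n1),
      n_perm = n_perm, seed = seed,
      exact = exact && !singlicate, n_assignments = n_assign,
      singlicate = singlicate, alternative = alternative,
      mks_min = mks_min, mfs_min = mfs_min,
      n_pool = length(pool)
    ),
    class = "kinase_scores"
  )
}

#' @export
print.kinase_scores <- function(x, ...) {
  cat(sprintf(
    "<kinase_scores> %d kinases, %d vs %d samples ('%s' vs '%s'), pool %d peptides\n",
    nrow(x$scores), x$group_sizes[1], x$group_sizes[2],
    x$condition, x$control, x$n_pool
  ))
  cat(sprintf(
    "  significance: %s; specificity: %d peptide draws; %d activated (MKS > %g, MFS > %g)\n",
    if (x$singlicate) "skipped (singlicate)"
    else if (x$exact) sprintf("exact over %d assignments", x$n_assignments)
    else sprintf("%d sampled permutations", x$n_perm),
    x$n_perm, sum(x$scores$activated), x$mks_min, x$mfs_min
  ))
  print(head(x$scores, 10))
  invisible(x)
}
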