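# Differential phosphosites and pathway ranking.
#
# Site-level corrected reporter-ion intensities (log2 scale) are compared
# between two groups with a per-site two-sample test (Welch by default).
# Pathways are then ranked by how many differential sites are catalyzed by
# at least one of their member kinases — a simple substrate-count sort, not
# an enrichment statistic, reflecting that a pathway whose kinases explain
# many phosphorylation events is confidently active.

#' Call differential phosphosites between two groups
#'
#' Runs a per-site two-sample test on log intensities (Welch's t by
#' default; Student's pooled-variance t available), adjusts p-values by
#' Benjamini-Hochberg (or not, in raw-p mode), and classifies significant
#' sites as increased or decreased in the condition group by the sign of
#' the mean difference. A site with zero variance in both groups and equal
#' means is assigned p = 1 by convention.
#'
#' @param intensities Long tibble: `site_id`, `sample_id`, `group`,
#'   `log_intensity`.
#' @param condition,control Group labels; "increased" means higher in
#'   `condition`.
#' @param test `"welch"` (default) or `"student"`.
#' @param alpha Significance level applied to the adjusted (or raw)
#'   p-value (default 0.05).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return An object of class `phospho_diff` with the per-site statistics
#'   tibble and the increased/decreased site sets; see
#'   [tidy.phospho_diff()].
#' @export
#' @examples
#' ph <- simulate_phosphosite_table(40, 6, 4, planted_pathways = 1, seed = 3)
#' dp <- differential_phosphosites(ph$intensities)
#' glance(dp)
differential_phosphosites <- function(intensities,
                                      condition = "condition",
                                      control = "control",
                                      test = c("welch", "student"),
                                      alpha = 0.05,
                                      adjust = c("BH", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  alpha <- check_number(alpha, "alpha", 0, 1)
  check_columns(intensities, c("site_id", "sample_id", "group",
                               "log_intensity"), "`intensities`")
  intensities <- filter(intensities, .data$group %in% c(condition, control))
  wide <- intensities %>%
    select("site_id", "sample_id", "log_intensity") %>%
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "log_intensity")
  M <- as.matrix(wide[, -1, drop = FALSE])
  rownames(M) <- wide$site_id
  grp <- intensities %>% distinct(.data$sample_id, .data$group)
  is_condition <- grp$group[match(colnames(M), grp$sample_id)] == condition
  n1 <- sum(is_condition)
  n2 <- sum(!is_condition)
  if (n1 < 2 || n2 < 2) {
    abort("variance-based tests need >= 2 samples per group")
  }

  M1 <- M[, is_condition, drop = FALSE]
  M2 <- M[, !is_condition, drop = FALSE]
  m1 <- unname(rowMeans(M1)); m2 <- unname(rowMeans(M2))
  v1 <- unname(row_vars(M1)); v2 <- unname(row_vars(M2))
  diff <- m1 - m2

  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(diff))
  }
  p <- 2 * pt(-abs(tstat), df)
  # zero variance in both groups: equal means -> p = 1; unequal -> p = 0
  degenerate <- v1 + v2 == 0
  p[degenerate & diff == 0] <- 1
  p[degenerate & diff != 0] <- 0

  q <- if (adjust == "BH") p.adjust(p, "BH") else p
  sig <- !is.na(q) & q < alpha
  stats <- tibble(
    site_id = rownames(M),
    n_condition = n1, n_control = n2,
    mean_condition = m1, mean_control = m2,
    log2_diff = diff,
    t = tstat, df = df, p = p, q = q,
    direction = dplyr::case_when(
      sig & diff > 0 ~ "increased",
      sig & diff < 0 ~ "decreased",
      TRUE ~ "unchanged"
    )
  )
  structure(
    list(
      stats = stats,
      increased = stats$site_id[stats$direction == "increased"],
      decreased = stats$site_id[stats$direction == "decreased"],
      condition = condition, control = control,
      test = test, alpha = alpha, adjust = adjust
    ),
    class = "phospho_diff"
  )
}

#' @export
print.phospho_diff <- function(x, ...) {
  cat(sprintf(
    "<phospho_diff> %d sites (%s test, %s-adjusted alpha %g): %d increased, %d decreased\n",
    nrow(x$stats), x$test, x$adjust, x$alpha,
    length(x$increased), length(x$decreased)
  ))
  invisible(x)
}

#' Rank pathways by differential-substrate counts
#'
#' Each pathway's support is the number of *distinct* differential sites
#' having at least one catalyzing kinase annotated to that pathway; a site
#' whose kinases span several pathways supports each of them once.
#' Annotations are treated as sets, so duplicated annotation rows never
#' change a count. Sites with no experimentally defined catalyzing kinase
#' cannot support any pathway. Pathways are sorted by count descending
#' (ties lexicographic) with dense ranks.
#'
#' @param diff A `phospho_diff` object, or a character vector of
#'   differential site ids.
#' @param site_kinases Tibble `site_id`, `kinase_id`: experimentally
#'   defined catalyzing kinases per site.
#' @param pathways Tibble `pathway_id`, `kinase_id` (e.g. read from a GMT
#'   file with [read_gmt()]).
#' @param top_k Optional: keep only the top `top_k` pathways.
#' @param direction Which differential sites support pathways when `diff`
#'   is a `phospho_diff`: `"increased"` (default, activity-driven),
#'   `"decreased"`, or `"both"`.
#' @return A tibble `pathway_id`, `n_kinases`, `n_sites`, `rank`.
#' @export
rank_pathways <- function(diff, site_kinases, pathways, top_k = NULL,
                          direction = c("increased", "decreased", "both")) {
  direction <- match.arg(direction)
  check_columns(site_kinases, c("site_id", "kinase_id"), "`site_kinases`")
  check_columns(pathways, c("pathway_id", "kinase_id"), "`pathways`")
  sites <- if (inherits(diff, "phospho_diff")) {
    switch(direction,
           increased = diff$increased,
           decreased = diff$decreased,
           both = c(diff$increased, diff$decreased))
  } else {
    as.character(diff)
  }
  sites <- unique(sites)
  if (length(sites) == 0L) {
    inform("no differential sites; returning an empty ranking")
    return(tibble(pathway_id = character(), n_kinases = integer(),
                  n_sites = integer(), rank = integer()))
  }

  site_kinases <- distinct(site_kinases)
  pathways <- distinct(pathways)
  support <- site_kinases %>%
    filter(.data$site_id %in% sites) %>%
    left_join(pathways, by = "kinase_id",
              relationship = "many-to-many") %>%
    filter(!is.na(.data$pathway_id)) %>%
    distinct(.data$pathway_id, .data$site_id)

  ranking <- pathways %>%
    group_by(.data$pathway_id) %>%
    summarise(n_kinases = n_distinct(.data$kinase_id), .groups = "drop") %>%
    left_join(count(support, .data$pathway_id, name = "n_sites"),
              by = "pathway_id") %>%
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L)) %>%
    arrange(desc(.data$n_sites), .data$pathway_id) %>%
    mutate(rank = dplyr::dense_rank(desc(.data$n_sites)))
  if (!is.null(top_k)) {
    top_k <- check_count(top_k, "top_k")
    ranking <- filter(ranking, .data$rank <= top_k)
  }
  ranking
}
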