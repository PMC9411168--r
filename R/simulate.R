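# Synthetic kinome-array experiments with planted ground truth.
#
# The generator emulates the structure of a porous 3D peptide microarray run:
# 144 peptide spots in a 12 x 12 grid, each imaged at exposure times of 10,
# 20, 50, 100 and 200 ms, with two comparison groups of samples. The signal
# model is linear in exposure with noise whose SD grows proportionally with
# exposure (so no exposure dominates the fit artificially); saturation is not
# modelled. The true distribution of spot fluorescence is not publicly
# characterised, so this linear-plus-noise model is an explicit stand-in.

#' Configuration for a synthetic kinome-array experiment
#'
#' Bundles every parameter of the synthetic generator, validates it, and
#' fixes the master RNG seed. Each generator draws from its own RNG stream
#' derived from `seed` and a stage key (see [derive_seed()]), so generated
#' objects are individually reproducible and mutually independent.
#'
#' @param n_peptides Number of peptide spots on the array (default 144, a
#'   12 x 12 grid).
#' @param exposure_times Camera exposure times in milliseconds, strictly
#'   positive and strictly increasing (default 10, 20, 50, 100, 200).
#' @param group_sizes Integer pair: samples in the condition group and in the
#'   control group (default 4 and 4).
#' @param n_kinases Number of kinases in the candidate map (default 50).
#' @param peptides_per_kinase Integer range (length 1 or 2): how many
#'   candidate peptides each kinase receives (default 6 to 12).
#' @param planted_kinases Kinases carrying a true activity shift: either a
#'   character vector of kinase ids or a single count, in which case that
#'   many kinases are sampled from the pool (default none).
#' @param effect_size True activity shift for planted kinases, expressed on
#'   the reduced (log2) value scale in units of the per-peptide value SD
#'   induced by the noise model (default 1.5).
#' @param noise_sd Additive signal noise: the reading at exposure `t` has SD
#'   `noise_sd * t` in fluorescence units, so that the implied slope noise is
#'   `noise_sd`-scaled (default 0.005 signal units per ms).
#' @param baseline_slope_range Range of true baseline slopes in signal units
#'   per ms (default 0.05 to 0.5, giving reduced values roughly 2.3 to 5.6).
#' @param intercept Optical background added to every reading (default 0).
#' @param in_vitro_prob Probability that a candidate row is an
#'   in-vitro-confirmed target (rank 0) rather than a homology prediction
#'   (default 0.1).
#' @param seed Master RNG seed (non-negative integer).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(planted_kinases = 5, seed = 7)
#' cfg$group_sizes
sim_config <- function(n_peptides = 144,
                       exposure_times = c(10, 20, 50, 100, 200),
                       group_sizes = c(4, 4),
                       n_kinases = 50,
                       peptides_per_kinase = c(6, 12),
                       planted_kinases = character(),
                       effect_size = 1.5,
                       noise_sd = 0.005,
                       baseline_slope_range = c(0.05, 0.5),
                       intercept = 0,
                       in_vitro_prob = 0.1,
                       seed = 1) {
  n_peptides <- check_count(n_peptides, "n_peptides")
  if (!is.numeric(exposure_times) || length(exposure_times) < 2L ||
      any(exposure_times <= 0) || any(diff(exposure_times) <= 0)) {
    abort("`exposure_times` must be >= 2 strictly positive, strictly increasing times")
  }
  if (length(group_sizes) != 2L) {
    abort("`group_sizes` must be a pair of counts (condition, control)")
  }
  group_sizes <- c(check_count(group_sizes[1], "group_sizes[1]"),
                   check_count(group_sizes[2], "group_sizes[2]"))
  n_kinases <- check_count(n_kinases, "n_kinases")
  if (!length(peptides_per_kinase) %in% 1:2) {
    abort("`peptides_per_kinase` must be a count or a range of counts")
  }
  peptides_per_kinase <- range(vapply(
    seq_along(peptides_per_kinase),
    function(i) check_count(peptides_per_kinase[i], "peptides_per_kinase"),
    integer(1)
  ))
  if (peptides_per_kinase[2] > n_peptides) {
    abort("`peptides_per_kinase` cannot exceed `n_peptides` (peptide pool size)")
  }
  effect_size <- check_number(effect_size, "effect_size", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  if (length(baseline_slope_range) != 2L || any(baseline_slope_range <= 0) ||
      baseline_slope_range[1] > baseline_slope_range[2]) {
    abort("`baseline_slope_range` must be an increasing pair of positive slopes")
  }
  intercept <- check_number(intercept, "intercept", min = 0)
  in_vitro_prob <- check_number(in_vitro_prob, "in_vitro_prob", 0, 1)
  seed <- check_count(seed, "seed", min = 0)

  kinase_ids <- sprintf("K%0*d", max(2L, nchar(n_kinases)), seq_len(n_kinases))
  if (is.numeric(planted_kinases) && length(planted_kinases) == 1L) {
    k <- check_count(planted_kinases, "planted_kinases", min = 0)
    if (k > n_kinases) abort("`planted_kinases` count exceeds `n_kinases`")
    planted_kinases <- with_stream(seed, "planted",
                                   sort(sample(kinase_ids, k)))
  } else {
    planted_kinases <- as.character(planted_kinases)
    if (!all(planted_kinases %in% kinase_ids)) {
      abort("`planted_kinases` contains ids outside the simulated kinase pool")
    }
  }

  structure(
    list(
      n_peptides = n_peptides,
      exposure_times = as.numeric(exposure_times),
      group_sizes = group_sizes,
      n_kinases = n_kinases,
      peptides_per_kinase = peptides_per_kinase,
      planted_kinases = planted_kinases,
      effect_size = effect_size,
      noise_sd = noise_sd,
      baseline_slope_range = as.numeric(baseline_slope_range),
      intercept = intercept,
      in_vitro_prob = in_vitro_prob,
      seed = seed,
      kinase_ids = kinase_ids,
      peptide_ids = sprintf("P%0*d", max(3L, nchar(n_peptides)),
                            seq_len(n_peptides))
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d peptides, exposures {%s} ms, groups %d vs %d\n",
              x$n_peptides, paste(x$exposure_times, collapse = ", "),
              x$group_sizes[1], x$group_sizes[2]))
  cat(sprintf("  %d kinases (%d planted at effect %.2f pooled SD), noise_sd %.4g, seed %d\n",
              x$n_kinases, length(x$planted_kinases), x$effect_size,
              x$noise_sd, x$seed))
  invisible(x)
}

# SD multiplier translating per-reading noise into OLS-slope noise for a
# given exposure design: Var(slope_hat) = noise_sd^2 * factor^2 when each
# reading at time t has SD noise_sd * t and the fit includes an intercept.
slope_sd_factor <- function(times) {
  w <- (times - mean(times)) / sum((times - mean(times))^2)
  sqrt(sum(w^2 * times^2))
}

#' Generate a synthetic kinase candidate table
#'
#' Emulates the structure of a homology-score candidate table: each kinase
#' receives a set of candidate peptides, each with a prediction score (spread
#' across the retention boundary of 300), a per-peptide rank in 1..20, and an
#' in-vitro flag (in-vitro-confirmed targets carry rank 0). Every kinase is
#' guaranteed at least one row that passes the default retention filter
#' (score > 300 and rank <= 12, or in-vitro), so every simulated kinase is
#' scoreable downstream; in particular every planted kinase has at least one
#' retained peptide.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `kinase_id`, `peptide_id`, `score`, `rank`,
#'   `in_vitro`.
#' @export
simulate_kinase_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "kinase_map", {
    rows <- purrr::map(config$kinase_ids, function(kid) {
      n_pep <- if (config$peptides_per_kinase[1] == config$peptides_per_kinase[2]) {
        config$peptides_per_kinase[1]
      } else {
        sample(config$peptides_per_kinase[1]:config$peptides_per_kinase[2], 1L)
      }
      peptides <- sample(config$peptide_ids, n_pep)
      in_vitro <- runif(n_pep) < config$in_vitro_prob
      rank <- ifelse(in_vitro, 0L, sample(1:20, n_pep, replace = TRUE))
      score <- round(runif(n_pep, 100, 500), 1)
      retained <- in_vitro | (score > 300 & rank <= 12)
      if (!any(retained)) {
        # guarantee one retained candidate so the kinase is scoreable
        score[1] <- round(runif(1, 310, 500), 1)
        rank[1] <- sample(1:12, 1L)
        in_vitro[1] <- FALSE
      }
      tibble(kinase_id = kid, peptide_id = peptides,
             score = score, rank = as.integer(rank), in_vitro = in_vitro)
    })
    bind_rows(rows) %>% arrange(.data$kinase_id, .data$peptide_id)
  })
}

# Retention filter used both by the generator's ground truth and by
# build_kinase_map(); kept in one place so the two can never drift apart.
retention_rule <- function(candidates, score_min = 300, max_rank = 12) {
  candidates$in_vitro |
    (candidates$score > score_min &
       candidates$rank >= 1 & candidates$rank <= max_rank)
}

#' Generate a synthetic kinome-array experiment
#'
#' Simulates per-spot fluorescence series for every (sample, peptide) pair.
#' The reading at exposure `t` is `intercept + slope * t + N(0, noise_sd*t)`.
#' Peptides that are retained targets of a planted kinase have their
#' condition-group slope multiplied so that the reduced per-peptide value
#' (log2 of 100 x slope) is higher in the condition group by
#' `effect_size` x the per-peptide value SD, in expectation. All other
#' peptides behave identically in both groups.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{signals}{long tibble: `sample_id`, `group`, `peptide_id`,
#'       `exposure_ms`, `signal`.}
#'     \item{candidates}{the kinase candidate table from
#'       [simulate_kinase_map()] (same stream, so identical to calling it
#'       directly).}
#'     \item{truth}{ground truth: per-kinase planted shifts, per-peptide
#'       baseline slopes and planted flags, and the retained
#'       kinase-to-peptide assignment.}
#'   }
#' @export
#' @examples
#' sim <- simulate_array_experiment(sim_config(seed = 7))
#' head(sim$signals)
simulate_array_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  candidates <- simulate_kinase_map(config)
  retained <- candidates[retention_rule(candidates), c("kinase_id", "peptide_id")]
  planted_peptides <- sort(unique(
    retained$peptide_id[retained$kinase_id %in% config$planted_kinases]
  ))
  for (kid in config$planted_kinases) {
    if (!any(retained$kinase_id == kid)) {
      abort(sprintf("planted kinase %s has no retained peptide", kid))
    }
  }

  n1 <- config$group_sizes[1]
  n2 <- config$group_sizes[2]
  samples <- tibble(
    sample_id = sprintf("S%d", seq_len(n1 + n2)),
    group = rep(c("condition", "control"), c(n1, n2))
  )

  with_stream(config$seed, "signals", {
    base_slope <- runif(config$n_peptides,
                        config$baseline_slope_range[1],
                        config$baseline_slope_range[2])
    # per-peptide SD of the reduced value implied by the noise model
    # (delta method on log2(100 * slope_hat))
    value_sd <- config$noise_sd * slope_sd_factor(config$exposure_times) /
      (base_slope * log(2))
    planted <- config$peptide_ids %in% planted_peptides
    cond_mult <- ifelse(planted, 2^(config$effect_size * value_sd), 1)

    grid <- tidyr::expand_grid(
      sample_id = samples$sample_id,
      peptide_id = config$peptide_ids,
      exposure_ms = config$exposure_times
    ) %>%
      left_join(samples, by = "sample_id")
    idx <- match(grid$peptide_id, config$peptide_ids)
    slope <- base_slope[idx] *
      ifelse(grid$group == "condition", cond_mult[idx], 1)
    grid$signal <- config$intercept + slope * grid$exposure_ms +
      rnorm(nrow(grid), 0, config$noise_sd * grid$exposure_ms)

    truth <- list(
      kinases = tibble(
        kinase_id = config$kinase_ids,
        planted = config$kinase_ids %in% config$planted_kinases,
        shift = ifelse(config$kinase_ids %in% config$planted_kinases,
                       config$effect_size, 0)
      ),
      peptides = tibble(
        peptide_id = config$peptide_ids,
        base_slope = base_slope,
        value_sd = value_sd,
        planted = planted
      ),
      assignment = retained,
      planted_kinases = config$planted_kinases
    )

    list(
      signals = grid %>%
        select("sample_id", "group", "peptide_id", "exposure_ms", "signal") %>%
        arrange(.data$sample_id, .data$peptide_id, .data$exposure_ms),
      candidates = candidates,
      truth = truth
    )
  })
}

#' Generate a random connected interaction network
#'
#' Builds an undirected, self-loop-free protein-interaction edge list that is
#' connected by construction: a uniform random spanning tree skeleton first,
#' then extra edges sampled uniformly from the remaining pairs until the
#' requested density is reached. Edges carry an interaction-type label
#' (positive / negative / context-dependent / unspecified) used for
#' reporting only.
#'
#' @param n_nodes Number of nodes (>= 2); ignored when `nodes` is given.
#' @param density Fraction of all possible node pairs that are edges; must
#'   yield at least `n_nodes - 1` edges.
#' @param seed RNG seed.
#' @param nodes Optional character vector of node identifiers (e.g. kinase
#'   ids plus interactor ids).
#' @return A tibble with columns `node_a`, `interaction`, `node_b`.
#' @export
simulate_interaction_network <- function(n_nodes, density = 0.05, seed = 1,
                                         nodes = NULL) {
  if (is.null(nodes)) {
    n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
    nodes <- sprintf("N%0*d", max(2L, nchar(n_nodes)), seq_len(n_nodes))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) abort("`nodes` must be unique identifiers")
    n_nodes <- length(nodes)
    if (n_nodes < 2L) abort("`n_nodes` must be >= 2")
  }
  density <- check_number(density, "density", min = 0, max = 1)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  n_edges <- round(density * n_pairs)
  if (n_edges < n_nodes - 1) {
    abort(sprintf(
      "`density` = %g yields %d edges; a connected graph on %d nodes needs >= %d",
      density, n_edges, n_nodes, n_nodes - 1
    ))
  }

  with_stream(seed, "network", {
    ord <- sample(n_nodes)
    tree <- cbind(ord[vapply(2:n_nodes, function(i) sample(i - 1L, 1L),
                             integer(1))],
                  ord[2:n_nodes])
    tree <- t(apply(tree, 1, sort))
    all_pairs <- t(combn(n_nodes, 2L))
    key <- function(m) paste(m[, 1], m[, 2])
    pool <- all_pairs[!(key(all_pairs) %in% key(tree)), , drop = FALSE]
    n_extra <- n_edges - nrow(tree)
    extra <- pool[sample(nrow(pool), n_extra), , drop = FALSE]
    edges <- rbind(tree, extra)
    tibble(
      node_a = nodes[edges[, 1]],
      interaction = sample(
        c("positive", "negative", "context-dependent", "unspecified"),
        nrow(edges), replace = TRUE, prob = c(0.3, 0.2, 0.1, 0.4)
      ),
      node_b = nodes[edges[, 2]]
    ) %>%
      arrange(.data$node_a, .data$node_b)
  })
}

#' Generate a synthetic phosphosite intensity table with pathway annotation
#'
#' Emulates site-level corrected reporter-ion intensities on the log2 scale:
#' two comparison groups, per-site baseline levels, and a positive planted
#' shift for every site catalyzed by a kinase belonging to a planted
#' pathway. Kinase-to-site and kinase-to-pathway annotations are drawn at
#' random; a configurable fraction of sites has no experimentally defined
#' catalyzing kinase at all (such sites can never support a pathway).
#'
#' @param n_sites,n_kinases,n_pathways Counts of phosphosites, kinases and
#'   pathways.
#' @param planted_pathways Pathways whose member kinases' substrate sites are
#'   shifted: a character vector of pathway ids or a single count to sample.
#' @param seed RNG seed.
#' @param group_sizes Integer pair of group sizes (default 4 and 4).
#' @param effect_size Planted shift in units of `noise_sd` (default 3).
#' @param noise_sd Within-group SD of log2 intensity (default 1).
#' @param annotated_frac Fraction of sites with >= 1 catalyzing kinase
#'   (default 0.8).
#' @return A list with `intensities` (long tibble: `site_id`, `sample_id`,
#'   `group`, `log_intensity`), `site_kinases` (`site_id`, `kinase_id`),
#'   `pathways` (`pathway_id`, `kinase_id`), and `truth` (differential site
#'   ids, planted pathway ids, planted kinase ids).
#' @export
simulate_phosphosite_table <- function(n_sites, n_kinases, n_pathways,
                                       planted_pathways = character(),
                                       seed = 1,
                                       group_sizes = c(4, 4),
                                       effect_size = 3,
                                       noise_sd = 1,
                                       annotated_frac = 0.8) {
  n_sites <- check_count(n_sites, "n_sites")
  n_kinases <- check_count(n_kinases, "n_kinases")
  n_pathways <- check_count(n_pathways, "n_pathways")
  group_sizes <- c(check_count(group_sizes[1], "group_sizes[1]"),
                   check_count(group_sizes[2], "group_sizes[2]"))
  effect_size <- check_number(effect_size, "effect_size", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  annotated_frac <- check_number(annotated_frac, "annotated_frac", 0, 1)

  site_ids <- sprintf("site%0*d", max(4L, nchar(n_sites)), seq_len(n_sites))
  kinase_ids <- sprintf("PK%0*d", max(2L, nchar(n_kinases)), seq_len(n_kinases))
  pathway_ids <- sprintf("PW%0*d", max(2L, nchar(n_pathways)),
                         seq_len(n_pathways))

  with_stream(seed, "phosphosites", {
    if (is.numeric(planted_pathways) && length(planted_pathways) == 1L) {
      k <- check_count(planted_pathways, "planted_pathways", min = 0)
      if (k > n_pathways) abort("`planted_pathways` count exceeds `n_pathways`")
      planted_pathways <- sort(sample(pathway_ids, k))
    } else {
      planted_pathways <- as.character(planted_pathways)
      if (!all(planted_pathways %in% pathway_ids)) {
        abort("`planted_pathways` contains ids outside the pathway pool")
      }
    }

    pathways <- bind_rows(purrr::map(kinase_ids, function(kid) {
      tibble(pathway_id = sample(pathway_ids, sample(1:2, 1L)),
             kinase_id = kid)
    }))
    # a planted pathway with no member kinase would be untestable: give it one
    for (pw in setdiff(planted_pathways, pathways$pathway_id)) {
      pathways <- bind_rows(pathways,
                            tibble(pathway_id = pw,
                                   kinase_id = sample(kinase_ids, 1L)))
    }
    pathways <- pathways %>%
      distinct() %>%
      arrange(.data$pathway_id, .data$kinase_id)

    site_kinases <- bind_rows(purrr::map(site_ids, function(sid) {
      if (runif(1) >= annotated_frac) return(NULL)
      tibble(site_id = sid, kinase_id = sample(kinase_ids, sample(1:3, 1L)))
    })) %>% arrange(.data$site_id, .data$kinase_id)

    planted_kinases <- sort(unique(
      pathways$kinase_id[pathways$pathway_id %in% planted_pathways]
    ))
    differential_sites <- sort(unique(
      site_kinases$site_id[site_kinases$kinase_id %in% planted_kinases]
    ))

    n1 <- group_sizes[1]
    n2 <- group_sizes[2]
    samples <- tibble(sample_id = sprintf("S%d", seq_len(n1 + n2)),
                      group = rep(c("condition", "control"), c(n1, n2)))
    base <- rnorm(n_sites, 20, 2)
    shift <- ifelse(site_ids %in% differential_sites,
                    effect_size * noise_sd, 0)

    intensities <- tidyr::expand_grid(site_id = site_ids,
                                      sample_id = samples$sample_id) %>%
      left_join(samples, by = "sample_id")
    idx <- match(intensities$site_id, site_ids)
    intensities$log_intensity <- base[idx] +
      shift[idx] * (intensities$group == "condition") +
      rnorm(nrow(intensities), 0, noise_sd)

    list(
      intensities = intensities %>%
        select("site_id", "sample_id", "group", "log_intensity") %>%
        arrange(.data$site_id, .data$sample_id),
      site_kinases = site_kinases,
      pathways = pathways,
      truth = list(
        differential_sites = differential_sites,
        planted_pathways = planted_pathways,
        planted_kinases = planted_kinases
      )
    )
  })
}
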