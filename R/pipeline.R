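# End-to-end driver: simulate -> process -> map -> score -> network ->
# pathways, with a machine-readable run report.

#' Run the full kinomic inference pipeline on a synthetic experiment
#'
#' Executes every stage in dependency order on data drawn from
#' [sim_config()]: signal generation, exposure-slope reduction and QC,
#' kinase-map construction, per-kinase scoring and activated calls,
#' seed-network expansion over a simulated interaction graph, and the
#' companion phosphosite/pathway ranking on a simulated reporter-intensity
#' table. Every stochastic stage derives its own stream from the config's
#' master seed, so an identical config yields byte-identical outputs and
#' report.
#'
#' When planted kinases exist, the phosphosite stage plants
#' `n_planted_pathways` pathways so the two arms of the pipeline carry a
#' consistent story; with no planted kinases the phosphosite table is null.
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations per kinase (default 1000).
#' @param r2_min,min_slope QC thresholds (defaults 0.90 and 0).
#' @param score_min,max_rank Map retention thresholds (defaults 300 and 12).
#' @param mks_min,mfs_min Activated-call thresholds (defaults 0 and 0.5).
#' @param alpha Phosphosite significance level (default 0.05).
#' @param max_nodes Exclusive network size cap (default 50).
#' @param top_k Pathways reported (default 5).
#' @param network_extra_nodes Non-kinase interactors added to the simulated
#'   graph (default 30).
#' @param network_density Edge density of the simulated graph (default
#'   0.06).
#' @param n_sites,n_pathways Size of the simulated phosphosite arm
#'   (defaults 400 sites, 23 pathways).
#' @param n_planted_pathways Planted pathways when the config plants
#'   kinases (default 2).
#' @param out_dir Optional directory: when given, every stage output is
#'   written there (TSV/SIF/GMT/JSON) together with the run report.
#' @return An object of class `kinact_run`: stage outputs plus `report`,
#'   a nested list with seeds, thresholds, per-stage record counts, the
#'   activated kinases, the network name and the top pathways.
#' @export
#' @examples
#' run <- run_pipeline(
#'   sim_config(n_peptides = 36, n_kinases = 8, planted_kinases = 2,
#'              seed = 11),
#'   n_perm = 200, n_sites = 60, n_pathways = 6
#' )
#' run$report$activated_kinases
run_pipeline <- function(config,
                         n_perm = 1000,
                         r2_min = 0.90, min_slope = 0,
                         score_min = 300, max_rank = 12,
                         mks_min = 0, mfs_min = 0.5,
                         alpha = 0.05,
                         max_nodes = 50, top_k = 5,
                         network_extra_nodes = 30,
                         network_density = 0.06,
                         n_sites = 400, n_pathways = 23,
                         n_planted_pathways = 2,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))

  sim <- simulate_array_experiment(config)
  values <- qc_filter(fit_exposure_slopes(sim$signals),
                      r2_min = r2_min, min_slope = min_slope)
  map <- build_kinase_map(sim$candidates, values,
                          score_min = score_min, max_rank = max_rank)
  scores <- score_kinases(values, map, n_perm = n_perm, seed = config$seed,
                          mks_min = mks_min, mfs_min = mfs_min)
  activated <- call_activated(scores$scores, mks_min, mfs_min)

  graph_nodes <- c(config$kinase_ids,
                   sprintf("X%02d", seq_len(network_extra_nodes)))
  edges <- simulate_interaction_network(
    nodes = graph_nodes, density = network_density,
    seed = derive_seed(config$seed, "pipeline_network"), n_nodes = NULL
  )
  network <- if (nrow(activated) > 0L) {
    expand_network(activated$kinase_id, edges, max_nodes = max_nodes)
  } else {
    NULL
  }

  phospho <- simulate_phosphosite_table(
    n_sites = n_sites, n_kinases = config$n_kinases,
    n_pathways = n_pathways,
    planted_pathways = if (length(config$planted_kinases) > 0L) {
      n_planted_pathways
    } else {
      character()
    },
    seed = derive_seed(config$seed, "pipeline_phospho"),
    group_sizes = config$group_sizes
  )
  diff <- differential_phosphosites(phospho$intensities, alpha = alpha)
  ranking <- rank_pathways(diff, phospho$site_kinases, phospho$pathways,
                           top_k = top_k)

  report <- list(
    package_version = as.character(utils::packageVersion("kinact")),
    seed = config$seed,
    orientation = list(condition = "condition", control = "control"),
    thresholds = list(
      r2_min = r2_min, min_slope = min_slope, score_min = score_min,
      max_rank = max_rank, mks_min = mks_min, mfs_min = mfs_min,
      alpha = alpha, max_nodes = max_nodes, n_perm = n_perm
    ),
    counts = list(
      signals = nrow(sim$signals),
      peptides = config$n_peptides,
      qc_passing_peptides = length(qc_passing(values)),
      candidate_rows = nrow(sim$candidates),
      retained_pairs = nrow(map),
      kinases_scored = nrow(scores$scores),
      kinases_activated = nrow(activated),
      graph_edges = nrow(edges),
      network_members = if (is.null(network)) 0L else nrow(network$members),
      phosphosites = length(unique(phospho$intensities$site_id)),
      sites_increased = length(diff$increased),
      sites_decreased = length(diff$decreased)
    ),
    activated_kinases = activated$kinase_id,
    network_name = if (is.null(network)) NA_character_ else network$name,
    network_halt = if (is.null(network)) NA_character_ else network$halt_reason,
    top_pathways = as.list(setNames(ranking$n_sites, ranking$pathway_id))
  )

  run <- structure(
    list(
      config = config, signals = sim$signals, truth = sim$truth,
      candidates = sim$candidates, values = values, map = map,
      scores = scores, activated = activated,
      edges = edges, network = network,
      phospho = phospho, diff = diff, ranking = ranking,
      report = report
    ),
    class = "kinact_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write every stage output of a pipeline run to a directory
#'
#' @param run A `kinact_run` from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "kinact_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_signals(run$signals, p("signals.tsv"))
  write_candidates(run$candidates, p("candidates.tsv"))
  write_values_wide(run$values, p("peptide_values.tsv"))
  readr::write_tsv(run$map, p("kinase_map.tsv"))
  readr::write_tsv(run$scores$scores, p("kinase_scores.tsv"))
  write_sif(run$edges, p("interactions.sif"))
  if (!is.null(run$network)) {
    write_sif(run$network$edges, p("network.sif"))
    readr::write_tsv(run$network$members, p("network_members.tsv"))
  }
  write_phosphosites(run$phospho$intensities, p("phosphosites.tsv"))
  readr::write_tsv(run$diff$stats, p("phosphosite_stats.tsv"))
  write_gmt(run$phospho$pathways, p("pathways.gmt"))
  readr::write_tsv(run$ranking, p("pathway_ranking.tsv"))
  write_truth_json(run$truth[c("planted_kinases")], p("ground_truth.json"))
  write_truth_json(run$report, p("run_report.json"))
  invisible(out_dir)
}

#' @export
print.kinact_run <- function(x, ...) {
  r <- x$report
  cat("<kinact_run>\n")
  cat(sprintf("  %d peptides (%d pass QC), %d kinases scored, %d activated\n",
              r$counts$peptides, r$counts$qc_passing_peptides,
              r$counts$kinases_scored, r$counts$kinases_activated))
  cat(sprintf("  network: %s (halt: %s); %d/%d phosphosites increased\n",
              r$network_name, r$network_halt,
              r$counts$sites_increased, r$counts$phosphosites))
  invisible(x)
}
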