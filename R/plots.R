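# Diagnostic plots for the main result types.

#' Plot kinase scores: MKS against Mean Final Score
#'
#' One point per kinase; the dashed lines mark the activated-call
#' thresholds (MKS > 0, MFS > 0.5) so activated kinases sit in the
#' upper-right region.
#'
#' @param object A `kinase_scores` from [score_kinases()].
#' @param label_activated Label activated kinases (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinase_scores <- function(object, label_activated = TRUE, ...) {
  df <- object$scores %>% filter(!is.na(.data$mks), !is.na(.data$mfs))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mks, y = .data$mfs)) +
    ggplot2::geom_vline(xintercept = object$mks_min, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$mfs_min, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$activated), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "Mean Kinase Statistic (condition - control)",
      y = "Mean Final Score (-log10 scale)",
      colour = "activated"
    ) +
    ggplot2::theme_minimal()
  if (label_activated && any(df$activated)) {
    p <- p + ggplot2::geom_text(
      data = filter(df, .data$activated),
      ggplot2::aes(label = .data$kinase_id),
      vjust = -0.7, size = 3, colour = "firebrick"
    )
  }
  p
}

#' Plot an expanded seed network
#'
#' Fruchterman-Reingold layout with seed nodes emphasised and the naming
#' node annotated.
#'
#' @param object A `seed_network` from [expand_network()].
#' @param seed Layout RNG seed (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seed_network <- function(object, seed = 1, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = object$members$node)
  )
  layout <- with_stream(seed, "layout", igraph::layout_with_fr(g))
  nodes <- object$members %>%
    mutate(x = layout[, 1], y = layout[, 2])
  segs <- object$edges %>%
    left_join(select(nodes, node_a = "node", xa = "x", ya = "y"),
              by = "node_a") %>%
    left_join(select(nodes, node_b = "node", xb = "x", yb = "y"),
              by = "node_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role,
                   size = .data$degree_in_network)
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(seed = "firebrick",
                                            expansion = "steelblue")) +
    ggplot2::labs(title = sprintf("Network '%s' (halt: %s)",
                                  object$name, object$halt_reason)) +
    ggplot2::theme_void()
}

#' Volcano plot of differential phosphosites
#'
#' @param object A `phospho_diff` from [differential_phosphosites()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phospho_diff <- function(object, ...) {
  df <- object$stats %>% mutate(neglog10p = -log10(pmax(.data$p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_diff,
                                   y = .data$neglog10p,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      increased = "firebrick", decreased = "steelblue",
      unchanged = "grey60"
    )) +
    ggplot2::labs(x = "log2 difference (condition - control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a pathway ranking
#'
#' @param ranking Output of [rank_pathways()].
#' @return A ggplot.
#' @export
plot_pathway_ranking <- function(ranking) {
  check_columns(ranking, c("pathway_id", "n_sites"), "`ranking`")
  ggplot2::ggplot(
    ranking,
    ggplot2::aes(x = stats::reorder(.data$pathway_id, .data$n_sites),
                 y = .data$n_sites)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "differential sites catalyzed by member kinases") +
    ggplot2::theme_minimal()
}
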