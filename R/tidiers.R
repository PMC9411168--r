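# broom-style tidiers for fitted result objects.

#' Tidy a kinase score table
#'
#' @param x A `kinase_scores` object from [score_kinases()].
#' @param ... Unused.
#' @return The per-kinase tibble: `kinase_id`, `n_peptides`, `n_dropped`,
#'   `mks`, significance and specificity p-values and scores, `mfs`,
#'   `activated`, sorted by MFS then MKS descending.
#' @export
tidy.kinase_scores <- function(x, ...) {
  x$scores
}

#' @rdname tidy.kinase_scores
#' @export
glance.kinase_scores <- function(x, ...) {
  tibble(
    n_kinases = nrow(x$scores),
    n_activated = sum(x$scores$activated),
    n_condition = x$group_sizes[1],
    n_control = x$group_sizes[2],
    n_peptide_pool = x$n_pool,
    n_perm = x$n_perm,
    exact_significance = x$exact,
    singlicate = x$singlicate,
    seed = x$seed
  )
}

#' Tidy a seed network
#'
#' @param x A `seed_network` from [expand_network()].
#' @param ... Unused.
#' @return The member tibble: `node`, `role` (seed/expansion), `admission`
#'   (0 for seeds, then admission order), `degree_in_network`.
#' @export
tidy.seed_network <- function(x, ...) {
  x$members
}

#' @rdname tidy.seed_network
#' @export
glance.seed_network <- function(x, ...) {
  tibble(
    name = x$name,
    n_members = nrow(x$members),
    n_seeds = length(x$seeds),
    n_edges = nrow(x$edges),
    halt_reason = x$halt_reason,
    max_nodes = x$max_nodes
  )
}

#' Tidy differential phosphosite results
#'
#' @param x A `phospho_diff` from [differential_phosphosites()].
#' @param ... Unused.
#' @return The per-site statistics tibble (means, difference, t, df, p, q,
#'   direction).
#' @export
tidy.phospho_diff <- function(x, ...) {
  x$stats
}

#' @rdname tidy.phospho_diff
#' @export
glance.phospho_diff <- function(x, ...) {
  tibble(
    n_sites = nrow(x$stats),
    n_increased = length(x$increased),
    n_decreased = length(x$decreased),
    test = x$test,
    adjust = x$adjust,
    alpha = x$alpha
  )
}
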