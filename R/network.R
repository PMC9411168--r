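# Seed-node network expansion.
#
# Activated kinases are used as seed nodes on a literature-style
# protein-interaction edge list. Each seed starts its own sub-network;
# non-member nodes are admitted one at a time, preferring the candidate
# with the most edges to the current members (ties: more edges to the
# seeds, then lexicographic id). Expansion halts when all per-seed
# sub-networks have merged into one, when admitting another node would
# bring the membership to the size cap, or when no remaining node touches
# a member. The finished network is named after its most interconnected
# member node.

#' Expand seed kinases into an interaction sub-network
#'
#' Grows a sub-network from the seed nodes by iteratively admitting the
#' outside node with the greatest connectivity: most edges to current
#' members first and, under the default tiebreak, most edges to the seed
#' set second (the `"seeds"` tiebreak swaps these two criteria); remaining
#' ties go to the lexicographically smallest id. Adjacent seeds belong to
#' the same sub-network from the start, and after every admission
#' sub-networks sharing a member are merged.
#'
#' Halting: `"intersected"` when (with >= 2 seeds) all per-seed sub-networks
#' have merged into one connected component; `"size_limit"` when one more
#' admission would bring the membership to `max_nodes` (the cap is
#' exclusive: a finished network always has fewer than `max_nodes`
#' members); `"exhausted"` when no outside node has an edge to any member.
#'
#' @param seeds Character vector of seed node ids (e.g. activated kinases);
#'   seeds absent from the graph are dropped with a message, and at least
#'   one must be present.
#' @param edges Edge-list tibble with columns `node_a`, `node_b` and
#'   optionally `interaction` (type labels are carried through for
#'   reporting only). The graph is undirected; self-loops and duplicate
#'   edges are rejected.
#' @param max_nodes Exclusive cap on network size (default 50).
#' @param tiebreak `"members"` (default) or `"seeds"`: which connectivity
#'   count is the primary admission criterion.
#' @return An object of class `seed_network` with the member table
#'   (node, role, admission order, degree inside the network), the induced
#'   edge set, the halt reason, and the naming node.
#' @export
#' @examples
#' edges <- tibble::tibble(node_a = c("A", "B"), node_b = c("B", "C"))
#' net <- expand_network(c("A", "C"), edges)
#' net$halt_reason
expand_network <- function(seeds, edges, max_nodes = 50,
                           tiebreak = c("members", "seeds")) {
  tiebreak <- match.arg(tiebreak)
  check_columns(edges, c("node_a", "node_b"), "`edges`")
  max_nodes <- check_count(max_nodes, "max_nodes", min = 2)
  if (length(seeds) == 0L) abort("`seeds` must be non-empty")
  if (any(edges$node_a == edges$node_b)) abort("edge list contains self-loops")
  ekey <- paste(pmin(edges$node_a, edges$node_b),
                pmax(edges$node_a, edges$node_b))
  if (anyDuplicated(ekey)) abort("edge list contains duplicate edges")

  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  adj <- build_adjacency(edges, nodes)
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    inform(sprintf("dropping %d seed(s) absent from the graph: %s",
                   length(missing), paste(missing, collapse = ", ")))
  }
  seeds_in <- sort(intersect(seeds, nodes))
  if (length(seeds_in) == 0L) abort("no seed is present in the graph")

  members <- seeds_in
  order_admitted <- seq_along(seeds_in) * 0L # seeds carry admission order 0
  multi <- length(seeds_in) > 1L
  halt <- NULL
  step <- 0L

  n_components <- function(mem) {
    g <- igraph::graph_from_data_frame(
      edges[edges$node_a %in% mem & edges$node_b %in% mem, c("node_a", "node_b")],
      directed = FALSE,
      vertices = data.frame(name = mem)
    )
    igraph::components(g)$no
  }

  if (multi && n_components(members) == 1L) halt <- "intersected"

  while (is.null(halt)) {
    cand <- setdiff(unlist(adj[members], use.names = FALSE), members)
    if (length(cand) == 0L) {
      halt <- "exhausted"
      break
    }
    cand <- sort(unique(cand))
    to_members <- vapply(cand, function(v) sum(adj[[v]] %in% members),
                         integer(1))
    to_seeds <- vapply(cand, function(v) sum(adj[[v]] %in% seeds_in),
                       integer(1))
    ord <- if (tiebreak == "members") {
      order(-to_members, -to_seeds, cand)
    } else {
      order(-to_seeds, -to_members, cand)
    }
    best <- cand[ord[1]]
    if (length(members) + 1L >= max_nodes) {
      halt <- "size_limit"
      break
    }
    step <- step + 1L
    members <- c(members, best)
    order_admitted <- c(order_admitted, step)
    if (multi && n_components(members) == 1L) halt <- "intersected"
  }

  sub_edges <- edges[edges$node_a %in% members & edges$node_b %in% members, ,
                     drop = FALSE]
  deg <- vapply(members, function(v) {
    sum(sub_edges$node_a == v) + sum(sub_edges$node_b == v)
  }, integer(1))
  member_tbl <- tibble(
    node = members,
    role = ifelse(members %in% seeds_in, "seed", "expansion"),
    admission = order_admitted,
    degree_in_network = deg
  )
  net <- structure(
    list(
      members = member_tbl,
      edges = as_tibble(sub_edges),
      seeds = seeds_in,
      halt_reason = halt,
      max_nodes = max_nodes,
      tiebreak = tiebreak,
      name = NA_character_
    ),
    class = "seed_network"
  )
  net$name <- name_network(net)
  net
}

build_adjacency <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(...) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]
    b <- edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Name a network by its most interconnected member
#'
#' Returns the member with the highest degree inside the induced
#' sub-network; ties are broken in favour of seed nodes, then by
#' lexicographic id.
#'
#' @param network A `seed_network` from [expand_network()].
#' @return A single node id.
#' @export
name_network <- function(network) {
  stopifnot(inherits(network, "seed_network"))
  m <- network$members
  if (nrow(m) == 0L) abort("network has no members")
  ord <- order(-m$degree_in_network, m$role != "seed", m$node)
  m$node[ord[1]]
}

#' @export
print.seed_network <- function(x, ...) {
  cat(sprintf(
    "<seed_network> '%s': %d members (%d seeds), %d edges, halted: %s\n",
    x$name, nrow(x$members), length(x$seeds), nrow(x$edges), x$halt_reason
  ))
  print(head(x$members, 10))
  invisible(x)
}
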