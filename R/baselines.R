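#' Flow hierarchy
#'
#' Fraction of edges not participating in any directed cycle.  An edge lies
#' on a cycle exactly when both endpoints belong to the same strongly
#' connected component (a self-loop always does), so
#' `FH = |{(u,v) : scc(u) != scc(v)}| / |E|`.  Equals 1 precisely for
#' acyclic graphs.
#'
#' @param g a directed graph with at least one edge.
#' @return numeric in \[0, 1\].
#' @examples
#' g <- make_digraph(c("a", "b", "a", "b"), c("b", "a", "c", "d"))
#' flow_hierarchy(g)  # 0.5
#' @export
flow_hierarchy <- function(g) {
  g <- as_digraph(g)
  m <- igraph::ecount(g)
  if (m == 0L) stop("flow hierarchy undefined for empty edge set")
  memb <- find_sccs(g)$membership
  el <- edge_pairs(g)
  sum(memb[el[, 1L]] != memb[el[, 2L]]) / m
}

#' Reaching centrality
#'
#' `local_reaching_centrality(g, i)` is the fraction of the other nodes
#' reachable from `i` along directed paths.  The global measure aggregates
#' the gaps to the best reacher:
#' `GRC = sum_i (C_max - C_i) / (|V| - 1)`,
#' where `C_max` is the largest local reaching centrality in the graph.
#' GRC equals 1 only for a star (one hub pointing to every other node and
#' no further edges); even perfect multi-level hierarchies score below 1.
#'
#' @param g a directed graph with at least two nodes.
#' @param i a node label.
#' @return numeric in \[0, 1\].
#' @examples
#' star <- gen_star(5)
#' global_reaching_centrality(star)  # 1
#' @export
local_reaching_centrality <- function(g, i) {
  g <- as_digraph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("reaching centrality needs at least two nodes")
  if (!i %in% igraph::V(g)$name) stop("node '", i, "' not in graph")
  reach <- igraph::subcomponent(g, i, mode = "out")
  (length(reach) - 1L) / (n - 1L)
}

#' @rdname local_reaching_centrality
#' @export
global_reaching_centrality <- function(g) {
  g <- as_digraph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("reaching centrality needs at least two nodes")
  # one BFS per node; sizes of out-components
  cr <- vapply(igraph::V(g)$name, function(v) {
    (length(igraph::subcomponent(g, v, mode = "out")) - 1L) / (n - 1L)
  }, numeric(1))
  sum(max(cr) - cr) / (n - 1L)
}

#' Agony-based hierarchy score
#'
#' Given an integer ranking of the nodes (0 = top of the hierarchy, larger =
#' lower), an edge is *backward* when it does not descend the hierarchy,
#' i.e. when `rank(source) >= rank(target)`; equal ranks count as backward,
#' otherwise the all-equal ranking would trivially be optimal for any graph.
#' The score is `1 - |backward| / |E|`.
#'
#' `agony_score()` handles the optimal-ranking case for acyclic graphs
#' only: a topological order has no backward edges, so the score is exactly
#' 1.  Minimizing agony over rankings of a cyclic graph requires a dedicated
#' solver and is not implemented; supply a ranking instead.
#'
#' @param g a directed graph with at least one edge.
#' @param ranking named integer vector covering every node of `g`.
#' @return numeric in \[0, 1\].
#' @examples
#' chain <- make_digraph(c("0", "1"), c("1", "2"))
#' agony_score_from_ranking(chain, c("0" = 0, "1" = 1, "2" = 2))  # 1
#' agony_score(chain)                                             # 1
#' @export
agony_score_from_ranking <- function(g, ranking) {
  g <- as_digraph(g)
  m <- igraph::ecount(g)
  if (m == 0L) stop("agony undefined for empty edge set")
  nm <- igraph::V(g)$name
  if (!all(nm %in% names(ranking))) {
    stop("ranking missing for node(s): ",
         paste(utils::head(setdiff(nm, names(ranking)), 5L), collapse = ", "))
  }
  el <- edge_pairs(g)
  backward <- sum(ranking[el[, 1L]] >= ranking[el[, 2L]])
  1 - backward / m
}

#' @rdname agony_score_from_ranking
#' @export
agony_score <- function(g) {
  g <- as_digraph(g)
  if (igraph::ecount(g) == 0L) stop("agony undefined for empty edge set")
  if (!is_dag(g)) {
    stop("agony minimization not implemented for cyclic graphs; ",
         "supply a ranking to agony_score_from_ranking()")
  }
  ord <- igraph::topo_sort(g, mode = "out")
  ranking <- stats::setNames(seq_along(ord) - 1L, igraph::V(g)$name[ord])
  agony_score_from_ranking(g, ranking)
}
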