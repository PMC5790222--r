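#' Condense a directed graph onto its strongly connected components
#'
#' Step 1 of the arborescence reduction.  Every strongly connected component
#' is collapsed into a single "super node" that inherits all incoming and
#' outgoing connections of its members; intra-component edges and self-loops
#' disappear, and parallel inter-component edges merge into one.  The result
#' is always a simple directed acyclic graph.
#'
#' Component identifiers are human-readable: a singleton keeps its node
#' label, a component with two or more members is named `scc:<smallest
#' member label>`.
#'
#' @param g a directed graph.
#' @return an object of class `condensed_dag`: a list with
#'   \describe{
#'     \item{dag}{the condensed graph (igraph, acyclic, simple)}
#'     \item{partition}{the [find_sccs()] result for `g`}
#'     \item{component_label}{character vector, component index -> identifier}
#'     \item{members}{named list, identifier -> original member labels}
#'     \item{n_original_edges}{distinct edge count of `g` (self-loops included)}
#'   }
#' @examples
#' g <- make_digraph(c("a", "b", "c", "c"), c("b", "a", "a", "d"))
#' condense(g)
#' @export
condense <- function(g) {
  g <- as_digraph(g)
  part <- find_sccs(g)
  n_comp <- length(part$components)
  lab <- vapply(part$components, function(members) {
    if (length(members) >= 2L) paste0("scc:", min(members)) else members
  }, character(1))
  dag <- igraph::make_empty_graph(n = n_comp, directed = TRUE)
  dag <- igraph::set_vertex_attr(dag, "name", value = lab)
  if (igraph::ecount(g) > 0L) {
    el <- edge_pairs(g)
    cu <- part$membership[el[, 1L]]
    cv <- part$membership[el[, 2L]]
    keep <- cu != cv
    if (any(keep)) {
      pair <- unique(cbind(cu[keep], cv[keep]))
      dag <- igraph::add_edges(dag, rbind(lab[pair[, 1L]], lab[pair[, 2L]]))
    }
  }
  structure(list(dag = dag,
                 partition = part,
                 component_label = lab,
                 members = stats::setNames(part$components, lab),
                 n_original_edges = igraph::ecount(g)),
            class = "condensed_dag")
}

#' @export
print.condensed_dag <- function(x, ...) {
  n_super <- sum(lengths(x$members) >= 2L)
  cat("Condensed DAG: ", igraph::vcount(x$dag), " components (",
      n_super, " non-trivial), ", igraph::ecount(x$dag), " edges\n", sep = "")
  invisible(x)
}

#' Out-closeness centrality
#'
#' For every node `i`, the reciprocal of the sum of shortest-path hop
#' distances from `i` to all nodes reachable from it; nodes that reach
#' nothing (leaves) score 0.  Nodes close to a root reach more nodes over
#' longer paths, so they have *lower* out-closeness — which is why the
#' rooting step keeps the incoming edge from the lowest-closeness parent.
#'
#' @param g a directed graph (typically the condensed DAG).
#' @return named numeric vector of nonnegative closeness values.
#' @examples
#' p <- make_digraph(c("0", "1"), c("1", "2"))
#' out_closeness(p)  # 1/3, 1, 0
#' @export
out_closeness <- function(g) {
  g <- as_digraph(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(g, mode = "out")
  d[!is.finite(d)] <- 0
  tot <- rowSums(d)
  cl <- ifelse(tot > 0, 1 / tot, 0)
  stats::setNames(as.numeric(cl), igraph::V(g)$name)
}

#' Root a condensed DAG into an arborescence forest
#'
#' Step 2 of the arborescence reduction.  Every node with in-degree greater
#' than one keeps only the incoming edge whose source has minimal
#' out-closeness (computed on the condensed DAG); ties are broken toward the
#' lexicographically smallest source identifier, a choice that can alter the
#' forest's shape but provably never its edge count.  Nodes with in-degree 0
#' are exactly the forest roots, so the forest always has
#' `vcount - n_roots` edges no matter which ties occur.
#'
#' @param cd a `condensed_dag` from [condense()], or any acyclic directed
#'   graph.
#' @return list with `forest` (igraph, an arborescence forest), `roots`
#'   (character vector of in-degree-0 identifiers) and `removed` (two-column
#'   character matrix of deleted edges).
#' @export
root_forest <- function(cd) {
  dag <- if (inherits(cd, "condensed_dag")) cd$dag else as_digraph(cd)
  if (!is_dag(dag)) {
    stop("input contains a directed cycle; run condense() first")
  }
  cl <- out_closeness(dag)
  nm <- igraph::V(dag)$name
  removed_idx <- integer(0)
  if (igraph::ecount(dag) > 0L) {
    el <- edge_pairs(dag)
    for (v in nm) {
      inc <- which(el[, 2L] == v)
      if (length(inc) <= 1L) next
      src <- el[inc, 1L]
      best <- inc[cl[src] == min(cl[src])]
      # tie-break: lexicographically smallest source label
      keep <- best[order(el[best, 1L])][1L]
      removed_idx <- c(removed_idx, setdiff(inc, keep))
    }
  }
  forest <- if (length(removed_idx)) {
    igraph::delete_edges(dag, removed_idx)
  } else dag
  indeg <- igraph::degree(forest, mode = "in")
  list(forest = forest,
       roots = nm[indeg == 0L],
       removed = if (length(removed_idx)) {
         edge_pairs(dag)[removed_idx, , drop = FALSE]
       } else {
         matrix(character(0), ncol = 2L)
       })
}

#' Arborescence score of a directed graph
#'
#' The hierarchicalness measure at the heart of the package.  The graph is
#' reduced to an arborescence forest in three steps — condensation of
#' strongly connected components ([condense()]), rooting by minimal
#' out-closeness ([root_forest()]), and the score itself — and the score is
#' the fraction of the original edges that survive the reduction:
#' `A = |E*| / |E|`, with `|E*|` the forest's edge count and `|E|` the
#' distinct-edge count of the input (self-loops included).  It ranges from 0
#' (the graph is a single strongly connected component: no hierarchy) to 1
#' (the graph already is an arborescence forest: a perfect hierarchy).
#'
#' A closed form follows from the pipeline: `|E*| = |V*| - z`, where `|V*|`
#' is the number of strongly connected components and `z` the number of
#' components with no incoming edge in the condensed DAG.
#'
#' @param g a directed graph with at least one edge.
#' @return an object of class `arborescence_result` with fields
#'   `score`, `score_num`/`score_den` (the exact fraction), `n_nodes`,
#'   `n_edges`, `n_condensed_nodes`, `n_condensed_edges` (edge count of the
#'   condensed DAG), `n_forest_edges`, `roots`, `forest` (igraph over
#'   component identifiers), `members` (identifier -> original labels),
#'   `removed_in_condensation` and `removed_in_rooting` (edge matrices).
#' @examples
#' tri <- make_digraph(c("a", "b", "c"), c("b", "c", "a"))
#' arborescence_score(tri)$score  # 0: a single strongly connected component
#' @export
arborescence_score <- function(g) {
  g <- as_digraph(g)
  n_edges <- igraph::ecount(g)
  if (n_edges == 0L) stop("score undefined for empty edge set")
  cd <- condense(g)
  rooted <- root_forest(cd)
  n_forest <- igraph::ecount(rooted$forest)
  el <- edge_pairs(g)
  memb <- cd$partition$membership
  intra <- memb[el[, 1L]] == memb[el[, 2L]]
  # parallel inter-component edges merged by condensation also count as
  # removed there; recover them as original edges minus one per dag edge
  removed_cond <- el[intra, , drop = FALSE]
  structure(list(
    score = n_forest / n_edges,
    score_num = n_forest,
    score_den = n_edges,
    n_nodes = igraph::vcount(g),
    n_edges = n_edges,
    n_condensed_nodes = igraph::vcount(cd$dag),
    n_condensed_edges = igraph::ecount(cd$dag),
    n_forest_edges = n_forest,
    roots = rooted$roots,
    forest = rooted$forest,
    members = cd$members,
    condensed = cd,
    removed_in_condensation = removed_cond,
    removed_in_rooting = rooted$removed
  ), class = "arborescence_result")
}

#' @export
print.arborescence_result <- function(x, ...) {
  cat("Arborescence score: ", x$score_num, "/", x$score_den, " = ",
      format(x$score, digits = 6), "\n", sep = "")
  cat("  nodes: ", x$n_nodes,
      "  edges: ", x$n_edges,
      "  components: ", x$n_condensed_nodes,
      "  condensed edges: ", x$n_condensed_edges, "\n", sep = "")
  cat("  forest edges: ", x$n_forest_edges,
      "  roots: ", length(x$roots), " (",
      paste(utils::head(x$roots, 5L), collapse = ", "),
      if (length(x$roots) > 5L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}
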