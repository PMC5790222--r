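#' Build a directed graph from an edge table
#'
#' The universal input type of the package is a directed simple graph with
#' opaque string node labels: an edge is an ordered pair `(source, target)`,
#' and `(i, j)` and `(j, i)` are distinct edges.  Duplicate ordered pairs in
#' the input are merged (with a warning); self-loops are kept, since they
#' count toward the edge total of every hierarchy score even though they can
#' never be part of a hierarchy.
#'
#' @param from,to character vectors of equal length giving edge endpoints,
#'   or `from` may be a two-column matrix/data frame of endpoints.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node labels.
#' @return an [igraph::igraph] directed graph with named vertices.
#' @examples
#' g <- make_digraph(c("a", "b"), c("b", "c"))
#' igraph::ecount(g)
#' @export
make_digraph <- function(from, to = NULL, nodes = NULL) {
  if (is.null(to)) {
    m <- as.matrix(from)
    if (ncol(m) < 2L) stop("edge input needs two columns (source, target)")
    from <- as.character(m[, 1L])
    to <- as.character(m[, 2L])
  } else {
    from <- as.character(from)
    to <- as.character(to)
  }
  if (length(from) != length(to)) stop("'from' and 'to' differ in length")
  if (anyNA(from) || anyNA(to)) stop("edge endpoints must not be NA")
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) merged")
    from <- from[!dup]
    to <- to[!dup]
  }
  labels <- unique(c(from, to, as.character(nodes)))
  g <- igraph::make_empty_graph(n = length(labels), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  g
}

#' @rdname make_digraph
#' @param g a directed igraph object (named or not; unnamed vertices get
#'   their integer index as label).
#' @export
as_digraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (!igraph::is_directed(g)) stop("graph must be directed")
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  if (anyDuplicated(paste(el[, 1L], el[, 2L], sep = "\r"))) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
    warning("duplicate edges merged")
  }
  g
}

edge_pairs <- function(g) igraph::as_edgelist(g, names = TRUE)

#' Does the graph contain self-loops?
#'
#' @param g a directed graph.
#' @return logical scalar.
#' @export
has_self_loops <- function(g) any(igraph::which_loop(g))

#' Strongly connected components
#'
#' Partitions the node set into maximal strongly connected components:
#' node sets in which every ordered pair of nodes is mutually reachable
#' along directed paths.  Singleton nodes (including nodes whose only cycle
#' is a self-loop) form their own components.
#'
#' @param g a directed graph.
#' @return a list with `components` (list of character vectors, disjoint and
#'   covering all nodes) and `membership` (named integer vector mapping each
#'   node to its component index).
#' @examples
#' g <- make_digraph(c("a", "b", "c"), c("b", "c", "a"))
#' find_sccs(g)$components
#' @export
find_sccs <- function(g) {
  g <- as_digraph(g)
  if (igraph::vcount(g) == 0L) {
    return(list(components = list(), membership = integer(0)))
  }
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  names(memb) <- igraph::V(g)$name
  comps <- split(names(memb), memb)
  names(comps) <- NULL
  list(components = comps, membership = memb)
}

#' Structural predicates: DAG, directed tree, arborescence, forest
#'
#' Nested classes of directed graphs, from least to most constrained:
#'
#' * `is_dag(g)`: no directed cycle — no strongly connected component of
#'   size two or more and no self-loop.
#' * `is_directed_tree(g)`: a DAG whose undirected skeleton has no simple
#'   cycle; equivalently, each weakly connected component has exactly
#'   (number of nodes − 1) edges.
#' * `is_arborescence(g)`: a weakly connected directed tree with exactly one
#'   node of in-degree 0 (the root) and all other nodes of in-degree 1, so
#'   every edge points away from the root and the root reaches every node by
#'   a unique path.
#' * `is_arborescence_forest(g)`: every weakly connected component is an
#'   arborescence.
#'
#' Every arborescence is a directed tree, and every directed tree is a DAG.
#'
#' @param g a directed graph.
#' @return logical scalar.
#' @examples
#' chain <- make_digraph(c("a", "b"), c("b", "c"))
#' is_arborescence(chain)
#' @export
is_dag <- function(g) {
  g <- as_digraph(g)
  if (has_self_loops(g)) return(FALSE)
  # igraph::is_dag() ignores self-loops in some versions, hence the explicit
  # check above.
  igraph::is_dag(g)
}

#' @rdname is_dag
#' @export
is_directed_tree <- function(g) {
  g <- as_digraph(g)
  if (!is_dag(g)) return(FALSE)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  e_per_comp <- tabulate(comp$membership[igraph::tail_of(g, igraph::E(g))],
                         nbins = comp$no)
  all(e_per_comp == sizes - 1L)
}

#' @rdname is_dag
#' @export
is_arborescence <- function(g) {
  g <- as_digraph(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(FALSE)
  if (!igraph::is_connected(g, mode = "weak")) return(FALSE)
  indeg <- igraph::degree(g, mode = "in", loops = TRUE)
  sum(indeg == 0L) == 1L && all(indeg <= 1L) && is_dag(g)
}

#' @rdname is_dag
#' @export
is_arborescence_forest <- function(g) {
  g <- as_digraph(g)
  if (igraph::vcount(g) == 0L) return(TRUE)
  comp <- igraph::components(g, mode = "weak")
  for (k in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == k))
    if (!is_arborescence(sub)) return(FALSE)
  }
  TRUE
}
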