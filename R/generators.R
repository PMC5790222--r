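#' Random directed graph generators
#'
#' Seeded generators for the three random families used in the synthetic
#' experiments, all returning directed graphs with string labels
#' `"1" ... "n"`:
#'
#' * `gen_erdos_renyi(n, m_edges)`: exactly `m_edges` distinct directed
#'   non-self-loop edges placed uniformly at random — the no-hierarchy
#'   reference model.
#' * `gen_watts_strogatz_directed(n, k, p)`: an undirected ring lattice in
#'   which every node links its `k` nearest neighbours, each edge rewired
#'   with probability `p`, then each undirected edge given a uniformly
#'   random direction; `n * k / 2` edges.  Structured (clustered, short
#'   paths) but still non-hierarchical.
#' * `gen_preferential_attachment_directed(n, m)`: degree-proportional
#'   growth from `m` initially isolated seed nodes — the first newcomer
#'   attaches to all of them — with every edge oriented from the older node
#'   to the newer.  The result is always acyclic, every non-seed node has
#'   in-degree `m`, and its arborescence score is 1/m (rooting deletes
#'   `m - 1` of each newcomer's incoming edges).
#'
#' @param n number of nodes.
#' @param m_edges number of edges, at most `n * (n - 1)`.
#' @param k even number of lattice neighbours per node, `k < n`.
#' @param p rewiring probability of the small-world model.
#' @param m edges attached by every new node, `1 <= m < n`.
#' @param rng_seed integer seed; equal seeds give identical graphs.
#' @return a directed igraph object.
#' @examples
#' g <- gen_erdos_renyi(20, 40, rng_seed = 1)
#' igraph::ecount(g)
#' @export
gen_erdos_renyi <- function(n, m_edges, rng_seed = 1L) {
  if (m_edges < 0 || m_edges > n * (n - 1)) {
    stop("m_edges must lie in [0, n*(n-1)]")
  }
  withr::local_seed(rng_seed)
  # ordered non-loop pairs indexed 1 .. n(n-1)
  idx <- sample.int(n * (n - 1L), m_edges)
  src <- (idx - 1L) %/% (n - 1L) + 1L
  off <- (idx - 1L) %% (n - 1L) + 1L
  dst <- ifelse(off >= src, off + 1L, off)
  make_digraph(as.character(src), as.character(dst),
               nodes = as.character(seq_len(n)))
}

#' @rdname gen_erdos_renyi
#' @export
gen_watts_strogatz_directed <- function(n, k, p = 0.05, rng_seed = 1L) {
  if (k %% 2 != 0 || k <= 0 || k >= n) stop("k must be even and 0 < k < n")
  withr::local_seed(rng_seed)
  und <- igraph::sample_smallworld(1, n, k / 2, p,
                                   loops = FALSE, multiple = FALSE)
  el <- igraph::as_edgelist(und, names = FALSE)
  flip <- stats::runif(nrow(el)) < 0.5
  from <- ifelse(flip, el[, 2L], el[, 1L])
  to <- ifelse(flip, el[, 1L], el[, 2L])
  make_digraph(as.character(from), as.character(to),
               nodes = as.character(seq_len(n)))
}

#' @rdname gen_erdos_renyi
#' @export
gen_preferential_attachment_directed <- function(n, m, rng_seed = 1L) {
  if (m < 1 || m >= n) stop("m must satisfy 1 <= m < n")
  withr::local_seed(rng_seed)
  deg <- numeric(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  pos <- 0L
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    targets <- if (v == m + 1L) {
      existing                       # first newcomer joins all seed nodes
    } else {
      sample(existing, m, prob = deg[existing])
    }
    span <- pos + seq_along(targets)
    from[span] <- targets            # old -> new orientation
    to[span] <- v
    pos <- pos + length(targets)
    deg[targets] <- deg[targets] + 1
    deg[v] <- deg[v] + length(targets)
  }
  make_digraph(as.character(from), as.character(to),
               nodes = as.character(seq_len(n)))
}

#' Deterministic toy topologies
#'
#' Small graphs with known hierarchy properties, useful as references and in
#' tests:
#'
#' * `gen_balanced_arborescence(branching, height)`: complete out-tree, all
#'   edges away from the root; a perfect hierarchy (score 1).
#' * `gen_wheel_flipped(n_rim)`: a hub pointing to every node of a rim whose
#'   edges run one way around the circle except exactly one reversed edge —
#'   acyclic, so flow hierarchy is 1, yet half its edges are horizontal and
#'   the arborescence score is 0.5.
#' * `gen_star(n)`: one hub with out-edges to the `n - 1` other nodes; the
#'   only topology whose global reaching centrality is 1.
#' * `gen_cycle(n)`: a single directed cycle — one strongly connected
#'   component, arborescence score 0.
#' * `gen_multiroot_toy()`: a small DAG with two in-degree-0 roots feeding
#'   shared descendants.
#'
#' @param branching children per internal node, `>= 1`.
#' @param height tree height, `>= 0` (0 gives a single node).
#' @param n_rim number of rim nodes, `>= 3`.
#' @param n number of nodes, `>= 2`.
#' @return a directed igraph object.
#' @examples
#' flow_hierarchy(gen_wheel_flipped(10))        # 1
#' arborescence_score(gen_wheel_flipped(10))$score  # 0.5
#' @export
gen_balanced_arborescence <- function(branching, height) {
  stopifnot(branching >= 1, height >= 0)
  n <- if (branching == 1L) height + 1L else {
    as.integer((branching^(height + 1L) - 1L) / (branching - 1L))
  }
  g <- igraph::make_tree(n, children = branching, mode = "out")
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n) - 1L))
  g
}

#' @rdname gen_balanced_arborescence
#' @export
gen_wheel_flipped <- function(n_rim) {
  stopifnot(n_rim >= 3)
  rim <- as.character(seq_len(n_rim))
  spokes_from <- rep("hub", n_rim)
  ring_from <- rim[seq_len(n_rim - 1L)]
  ring_to <- rim[seq_len(n_rim - 1L) + 1L]
  # closing edge rim[n] -> rim[1] is flipped to rim[1] -> rim[n]
  make_digraph(c(spokes_from, ring_from, rim[1L]),
               c(rim, ring_to, rim[n_rim]))
}

#' @rdname gen_balanced_arborescence
#' @export
gen_star <- function(n) {
  stopifnot(n >= 2)
  make_digraph(rep("hub", n - 1L), as.character(seq_len(n - 1L)))
}

#' @rdname gen_balanced_arborescence
#' @export
gen_cycle <- function(n) {
  stopifnot(n >= 2)
  v <- as.character(seq_len(n))
  make_digraph(v, c(v[-1L], v[1L]))
}

#' @rdname gen_balanced_arborescence
#' @export
gen_multiroot_toy <- function() {
  make_digraph(c("r1", "r2", "r1", "r2", "c", "c"),
               c("c", "c", "d", "e", "f", "g"))
}

#' Reference toy graphs for the arborescence reduction
#'
#' Four hand-constructed graphs illustrating the nested structural classes
#' and the full reduction pipeline.  Each constructor re-checks its defining
#' structural facts before returning (a built-in self-test):
#'
#' * `toy_dag()`: 9 nodes, 10 edges; acyclic but neither a tree (its
#'   skeleton walks 0–2–5–1–0) nor an arborescence (nodes 5 and 6 have
#'   in-degree 2).  Two rooting deletions leave an 8-edge arborescence:
#'   score 0.8.
#' * `toy_tree()`: 9 nodes, 8 edges; a directed tree with two in-degree-0
#'   nodes (0 and 3) that is not an arborescence because node 2 has two
#'   parents.  Rooting deletes exactly the root-pointing edge (3, 2):
#'   score 0.875.
#' * `toy_arborescence()`: a 9-node arborescence rooted at 0: score 1.
#' * `toy_scc_graph()`: 15 nodes, 20 edges with two strongly connected
#'   components, \{6,7,8\} and \{11,12,13,14\}; condensing them and rooting
#'   the resulting 10-component DAG preserves 9 edges: score 9/20 = 0.45.
#'
#' @return a directed igraph object.
#' @examples
#' arborescence_score(toy_scc_graph())$score  # 0.45
#' @export
toy_dag <- function() {
  g <- make_digraph(
    c("0", "0", "0", "1", "2", "2", "3", "3", "4", "4"),
    c("1", "2", "3", "5", "5", "6", "6", "4", "7", "8"))
  stopifnot(igraph::ecount(g) == 10L, is_dag(g), !is_directed_tree(g),
            all(igraph::degree(g, c("5", "6"), mode = "in") == 2L))
  g
}

#' @rdname toy_dag
#' @export
toy_tree <- function() {
  g <- make_digraph(
    c("0", "0", "3", "1", "1", "2", "3", "7"),
    c("1", "2", "2", "4", "5", "6", "7", "8"))
  indeg <- igraph::degree(g, mode = "in")
  stopifnot(igraph::ecount(g) == 8L, is_directed_tree(g), !is_arborescence(g),
            setequal(names(indeg)[indeg == 0L], c("0", "3")))
  g
}

#' @rdname toy_dag
#' @export
toy_arborescence <- function() {
  g <- make_digraph(
    c("0", "0", "1", "1", "2", "2", "3", "3"),
    c("1", "2", "3", "4", "5", "6", "7", "8"))
  stopifnot(is_arborescence(g),
            igraph::degree(g, "0", mode = "in") == 0L)
  g
}

#' @rdname toy_dag
#' @export
toy_scc_graph <- function() {
  g <- make_digraph(
    c("6", "7", "8", "11", "12", "13", "14",
      "0", "0", "0", "1", "2", "2", "3", "8", "8", "4", "9", "10", "14"),
    c("7", "8", "6", "12", "13", "14", "11",
      "1", "2", "4", "3", "3", "6", "7", "9", "10", "10", "11", "12", "5"))
  sccs <- find_sccs(g)$components
  big <- sccs[lengths(sccs) > 1L]
  stopifnot(igraph::ecount(g) == 20L, igraph::vcount(g) == 15L,
            length(big) == 2L,
            any(vapply(big, setequal, logical(1), c("6", "7", "8"))),
            any(vapply(big, setequal, logical(1), c("11", "12", "13", "14"))))
  g
}

#' Score sweeps over random-graph families
#'
#' `sweep_scores()` generates `n_replicates` seeded graphs per grid point
#' and family and records the mean and standard deviation of each requested
#' hierarchy measure — the experiment behind the synthetic benchmark: random
#' families (`er`, `ws`) drift to low scores as density grows while the
#' hierarchical family (`pa`) stays high.  `pa_er_ratio()` reduces the two
#' sweeps to the ratio of preferential-attachment to Erdős–Rényi means,
#' the discriminative power of each measure (ratios with a zero denominator
#' are `Inf`).
#'
#' Grid points are target edge counts; each family realizes them with its
#' own parameter (`er`: exactly; `ws`: `k = 2e/n` rounded to even; `pa`:
#' `m = round(e/n)`, giving `m (n - m)` edges).  The agony measure applies
#' only to acyclic graphs and is recorded as `NA` when a replicate is
#' cyclic.
#'
#' @param model one of `"er"`, `"ws"`, `"pa"`.
#' @param n nodes per graph.
#' @param edge_grid integer vector of target edge counts.
#' @param n_replicates graphs per grid point.
#' @param measures subset of `c("arb", "fh", "grc", "agony")`.
#' @param rng_seed integer seed; replicate `r` of grid point `i` derives its
#'   own sub-seed, so records are independent of evaluation order.
#' @return a data frame with columns `model`, `n_nodes`, `n_edges`
#'   (realized), `measure`, `mean`, `sd`, `n_replicates`.
#' @examples
#' sweep_scores("er", n = 30, edge_grid = c(60, 120), n_replicates = 5,
#'              measures = "arb", rng_seed = 1)
#' @export
sweep_scores <- function(model = c("er", "ws", "pa"), n = 100L,
                         edge_grid = c(200L, 500L, 1000L),
                         n_replicates = 100L,
                         measures = c("arb", "fh", "grc"),
                         rng_seed = 1L) {
  model <- match.arg(model)
  measures <- match.arg(measures, c("arb", "fh", "grc", "agony"),
                        several.ok = TRUE)
  seeds <- withr::with_seed(rng_seed,
                            matrix(sample.int(.Machine$integer.max - 1L,
                                              length(edge_grid) * n_replicates),
                                   nrow = length(edge_grid)))
  rows <- list()
  for (i in seq_along(edge_grid)) {
    e <- edge_grid[i]
    graphs <- lapply(seq_len(n_replicates), function(r) {
      s <- seeds[i, r]
      switch(model,
             er = gen_erdos_renyi(n, e, rng_seed = s),
             ws = {
               k <- max(2L, 2L * round(e / n))
               gen_watts_strogatz_directed(n, k, rng_seed = s)
             },
             pa = gen_preferential_attachment_directed(
               n, max(1L, min(n - 1L, round(e / n))), rng_seed = s))
    })
    realized <- mean(vapply(graphs, igraph::ecount, numeric(1)))
    for (msr in measures) {
      f <- score_fun(msr)
      vals <- vapply(graphs, function(g) {
        if (msr == "agony" && !is_dag(g)) return(NA_real_)
        f(g)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, n_nodes = n, n_edges = realized, measure = msr,
        mean = mean(vals), sd = if (n_replicates > 1L) stats::sd(vals) else 0,
        n_replicates = n_replicates, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname sweep_scores
#' @export
pa_er_ratio <- function(n = 100L, edge_grid = c(200L, 500L, 1000L),
                        n_replicates = 100L,
                        measures = c("arb", "fh", "grc"),
                        rng_seed = 1L) {
  pa <- sweep_scores("pa", n, edge_grid, n_replicates, measures, rng_seed)
  er <- sweep_scores("er", n, edge_grid, n_replicates, measures, rng_seed)
  out <- pa[, c("measure", "n_nodes")]
  out$target_edges <- rep(edge_grid, each = length(measures))
  out$mean_pa <- pa$mean
  out$mean_er <- er$mean
  out$ratio <- ifelse(er$mean > 0, pa$mean / er$mean,
                      ifelse(pa$mean > 0, Inf, NaN))
  out
}
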