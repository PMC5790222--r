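# Brute-force reference implementations, independent of the package's (and
# igraph's) algorithms: boolean transitive closure by repeated squaring.

# adjacency matrix in vertex order (self-loops on the diagonal)
adj_matrix <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  a <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) a[el] <- TRUE
  a
}

# closure[i, j]: a directed path of length >= 1 from i to j exists
path_closure <- function(a) {
  n <- nrow(a)
  reach <- a
  repeat {
    nxt <- reach | (reach %*% a > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# mutual-reachability classes (paths of length >= 0), as sets of labels
scc_oracle <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  reach <- path_closure(adj_matrix(g))
  diag(reach) <- TRUE
  mutual <- reach & t(reach)
  classes <- unique(apply(mutual, 1, paste, collapse = ""))
  lapply(classes, function(sig) {
    rownames(mutual)[apply(mutual, 1, paste, collapse = "") == sig]
  })
}

# per-edge cycle membership: edge (u, v) lies on a directed cycle iff it is
# a self-loop or some path leads back from v to u
flow_hierarchy_oracle <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  reach <- path_closure(adj_matrix(g))
  in_cycle <- vapply(seq_len(nrow(el)), function(e) {
    u <- el[e, 1L]; v <- el[e, 2L]
    u == v || reach[v, u]
  }, logical(1))
  mean(!in_cycle)
}

same_partition <- function(p1, p2) {
  key <- function(p) sort(vapply(p, function(s) paste(sort(s), collapse = ","),
                                 character(1)))
  identical(key(p1), key(p2))
}

# seeded random digraph over n nodes with edge probability p
random_digraph <- function(n, p, seed, loops = FALSE) {
  withr::with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    if (!loops) pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p
    make_digraph(as.character(pairs$from[keep]),
                 as.character(pairs$to[keep]),
                 nodes = as.character(seq_len(n)))
  })
}

degree_table <- function(g) {
  d <- data.frame(node = igraph::V(g)$name,
                  indeg = as.integer(igraph::degree(g, mode = "in")),
                  outdeg = as.integer(igraph::degree(g, mode = "out")))
  d <- d[order(d$node), ]
  rownames(d) <- NULL
  d
}
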