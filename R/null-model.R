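#' Degree-preserving double edge switch
#'
#' Randomizes a directed graph while preserving every node's in-degree and
#' out-degree exactly.  Two distinct edges `a -> b` and `c -> d` are drawn
#' uniformly at random and rewired to `c -> b` and `a -> d`.  A proposal is
#' aborted — and a fresh attempt made — when either replacement edge already
#' exists or would be a self-loop (`c == b` or `a == d`).  Aborted proposals
#' do not count toward `n_swaps`; edges may be rewired back later.
#'
#' @param g a directed graph with at least two edges.
#' @param n_swaps number of successful switches to perform; the customary
#'   default is one per edge.
#' @param rng_seed integer seed making the rewiring reproducible.
#' @return a rewired directed graph with identical per-node degree sequences.
#' @examples
#' g <- make_digraph(c("a", "c"), c("b", "d"))
#' edge_pairs_of <- igraph::as_edgelist(double_edge_switch(g, 1, 1))
#' @export
double_edge_switch <- function(g, n_swaps = igraph::ecount(g), rng_seed = 1L) {
  g <- as_digraph(g)
  m <- igraph::ecount(g)
  if (m < 2L) stop("double edge switch needs at least two edges")
  el <- edge_pairs(g)
  withr::local_seed(rng_seed)
  res <- rewire_edgelist(el, n_swaps)
  out <- make_digraph(res[, 1L], res[, 2L], nodes = igraph::V(g)$name)
  out
}

# in-place double-edge-switch on a 2-column character matrix;
# on_exhausted: what to do after 100 * n_swaps consecutive aborts — a degree
# sequence with a (nearly) unique realization cannot be rewired further
rewire_edgelist <- function(el, n_swaps, on_exhausted = c("error", "keep")) {
  on_exhausted <- match.arg(on_exhausted)
  m <- nrow(el)
  from <- el[, 1L]
  to <- el[, 2L]
  seen <- new.env(hash = TRUE, size = 2L * m)
  for (e in seq_len(m)) assign(paste(from[e], to[e], sep = "\r"), TRUE, seen)
  done <- 0L
  aborted <- 0L
  max_abort <- 100L * max(n_swaps, 1L)
  while (done < n_swaps) {
    if (aborted >= max_abort) {
      if (on_exhausted == "keep") break
      stop("degree sequence too constrained: ", aborted,
           " consecutive rewiring proposals aborted")
    }
    e1 <- sample.int(m, 1L)
    e2 <- sample.int(m, 1L)
    if (e1 == e2) { aborted <- aborted + 1L; next }
    a <- from[e1]; b <- to[e1]
    c_ <- from[e2]; d <- to[e2]
    if (c_ == b || a == d) { aborted <- aborted + 1L; next }
    k1 <- paste(c_, b, sep = "\r")
    k2 <- paste(a, d, sep = "\r")
    if (exists(k1, envir = seen, inherits = FALSE) ||
        exists(k2, envir = seen, inherits = FALSE)) {
      aborted <- aborted + 1L
      next
    }
    rm(list = c(paste(a, b, sep = "\r"), paste(c_, d, sep = "\r")),
       envir = seen)
    assign(k1, TRUE, seen)
    assign(k2, TRUE, seen)
    from[e1] <- c_           # c -> b
    from[e2] <- a            # a -> d
    done <- done + 1L
    aborted <- 0L
  }
  cbind(from, to, deparse.level = 0L)
}

score_fun <- function(score_name) {
  switch(match.arg(score_name, c("arb", "fh", "grc", "agony")),
         arb = function(g) arborescence_score(g)$score,
         fh = flow_hierarchy,
         grc = global_reaching_centrality,
         agony = agony_score)
}

classify_null <- function(observed, mean, sd) {
  if (sd == 0) {
    # two-sigma rule undefined at sd = 0; fall back to sign of the gap
    if (observed > mean) "+" else if (observed < mean) "-" else "x"
  } else if (observed >= mean + 2 * sd) {
    "+"
  } else if (observed <= mean - 2 * sd) {
    "-"
  } else {
    "x"
  }
}

#' Null-model significance test for a hierarchy score
#'
#' Compares the observed score of a graph with its distribution over
#' degree-preserving null models.  Each of the `n_models` replicates is an
#' independent [double_edge_switch()] randomization restarted from the
#' original graph (one successful switch per edge).  The network is labelled
#' `"+"` (hierarchy) when the observed score is at least two standard
#' deviations above the null mean, `"-"` (anti-hierarchy) when at least two
#' below, and `"x"` otherwise.  The pseudo p-value is the plain fraction of
#' null scores greater than or equal to the observation.
#'
#' @param g a directed graph.
#' @param score_name one of `"arb"`, `"fh"`, `"grc"`, `"agony"`.  The agony
#'   case requires the graph and all its rewirings to be acyclic.
#' @param n_models number of null replicates.
#' @param rng_seed integer seed; replicate `k` draws its own seed from a
#'   stream derived from `rng_seed`, so results do not depend on evaluation
#'   order.
#' @return an object of class `null_model_stats` with fields `observed`,
#'   `null_scores`, `mean`, `sd`, `z`, `pseudo_p`, `label`, `score_name`,
#'   `n_models`, `rng_seed`.
#' @examples
#' g <- gen_preferential_attachment_directed(30, 2, rng_seed = 7)
#' null_test(g, "arb", n_models = 20, rng_seed = 7)
#' @export
null_test <- function(g, score_name = c("arb", "fh", "grc", "agony"),
                      n_models = 1000L, rng_seed = 1L) {
  score_name <- match.arg(score_name)
  g <- as_digraph(g)
  f <- score_fun(score_name)
  observed <- f(g)
  el <- edge_pairs(g)
  nodes <- igraph::V(g)$name
  n_swaps <- nrow(el)
  rep_seeds <- withr::with_seed(rng_seed,
                                sample.int(.Machine$integer.max - 1L, n_models))
  null_scores <- vapply(seq_len(n_models), function(k) {
    rewired <- withr::with_seed(rep_seeds[k],
                                rewire_edgelist(el, n_swaps,
                                                on_exhausted = "keep"))
    f(make_digraph(rewired[, 1L], rewired[, 2L], nodes = nodes))
  }, numeric(1))
  mu <- mean(null_scores)
  sdev <- stats::sd(null_scores)
  structure(list(
    observed = observed,
    null_scores = null_scores,
    mean = mu,
    sd = sdev,
    z = if (sdev > 0) (observed - mu) / sdev else NA_real_,
    pseudo_p = mean(null_scores >= observed),
    label = classify_null(observed, mu, sdev),
    score_name = score_name,
    n_models = n_models,
    rng_seed = rng_seed
  ), class = "null_model_stats")
}

#' @export
print.null_model_stats <- function(x, ...) {
  cat("Null-model test (", x$score_name, ", ", x$n_models,
      " degree-preserving replicates, seed ", x$rng_seed, ")\n", sep = "")
  cat(sprintf("  observed %.6f | null %.6f +/- %.6f | z = %s | pseudo p = %.4f | label %s\n",
              x$observed, x$mean, x$sd,
              if (is.na(x$z)) "NA" else sprintf("%.3f", x$z),
              x$pseudo_p, x$label))
  invisible(x)
}

#' Tabulate one or several null-model tests
#'
#' @param stats a `null_model_stats` object or a list of them.
#' @return a data frame with one row per test: measure, observed, mean, sd,
#'   z, pseudo_p, label.
#' @export
null_stats_table <- function(stats) {
  if (inherits(stats, "null_model_stats")) stats <- list(stats)
  do.call(rbind, lapply(stats, function(x) {
    data.frame(measure = x$score_name, observed = x$observed,
               mean = x$mean, sd = x$sd, z = x$z,
               pseudo_p = x$pseudo_p, label = x$label,
               stringsAsFactors = FALSE)
  }))
}
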