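test_that("condensation collapses SCCs into a simple acyclic graph", {
  cd <- condense(toy_scc_graph())
  expect_equal(igraph::vcount(cd$dag), 10)
  expect_true(is_dag(cd$dag))
  expect_setequal(cd$members[["scc:6"]], c("6", "7", "8"))
  expect_setequal(cd$members[["scc:11"]], c("11", "12", "13", "14"))

  # a pure cycle collapses to one node with no edges
  cd2 <- condense(gen_cycle(4))
  expect_equal(igraph::vcount(cd2$dag), 1)
  expect_equal(igraph::ecount(cd2$dag), 0)

  # a DAG condenses to an isomorphic copy of itself
  d <- toy_dag()
  cd3 <- condense(d)
  expect_equal(igraph::vcount(cd3$dag), igraph::vcount(d))
  expect_equal(igraph::ecount(cd3$dag), igraph::ecount(d))

  # parallel inter-component edges merge; intra edges and self-loops vanish
  g <- make_digraph(c("a", "b", "a", "b", "c"), c("b", "a", "c", "c", "c"))
  cdg <- condense(g)
  expect_equal(igraph::vcount(cdg$dag), 2)
  expect_equal(igraph::ecount(cdg$dag), 1)
})

test_that("out-closeness follows the reciprocal-distance-sum definition", {
  path3 <- make_digraph(c("0", "1"), c("1", "2"))
  expect_equal(out_closeness(path3),
               c("0" = 1 / 3, "1" = 1, "2" = 0))

  star <- gen_star(4)
  cl <- out_closeness(star)
  expect_equal(unname(cl["hub"]), 1 / 3)
  expect_true(all(cl[setdiff(names(cl), "hub")] == 0))

  diamond <- make_digraph(c("r", "r", "a"), c("a", "b", "b"))
  expect_equal(out_closeness(diamond), c("r" = 1 / 2, "a" = 1, "b" = 0))
})

test_that("rooting keeps the incoming edge from the lowest-closeness parent", {
  rooted <- root_forest(condense(toy_tree()))
  expect_equal(rooted$removed, cbind("3", "2"))
  expect_setequal(rooted$roots, c("0", "3"))
  expect_true(is_arborescence_forest(rooted$forest))

  diamond <- make_digraph(c("r", "r", "a"), c("a", "b", "b"))
  rooted2 <- root_forest(condense(diamond))
  el <- igraph::as_edgelist(rooted2$forest, names = TRUE)
  expect_setequal(paste(el[, 1], el[, 2]), c("r a", "r b"))

  chain <- make_digraph(c("a", "b"), c("b", "c"))
  rooted3 <- root_forest(condense(chain))
  expect_equal(nrow(rooted3$removed), 0)
  expect_equal(igraph::ecount(rooted3$forest), 2)

  expect_error(root_forest(make_digraph(c("a", "b"), c("b", "a"))), "cycle")
})

test_that("worked toy examples score as expected", {
  expect_equal(arborescence_score(toy_dag())$score, 0.8)
  expect_equal(arborescence_score(toy_tree())$score, 0.875)
  expect_equal(arborescence_score(toy_arborescence())$score, 1)
  res <- arborescence_score(toy_scc_graph())
  expect_equal(res$score, 0.45)
  expect_equal(res$score_num, 9)
  expect_equal(res$score_den, 20)
})

test_that("score extremes: cycles give 0, arborescence forests give 1", {
  for (n in c(2, 5, 9)) {
    expect_equal(arborescence_score(gen_cycle(n))$score, 0)
  }
  expect_equal(arborescence_score(gen_balanced_arborescence(3, 2))$score, 1)
  expect_error(arborescence_score(make_digraph(character(0), character(0),
                                               nodes = "x")),
               "empty edge set")
})

test_that("closed form holds on random graphs: score = (|V*| - sources)/|E|", {
  for (seed in 1:120) {
    n <- 3 + seed %% 12
    g <- random_digraph(n, 0.08 + (seed %% 9) / 12, seed,
                        loops = seed %% 7 == 0)
    if (igraph::ecount(g) == 0) next
    res <- arborescence_score(g)
    z <- sum(igraph::degree(condense(g)$dag, mode = "in") == 0)
    expect_equal(res$score,
                 (res$n_condensed_nodes - z) / res$n_edges,
                 info = paste("seed", seed))
    expect_equal(res$n_forest_edges,
                 res$n_condensed_nodes - length(res$roots))
    expect_true(is_arborescence_forest(res$forest))
    expect_true(res$score >= 0 && res$score <= 1)
  }
})

test_that("relabelling nodes never changes the score or the counts", {
  for (seed in 1:25) {
    g <- random_digraph(8, 0.25, seed + 300)
    if (igraph::ecount(g) == 0) next
    perm <- withr::with_seed(seed, sample(igraph::V(g)$name))
    names(perm) <- igraph::V(g)$name
    el <- igraph::as_edgelist(g, names = TRUE)
    g2 <- make_digraph(perm[el[, 1]], perm[el[, 2]],
                       nodes = unname(perm))
    r1 <- arborescence_score(g)
    r2 <- arborescence_score(g2)
    expect_equal(r1$score, r2$score, info = paste("seed", seed))
    expect_equal(r1$n_forest_edges, r2$n_forest_edges)
    expect_equal(length(r1$roots), length(r2$roots))
  }
})

test_that("adding an intra-SCC edge strictly decreases the score", {
  g <- make_digraph(c("a", "b", "c", "a", "d"),
                    c("b", "c", "a", "d", "e"))
  before <- arborescence_score(g)$score
  g2 <- igraph::add_edges(g, c("b", "a"))
  expect_lt(arborescence_score(g2)$score, before)
})

test_that("isolated nodes become roots without touching the score", {
  g <- make_digraph(c("a", "b"), c("b", "c"), nodes = c("lonely"))
  res <- arborescence_score(g)
  expect_equal(res$score, 1)
  expect_true("lonely" %in% res$roots)
  expect_true(is_arborescence_forest(res$forest))
})

test_that("self-loops count in the denominator but never survive", {
  g <- make_digraph(c("a", "b", "b"), c("b", "c", "b"))
  res <- arborescence_score(g)
  expect_equal(res$score, 2 / 3)
})

test_that("score is at most the flow hierarchy on every test graph", {
  for (seed in 1:30) {
    g <- random_digraph(7, 0.3, seed + 600)
    if (igraph::ecount(g) == 0) next
    expect_lte(arborescence_score(g)$score, flow_hierarchy(g) + 1e-12)
  }
})
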