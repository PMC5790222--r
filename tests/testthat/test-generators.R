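test_that("Erdos-Renyi: exact edge count, no loops, seed-deterministic", {
  g <- gen_erdos_renyi(100, 500, rng_seed = 11)
  expect_equal(igraph::ecount(g), 500)
  expect_equal(igraph::vcount(g), 100)
  expect_false(has_self_loops(g))
  expect_identical(igraph::as_edgelist(gen_erdos_renyi(50, 200, 7)),
                   igraph::as_edgelist(gen_erdos_renyi(50, 200, 7)))
  expect_equal(igraph::ecount(gen_erdos_renyi(10, 0, 1)), 0)
  # saturated case uses every ordered pair
  full <- gen_erdos_renyi(5, 20, 1)
  expect_equal(igraph::ecount(full), 20)
  expect_error(gen_erdos_renyi(5, 21, 1), "m_edges")
})

test_that("Watts-Strogatz: nk/2 edges, even-k contract, determinism", {
  g <- gen_watts_strogatz_directed(100, 10, rng_seed = 5)
  expect_equal(igraph::ecount(g), 500)
  expect_error(gen_watts_strogatz_directed(100, 7), "even")
  expect_identical(igraph::as_edgelist(gen_watts_strogatz_directed(40, 4, 0.05, 3)),
                   igraph::as_edgelist(gen_watts_strogatz_directed(40, 4, 0.05, 3)))
  # p = 0: pure oriented lattice, every node has total degree k
  lattice <- gen_watts_strogatz_directed(20, 4, p = 0, rng_seed = 2)
  expect_true(all(igraph::degree(lattice, mode = "all") == 4))
})

test_that("preferential attachment: acyclic, in-degree m, score exactly 1/m", {
  for (m in c(1, 2, 3, 5)) {
    g <- gen_preferential_attachment_directed(60, m, rng_seed = m)
    expect_true(is_dag(g))
    indeg <- igraph::degree(g, mode = "in")
    non_seed <- as.character((m + 1):60)
    expect_true(all(indeg[non_seed] == m))
    expect_equal(arborescence_score(g)$score, 1 / m)
  }
  expect_true(is_arborescence_forest(
    gen_preferential_attachment_directed(30, 1, rng_seed = 9)))
  expect_error(gen_preferential_attachment_directed(10, 10), "m must")
})

test_that("balanced arborescence geometry and perfect score", {
  g <- gen_balanced_arborescence(2, 3)
  expect_equal(igraph::vcount(g), 15)
  expect_equal(igraph::ecount(g), 14)
  expect_true(is_arborescence(g))
  expect_equal(arborescence_score(g)$score, 1)
  expect_equal(igraph::vcount(gen_balanced_arborescence(4, 0)), 1)
  expect_equal(igraph::vcount(gen_balanced_arborescence(1, 3)), 4)
})

test_that("flipped wheel: acyclic, 2r edges, FH 1 but score 0.5", {
  for (r in c(3, 10, 17)) {
    g <- gen_wheel_flipped(r)
    expect_equal(igraph::ecount(g), 2 * r)
    expect_true(is_dag(g))
    expect_equal(flow_hierarchy(g), 1)
    expect_equal(arborescence_score(g)$score, 0.5)
  }
})

test_that("star, cycle and multi-root toys have their defining scores", {
  expect_equal(global_reaching_centrality(gen_star(9)), 1)
  expect_equal(arborescence_score(gen_cycle(7))$score, 0)
  toy <- gen_multiroot_toy()
  indeg <- igraph::degree(toy, mode = "in")
  expect_gte(sum(indeg == 0), 2)
  expect_equal(flow_hierarchy(toy), 1)
  expect_equal(agony_score(toy), 1)
  expect_lt(arborescence_score(toy)$score, 1)
})

test_that("sweep records means and dispersions per family and grid point", {
  tab <- sweep_scores("er", n = 30, edge_grid = c(40, 90), n_replicates = 6,
                      measures = c("arb", "fh"), rng_seed = 1)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mean >= 0 & tab$mean <= 1))
  expect_true(all(tab$sd >= 0))
  expect_equal(unique(tab$n_edges), c(40, 90))

  one <- sweep_scores("pa", n = 30, edge_grid = 60, n_replicates = 1,
                      measures = "fh", rng_seed = 1)
  expect_equal(one$sd, 0)
  # the PA family is acyclic by construction: FH is identically 1
  many <- sweep_scores("pa", n = 40, edge_grid = c(80, 120), n_replicates = 5,
                       measures = "fh", rng_seed = 2)
  expect_true(all(many$mean == 1))
  expect_true(all(many$sd == 0))
})

test_that("dense random graphs drift to near-zero arborescence scores", {
  tab <- sweep_scores("er", n = 60, edge_grid = c(60, 360), n_replicates = 8,
                      measures = "arb", rng_seed = 3)
  expect_lt(tab$mean[tab$n_edges == 360], tab$mean[tab$n_edges == 60])
  expect_lt(tab$mean[tab$n_edges == 360], 0.1)
})

test_that("PA/ER ratio exceeds 1 for the arborescence measure", {
  tab <- pa_er_ratio(n = 50, edge_grid = c(100, 200), n_replicates = 8,
                     measures = "arb", rng_seed = 4)
  expect_true(all(tab$ratio > 1))
})

test_that("identical families in numerator and denominator give ratio near 1", {
  er1 <- sweep_scores("er", n = 40, edge_grid = 120, n_replicates = 15,
                      measures = "arb", rng_seed = 5)
  er2 <- sweep_scores("er", n = 40, edge_grid = 120, n_replicates = 15,
                      measures = "arb", rng_seed = 6)
  expect_equal(er1$mean / er2$mean, 1, tolerance = 0.35)
})
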