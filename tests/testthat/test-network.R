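make_net <- function(edges, nodes, layer = "x") {
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes,
                                                      layer = layer))
}

test_that("weighted density closed forms hold", {
  full <- make_net(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                              weight = 1), c("a", "b", "c"))
  expect_equal(weighted_density(full), 1)
  empty <- make_net(data.frame(from = character(), to = character(),
                               weight = numeric()), c("a", "b", "c"))
  expect_equal(weighted_density(empty), 0)
  single <- make_net(data.frame(from = "a", to = "b", weight = 0.6),
                     c("a", "b", "c"))
  expect_equal(weighted_density(single), 0.2)  # 2 * 0.6 / 6
  one_node <- make_net(data.frame(from = character(), to = character(),
                                  weight = numeric()), "a")
  expect_error(weighted_density(one_node), "fewer than 2")
})

test_that("bipartite density closed forms hold", {
  expect_equal(bipartite_density(data.frame(weight = rep(1, 6)), 2, 3), 1)
  expect_equal(bipartite_density(data.frame(weight = numeric()), 2, 3), 0)
  expect_equal(bipartite_density(data.frame(weight = 0.9), 2, 3), 0.15)
  expect_error(bipartite_density(data.frame(weight = 1), 0, 3), "empty layer")
})

test_that("average shortest path length uses reciprocal-weight distances", {
  two <- make_net(data.frame(from = "a", to = "b", weight = 0.5), c("a", "b"))
  expect_equal(average_shortest_path_length(two), 2)
  tri <- make_net(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                             weight = 1), c("a", "b", "c"))
  expect_equal(average_shortest_path_length(tri), 1)
  # 4-node path graph, weights 1, 0.5, 0.25 -> edge lengths 1, 2, 4; the six
  # unordered pair distances are ab=1, ac=3, ad=7, bc=2, bd=6, cd=4 -> 23/6
  path4 <- make_net(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                               weight = c(1, 0.5, 0.25)), letters[1:4])
  expect_equal(average_shortest_path_length(path4), 23 / 6)
  disc <- make_net(data.frame(from = "a", to = "b", weight = 1),
                   c("a", "b", "c"))
  expect_error(average_shortest_path_length(disc), "disconnected")
  expect_equal(average_shortest_path_length(disc, largest_component = TRUE), 1)
})

test_that("layer networks keep only permutation-significant MI edges", {
  spec <- cohort_spec(500, list(layer_def("A", 4)),
                      blocks = list(block_def("A", 2, 0.9)), seed = 13)
  co <- generate_cohort(spec)
  net <- build_layer_network(co, "A", n_perm = 200, seed = 13)
  expect_setequal(igraph::V(net)$name, paste0("A_0", 1:4))
  eid <- igraph::get_edge_ids(net, c("A_01", "A_02"))
  expect_gt(eid, 0)  # planted block pair is an edge
  at <- association_table(co, n_perm = 200, seed = 13)
  row <- at[at$var_a == "A_01" & at$var_b == "A_02", ]
  expect_equal(igraph::E(net)$weight[eid], row$nmi)  # weight = nmi
  expect_error(build_layer_network(co, "Z"), "unknown layer")
})

test_that("interlayer edges use the same criterion and reject identical layers", {
  spec <- cohort_spec(500, list(layer_def("A", 3), layer_def("B", 3)),
                      chains = list(chain_def(c("A_01", "B_01"), 0.8)),
                      seed = 14)
  co <- generate_cohort(spec)
  e <- build_interlayer_edges(co, "A", "B", n_perm = 200, seed = 14)
  expect_true(any(e$from == "A_01" & e$to == "B_01" |
                  e$from == "B_01" & e$to == "A_01"))
  expect_error(build_interlayer_edges(co, "A", "A"), "distinct")
})

test_that("multilayer assembly unions layers and rejects duplicate nodes", {
  n1 <- make_net(data.frame(from = "a1", to = "a2", weight = 0.5,
                            mi = 0.3, p = 0.01), c("a1", "a2"), "A")
  n2 <- make_net(data.frame(from = "b1", to = "b2", weight = 0.4,
                            mi = 0.2, p = 0.01), c("b1", "b2"), "B")
  mln <- assemble_multilayer(list(A = n1, B = n2))
  expect_equal(igraph::vcount(mln), 4)
  expect_equal(igraph::ecount(mln), 2)
  expect_equal(igraph::components(mln)$no, 2)
  inter <- data.frame(from = "a1", to = "b1", weight = 0.2, mi = 0.1,
                      p = 0.02)
  mln2 <- assemble_multilayer(list(A = n1, B = n2), list(inter))
  expect_equal(igraph::ecount(mln2), 3)
  n_dup <- make_net(data.frame(from = "a1", to = "x", weight = 0.1,
                               mi = 0.1, p = 0.01), c("a1", "x"), "B")
  expect_error(assemble_multilayer(list(A = n1, B = n_dup)), "duplicated")
})

test_that("connectance matrix is symmetric with block-diagonal dominance on block-structured data", {
  spec <- cohort_spec(
    800,
    list(layer_def("L1", 5), layer_def("L2", 5), layer_def("L3", 5)),
    blocks = list(block_def("L1", 4, 0.8), block_def("L2", 4, 0.8),
                  block_def("L3", 4, 0.8)),
    seed = 15)
  co <- generate_cohort(spec)
  mln <- build_multilayer_network(co, n_perm = 200, seed = 15)
  C <- connectance_matrix(mln)
  expect_equal(C, t(C))
  expect_true(all(diag(C) > max(C[upper.tri(C)])))
})

test_that("single-layer connectance equals that layer's weighted density", {
  spec <- cohort_spec(400, list(layer_def("A", 4)),
                      blocks = list(block_def("A", 3, 0.9)), seed = 16)
  co <- generate_cohort(spec)
  net <- build_layer_network(co, "A", n_perm = 200, seed = 16)
  C <- connectance_matrix(net)
  expect_equal(dim(C), c(1L, 1L))
  expect_equal(C[1, 1], weighted_density(net))
})

test_that("signed network carries signed Pearson weights on significant pairs", {
  set.seed(17)
  n <- 300
  x <- rnorm(n)
  co <- structure(list(
    data = data.frame(A_01 = x, A_02 = -x + rnorm(n, sd = 0.01),
                      B_01 = rnorm(n)),
    meta = data.frame(variable = c("A_01", "A_02", "B_01"),
                      layer = c("A", "A", "B"),
                      kind = "continuous", n_levels = 3),
    group = factor(rep("control", n)), spec = NULL), class = "cohort")
  sn <- build_signed_network(co, n_perm = 200, seed = 17)
  eid <- igraph::get_edge_ids(sn, c("A_01", "A_02"))
  expect_gt(eid, 0)
  expect_lt(igraph::E(sn)$weight[eid], -0.99)  # anti-correlated pair
  expect_equal(igraph::vcount(sn), 3)          # isolated nodes retained
})

test_that("planted edges are recovered and false edges stay near the alpha level", {
  spec <- cohort_spec(
    1000, list(layer_def("A", 8), layer_def("B", 8)),
    blocks = list(block_def("A", 5, 0.75), block_def("B", 4, 0.8)),
    seed = 18)
  co <- generate_cohort(spec)
  gt <- ground_truth(spec)
  mln <- build_multilayer_network(co, n_perm = 200, seed = 18)
  planted <- gt$planted_edges
  hit <- mapply(function(a, b) igraph::get_edge_ids(mln, c(a, b)) > 0,
                planted$var_a, planted$var_b)
  expect_gte(mean(hit), 0.9)
  all_pairs <- t(combn(igraph::V(mln)$name, 2))
  pk <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
              pmax(all_pairs[, 1], all_pairs[, 2]))
  planted_k <- paste(pmin(planted$var_a, planted$var_b),
                     pmax(planted$var_a, planted$var_b))
  null_pairs <- all_pairs[!pk %in% planted_k, , drop = FALSE]
  false_edge <- mapply(function(a, b) igraph::get_edge_ids(mln, c(a, b)) > 0,
                       null_pairs[, 1], null_pairs[, 2])
  expect_lte(mean(false_edge), 0.08)
})
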