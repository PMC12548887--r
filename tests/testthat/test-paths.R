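test_that("maximal lagged cross-correlation finds exact copies and shifts", {
  set.seed(1)
  u <- as.numeric(rbinom(80, 1, 0.5))
  m <- max_cross_correlation(u, u, max_lag = 10)
  expect_equal(m$cc, 1)
  expect_equal(m$lag, 0)
  v <- c(rep(0, 3), u[1:77])  # u delayed by 3 steps
  m3 <- max_cross_correlation(u, v, max_lag = 10)
  expect_equal(m3$cc, 1)
  expect_equal(m3$lag, 3)
  expect_error(max_cross_correlation(u[1:10], u[1:10], max_lag = 10),
               "too short")
})

test_that("cross-correlation matches a brute-force lag scan on noise traces", {
  set.seed(2)
  for (rep in 1:10) {
    u <- as.numeric(rbinom(100, 1, 0.5))
    v <- as.numeric(rbinom(100, 1, 0.5))
    m <- max_cross_correlation(u, v, max_lag = 10)
    # independent recomputation of the full lag grid
    n <- 100
    grid <- sapply(-10:10, function(l) {
      a <- if (l >= 0) u[1:(n - l)] else u[(1 - l):n]
      b <- if (l >= 0) v[(1 + l):n] else v[1:(n + l)]
      if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    })
    expect_equal(m$cc, max(grid), tolerance = 1e-12)
    expect_lt(m$cc, 0.6)  # independent noise stays small
  }
})

test_that("zero-variance segments yield correlation 0", {
  u <- rep(1, 60)
  v <- as.numeric(rbinom(60, 1, 0.5))
  m <- max_cross_correlation(u, v, max_lag = 5)
  expect_equal(m$cc, 0)
})

test_that("reweighting inverts cross-correlations on the unchanged topology", {
  net <- triad_network(w_ba = 0.4, w_ca = 0.5)
  ccmap <- data.frame(from = c("B", "C"), to = c("A", "A"),
                      cc = c(1, 0.5), lag = c(0L, 1L))
  g <- reweight_network(net, ccmap)
  expect_equal(igraph::ecount(g), 2)
  eid <- igraph::get_edge_ids(g, c("C", "A"))
  expect_equal(igraph::E(g)$length[eid], 2)  # 1 / 0.5
  eid1 <- igraph::get_edge_ids(g, c("B", "A"))
  expect_equal(igraph::E(g)$length[eid1], 1)
  # edges at or below the floor are dropped; no new edges ever appear
  ccmap$cc <- c(1e-4, -0.2)
  g2 <- reweight_network(net, ccmap)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 3)
})

test_that("k lowest-score paths solve the diamond example in order", {
  edges <- data.frame(from = c("A", "B", "A", "C"),
                      to = c("B", "D", "C", "D"),
                      length = c(1, 1, 1, 2))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = LETTERS[1:4],
                                                           layer = "x"))
  paths <- k_lowest_score_paths(g, "A", "D", k = 10)
  expect_equal(length(paths), 2)
  expect_equal(paths[[1]]$nodes, c("A", "B", "D"))
  expect_equal(paths[[1]]$score, 2)
  expect_equal(paths[[2]]$nodes, c("A", "C", "D"))
  expect_equal(paths[[2]]$score, 3)

  single <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", length = 1.25), directed = FALSE,
    vertices = data.frame(name = c("A", "B"), layer = "x"))
  p1 <- k_lowest_score_paths(single, "A", "B", k = 3)
  expect_equal(length(p1), 1)
  expect_equal(p1[[1]]$score, 1.25)

  disc <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", length = 1), directed = FALSE,
    vertices = data.frame(name = c("A", "B", "Z"), layer = "x"))
  expect_equal(k_lowest_score_paths(disc, "A", "Z", k = 3), list())
})

test_that("k lowest-score paths match exhaustive enumeration on random graphs", {
  set.seed(3)
  n_checked <- 0
  for (rep in 1:100) {
    rg <- random_length_graph(sample(4:8, 1), p_edge = 0.5)
    src <- rg$nodes[1]; tgt <- rg$nodes[length(rg$nodes)]
    oracle <- enumerate_simple_paths(rg$edges, src, tgt)
    k <- sample(1:12, 1)
    paths <- k_lowest_score_paths(rg$graph, src, tgt, k = k)
    expect_equal(length(paths), min(k, nrow(oracle)))
    if (nrow(oracle) == 0) next
    n_checked <- n_checked + 1
    got_scores <- vapply(paths, `[[`, 0, "score")
    expect_equal(got_scores, oracle$score[seq_along(paths)], tolerance = 1e-9)
    expect_false(is.unsorted(round(got_scores, 9)))
    got_keys <- vapply(paths, function(p) paste(p$nodes, collapse = " -> "), "")
    expect_equal(got_keys, oracle$path[seq_along(paths)])
    # returned paths are simple and graph-valid
    for (p in paths) {
      expect_equal(anyDuplicated(p$nodes), 0)
      for (i in seq_len(length(p$nodes) - 1))
        expect_gt(igraph::get_edge_ids(rg$graph,
                                       c(p$nodes[i], p$nodes[i + 1])), 0)
    }
  }
  expect_gt(n_checked, 50)  # most random graphs connect source to target
})

test_that("all-pairs extraction yields k paths per reachable pair and skips unreachable ones", {
  net <- star_network(5)  # all spokes reachable from the hub
  igraph::V(net)$layer <- c("x", rep("pheno", 3), "x", "x")
  cfg <- simulation_config("hub", steps = 60, seed = 2)
  paths <- all_pairs_top_paths(net, inputs = "hub", target_layer = "pheno",
                               cfg = cfg, k = 3, seed = 2)
  expect_setequal(unique(paths$target), paste0("s", 1:3))
  expect_true(all(table(paths$target) <= 3))
  expect_true(all(paths$score >= unlist(lapply(paths$path, function(p)
    length(split_path(p)) - 1))))  # score >= path length since cc <= 1
  # per-target ranks ascend with score
  for (tg in unique(paths$target)) {
    sub <- paths[paths$target == tg, ]
    expect_false(is.unsorted(sub$score))
    expect_equal(sub$rank, seq_len(nrow(sub)))
  }
})

test_that("node path frequencies are path-count fractions", {
  pdf <- data.frame(input = "a", target = "d", rank = 1:3, score = 1:3,
                    path = c("a -> b -> d", "a -> b -> c -> d", "a -> d"),
                    stringsAsFactors = FALSE)
  f <- node_path_frequency(pdf)
  expect_equal(f[["a"]], 1)
  expect_equal(f[["b"]], 2 / 3)
  expect_equal(f[["c"]], 1 / 3)
  f2 <- node_path_frequency(pdf, nodes = c("a", "z"))
  expect_equal(f2[["z"]], 0)
  expect_error(node_path_frequency(pdf[0, ]), "empty")
})

test_that("phenotype co-occurrence counts consecutive phenotype pairs symmetrically", {
  pdf <- data.frame(path = c("a -> p1 -> p2", "a -> p1 -> p2 -> p3",
                             "a -> b -> p3"), stringsAsFactors = FALSE)
  M <- phenotype_cooccurrence(pdf, c("p1", "p2", "p3"))
  expect_equal(M, t(M))
  expect_equal(M["p1", "p2"], 2L)
  expect_equal(M["p2", "p3"], 1L)
  expect_equal(M["p1", "p3"], 0L)
  expect_equal(sum(diag(M)), 0L)
  M0 <- phenotype_cooccurrence(data.frame(path = "a -> b -> p1"),
                               c("p1", "p2"))
  expect_true(all(M0 == 0))
})
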