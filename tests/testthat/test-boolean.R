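test_that("the three-node worked example updates as the signed threshold rule dictates", {
  net <- triad_network()  # B-A weight -0.3, C-A weight +0.5
  states <- c(A = 0, B = 1, C = 1)
  s <- weighted_inputs(states, net)
  expect_equal(s[["A"]], 0.2)  # -0.3 + 0.5
  nxt <- update_step(states, net)
  expect_equal(nxt[["A"]], 1)  # positive net input activates A
  # second step: A active now drives its neighbors
  nxt2 <- update_step(nxt, net)
  expect_equal(nxt2[["C"]], 1)  # +0.5 from A keeps C active
  expect_equal(nxt2[["B"]], 0)  # -0.3 from A inactivates B
})

test_that("isolated nodes and exact ties become inactive", {
  net <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("c", "c"), weight = c(0.4, -0.4)),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c", "iso"), layer = "x"))
  nxt <- update_step(c(a = 1, b = 1, c = 1, iso = 1), net)
  expect_equal(nxt[["c"]], 0)    # tie: +0.4 - 0.4 = 0
  expect_equal(nxt[["iso"]], 0)  # no neighbors
  nxt0 <- update_step(c(a = 0, b = 0, c = 1, iso = 0), net)
  expect_equal(nxt0[["c"]], 0)   # all neighbors inactive -> sum 0
})

test_that("noise limits behave as flips", {
  s <- c(a = 1, b = 0, c = 1)
  set.seed(1)
  expect_identical(apply_noise(s, 0), s)
  expect_identical(apply_noise(s, 1), c(a = 0, b = 1, c = 0))
  expect_identical(apply_noise(s, 1, exempt = "b"), c(a = 0, b = 0, c = 0))
})

test_that("flip fraction matches the binomial rate at noise 0.05", {
  set.seed(2)
  n_nodes <- 100; n_steps <- 100
  flips <- 0
  s <- stats::setNames(rep(1, n_nodes), paste0("n", 1:n_nodes))
  for (i in 1:n_steps) flips <- flips + sum(apply_noise(s, 0.05) != s)
  rate <- flips / (n_nodes * n_steps)
  se <- sqrt(0.05 * 0.95 / (n_nodes * n_steps))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("square wave alternates with the configured half-period and phase", {
  w <- square_wave(25, 10, "active")
  expect_equal(w[1:10], rep(1, 10))
  expect_equal(w[11:20], rep(0, 10))
  expect_equal(w[21:25], rep(1, 5))
  expect_equal(square_wave(6, 2, "inactive"), c(0, 0, 1, 1, 0, 0))
})

test_that("forced simulations clamp the input exactly and are seed-deterministic", {
  net <- star_network(6)
  cfg <- simulation_config("hub", steps = 60, noise_prob = 0.05, seed = 99)
  tr1 <- run_forced_simulation(net, cfg)
  tr2 <- run_forced_simulation(net, cfg)
  expect_identical(unclass(tr1), unclass(tr2))
  expect_equal(dim(tr1), c(7, 60))
  expect_equal(tr1["hub", ], square_wave(60, 10, "active"))
  tr3 <- run_forced_simulation(net, simulation_config("hub", steps = 60,
                                                      seed = 100))
  expect_false(identical(unclass(tr1), unclass(tr3)))
  expect_error(run_forced_simulation(net, simulation_config("nope")),
               "unknown input node")
})

test_that("noise-free dynamics on an undirected positive chain propagate activation then saturate", {
  # input - a - b with positive weights: the clamped input is visible to its
  # neighbors within the step, so activation reaches a immediately and b one
  # step later; once a and b are both active they sustain each other even
  # when the input switches off (undirected positive feedback), so the
  # traces saturate rather than copying the wave
  net <- igraph::graph_from_data_frame(
    data.frame(from = c("in", "a"), to = c("a", "b"), weight = c(0.6, 0.6)),
    directed = FALSE,
    vertices = data.frame(name = c("in", "a", "b"), layer = "x"))
  cfg <- simulation_config("in", steps = 40, half_period = 10,
                           noise_prob = 0, init_active_prob = 0, seed = 1)
  tr <- run_forced_simulation(net, cfg)
  expect_equal(tr["in", ], square_wave(40, 10, "active"))
  expect_true(all(tr["a", ] == 1))      # activated by the clamped input
  expect_equal(unname(tr["b", 1]), 0)   # one-step delay through a
  expect_true(all(tr["b", 2:40] == 1))  # saturation: a and b lock active
})

test_that("spokes of a star copy the forcing wave exactly at zero noise", {
  # spokes have no other neighbors, so there is no feedback and every spoke
  # reproduces the clamped wave (visible within the same step)
  net <- star_network(4)
  cfg <- simulation_config("hub", steps = 50, half_period = 10,
                           noise_prob = 0, init_active_prob = 0, seed = 5)
  tr <- run_forced_simulation(net, cfg)
  w <- square_wave(50, 10, "active")
  for (s in paste0("s", 1:4))
    expect_equal(tr[s, ], w)
})

test_that("noise-free traces are eventually periodic (finite state space)", {
  set.seed(31)
  for (rep in 1:5) {
    nodes <- paste0("n", 1:6)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    net <- igraph::graph_from_data_frame(
      data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                 weight = round(runif(sum(keep), -1, 1), 2)),
      directed = FALSE, vertices = data.frame(name = nodes, layer = "x"))
    cfg <- simulation_config("n1", steps = 700, half_period = 5,
                             noise_prob = 0, seed = rep)
    tr <- run_forced_simulation(net, cfg)
    # deterministic dynamics on at most 2^5 states x 10 forcing phases must
    # revisit a (state, phase) pair within 321 steps; from the first revisit
    # the trajectory is exactly periodic
    keys <- paste(apply(tr, 2, paste, collapse = ""),
                  (seq_len(700) - 1L) %% 10L)
    t2 <- which(duplicated(keys))[1]
    t1 <- which(keys == keys[t2])[1]
    expect_lte(t2, 321)
    period <- t2 - t1
    horizon <- seq(t1, 700 - period)
    expect_equal(tr[, horizon + period], tr[, horizon], ignore_attr = TRUE)
  }
})

test_that("traces round-trip through delimited text", {
  net <- star_network(3)
  cfg <- simulation_config("hub", steps = 30, seed = 7)
  tr <- run_forced_simulation(net, cfg)
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(unclass(back), unclass(tr), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(tr))
})
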