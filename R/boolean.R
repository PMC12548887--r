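# Synchronous Boolean threshold dynamics on the signed network, with random
# initialization, per-node flip noise, and square-wave clamping of one input.

#' Configuration of a forced Boolean simulation
#'
#' @param input_node node id to clamp to the square wave.
#' @param steps number of iterations (default 100).
#' @param half_period iterations per forcing phase (default 10: 10 active,
#'   then 10 inactive).
#' @param noise_prob per-node per-step state-flip probability (default 0.05).
#' @param init_active_prob probability a node starts active (default 0.5).
#' @param input_initial_phase `"active"` or `"inactive"` first phase.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(input_node, steps = 100L, half_period = 10L,
                              noise_prob = 0.05, init_active_prob = 0.5,
                              input_initial_phase = c("active", "inactive"),
                              seed = 1L) {
  stopifnot(steps >= 1, half_period >= 1,
            noise_prob >= 0, noise_prob <= 1,
            init_active_prob >= 0, init_active_prob <= 1)
  structure(list(input_node = input_node, steps = as.integer(steps),
                 half_period = as.integer(half_period),
                 noise_prob = noise_prob, init_active_prob = init_active_prob,
                 input_initial_phase = match.arg(input_initial_phase),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Square-wave forcing signal
#'
#' @param steps total length.
#' @param half_period iterations per phase.
#' @param initial_phase `"active"` (starts at 1) or `"inactive"`.
#' @return 0/1 vector of length `steps`.
#' @export
square_wave <- function(steps, half_period, initial_phase = "active") {
  phase <- ((seq_len(steps) - 1L) %/% half_period) %% 2L
  if (initial_phase == "active") as.numeric(phase == 0L) else as.numeric(phase == 1L)
}

# Signed weighted adjacency matrix of a network (dense; node order = V(net)).
signed_adjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE))
}

#' Weighted inputs to each node
#'
#' For each node v, the signed sum over its neighbors u of
#' `weight(u, v) * state(u)`; inactive neighbors (state 0) contribute
#' nothing.
#'
#' @param states named 0/1 vector over all nodes.
#' @param net an igraph with signed edge attribute `weight`, or its
#'   precomputed adjacency matrix.
#' @return named numeric vector of weighted input sums.
#' @export
weighted_inputs <- function(states, net) {
  W <- if (is.matrix(net)) net else signed_adjacency(net)
  stopifnot(all(rownames(W) %in% names(states)))
  drop(W %*% states[rownames(W)])
}

#' One synchronous Boolean update step
#'
#' Every node becomes active iff its weighted input sum is strictly positive;
#' isolated nodes and exact ties (sum 0) become inactive.
#'
#' @inheritParams weighted_inputs
#' @return named 0/1 vector of next states.
#' @export
update_step <- function(states, net) {
  s <- weighted_inputs(states, net)
  stats::setNames(as.numeric(s > 0), names(s))
}

#' Apply flip noise to Boolean states
#'
#' Each non-exempt node independently flips its state with probability
#' `noise_prob` (draws from the current RNG stream).
#'
#' @param states named 0/1 vector.
#' @param noise_prob flip probability.
#' @param exempt node ids never flipped (e.g. the clamped input).
#' @return named 0/1 vector.
#' @export
apply_noise <- function(states, noise_prob, exempt = NULL) {
  if (noise_prob <= 0) return(states)
  flip <- runif(length(states)) < noise_prob
  if (!is.null(exempt)) flip[names(states) %in% exempt] <- FALSE
  states[flip] <- 1 - states[flip]
  states
}

#' Run a forced Boolean simulation
#'
#' Initializes every node active with probability `init_active_prob`, then at
#' each step: clamps the input node to the square wave, applies one
#' synchronous update to all other nodes, applies flip noise (input exempt),
#' and records the states. Deterministic given `cfg$seed`.
#'
#' @param net an igraph signed network.
#' @param cfg a [simulation_config()].
#' @return a `state_trace`: nodes x steps 0/1 matrix with rownames = node
#'   ids and attribute `config`.
#' @export
run_forced_simulation <- function(net, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nodes <- igraph::V(net)$name
  if (!cfg$input_node %in% nodes)
    stop("unknown input node '", cfg$input_node, "'")
  W <- signed_adjacency(net)
  wave <- square_wave(cfg$steps, cfg$half_period, cfg$input_initial_phase)
  set.seed(cfg$seed)
  state <- stats::setNames(as.numeric(rbinom(length(nodes), 1L,
                                             cfg$init_active_prob)), nodes)
  trace <- matrix(0, length(nodes), cfg$steps,
                  dimnames = list(nodes, NULL))
  for (t in seq_len(cfg$steps)) {
    state[cfg$input_node] <- wave[t]
    nxt <- update_step(state, W)
    nxt[cfg$input_node] <- wave[t]
    nxt <- apply_noise(nxt, cfg$noise_prob, exempt = cfg$input_node)
    trace[, t] <- nxt[nodes]
    state <- nxt
  }
  structure(trace, config = cfg, class = c("state_trace", "matrix", "array"))
}

#' Write / read a state trace as delimited text
#'
#' The trace is a nodes x time 0/1 matrix; the simulation configuration is
#' stored in a `#`-prefixed header block.
#'
#' @param trace a `state_trace`.
#' @param file output path (a `.gz` suffix writes gzip-compressed text).
#' @export
write_trace <- function(trace, file) {
  cfg <- attr(trace, "config")
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  hdr <- vapply(names(unclass(cfg)), function(k)
    sprintf("# %s: %s", k, as.character(cfg[[k]])), "")
  writeLines(hdr, con)
  write.table(unclass(trace)[, , drop = FALSE], con, sep = "\t",
              quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_trace
#' @param file path written by `write_trace`.
#' @export
read_trace <- function(file) {
  x <- read.table(file, sep = "\t", comment.char = "#", row.names = 1L)
  m <- as.matrix(x)
  dimnames(m) <- list(rownames(x), NULL)
  structure(m, class = c("state_trace", "matrix", "array"))
}
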