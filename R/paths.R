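# Cross-correlation of simulation traces, dynamic reweighting of the signed
# network, and k-lowest-score (loopless) path extraction.

#' Maximal lagged cross-correlation of two Boolean traces
#'
#' For each integer lag in `[-max_lag, max_lag]`, the Pearson correlation
#' between the overlapping segments of `u` and `v` shifted by the lag
#' (positive lag = `v` delayed relative to `u`). A zero-variance segment
#' yields correlation 0 at that lag. The maximum over lags is returned; ties
#' are broken towards the smallest absolute lag, then the smaller lag.
#'
#' @param u,v equal-length numeric series (0/1 traces).
#' @param max_lag largest lag magnitude considered.
#' @return list with `cc` (maximal correlation) and `lag` (its argmax).
#' @export
max_cross_correlation <- function(u, v, max_lag = 10L) {
  n <- length(u)
  stopifnot(length(v) == n)
  if (n < 2L * max_lag + 2L)
    stop("series too short for max_lag = ", max_lag)
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- u[seq_len(n - l)]; b <- v[seq_len(n - l) + l]
    } else {
      a <- u[seq_len(n + l) - l]; b <- v[seq_len(n + l)]
    }
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }, numeric(1))
  best <- max(cc)
  cand <- which(cc >= best - 1e-15)
  pick <- cand[order(abs(lags[cand]), lags[cand])][1L]
  list(cc = cc[pick], lag = lags[pick])
}

#' Cross-correlation map over the edges of a network
#'
#' Computes the maximal lagged cross-correlation for every edge of the
#' signed network from a simulation trace. No new edges are introduced:
#' the map is defined only on the original topology.
#'
#' @param trace a `state_trace` (nodes x steps).
#' @param net the signed igraph whose edges are scored.
#' @param max_lag lag window (default: the forcing half-period of the
#'   trace's config, else 10).
#' @return data.frame: from, to, cc, lag.
#' @export
cross_correlation_map <- function(trace, net, max_lag = NULL) {
  if (is.null(max_lag)) {
    cfg <- attr(trace, "config")
    max_lag <- if (!is.null(cfg)) cfg$half_period else 10L
  }
  el <- igraph::as_data_frame(net, what = "edges")
  cc <- numeric(nrow(el)); lag <- integer(nrow(el))
  for (i in seq_len(nrow(el))) {
    m <- max_cross_correlation(trace[el$from[i], ], trace[el$to[i], ], max_lag)
    cc[i] <- m$cc; lag[i] <- m$lag
  }
  data.frame(from = el$from, to = el$to, cc = cc, lag = lag,
             stringsAsFactors = FALSE)
}

#' Reweight a network by reciprocal cross-correlations
#'
#' Keeps the original topology; each edge receives length `1 / cc`. Edges
#' with `cc <= cc_floor` (including non-positive maxima) are dropped as
#' dynamically uninformative.
#'
#' @param net the signed igraph.
#' @param ccmap result of [cross_correlation_map()].
#' @param cc_floor minimum usable cross-correlation (default 1e-3).
#' @return an igraph with edge attributes `length` (= 1/cc) and `cc`.
#' @export
reweight_network <- function(net, ccmap, cc_floor = 1e-3) {
  keep <- ccmap$cc > cc_floor
  igraph::graph_from_data_frame(
    data.frame(from = ccmap$from[keep], to = ccmap$to[keep],
               length = 1 / ccmap$cc[keep], cc = ccmap$cc[keep],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = igraph::V(net)$name,
                          layer = igraph::V(net)$layer))
}

path_key <- function(nodes) paste(nodes, collapse = " -> ")

#' k lowest-score loopless paths
#'
#' The k simple paths of smallest score (sum of edge `length` along the
#' path), in ascending order, computed with a loopless k-shortest-paths
#' (Yen-type) search; ties are broken deterministically by lexicographic
#' node sequence. Fewer than k paths are returned if fewer exist; no path
#' yields an empty list.
#'
#' @param graph an igraph with positive edge attribute `length`.
#' @param source,target distinct node ids.
#' @param k number of paths (default 10).
#' @return list of `path_result` lists: `nodes`, `score`, `source`, `target`.
#' @export
k_lowest_score_paths <- function(graph, source, target, k = 10L) {
  stopifnot(!identical(source, target))
  nodes <- igraph::V(graph)$name
  if (!source %in% nodes) stop("unknown source '", source, "'")
  if (!target %in% nodes) stop("unknown target '", target, "'")
  len <- igraph::E(graph)$length
  d <- igraph::distances(graph, v = source, to = target, weights = len)
  if (!is.finite(d[1, 1])) return(list())

  k_req <- as.integer(k)
  repeat {
    res <- suppressWarnings(igraph::k_shortest_paths(
      graph, from = source, to = target, k = k_req, weights = len))
    scores <- vapply(res$epaths, function(ep)
      sum(igraph::edge_attr(graph, "length", ep)), numeric(1))
    exhausted <- length(scores) < k_req
    if (exhausted || length(scores) < k) break
    kth <- sort(scores)[k]
    if (scores[length(scores)] > kth + 1e-12) break  # full tie class captured
    if (k_req >= 10000L) break
    k_req <- k_req * 2L + 5L
  }
  seqs <- lapply(res$vpaths, names)
  keys <- vapply(seqs, path_key, "")
  # round before ordering so float noise in equal-score sums cannot override
  # the lexicographic tie-break
  ord <- order(round(scores, 9), keys)
  ord <- ord[seq_len(min(k, length(ord)))]
  lapply(ord, function(i)
    structure(list(nodes = seqs[[i]], score = scores[i], source = source,
                   target = target), class = "path_result"))
}

paths_to_frame <- function(paths, input) {
  if (length(paths) == 0L)
    return(data.frame(input = character(), target = character(),
                      rank = integer(), score = numeric(), path = character(),
                      stringsAsFactors = FALSE))
  data.frame(input = input,
             target = vapply(paths, `[[`, "", "target"),
             rank = seq_along(paths),
             score = vapply(paths, `[[`, 0, "score"),
             path = vapply(paths, function(p) path_key(p$nodes), ""),
             stringsAsFactors = FALSE)
}

#' Split a path string back into its node sequence
#'
#' @param path a path string produced by the path tables (`"a -> b -> c"`).
#' @return character vector of node ids.
#' @export
split_path <- function(path) strsplit(path, " -> ", fixed = TRUE)[[1L]]

#' Top paths for every input-target combination
#'
#' Runs one forced Boolean simulation per input node (sub-seed derived from
#' the master seed and the input's name), converts the trace into reciprocal
#' cross-correlation edge lengths, and extracts the k lowest-score paths to
#' every target node.
#'
#' @param net the signed igraph network.
#' @param inputs character vector of input (source) node ids.
#' @param targets character vector of target node ids, or `NULL` to use all
#'   nodes of `target_layer`.
#' @param target_layer layer whose nodes are the targets (default
#'   `"phenotype"`).
#' @param cfg a [simulation_config()] template; its `input_node` and `seed`
#'   are overridden per input.
#' @param k paths per (input, target) pair.
#' @param max_lag lag window (default `cfg$half_period`).
#' @param cc_floor see [reweight_network()].
#' @param seed master seed for the per-input simulations.
#' @return data.frame: input, target, rank, score, path. Unreachable
#'   targets contribute no rows.
#' @export
all_pairs_top_paths <- function(net, inputs, targets = NULL,
                                target_layer = "phenotype",
                                cfg = simulation_config(inputs[1L]),
                                k = 10L, max_lag = NULL, cc_floor = 1e-3,
                                seed = 1L) {
  if (is.null(targets))
    targets <- igraph::V(net)$name[igraph::V(net)$layer == target_layer]
  if (length(targets) == 0L) stop("no target nodes")
  if (is.null(max_lag)) max_lag <- cfg$half_period
  out <- list()
  for (inp in inputs) {
    icfg <- cfg
    icfg$input_node <- inp
    icfg$seed <- derive_seed(seed, paste0("sim:", inp))
    trace <- run_forced_simulation(net, icfg)
    ccmap <- cross_correlation_map(trace, net, max_lag)
    g <- reweight_network(net, ccmap, cc_floor)
    for (tg in setdiff(targets, inp)) {
      paths <- k_lowest_score_paths(g, inp, tg, k)
      out[[length(out) + 1L]] <- paths_to_frame(paths, inp)
    }
  }
  do.call(rbind, out)
}

#' Node path-appearance frequency
#'
#' For each network node appearing in a path collection, the fraction of
#' paths containing it.
#'
#' @param paths_df data.frame with a `path` column (as from
#'   [all_pairs_top_paths()]).
#' @param nodes optional node universe to report (others get 0).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
node_path_frequency <- function(paths_df, nodes = NULL) {
  if (nrow(paths_df) == 0L) stop("empty path collection")
  seqs <- lapply(paths_df$path, split_path)
  counts <- table(unlist(lapply(seqs, unique)))
  freq <- as.numeric(counts) / nrow(paths_df)
  names(freq) <- names(counts)
  if (!is.null(nodes)) {
    full <- stats::setNames(numeric(length(nodes)), nodes)
    full[names(freq)[names(freq) %in% nodes]] <-
      freq[names(freq) %in% nodes]
    freq <- full
  }
  freq
}

#' Phenotype-layer co-occurrence matrix
#'
#' Counts, over a path collection, how often each pair of phenotype-layer
#' nodes appears as consecutive nodes within a path. Symmetric.
#'
#' @param paths_df data.frame with a `path` column.
#' @param phenotype_nodes character vector of phenotype-layer node ids.
#' @return symmetric integer matrix over `phenotype_nodes`.
#' @export
phenotype_cooccurrence <- function(paths_df, phenotype_nodes) {
  M <- matrix(0L, length(phenotype_nodes), length(phenotype_nodes),
              dimnames = list(phenotype_nodes, phenotype_nodes))
  for (p in paths_df$path) {
    s <- split_path(p)
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      a <- s[i]; b <- s[i + 1L]
      if (a %in% phenotype_nodes && b %in% phenotype_nodes) {
        M[a, b] <- M[a, b] + 1L
        M[b, a] <- M[b, a] + 1L
      }
    }
  }
  M
}

#' Write a path collection as structured text
#'
#' @param paths_df data.frame from [all_pairs_top_paths()].
#' @param file output path.
#' @export
write_paths <- function(paths_df, file) {
  write.table(paths_df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
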