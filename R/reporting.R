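# Aggregate outputs: focal-node connectivity summaries, stratified per-group
# pipeline runs, source-restricted shortest-path selections, summary plots.

#' Connectivity of a focal node set across layers
#'
#' For each layer other than the focal nodes' own internal connections:
#' the number of multilayer-network edges between the focal set and that
#' layer, and the mean edge weight (normalized MI) over them.
#'
#' @param mln an igraph multilayer network (vertex attribute `layer`, edge
#'   attribute `weight`).
#' @param focal_nodes character vector of node ids.
#' @return data.frame: layer, n_edges, mean_weight (`NA` when no edges).
#' @export
focal_connectivity <- function(mln, focal_nodes) {
  nodes <- igraph::V(mln)$name
  if (!all(focal_nodes %in% nodes))
    stop("unknown focal node(s): ",
         paste(setdiff(focal_nodes, nodes), collapse = ", "))
  lay <- igraph::V(mln)$layer
  el <- igraph::as_data_frame(mln, what = "edges")
  a_f <- el$from %in% focal_nodes
  b_f <- el$to %in% focal_nodes
  ext <- xor(a_f, b_f)  # exactly one endpoint focal
  other <- ifelse(el$from[ext] %in% focal_nodes, el$to[ext], el$from[ext])
  other_layer <- lay[match(other, nodes)]
  layers <- unique(lay)
  data.frame(
    layer = layers,
    n_edges = vapply(layers, function(l) sum(other_layer == l), 0L),
    mean_weight = vapply(layers, function(l) {
      w <- el$weight[ext][other_layer == l]
      if (length(w)) mean(w) else NA_real_
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the thresholds and stage parameters of the full analysis:
#' association testing, network construction, Boolean simulation, path
#' extraction and (optionally) permutation controls. The master `seed`
#' governs every stage's sub-seeds.
#'
#' @param alpha edge significance level.
#' @param n_perm permutations per association test.
#' @param n_bins continuous bin count (`NULL` = [default_bins()]).
#' @param sim [simulation_config()] template (its input node is overridden
#'   per source).
#' @param source_layers layers whose nodes act as inputs (`NULL` = all
#'   non-target layers).
#' @param target_layer the phenotype layer name.
#' @param k paths per (input, target) pair.
#' @param max_lag,cc_floor see [cross_correlation_map()],
#'   [reweight_network()].
#' @param controls run [control_analysis()]?
#' @param n_networks,threshold,swaps_per_edge control parameters.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, n_perm = 1000L, n_bins = NULL,
                            sim = simulation_config("placeholder"),
                            source_layers = NULL, target_layer = "phenotype",
                            k = 10L, max_lag = NULL, cc_floor = 1e-3,
                            controls = FALSE, n_networks = 100L,
                            threshold = 0.01, swaps_per_edge = 10L,
                            seed = 1L) {
  structure(list(alpha = alpha, n_perm = as.integer(n_perm), n_bins = n_bins,
                 sim = sim, source_layers = source_layers,
                 target_layer = target_layer, k = as.integer(k),
                 max_lag = max_lag, cc_floor = cc_floor, controls = controls,
                 n_networks = as.integer(n_networks), threshold = threshold,
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full multilayer path-analysis pipeline on a cohort
#'
#' Associations -> multilayer MI network + connectance -> signed Pearson
#' network -> per-input Boolean simulations -> top-path extraction ->
#' optional permutation controls.
#'
#' @param cohort a `cohort` object.
#' @param config a [pipeline_config()].
#' @param inputs optional explicit input node ids (overrides
#'   `config$source_layers`).
#' @return list: `assoc`, `mln`, `connectance`, `signed`, `paths`,
#'   `node_frequency`, and `controls` (when requested).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), inputs = NULL) {
  assoc <- association_table(cohort, n_perm = config$n_perm,
                             n_bins = config$n_bins, seed = config$seed)
  mln <- build_multilayer_network(cohort, alpha = config$alpha, assoc = assoc)
  conn <- connectance_matrix(mln)
  signed <- build_signed_network(cohort, alpha = config$alpha, assoc = assoc)
  layers <- unique(cohort$meta$layer)
  src_layers <- if (is.null(config$source_layers))
    setdiff(layers, config$target_layer) else config$source_layers
  if (is.null(inputs))
    inputs <- cohort$meta$variable[cohort$meta$layer %in% src_layers]
  paths <- all_pairs_top_paths(
    signed, inputs = inputs, target_layer = config$target_layer,
    cfg = config$sim, k = config$k, max_lag = config$max_lag,
    cc_floor = config$cc_floor, seed = derive_seed(config$seed, "sims"))
  out <- list(assoc = assoc, mln = mln, connectance = conn, signed = signed,
              paths = paths,
              node_frequency = if (nrow(paths)) node_path_frequency(paths)
                               else numeric())
  if (isTRUE(config$controls) && nrow(paths) > 0) {
    out$controls <- control_analysis(
      paths, signed, cfg = config$sim, n_networks = config$n_networks,
      threshold = config$threshold, k = config$k, max_lag = config$max_lag,
      cc_floor = config$cc_floor, swaps_per_edge = config$swaps_per_edge,
      seed = derive_seed(config$seed, "controls"))
  }
  out
}

#' Stratified per-group pipeline runs
#'
#' Runs the whole pipeline separately within each diagnostic group, as in
#' stratified control / MCI / AD analyses. Groups below `min_n` subjects are
#' skipped with a warning.
#'
#' @param cohort a `cohort` object (its `group` factor defines the strata).
#' @param config a [pipeline_config()].
#' @param min_n minimum subjects per group (default 50).
#' @param inputs optional explicit input node ids.
#' @return named list of [run_pipeline()] results, one per retained group.
#' @export
stratified_run <- function(cohort, config = pipeline_config(), min_n = 50L,
                           inputs = NULL) {
  groups <- levels(cohort$group)
  out <- list()
  for (g in groups) {
    idx <- which(cohort$group == g)
    if (length(idx) < min_n) {
      warning("group '", g, "' has ", length(idx), " subjects (< ", min_n,
              "); skipped")
      next
    }
    sub <- cohort
    sub$data <- cohort$data[idx, , drop = FALSE]
    sub$group <- droplevels(cohort$group[idx])
    out[[g]] <- run_pipeline(sub, config, inputs = inputs)
  }
  out
}

#' Pooled lowest-score paths from restricted sources
#'
#' The `n` lowest-score paths from any of the given source nodes to any node
#' of the target layer, pooled and sorted by score (ties by lexicographic
#' node sequence).
#'
#' @param graph a reweighted igraph (edge attribute `length`, vertex
#'   attribute `layer`).
#' @param sources character vector of source node ids.
#' @param target_layer target layer name.
#' @param n number of paths returned (default 20).
#' @return data.frame: input, target, rank, score, path (empty when nothing
#'   is reachable).
#' @export
source_restricted_shortest_paths <- function(graph, sources,
                                             target_layer = "phenotype",
                                             n = 20L) {
  nodes <- igraph::V(graph)$name
  if (!all(sources %in% nodes))
    stop("unknown source(s): ", paste(setdiff(sources, nodes), collapse = ", "))
  targets <- nodes[igraph::V(graph)$layer == target_layer]
  pool <- list()
  for (s in sources) for (tg in setdiff(targets, s)) {
    paths <- k_lowest_score_paths(graph, s, tg, k = n)
    pool[[length(pool) + 1L]] <- paths_to_frame(paths, s)
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool) || nrow(pool) == 0L) return(paths_to_frame(list(), "x")[0, ])
  pool <- pool[order(pool$score, pool$path), , drop = FALSE]
  pool <- pool[seq_len(min(n, nrow(pool))), , drop = FALSE]
  pool$rank <- seq_len(nrow(pool))
  rownames(pool) <- NULL
  pool
}

#' Plot a connectance matrix as a heatmap
#'
#' @param C matrix from [connectance_matrix()].
#' @param main plot title.
#' @export
plot_connectance <- function(C, main = "Layer connectance") {
  L <- nrow(C)
  graphics::image(seq_len(L), seq_len(L), t(C[L:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
  graphics::axis(1, seq_len(L), colnames(C), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(L), rev(rownames(C)), las = 2, cex.axis = 0.8)
  for (i in seq_len(L)) for (j in seq_len(L))
    graphics::text(j, L - i + 1, sprintf("%.3f", C[i, j]), cex = 0.7)
  invisible(C)
}

#' Bar chart of node path-appearance frequencies
#'
#' @param freq named vector from [node_path_frequency()].
#' @param top show at most this many nodes (by frequency).
#' @export
plot_path_frequency <- function(freq, top = 20L) {
  freq <- sort(freq, decreasing = TRUE)
  freq <- freq[seq_len(min(top, length(freq)))]
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(freq, las = 2, ylab = "fraction of paths",
                    main = "Node path frequency", cex.names = 0.7)
  invisible(freq)
}
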