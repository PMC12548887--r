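# Per-layer MI networks, inter-layer bipartite edges, the assembled
# multilayer network, the signed Pearson network for dynamics, and
# connectivity (connectance) summaries.

assoc_subset <- function(cohort, vars_a, vars_b = NULL, n_perm, n_bins, seed,
                         assoc = NULL) {
  if (!is.null(assoc)) {
    if (is.null(vars_b)) {
      keep <- assoc$var_a %in% vars_a & assoc$var_b %in% vars_a
    } else {
      keep <- (assoc$var_a %in% vars_a & assoc$var_b %in% vars_b) |
              (assoc$var_a %in% vars_b & assoc$var_b %in% vars_a)
    }
    return(assoc[keep, , drop = FALSE])
  }
  if (is.null(vars_b)) {
    pairs <- t(combn(vars_a, 2L))
  } else {
    pairs <- as.matrix(expand.grid(vars_a, vars_b, stringsAsFactors = FALSE))
  }
  association_table(cohort, pairs = pairs, n_perm = n_perm, n_bins = n_bins,
                    seed = seed)
}

#' Build a within-layer mutual-information network
#'
#' Nodes are the layer's variables; an undirected edge joins every pair whose
#' one-tailed MI permutation p-value is below `alpha`, weighted by the
#' normalized mutual information.
#'
#' @param cohort a `cohort` object.
#' @param layer layer name.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per pair (default 1000).
#' @param n_bins continuous bin count (default [default_bins()]).
#' @param seed master seed for per-pair permutation streams.
#' @param assoc optional precomputed [association_table()] to reuse.
#' @return an igraph with vertex attribute `layer` and edge attributes
#'   `weight` (nmi), `mi`, `p`.
#' @export
build_layer_network <- function(cohort, layer, alpha = 0.05, n_perm = 1000L,
                                n_bins = NULL, seed = 1L, assoc = NULL) {
  vars <- cohort$meta$variable[cohort$meta$layer == layer]
  if (length(vars) == 0L) stop("unknown layer '", layer, "'")
  if (length(vars) < 2L) stop("layer '", layer, "' has fewer than 2 variables")
  a <- assoc_subset(cohort, vars, NULL, n_perm, n_bins, seed, assoc)
  sig <- a[!is.na(a$p_mi) & a$p_mi < alpha, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sig$var_a, to = sig$var_b, weight = sig$nmi,
               mi = sig$mi, p = sig$p_mi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = vars, layer = layer))
  g
}

#' Inter-layer bipartite edges
#'
#' Significant cross-layer pairs under the same MI permutation criterion and
#' nmi weighting as within-layer edges.
#'
#' @inheritParams build_layer_network
#' @param layer_i,layer_j distinct layer names.
#' @return data.frame: from, to, weight (nmi), mi, p.
#' @export
build_interlayer_edges <- function(cohort, layer_i, layer_j, alpha = 0.05,
                                   n_perm = 1000L, n_bins = NULL, seed = 1L,
                                   assoc = NULL) {
  if (identical(layer_i, layer_j)) stop("layers must be distinct")
  vi <- cohort$meta$variable[cohort$meta$layer == layer_i]
  vj <- cohort$meta$variable[cohort$meta$layer == layer_j]
  if (length(vi) == 0L) stop("unknown layer '", layer_i, "'")
  if (length(vj) == 0L) stop("unknown layer '", layer_j, "'")
  a <- assoc_subset(cohort, vi, vj, n_perm, n_bins, seed, assoc)
  sig <- a[!is.na(a$p_mi) & a$p_mi < alpha, , drop = FALSE]
  data.frame(from = sig$var_a, to = sig$var_b, weight = sig$nmi, mi = sig$mi,
             p = sig$p_mi, stringsAsFactors = FALSE)
}

#' Assemble a multilayer network
#'
#' Union of per-layer networks plus inter-layer edges; no hierarchy is
#' imposed — any pair of layers may be connected.
#'
#' @param layer_nets named list of [build_layer_network()] results.
#' @param interlayer_edges list of [build_interlayer_edges()] data.frames.
#' @return an igraph whose vertices carry a `layer` attribute.
#' @export
assemble_multilayer <- function(layer_nets, interlayer_edges = list()) {
  verts <- do.call(rbind, lapply(layer_nets, function(g)
    data.frame(name = igraph::V(g)$name, layer = igraph::V(g)$layer,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(verts$name))
    stop("duplicated node across layers: ",
         paste(unique(verts$name[duplicated(verts$name)]), collapse = ", "))
  edge_frames <- lapply(layer_nets, function(g) {
    e <- igraph::as_data_frame(g, what = "edges")
    if (nrow(e) == 0)
      e <- data.frame(from = character(), to = character(), weight = numeric(),
                      mi = numeric(), p = numeric())
    e[, c("from", "to", "weight", "mi", "p")]
  })
  inter <- lapply(interlayer_edges, function(e)
    e[, c("from", "to", "weight", "mi", "p"), drop = FALSE])
  edges <- do.call(rbind, c(edge_frames, inter))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Convenience builder for the full multilayer network
#'
#' All per-layer networks and all inter-layer edge sets from one association
#' table (computed once if not supplied).
#'
#' @inheritParams build_layer_network
#' @return an igraph multilayer network.
#' @export
build_multilayer_network <- function(cohort, alpha = 0.05, n_perm = 1000L,
                                     n_bins = NULL, seed = 1L, assoc = NULL) {
  if (is.null(assoc))
    assoc <- association_table(cohort, n_perm = n_perm, n_bins = n_bins,
                               seed = seed)
  layers <- unique(cohort$meta$layer)
  nets <- lapply(layers, function(l)
    build_layer_network(cohort, l, alpha, n_perm, n_bins, seed, assoc))
  names(nets) <- layers
  lp <- t(combn(layers, 2L))
  inter <- lapply(seq_len(nrow(lp)), function(i)
    build_interlayer_edges(cohort, lp[i, 1L], lp[i, 2L], alpha, n_perm,
                           n_bins, seed, assoc))
  assemble_multilayer(nets, inter)
}

#' Weighted network density
#'
#' `2 * sum(weights) / (|V| * (|V| - 1))`: the unweighted connection density
#' with the edge count replaced by the sum of edge weights.
#'
#' @param net an igraph with edge attribute `weight`.
#' @return weighted density.
#' @export
weighted_density <- function(net) {
  nv <- igraph::vcount(net)
  if (nv < 2L) stop("density undefined for fewer than 2 nodes")
  w <- if (igraph::ecount(net) == 0) 0 else sum(igraph::E(net)$weight)
  2 * w / (nv * (nv - 1))
}

#' Bipartite (inter-layer) weighted density
#'
#' Sum of inter-layer edge weights divided by the maximum possible number of
#' cross connections `n_i * n_j`.
#'
#' @param edges data.frame with a `weight` column (or a numeric vector of
#'   weights); the inter-layer edges.
#' @param n_i,n_j layer sizes (>= 1).
#' @return bipartite weighted density.
#' @export
bipartite_density <- function(edges, n_i, n_j) {
  if (n_i < 1L || n_j < 1L) stop("empty layer")
  w <- if (is.data.frame(edges)) edges$weight else edges
  sum(w) / (n_i * n_j)
}

#' Connectance matrix of a multilayer network
#'
#' Symmetric L x L matrix: diagonal entries are within-layer weighted
#' densities, off-diagonal entries bipartite weighted densities between the
#' two layers.
#'
#' @param mln an igraph multilayer network (vertex attribute `layer`).
#' @return numeric matrix with layer-name dimnames.
#' @export
connectance_matrix <- function(mln) {
  lay <- igraph::V(mln)$layer
  layers <- unique(lay)
  L <- length(layers)
  sizes <- table(factor(lay, levels = layers))
  if (any(sizes == 0)) stop("empty layer")
  el <- igraph::as_data_frame(mln, what = "edges")
  la <- lay[match(el$from, igraph::V(mln)$name)]
  lb <- lay[match(el$to, igraph::V(mln)$name)]
  C <- matrix(0, L, L, dimnames = list(layers, layers))
  for (i in seq_len(L)) {
    ni <- sizes[[i]]
    if (ni >= 2) {
      win <- sum(el$weight[la == layers[i] & lb == layers[i]])
      C[i, i] <- 2 * win / (ni * (ni - 1))
    }
    for (j in seq_len(L)[-seq_len(i)]) {
      cross <- (la == layers[i] & lb == layers[j]) |
               (la == layers[j] & lb == layers[i])
      C[i, j] <- C[j, i] <- sum(el$weight[cross]) / (ni * sizes[[j]])
    }
  }
  C
}

#' Build the signed Pearson network
#'
#' One network over all layers jointly: an edge joins every variable pair
#' significant under the two-tailed Pearson permutation test, weighted by the
#' signed correlation coefficient (positive = activating, negative =
#' inhibitory). Pairs with a constant member carry no edge. Disconnected
#' nodes are retained.
#'
#' @inheritParams build_layer_network
#' @return an igraph with vertex attribute `layer` and edge attributes
#'   `weight` (signed r) and `p`.
#' @export
build_signed_network <- function(cohort, alpha = 0.05, n_perm = 1000L,
                                 seed = 1L, assoc = NULL) {
  if (nrow(cohort$meta) < 2L) stop("need at least 2 variables")
  if (is.null(assoc))
    assoc <- association_table(cohort, n_perm = n_perm, seed = seed)
  sig <- assoc[!is.na(assoc$p_r) & assoc$p_r < alpha & assoc$r != 0, ,
               drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = sig$var_a, to = sig$var_b, weight = sig$r, p = sig$p_r,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = cohort$meta$variable,
                          layer = cohort$meta$layer))
}

#' Average shortest path length
#'
#' Mean over ordered node pairs of the shortest-path distance, with edge
#' length taken as the reciprocal of the edge weight (strong connections =
#' short distances).
#'
#' @param net an igraph with positive edge attribute `weight`.
#' @param largest_component if `TRUE`, restrict to the largest connected
#'   component instead of erroring on a disconnected graph.
#' @return average shortest path length.
#' @export
average_shortest_path_length <- function(net, largest_component = FALSE) {
  if (!igraph::is_connected(net)) {
    if (!largest_component) stop("graph is disconnected; set largest_component = TRUE")
    comp <- igraph::components(net)
    net <- igraph::induced_subgraph(net, which(comp$membership ==
                                               which.max(comp$csize)))
  }
  nv <- igraph::vcount(net)
  if (nv < 2L) stop("need at least 2 nodes")
  D <- igraph::distances(net, weights = 1 / igraph::E(net)$weight)
  sum(D[upper.tri(D)]) * 2 / (nv * (nv - 1))
}

#' Write a network as a flat edge list / node-link text
#'
#' `write_edge_list` writes a tab-delimited edge table (source, target,
#' weight, further edge attributes); `write_node_link` writes a JSON-like
#' node-link structure via [yaml::write_yaml()] (nodes: id, layer; links:
#' source, target, attributes).
#'
#' @param net an igraph.
#' @param file output path.
#' @export
write_edge_list <- function(net, file) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  write.table(el, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
write_node_link <- function(net, file) {
  nodes <- igraph::as_data_frame(net, what = "vertices")
  links <- igraph::as_data_frame(net, what = "edges")
  names(links)[1:2] <- c("source", "target")
  yaml::write_yaml(list(nodes = lapply(seq_len(nrow(nodes)), function(i)
                          as.list(nodes[i, , drop = FALSE])),
                        links = lapply(seq_len(nrow(links)), function(i)
                          as.list(links[i, , drop = FALSE]))),
                   file)
  invisible(file)
}
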