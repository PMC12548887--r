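# Independent oracles used across tests.

# Mutual information (nats) by direct summation over a contingency table.
mi_from_table <- function(tab) {
  N <- sum(tab)
  px <- rowSums(tab) / N
  py <- colSums(tab) / N
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / N
    if (pij > 0) mi <- mi + pij * log(pij / (px[i] * py[j]))
  }
  mi
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Exhaustive enumeration of all simple paths from source to target with their
# scores, by recursive depth-first search over an edge-length list. Returns a
# data.frame sorted by (score, lexicographic joined node sequence).
enumerate_simple_paths <- function(edges, source, target) {
  # edges: data.frame from, to, length (undirected)
  nb <- list()
  add <- function(a, b, l) {
    nb[[a]] <<- rbind(nb[[a]], data.frame(to = b, len = l,
                                          stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$from[i], edges$to[i], edges$length[i])
    add(edges$to[i], edges$from[i], edges$length[i])
  }
  out <- list()
  recurse <- function(node, visited, score) {
    if (node == target) {
      out[[length(out) + 1L]] <<- list(path = paste(visited, collapse = " -> "),
                                       score = score)
      return(invisible())
    }
    step <- nb[[node]]
    if (is.null(step)) return(invisible())
    for (i in seq_len(nrow(step))) {
      nxt <- step$to[i]
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), score + step$len[i])
    }
  }
  recurse(source, source, 0)
  if (length(out) == 0L)
    return(data.frame(path = character(), score = numeric()))
  df <- data.frame(path = vapply(out, `[[`, "", "path"),
                   score = vapply(out, `[[`, 0, "score"),
                   stringsAsFactors = FALSE)
  df[order(round(df$score, 9), df$path), , drop = FALSE]
}

# Random connected-ish weighted graph for path-oracle tests.
random_length_graph <- function(n_nodes, p_edge = 0.5) {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      length = round(runif(sum(keep), 0.5, 3), 2),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$layer <- "x"
  list(graph = g, edges = edges, nodes = nodes)
}

# Small hand-built signed network: Fig-1-style triad.
triad_network <- function(w_ba = -0.3, w_ca = 0.5) {
  igraph::graph_from_data_frame(
    data.frame(from = c("B", "C"), to = c("A", "A"),
               weight = c(w_ba, w_ca)),
    directed = FALSE,
    vertices = data.frame(name = c("A", "B", "C"), layer = "x"))
}

# Star-forced network: hub input with positive spokes; spokes copy the
# forcing wave with delay 1, so it is strongly coupled without feedback.
star_network <- function(n_spokes = 8, w = 0.8) {
  spokes <- paste0("s", seq_len(n_spokes))
  igraph::graph_from_data_frame(
    data.frame(from = "hub", to = spokes, weight = w),
    directed = FALSE,
    vertices = data.frame(name = c("hub", spokes), layer = "x"))
}
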