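# small graph constructors used across the suite

graph_from_pairs <- function(from, to, isolated = character(0)) {
  nodes <- unique(c(from, to, isolated))
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
}

named_graph <- function(g, prefix = "n") {
  igraph::V(g)$name <- paste0(prefix, seq_len(igraph::vcount(g)))
  g
}

random_named_gnp <- function(n, p) {
  named_graph(igraph::sample_gnp(n, p))
}

random_named_gnm <- function(n, m) {
  named_graph(igraph::sample_gnm(n, m))
}

# block-structured distance matrix: within-cluster distance `within`,
# between-cluster `between`
block_distance_matrix <- function(labels, within = 0.1, between = 0.9) {
  nms <- labels$name
  M <- matrix(between, length(nms), length(nms), dimnames = list(nms, nms))
  for (cl in unique(labels$cluster)) {
    i <- nms[labels$cluster == cl]
    M[i, i] <- within
  }
  diag(M) <- 0
  M
}

cluster_labels <- function(n_clusters, size, prefix = "g") {
  nms <- sprintf("%s%02d", prefix, seq_len(n_clusters * size))
  data.frame(name = nms, cluster = rep(LETTERS[seq_len(n_clusters)],
                                       each = size),
             stringsAsFactors = FALSE)
}
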