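#' Catalog of connected subgraph types on k nodes
#'
#' The isomorphism classes of connected simple graphs on `k` nodes, in the
#' fixed order used for all count vectors: for `k = 3` the 3-path and the
#' triangle; for `k = 4` the 4-path, the 3-star (claw), the 4-cycle, the paw
#' (triangle plus pendant edge), the diamond (K4 minus an edge) and the
#' complete graph K4.
#'
#' @param k Subgraph order, 3 or 4.
#' @return A character vector of type names, with attribute `k`.
#' @export
subgraph_catalog <- function(k) {
  if (!(length(k) == 1 && k %in% c(3, 4))) {
    stop("unsupported subgraph order: k must be 3 or 4")
  }
  types <- if (k == 3) {
    c("p3", "k3")
  } else {
    c("p4", "claw", "c4", "paw", "diamond", "k4")
  }
  structure(types, k = k)
}

count_cols <- function(k) if (k == 3) 1:2 else 3:8

#' Count connected induced k-node subgraphs
#'
#' Counts, for each type in [subgraph_catalog()], the number of k-node
#' subsets of the graph whose induced subgraph is connected and of that
#' type. Uses combinatorial degree/codegree/triangle formulas (compiled),
#' which agree exactly with exhaustive enumeration
#' ([count_by_enumeration()]).
#'
#' @param g An igraph graph.
#' @param k Subgraph order, 3 or 4.
#' @return A named numeric vector of counts, one per catalog type.
#' @export
count_induced <- function(g, k = 4) {
  types <- subgraph_catalog(k)
  if (igraph::vcount(g) < k) {
    return(stats::setNames(numeric(length(types)), types))
  }
  all8 <- count34_cpp(adj_list0(g))
  stats::setNames(all8[count_cols(k)], types)
}

#' Count connected induced k-node subgraphs by exhaustive enumeration
#'
#' Brute-force oracle: iterates over all k-node subsets, tests connectivity
#' of the induced subgraph and classifies it by its sorted degree sequence
#' (for connected graphs on at most 4 nodes the degree sequence, together
#' with the edge count, identifies the class; the triangle count is implied).
#' Intended for small graphs and as an independent check of
#' [count_induced()].
#'
#' @param g An igraph graph (at most a few thousand k-subsets recommended).
#' @param k Subgraph order, 3 or 4.
#' @return A named numeric vector of counts, one per catalog type.
#' @export
count_by_enumeration <- function(g, k = 4) {
  types <- subgraph_catalog(k)
  counts <- stats::setNames(numeric(length(types)), types)
  n <- igraph::vcount(g)
  if (n < k) return(counts)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- (A > 0) + 0
  subsets <- utils::combn(n, k)
  for (i in seq_len(ncol(subsets))) {
    B <- A[subsets[, i], subsets[, i]]
    deg <- rowSums(B)
    if (min(deg) == 0) next
    # reachability check on <= 4 nodes
    R <- diag(k) + B
    R <- (R %*% R %*% R) > 0
    if (!all(R[1, ])) next
    sig <- paste(sort(deg), collapse = "")
    cls <- switch(sig,
      "112" = "p3", "222" = "k3",
      "1122" = "p4", "1113" = "claw", "2222" = "c4",
      "1223" = "paw", "2233" = "diamond", "3333" = "k4",
      NA_character_
    )
    counts[cls] <- counts[cls] + 1
  }
  counts
}

#' Per-ego subgraph census of a graph
#'
#' Extracts the two-step ego-network of each requested node and counts the
#' connected induced k-node subgraphs in each, returning one row per ego.
#' This is the basic ingredient of the Netdis statistic; all counting runs
#' in compiled code on the full graph's adjacency structure.
#'
#' @param g An igraph graph.
#' @param k Subgraph order, 3 or 4 (default 4).
#' @param ego_ids Character vector of ego node names; `NULL` (default)
#'   censuses every node.
#' @return A data frame with columns `ego`, `n_nodes`, `n_edges`, `density`
#'   and one count column per catalog type, of class `ego_census`.
#' @export
ego_census <- function(g, k = 4, ego_ids = NULL) {
  types <- subgraph_catalog(k)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  if (is.null(ego_ids)) {
    idx <- seq_along(vn)
    ego_ids <- vn
  } else {
    idx <- match(ego_ids, vn)
    if (anyNA(idx)) stop("unknown ego node(s): ",
                         paste(ego_ids[is.na(idx)], collapse = ", "))
  }
  m <- ego_census_cpp(adj_list0(g), as.integer(idx - 1L))
  nn <- m[, 1]
  dens <- ifelse(nn >= 2, 2 * m[, 2] / (nn * (nn - 1)), 0)
  out <- data.frame(
    ego = ego_ids, n_nodes = nn, n_edges = m[, 2], density = dens,
    stringsAsFactors = FALSE
  )
  cnt <- m[, count_cols(k) + 2, drop = FALSE]
  colnames(cnt) <- types
  out <- cbind(out, as.data.frame(cnt))
  attr(out, "k") <- k
  class(out) <- c("ego_census", "data.frame")
  out
}

#' Write a per-ego census as TSV
#'
#' @param census An [ego_census()] data frame.
#' @param path Output file path.
#' @export
write_ego_census <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
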