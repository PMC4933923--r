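#' @useDynLib egonetdis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-comment line names one edge by its two endpoint labels; extra
#' tokens (e.g. weights) are ignored. Lines starting with `#` are comments.
#' A line with a single token declares an isolated node. Duplicate edges
#' (in either orientation) collapse to one edge and self-loops are dropped,
#' each with a warning, so the result is always a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @return An [igraph::igraph] object with character vertex names.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  toks <- toks[vapply(toks, function(x) length(x) > 0 && nzchar(x[1]), logical(1))]
  if (length(toks) == 0) stop("empty graph: no nodes or edges in ", path)

  ntok <- vapply(toks, length, integer(1))
  if (any(ntok > 2)) {
    warning("extra tokens (e.g. edge weights) ignored on ",
            sum(ntok > 2), " line(s); graphs are treated as unweighted")
  }
  singles <- vapply(toks[ntok == 1], `[`, character(1), 1)
  pairs <- toks[ntok >= 2]
  from <- vapply(pairs, `[`, character(1), 1)
  to <- vapply(pairs, `[`, character(1), 2)

  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop line(s)")
    from <- from[!loops]
    to <- to[!loops]
  }
  nodes <- unique(c(from, to, singles))
  if (length(nodes) == 0) stop("empty graph: no nodes or edges in ", path)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a whitespace-separated edge list
#'
#' Isolated nodes are written as single-token lines so that a read/write
#' round trip preserves the node set.
#'
#' @param g An igraph graph.
#' @param path Output file path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  iso <- setdiff(igraph::V(g)$name, unique(c(el[, 1], el[, 2])))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(el) > 0) writeLines(paste(el[, 1], el[, 2]), con)
  if (length(iso) > 0) writeLines(iso, con)
  invisible(path)
}

#' Edge density of a graph
#'
#' Returns 2|E| / (|V| (|V|-1)), and 0 for graphs with fewer than two nodes.
#'
#' @param g An igraph graph.
#' @return A fraction in \[0, 1\].
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Two-step ego-network of a node
#'
#' The induced subgraph on all nodes within two edges of the focal node
#' (including the node itself), with every edge of the parent graph between
#' those nodes. Distances are unweighted hop counts.
#'
#' @param g An igraph graph.
#' @param v A vertex name (or index) present in `g`.
#' @return An object of class `ego_network`: a list with elements `ego`
#'   (the focal node's name), `graph` (the induced igraph subgraph) and
#'   `density` (its edge density).
#' @export
two_step_ego <- function(g, v) {
  if (is.character(v) && !(v %in% igraph::V(g)$name)) {
    stop("unknown node: ", v)
  }
  sub <- igraph::make_ego_graph(g, order = 2, nodes = v, mode = "all")[[1]]
  vname <- if (is.character(v)) v else igraph::V(g)$name[v]
  structure(
    list(ego = vname, graph = sub, density = graph_density(sub)),
    class = "ego_network"
  )
}

#' @export
print.ego_network <- function(x, ...) {
  cat("Two-step ego-network of node '", x$ego, "': ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges, density ", signif(x$density, 4), "\n", sep = "")
  invisible(x)
}

# 0-based sorted adjacency lists for the C++ census routines
adj_list0 <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  src <- c(el[, 1], el[, 2])
  dst <- c(el[, 2], el[, 1])
  o <- order(src, dst)
  adj <- split(as.integer(dst[o] - 1L), factor(src[o], levels = seq_len(n)))
  unname(adj)
}
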