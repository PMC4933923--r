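#' Build a density-binned expectation table from a reference graph
#'
#' Computes the two-step ego-network of every node of the reference graph,
#' bins the egos by edge density into intervals of width `bin_width`
#' (`[i * bin_width, (i + 1) * bin_width)`), and stores the mean subgraph
#' count vector of each non-empty bin. At query time a density maps to its
#' bin, falling back to the nearest non-empty bin (ties towards lower
#' density), so every query resolves to exactly one expectation vector.
#'
#' @param ref An igraph graph with at least one edge.
#' @param k Subgraph order, 3 or 4 (default 4).
#' @param bin_width Density-bin width in (0, 1]; default 0.01.
#' @param ref_name Identifier recorded as the table's provenance.
#' @return An object of class `expectation_table`.
#' @export
build_expectation_table <- function(ref, k = 4, bin_width = 0.01,
                                    ref_name = "reference") {
  if (igraph::ecount(ref) == 0) {
    stop("degenerate reference: graph has no edges")
  }
  if (!(bin_width > 0 && bin_width <= 1)) stop("bin_width must be in (0, 1]")
  types <- subgraph_catalog(k)
  cen <- ego_census(ref, k = k)
  n_bins <- floor(1 / bin_width) + 1L # densities in [0, 1]; 1.0 gets own bin
  bin <- pmin(floor(cen$density / bin_width), n_bins - 1L)
  cnt <- as.matrix(cen[, types, drop = FALSE])
  means <- rowsum(cnt, group = bin, reorder = TRUE)
  n_per <- as.vector(table(bin))
  means <- means / n_per
  occupied <- as.integer(rownames(means))

  # precompute nearest-non-empty-bin lookup for every possible query bin
  lookup <- vapply(0:(n_bins - 1L), function(b) {
    d <- abs(occupied - b)
    # ties resolved towards the lower-density bin
    occupied[order(d, occupied)][1]
  }, integer(1))

  structure(
    list(k = k, bin_width = bin_width, types = types,
         bins = data.frame(bin = occupied, lower = occupied * bin_width,
                           n_egos = n_per, means, check.names = FALSE),
         expectations = means, lookup = lookup, n_bins = n_bins,
         provenance = ref_name),
    class = "expectation_table"
  )
}

#' @export
print.expectation_table <- function(x, ...) {
  cat("Netdis expectation table (k = ", x$k, ", bin width ", x$bin_width,
      ")\n  reference: ", x$provenance, "\n  ", nrow(x$bins),
      " non-empty density bin(s) from ", sum(x$bins$n_egos),
      " reference ego-networks\n", sep = "")
  invisible(x)
}

#' Expected subgraph counts at given ego densities
#'
#' @param table An [build_expectation_table()] object.
#' @param density Numeric vector of ego densities in \[0, 1\].
#' @return A matrix with one row per density, one column per type.
#' @export
expected_counts <- function(table, density) {
  b <- pmin(floor(density / table$bin_width), table$n_bins - 1L)
  tgt <- table$lookup[b + 1L]
  table$expectations[match(tgt, table$bins$bin), , drop = FALSE]
}

#' Write an expectation table as TSV
#'
#' @param table An expectation table.
#' @param path Output file path.
#' @export
write_expectation_table <- function(table, path) {
  utils::write.table(table$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# centered per-ego count matrix: observed minus density-matched expectation
centered_matrix <- function(census, table) {
  stopifnot(attr(census, "k") == table$k)
  obs <- as.matrix(census[, table$types, drop = FALSE])
  obs - expected_counts(table, census$density)
}

#' Sum of centered subgraph counts over ego-networks
#'
#' For each subgraph type w, S_w(G) is the sum over the listed ego-networks
#' of the observed count minus the expected count among reference
#' ego-networks of similar density. Ego-networks with fewer than k nodes
#' contribute 0 observed counts (minus the expectation) under the same rule.
#'
#' @param g An igraph graph.
#' @param table An [build_expectation_table()] object.
#' @param ego_ids Character vector of ego nodes to sum over; `NULL` uses
#'   every node.
#' @param census Optionally, a precomputed [ego_census()] of `g` covering
#'   `ego_ids` (rows are subset by ego name); avoids recounting.
#' @return An object of class `centered_sums`: list with `k`, the named
#'   vector `S`, and `n_egos_used`.
#' @export
centered_sums <- function(g, table, ego_ids = NULL, census = NULL) {
  if (!is.null(ego_ids) && length(ego_ids) == 0) {
    stop("empty ego sample: no ego-networks to sum over")
  }
  if (is.null(census)) {
    census <- ego_census(g, k = table$k, ego_ids = ego_ids)
  } else if (!is.null(ego_ids)) {
    idx <- match(ego_ids, census$ego)
    if (anyNA(idx)) stop("census does not cover all requested egos")
    census <- census[idx, , drop = FALSE]
    attr(census, "k") <- table$k
  }
  cm <- centered_matrix(census, table)
  structure(
    list(k = table$k, S = colSums(cm), n_egos_used = nrow(cm)),
    class = "centered_sums"
  )
}

#' @export
print.centered_sums <- function(x, ...) {
  cat("Centered subgraph count sums (k = ", x$k, ", ", x$n_egos_used,
      " ego-networks)\n", sep = "")
  print(signif(x$S, 6))
  invisible(x)
}

#' The netD2s statistic and Netdis distance for two centered-sum vectors
#'
#' Each type's sums are rescaled as s_w(G) = S_w(G) / sqrt(S_w(G)^2 +
#' S_w(H)^2), and netD2s is the normalised inner product
#' sum_w s_w(G) s_w(H) / sqrt(sum_w s_w(G)^2 * sum_w s_w(H)^2), which lies
#' in \[-1, 1\] by the Cauchy-Schwarz inequality. The Netdis distance is
#' (1 - netD2s) / 2 in \[0, 1\]. Types with S_w(G)^2 + S_w(H)^2 = 0 carry no
#' information about the pair and are excluded from all three sums.
#'
#' @param SG,SH `centered_sums` objects of the same order k, not both zero.
#' @return An object of class `netdis_result`: list with `netd2s`, `netdis`
#'   and `per_type_terms` (each type's contribution to the numerator).
#' @export
netd2s <- function(SG, SH) {
  stopifnot(inherits(SG, "centered_sums"), inherits(SH, "centered_sums"))
  if (SG$k != SH$k) stop("centered sums have different subgraph orders")
  a <- SG$S
  b <- SH$S
  denom <- sqrt(a^2 + b^2)
  keep <- denom > 0
  if (!any(keep)) {
    stop("degenerate comparison: all centered sums are zero in both networks")
  }
  sa <- a[keep] / denom[keep]
  sb <- b[keep] / denom[keep]
  terms <- stats::setNames(numeric(length(a)), names(a))
  norm <- sqrt(sum(sa^2) * sum(sb^2))
  terms[keep] <- sa * sb / norm
  val <- sum(sa * sb) / norm
  val <- max(-1, min(1, val)) # guard rounding at the Cauchy-Schwarz bound
  structure(
    list(netd2s = val, netdis = (1 - val) / 2, per_type_terms = terms),
    class = "netdis_result"
  )
}

#' @export
print.netdis_result <- function(x, ...) {
  cat("netD2s = ", signif(x$netd2s, 6), ";  Netdis = ",
      signif(x$netdis, 6), "\n", sep = "")
  invisible(x)
}

#' Netdis distance between two graphs
#'
#' Convenience wrapper: centered sums over all (or sampled) ego-networks of
#' each graph, then the Netdis distance.
#'
#' @param g,h igraph graphs.
#' @param table An expectation table.
#' @param spec Optional [sample_spec()]; `NULL` uses all ego-networks.
#' @return A `netdis_result`.
#' @export
netdis <- function(g, h, table, spec = NULL) {
  ids_g <- if (is.null(spec)) NULL else sample_ego_ids(g, spec, stream = "G")
  ids_h <- if (is.null(spec)) NULL else sample_ego_ids(h, spec, stream = "H")
  netd2s(centered_sums(g, table, ids_g), centered_sums(h, table, ids_h))
}

#' Pairwise Netdis distance matrix
#'
#' Computes the Netdis distance for every pair of graphs. Each graph's ego
#' sample (if any) is drawn once, from a substream derived from the run seed
#' and the graph's name, and reused across all pairwise comparisons, so the
#' matrix is internally consistent. Degenerate pairs (all centered sums
#' zero) yield `NA` with a warning.
#'
#' @param graphs Named list of igraph graphs (length >= 2).
#' @param table An expectation table.
#' @param spec Optional [sample_spec()]; `NULL` uses all ego-networks.
#' @return A symmetric numeric matrix of class `netdis_matrix` with zero
#'   diagonal and graph names as dimnames.
#' @export
pairwise_netdis <- function(graphs, table, spec = NULL) {
  n <- length(graphs)
  if (n < 2) stop("need at least two graphs")
  nms <- names(graphs)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))) {
    stop("graphs must be a list with unique non-empty names")
  }
  sums <- lapply(nms, function(nm) {
    ids <- if (is.null(spec)) NULL else {
      sample_ego_ids(graphs[[nm]], spec, stream = nm)
    }
    centered_sums(graphs[[nm]], table, ids)
  })
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(netd2s(sums[[i]], sums[[j]])$netdis,
                    error = function(e) NA_real_)
      if (is.na(d)) {
        warning("degenerate comparison between '", nms[i], "' and '",
                nms[j], "'; entry set to NA")
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  class(D) <- c("netdis_matrix", "matrix", "array")
  D
}

#' @export
print.netdis_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
round.netdis_matrix <- function(x, digits = 0) {
  structure(round(unclass(x), digits), class = class(x))
}

#' Write a distance matrix as TSV
#'
#' Full symmetric matrix with row and column headers, 6 significant digits,
#' missing entries as `NA`.
#'
#' @param D A distance matrix with dimnames.
#' @param path Output file path.
#' @export
write_distance_matrix <- function(D, path) {
  M <- signif(unclass(D), 6)
  df <- data.frame(name = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path TSV file path.
#' @return A numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}
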