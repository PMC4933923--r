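#' Dependency-neighbourhood balance statistics
#'
#' The sub-sampling theory behind ego-network sampling assumes the
#' dependency neighbourhoods (two-step ego node sets) do not vary too much
#' in size and do not overlap too heavily on average. This computes the
#' exact neighbourhood size gamma_i = |two-step neighbourhood \\ {i}| for
#' every node, summary dispersion statistics, an estimate of the mean
#' pairwise Jaccard overlap of closed neighbourhoods over randomly drawn
#' node pairs, the count of nodes with gamma outside the band
#' `[mean/tau, tau*mean]`, and the count of large dense ego-networks
#' (clique-like regions of the kind that break sub-sampling).
#'
#' @param g An igraph graph.
#' @param tau Balance factor (> 1, default 3) for the unbalanced-size band.
#' @param pair_sample Number of node pairs for the overlap estimate
#'   (default 1000).
#' @param seed Integer RNG seed for the pair draw.
#' @return An object of class `neighbourhood_stats` with fields `sizes`
#'   (named gamma vector), `mean_size`, `cv_size`,
#'   `mean_pairwise_overlap`, `n_unbalanced`, `n_dense` (egos with >= 10
#'   nodes and density >= 0.5), `tau`.
#' @export
neighbourhood_stats <- function(g, tau = 3, pair_sample = 1000, seed = 1L) {
  if (tau <= 1) stop("tau must be > 1")
  if (pair_sample < 1) stop("pair_sample must be >= 1")
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  n <- length(vn)

  cen <- ego_census(g, k = 3) # sizes and densities for every ego
  sizes <- stats::setNames(cen$n_nodes - 1L, vn)
  mu <- mean(sizes)
  cv <- if (mu > 0) stats::sd(sizes) / mu else 0
  n_unb <- if (mu > 0) sum(sizes < mu / tau | sizes > tau * mu) else 0L
  n_dense <- sum(cen$n_nodes >= 10 & cen$density >= 0.5)

  overlap <- 0
  if (n >= 2) {
    pairs <- with_stream_seed(seed, "overlap_pairs", {
      cbind(sample.int(n, pair_sample, replace = TRUE),
            sample.int(n, pair_sample, replace = TRUE))
    })
    pairs[pairs[, 1] == pairs[, 2], 2] <-
      (pairs[pairs[, 1] == pairs[, 2], 2] %% n) + 1L
    uniq <- sort(unique(as.vector(pairs)))
    hoods <- igraph::ego(g, order = 2, nodes = uniq, mode = "all")
    hoods <- lapply(hoods, as.integer)
    names(hoods) <- as.character(uniq)
    jac <- vapply(seq_len(nrow(pairs)), function(i) {
      a <- hoods[[as.character(pairs[i, 1])]]
      b <- hoods[[as.character(pairs[i, 2])]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    }, numeric(1))
    overlap <- mean(jac)
  }

  structure(
    list(sizes = sizes, mean_size = mu, cv_size = cv,
         mean_pairwise_overlap = overlap, n_unbalanced = n_unb,
         n_dense = n_dense, tau = tau),
    class = "neighbourhood_stats"
  )
}

#' @export
print.neighbourhood_stats <- function(x, ...) {
  cat("Neighbourhood balance statistics (", length(x$sizes), " nodes)\n",
      "  mean gamma: ", signif(x$mean_size, 4),
      "   cv: ", signif(x$cv_size, 4), "\n",
      "  mean pairwise overlap (Jaccard): ",
      signif(x$mean_pairwise_overlap, 4), "\n",
      "  nodes outside [mean/", x$tau, ", ", x$tau, "*mean]: ",
      x$n_unbalanced, "\n",
      "  large dense ego-networks: ", x$n_dense, "\n", sep = "")
  invisible(x)
}

#' Advisory flag for sub-sampling risk
#'
#' Heuristic proxies for the balance conditions of the sampling theory:
#' warns when neighbourhood sizes are highly dispersed, when neighbourhoods
#' overlap heavily on average, or when the network contains large dense
#' (clique-like) ego-networks that differ sharply from the rest of the
#' network — the canonical failure case for ego-network sub-sampling. The
#' report is advisory and never blocks computation.
#'
#' @param stats A [neighbourhood_stats()] object.
#' @param max_cv Flag when the coefficient of variation of gamma exceeds
#'   this (default 2).
#' @param max_overlap Flag when the mean pairwise Jaccard overlap exceeds
#'   this (default 0.5) while neighbourhood sizes are unequal (cv > 0.1);
#'   fully uniform structures such as a single clique are exchangeable and
#'   exempt.
#' @param max_dense Flag when more than this many ego-networks are large
#'   (>= 10 nodes) and dense (density >= 0.5) (default 0) while such egos
#'   remain a minority (< 25% of nodes) — a small clique-like region that
#'   differs sharply from the rest of the network.
#' @return An object of class `risk_report`: list with logical `flagged`,
#'   character vector `reasons`, and the input `stats`.
#' @export
flag_subsampling_risk <- function(stats, max_cv = 2, max_overlap = 0.5,
                                  max_dense = 0) {
  stopifnot(inherits(stats, "neighbourhood_stats"))
  reasons <- character(0)
  if (stats$cv_size > max_cv) {
    reasons <- c(reasons, sprintf(
      "neighbourhood sizes highly dispersed (cv = %.3g > %.3g)",
      stats$cv_size, max_cv))
  }
  if (stats$mean_pairwise_overlap > max_overlap && stats$cv_size > 0.1) {
    reasons <- c(reasons, sprintf(
      "unequal neighbourhoods overlap heavily (mean Jaccard = %.3g > %.3g)",
      stats$mean_pairwise_overlap, max_overlap))
  }
  if (stats$n_dense > max_dense &&
      stats$n_dense < 0.25 * length(stats$sizes)) {
    reasons <- c(reasons, sprintf(
      "%d large dense ego-network(s) differ sharply from the rest",
      stats$n_dense))
  }
  structure(list(flagged = length(reasons) > 0, reasons = reasons,
                 stats = stats),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  if (x$flagged) {
    cat("Sub-sampling risk: FLAGGED\n")
    for (r in x$reasons) cat("  - ", r, "\n", sep = "")
    cat("Netdis sub-sampling estimates may converge poorly on this",
        "network;\nconsider using all ego-networks or a larger sample.\n")
  } else {
    cat("Sub-sampling risk: no warning at the configured thresholds.\n")
  }
  invisible(x)
}

#' Write per-node neighbourhood sizes as TSV
#'
#' @param stats A [neighbourhood_stats()] object.
#' @param path Output file path.
#' @export
write_neighbourhood_sizes <- function(stats, path) {
  utils::write.table(
    data.frame(node = names(stats$sizes), gamma = as.integer(stats$sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
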