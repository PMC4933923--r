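as_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stats::setNames(as.character(labels$cluster), labels$name)
  } else {
    stats::setNames(as.character(labels), names(labels))
  }
}

check_matrix_labels <- function(D, lab) {
  nms <- rownames(D)
  if (is.null(nms)) stop("distance matrix needs dimnames")
  missing <- setdiff(nms, names(lab))
  if (length(missing)) {
    stop("unlabelled item(s): ", paste(missing, collapse = ", "))
  }
  # items with any missing distance are excluded and logged
  bad <- nms[apply(is.na(unclass(D)[nms, nms, drop = FALSE]) &
                     !diag(length(nms)), 1, any)]
  if (length(bad)) {
    message("excluding ", length(bad),
            " item(s) with missing distances: ",
            paste(bad, collapse = ", "))
  }
  setdiff(nms, bad)
}

# indices of the k nearest other items, ties broken by lexicographic name
nearest_others <- function(d, self, k) {
  cand <- setdiff(names(d), self)
  cand[order(d[cand], cand)][seq_len(k)]
}

#' Nearest-neighbour score (1-NN)
#'
#' The fraction of items whose single nearest other item (ties broken by
#' lexicographically smallest name) belongs to the same ground-truth
#' cluster.
#'
#' @param D Symmetric distance matrix with dimnames; `NA` entries cause the
#'   affected items to be excluded (with a message).
#' @param labels Cluster labels: a data frame with columns `name` and
#'   `cluster`, or a named character vector.
#' @return A fraction in \[0, 1\].
#' @export
nn_score <- function(D, labels) {
  lab <- as_labels(labels)
  nms <- check_matrix_labels(D, lab)
  if (length(nms) < 2) stop("need at least two scoreable items")
  M <- unclass(D)[nms, nms, drop = FALSE]
  hits <- vapply(nms, function(g) {
    lab[nearest_others(M[g, ], g, 1L)] == lab[g]
  }, logical(1))
  mean(hits)
}

#' Cluster-size-adaptive nearest-neighbour score (k_C-NN)
#'
#' For each item G in a cluster of size C_G, takes its C_G - 1 nearest other
#' items and scores the fraction of them in G's own cluster; the score is
#' the mean over items. Items in singleton clusters (k = 0) are skipped. A
#' perfect score of 1 requires every within-cluster separation to be smaller
#' than every between-cluster separation.
#'
#' @inheritParams nn_score
#' @return A fraction in \[0, 1\].
#' @export
kc_nn_score <- function(D, labels) {
  lab <- as_labels(labels)
  nms <- check_matrix_labels(D, lab)
  M <- unclass(D)[nms, nms, drop = FALSE]
  sizes <- table(lab[nms])
  per_item <- vapply(nms, function(g) {
    k <- sizes[[lab[g]]] - 1L
    if (k == 0L) return(NA_real_)
    nb <- nearest_others(M[g, ], g, k)
    mean(lab[nb] == lab[g])
  }, numeric(1))
  if (all(is.na(per_item))) {
    stop("k_C-NN undefined: all clusters are singletons")
  }
  mean(per_item, na.rm = TRUE)
}

#' Random-distance-matrix baseline for the nearest-neighbour scores
#'
#' Draws `n_matrices` random symmetric matrices with i.i.d. Uniform(0, 1)
#' upper-triangle entries and zero diagonal, scores each against the labels,
#' and returns the mean scores. This is the chance level against which
#' Netdis performance is judged.
#'
#' @param labels Cluster labels (data frame or named vector).
#' @param n_matrices Number of random matrices (default 50).
#' @param seed Integer RNG seed.
#' @return A list with `nn`, `kc_nn` (mean scores) and `nn_scores`,
#'   `kc_nn_scores` (per-matrix values).
#' @export
random_baseline <- function(labels, n_matrices = 50, seed = 1L) {
  if (n_matrices < 1) stop("n_matrices must be >= 1")
  lab <- as_labels(labels)
  nms <- names(lab)
  n <- length(nms)
  res <- with_stream_seed(seed, "baseline", {
    vapply(seq_len(n_matrices), function(i) {
      M <- matrix(0, n, n, dimnames = list(nms, nms))
      M[upper.tri(M)] <- stats::runif(n * (n - 1) / 2)
      M <- M + t(M)
      c(nn_score(M, lab), kc_nn_score(M, lab))
    }, numeric(2))
  })
  list(nn = mean(res[1, ]), kc_nn = mean(res[2, ]),
       nn_scores = res[1, ], kc_nn_scores = res[2, ])
}

#' Read cluster labels from a two-column TSV (name, cluster)
#'
#' @param path TSV file path; a header line `name<TAB>cluster` is optional.
#' @return A data frame with columns `name` and `cluster`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, ])), c("name", "cluster"))) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(name = as.character(df[[1]]), cluster = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write cluster labels as TSV
#'
#' @param labels Data frame with columns `name` and `cluster`.
#' @param path Output file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("name", "cluster")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
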