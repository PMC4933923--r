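# internal: centered_sums object from a precomputed centered matrix subset
sums_from_rows <- function(cm, rows, k) {
  structure(list(k = k, S = colSums(cm[rows, , drop = FALSE]),
                 n_egos_used = length(rows)),
            class = "centered_sums")
}

pairwise_from_sums <- function(sums) {
  nms <- names(sums)
  n <- length(sums)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(netd2s(sums[[i]], sums[[j]])$netdis,
                    error = function(e) NA_real_)
      D[i, j] <- D[j, i] <- d
    }
  }
  class(D) <- c("netdis_matrix", "matrix", "array")
  D
}

#' The built-in Erdős–Rényi reference graph
#'
#' A G(n, m) draw with 5,000 nodes and 50,000 edges, the standard built-in
#' centering reference when no empirical reference network is supplied.
#'
#' @param seed Integer RNG seed.
#' @param n,m Node and edge counts (defaults 5000 and 50000).
#' @return An igraph graph.
#' @export
default_reference <- function(seed = 1L, n = 5000, m = 50000) {
  generate(model_spec("erdos_renyi", n, list(m = m),
                      seed = derive_seed(seed, "reference")))
}

resolve_reference <- function(reference, seed) {
  if (is.null(reference))

    list(graph = default_reference(seed), name = "builtin_er_5000_50000")
  else if (igraph::is_igraph(reference))
    list(graph = reference, name = "user_graph")
  else
    list(graph = read_edge_list(reference), name = reference)
}

resolve_spec <- function(sample_frac, sample_count, seed) {
  if (!is.null(sample_frac) && !is.null(sample_count)) {
    stop("give either sample_frac or sample_count, not both")
  }
  if (!is.null(sample_frac)) {
    sample_spec("fraction", sample_frac, seed = seed)
  } else if (!is.null(sample_count)) {
    sample_spec("count", sample_count, seed = seed)
  } else {
    NULL
  }
}

#' Compare a set of networks with (optionally sub-sampled) Netdis
#'
#' Reads the input graphs, builds the expectation table from the reference,
#' computes the pairwise Netdis matrix, and (if `out_dir` is given) writes
#' the distance matrix, per-graph centered sums, the expectation table and a
#' run manifest.
#'
#' @param inputs Named character vector of edge-list paths, or a named list
#'   of igraph graphs (>= 2).
#' @param reference Reference for centering: `NULL` for the built-in
#'   Erdős–Rényi graph with 5,000 nodes and 50,000 edges, an igraph graph,
#'   or an edge-list path.
#' @param k Subgraph order (default 4).
#' @param bin_width Density-bin width (default 0.01).
#' @param sample_frac,sample_count Optional ego-network sample size, as a
#'   fraction of nodes or an absolute count (mutually exclusive); default
#'   uses all ego-networks.
#' @param seed Integer run seed; all sampling derives from it.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `distances` (the Netdis matrix), `sums`
#'   (per-graph centered sums) and `table` (the expectation table).
#' @export
run_compare <- function(inputs, reference = NULL, k = 4, bin_width = 0.01,
                        sample_frac = NULL, sample_count = NULL, seed = 1L,
                        out_dir = NULL) {
  graphs <- if (is.list(inputs)) inputs else {
    nms <- if (is.null(names(inputs))) {
      sub("\\.[^.]*$", "", basename(inputs))
    } else names(inputs)
    stats::setNames(lapply(inputs, read_edge_list), nms)
  }
  if (length(graphs) < 2) stop("need at least two input graphs")
  ref <- resolve_reference(reference, seed)
  spec <- resolve_spec(sample_frac, sample_count, seed)
  table <- build_expectation_table(ref$graph, k = k, bin_width = bin_width,
                                   ref_name = ref$name)
  sums <- lapply(names(graphs), function(nm) {
    ids <- if (is.null(spec)) NULL else {
      sample_ego_ids(graphs[[nm]], spec, stream = nm)
    }
    centered_sums(graphs[[nm]], table, ids)
  })
  names(sums) <- names(graphs)
  D <- pairwise_from_sums(sums)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_distance_matrix(D, file.path(out_dir, "netdis_matrix.tsv"))
    write_expectation_table(table, file.path(out_dir,
                                             "expectation_table.tsv"))
    smat <- do.call(rbind, lapply(sums, function(s) s$S))
    utils::write.table(
      data.frame(name = names(sums), n_egos = vapply(sums, function(s)
        s$n_egos_used, numeric(1)), smat, check.names = FALSE),
      file.path(out_dir, "centered_sums.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    manifest <- c(
      paste0("seed\t", seed), paste0("k\t", k),
      paste0("bin_width\t", bin_width),
      paste0("reference\t", ref$name),
      paste0("sampling\t", if (is.null(spec)) "all egos" else {
        paste0(spec$mode, "=", spec$value)
      }),
      paste0("inputs\t", paste(names(graphs), collapse = ","))
    )
    writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  }
  invisible(list(distances = D, sums = sums, table = table))
}

#' Sub-sampling sweep experiment on a generated benchmark suite
#'
#' Generates a labelled benchmark suite, censuses every ego-network of every
#' graph once, then sweeps the given sampling fractions, recomputing the
#' Netdis matrix and the nearest-neighbour scores for `repetitions`
#' independent ego samples per fraction. Because the per-ego centered counts
#' are reused, each repetition costs only a row-subset sum. The random
#' distance-matrix baseline is computed alongside.
#'
#' @param n Nodes per generated graph.
#' @param target_degree Target mean degree (default 20).
#' @param replicates Graphs per model (default 5).
#' @param models Models to include (default: the five-model design without
#'   `chung_lu`).
#' @param fractions Ego-sampling fractions to sweep (default
#'   `c(0.01, 0.05, 0.1, 0.5, 1)`).
#' @param repetitions Independent samples per fraction (default 20; a
#'   fraction of 1 is deterministic, so its repetitions coincide).
#' @param k Subgraph order (default 4).
#' @param bin_width Density-bin width (default 0.01).
#' @param reference Reference graph (igraph), edge-list path, or `NULL` for
#'   the built-in Erdős–Rényi reference.
#' @param n_baseline Random matrices for the baseline (default 50).
#' @param seed Integer run seed.
#' @param out_dir Output directory for `scores.tsv`, `baseline.tsv` and
#'   `labels.tsv`, or `NULL`.
#' @return Invisibly, a list with `scores` (long data frame: fraction,
#'   repetition, nn, kc_nn), `baseline` (from [random_baseline()]), `labels`
#'   and `suite`.
#' @export
run_experiment <- function(n, target_degree = 20, replicates = 5,
                           models = c("erdos_renyi", "configuration",
                                      "geometric3d",
                                      "geometric_duplication",
                                      "duplication_divergence"),
                           fractions = c(0.01, 0.05, 0.1, 0.5, 1),
                           repetitions = 20, k = 4, bin_width = 0.01,
                           reference = NULL, n_baseline = 50, seed = 1L,
                           out_dir = NULL) {
  if (repetitions < 1) stop("repetitions must be >= 1")
  suite <- benchmark_suite(n, target_degree, replicates, models,
                           seed = derive_seed(seed, "suite"))
  ref <- resolve_reference(reference, seed)
  table <- build_expectation_table(ref$graph, k = k, bin_width = bin_width,
                                   ref_name = ref$name)

  cms <- lapply(suite$graphs, function(g) {
    cm <- centered_matrix(ego_census(g, k = k), table)
    rownames(cm) <- igraph::V(g)$name
    cm
  })

  rows <- list()
  for (f in fractions) {
    for (r in seq_len(repetitions)) {
      sums <- lapply(names(cms), function(nm) {
        cm <- cms[[nm]]
        size <- ceiling(f * nrow(cm))
        ids <- with_stream_seed(seed, paste0("f", f, "_rep", r, "_", nm),
                                sample.int(nrow(cm), size))
        sums_from_rows(cm, ids, k)
      })
      names(sums) <- names(cms)
      D <- pairwise_from_sums(sums)
      rows[[length(rows) + 1]] <- data.frame(
        fraction = f, repetition = r,
        nn = nn_score(D, suite$labels),
        kc_nn = kc_nn_score(D, suite$labels)
      )
    }
  }
  scores <- do.call(rbind, rows)
  baseline <- random_baseline(suite$labels, n_baseline,
                              seed = derive_seed(seed, "baseline"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(score = c("nn_baseline", "kc_nn_baseline"),
                 value = c(baseline$nn, baseline$kc_nn)),
      file.path(out_dir, "baseline.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_labels(suite$labels, file.path(out_dir, "labels.tsv"))
  }
  invisible(list(scores = scores, baseline = baseline,
                 labels = suite$labels, suite = suite))
}
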