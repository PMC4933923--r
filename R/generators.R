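#' Random-graph model specification
#'
#' @param model One of `"erdos_renyi"`, `"configuration"`, `"geometric3d"`,
#'   `"geometric_duplication"`, `"chung_lu"`,
#'   `"duplication_divergence"`.
#' @param n Node count (>= 2).
#' @param params Named list of model parameters: `erdos_renyi` needs `m`
#'   (edge count); `configuration` needs `degree_seq`; `geometric3d` needs
#'   `r` (connection radius in the unit cube); `geometric_duplication` needs
#'   `r` and optionally `sigma` (offset sd, default 0.05) and `n_seed`
#'   (initial uniform points, default 5); `chung_lu` needs `weights`;
#'   `duplication_divergence` needs `p` (edge retention) and optionally `q`
#'   (anchor-link probability, default 0.5).
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model, n, params = list(), seed = 1L) {
  models <- c("erdos_renyi", "configuration", "geometric3d",
              "geometric_duplication", "chung_lu", "duplication_divergence")
  if (!(model %in% models)) stop("unknown model: ", model)
  if (n < 2) stop("n must be >= 2")
  structure(list(model = model, n = as.integer(n), params = params,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  pp <- vapply(x$params, function(p) {
    if (length(p) > 4) paste0("<", length(p), " values>")
    else paste(signif(p, 4), collapse = ",")
  }, character(1))
  cat("Model spec: ", x$model, ", n = ", x$n, ", seed = ", x$seed,
      if (length(pp)) paste0("\n  params: ",
                             paste(names(pp), pp, sep = "=", collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

need_param <- function(spec, name) {
  if (is.null(spec$params[[name]])) {
    stop("model '", spec$model, "' requires parameter '", name, "'")
  }
  spec$params[[name]]
}

# all edges between points within distance r in the unit cube, in blocks to
# bound memory; returns a 2-column index matrix
radius_edges <- function(pts, r) {
  n <- nrow(pts)
  r2 <- r * r
  out <- vector("list", 0)
  block <- 512L
  for (start in seq(1L, n - 1L, by = block)) {
    i <- start:min(start + block - 1L, n - 1L)
    rest <- (start + 1L):n
    d2 <- outer(pts[i, 1], pts[rest, 1], "-")^2 +
      outer(pts[i, 2], pts[rest, 2], "-")^2 +
      outer(pts[i, 3], pts[rest, 3], "-")^2
    hit <- which(d2 <= r2, arr.ind = TRUE)
    ii <- i[hit[, 1]]
    jj <- rest[hit[, 2]]
    keep <- jj > ii
    if (any(keep)) out[[length(out) + 1]] <- cbind(ii[keep], jj[keep])
  }
  if (length(out) == 0) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

gen_erdos_renyi <- function(n, params) {
  m <- params$m
  igraph::sample_gnm(n, m)
}

gen_configuration <- function(n, params) {
  ds <- params$degree_seq
  if (length(ds) != n) stop("degree sequence length must equal n")
  if (sum(ds) %% 2 != 0) stop("degree sequence sum must be even")
  g <- igraph::sample_degseq(ds, method = "configuration")
  igraph::simplify(g) # erased stub-matching: drop loops and multi-edges
}

gen_geometric3d <- function(n, params) {
  r <- params$r
  pts <- matrix(stats::runif(3 * n), ncol = 3)
  igraph::graph_from_edgelist(radius_edges(pts, r), directed = FALSE) |>
    pad_to_n(n)
}

gen_geometric_duplication <- function(n, params) {
  r <- params$r
  sigma <- if (is.null(params$sigma)) 0.05 else params$sigma
  n_seed <- if (is.null(params$n_seed)) 5L else as.integer(params$n_seed)
  n_seed <- min(n_seed, n)
  pts <- matrix(0, n, 3)
  pts[seq_len(n_seed), ] <- stats::runif(3 * n_seed)
  for (t in seq_len(n - n_seed) + n_seed) {
    parent <- sample.int(t - 1L, 1L)
    pts[t, ] <- pmin(pmax(pts[parent, ] + stats::rnorm(3, 0, sigma), 0), 1)
  }
  igraph::graph_from_edgelist(radius_edges(pts, r), directed = FALSE) |>
    pad_to_n(n)
}

gen_chung_lu <- function(n, params) {
  w <- params$weights
  if (length(w) != n) stop("weights length must equal n")
  S <- sum(w)
  edges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    p <- pmin(1, w[i] * w[j] / S)
    hit <- j[stats::runif(length(j)) < p]
    if (length(hit)) edges[[i]] <- cbind(i, hit)
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) el <- matrix(integer(0), ncol = 2)
  pad_to_n(igraph::graph_from_edgelist(el, directed = FALSE), n)
}

gen_duplication_divergence <- function(n, params) {
  p <- params$p
  q <- if (is.null(params$q)) 0.5 else params$q
  adj <- vector("list", n)
  adj[[1]] <- 2L
  adj[[2]] <- 1L
  for (t in 3:n) {
    anchor <- sample.int(t - 1L, 1L)
    nb <- adj[[anchor]]
    kept <- nb[stats::runif(length(nb)) < p]
    if (stats::runif(1) < q) kept <- c(kept, anchor)
    kept <- unique(kept)
    adj[[t]] <- kept
    for (u in kept) adj[[u]] <- c(adj[[u]], t)
  }
  deg <- lengths(adj)
  el <- cbind(rep.int(seq_len(n), deg), unlist(adj))
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  pad_to_n(igraph::graph_from_edgelist(el, directed = FALSE), n)
}

pad_to_n <- function(g, n) {
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  g
}

#' Generate a graph from a model specification
#'
#' Produces a simple undirected graph on `spec$n` nodes (named `v1 ... vn`),
#' deterministically given the spec's seed. Isolated nodes are kept so the
#' node count is exact.
#'
#' @param spec A [model_spec()].
#' @return An igraph graph.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  gen <- switch(spec$model,
    erdos_renyi = function() gen_erdos_renyi(spec$n, spec$params),
    configuration = function() gen_configuration(spec$n, spec$params),
    geometric3d = function() gen_geometric3d(spec$n, spec$params),
    geometric_duplication = function() {
      gen_geometric_duplication(spec$n, spec$params)
    },
    chung_lu = function() gen_chung_lu(spec$n, spec$params),
    duplication_divergence = function() {
      gen_duplication_divergence(spec$n, spec$params)
    }
  )
  switch(spec$model,
    erdos_renyi = need_param(spec, "m"),
    configuration = need_param(spec, "degree_seq"),
    geometric3d = need_param(spec, "r"),
    geometric_duplication = need_param(spec, "r"),
    chung_lu = need_param(spec, "weights"),
    duplication_divergence = need_param(spec, "p")
  )
  g <- with_stream_seed(spec$seed, spec$model, gen())
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}

#' Choose model parameters to hit a target average degree
#'
#' Returns a [model_spec()] whose generated graphs have average degree close
#' to `target`. Erdős–Rényi uses the closed form m = n * target / 2; the
#' configuration model's average degree is fixed by its degree sequence
#' (which must be supplied); the remaining models bisect their free
#' parameter (radius, weight scale, or retention probability) against the
#' mean degree averaged over 5 generated graphs, stopping within 5% of the
#' target.
#'
#' @param model Model name (see [model_spec()]).
#' @param n Node count.
#' @param target Target mean degree, must be < n - 1.
#' @param seed Integer RNG seed for the matching draws and the returned spec.
#' @param degree_seq Degree sequence (configuration model only).
#' @param weights Base weights for `chung_lu`; the matcher rescales them.
#' @param sigma,n_seed,q Fixed secondary parameters passed through to the
#'   respective models.
#' @return A `model_spec` whose free parameter has been calibrated.
#' @export
match_average_degree <- function(model, n, target, seed = 1L,
                                 degree_seq = NULL, weights = NULL,
                                 sigma = 0.05, n_seed = 5L, q = 0.5) {
  if (target >= n - 1) stop("target mean degree must be < n - 1")
  if (model == "erdos_renyi") {
    return(model_spec(model, n, list(m = round(n * target / 2)), seed))
  }
  if (model == "configuration") {
    if (is.null(degree_seq)) stop("configuration model needs degree_seq")
    ds <- even_degree_seq(degree_seq)
    return(model_spec(model, n, list(degree_seq = ds), seed))
  }

  spec_at <- function(par, s) {
    params <- switch(model,
      geometric3d = list(r = par),
      geometric_duplication = list(r = par, sigma = sigma, n_seed = n_seed),
      chung_lu = list(weights = weights * par * target / mean(weights)),
      duplication_divergence = list(p = par, q = q)
    )
    model_spec(model, n, params, s)
  }
  if (model == "chung_lu" && is.null(weights)) {
    stop("chung_lu matching needs base weights")
  }
  mean_deg <- function(par) {
    mean(vapply(1:5, function(i) {
      g <- generate(spec_at(par, derive_seed(seed, paste0("match", i))))
      2 * igraph::ecount(g) / igraph::vcount(g)
    }, numeric(1)))
  }
  bracket <- switch(model,
    geometric3d = c(1e-4, sqrt(3)),
    geometric_duplication = c(1e-4, sqrt(3)),
    chung_lu = c(0.2, 5),
    duplication_divergence = c(0.01, 0.999)
  )
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- mean_deg(lo)
  f_hi <- mean_deg(hi)
  if (!(f_lo <= target && target <= f_hi)) {
    stop("matching failure: target degree ", target,
         " outside achievable range [", signif(f_lo, 3), ", ",
         signif(f_hi, 3), "] for ", model)
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    f_mid <- mean_deg(mid)
    if (abs(f_mid - target) <= 0.05 * target) break
    if (f_mid < target) lo <- mid else hi <- mid
  }
  spec_at(mid, seed)
}

# make a degree-sequence sum even by decrementing one maximal entry
even_degree_seq <- function(ds) {
  if (sum(ds) %% 2 != 0) {
    i <- which.max(ds)
    ds[i] <- ds[i] - 1L
  }
  ds
}

#' Generate a labelled benchmark suite of random graphs
#'
#' Generates `replicates` graphs from each model, with parameters matched so
#' every model's mean degree is approximately `target_degree`, and
#' ground-truth cluster labels equal to the model names. The configuration
#' model's degree sequence is the degree sequence of the first
#' duplication-divergence graph of the same suite, and the Chung-Lu weights
#' default to that sequence too (rescaled during matching).
#'
#' @param n Node count per graph.
#' @param target_degree Target mean degree (default 20).
#' @param replicates Graphs per model (>= 1, default 5).
#' @param models Character vector of model names to include; the default is
#'   all six. Large-network designs conventionally drop `chung_lu`.
#' @param seed Integer run seed; all model matching and generation derive
#'   substreams from it.
#' @return A list with `graphs` (named list of igraph graphs, names
#'   `<model>_<replicate>`) and `labels` (data frame with columns `name`,
#'   `cluster`).
#' @export
benchmark_suite <- function(n, target_degree = 20, replicates = 5,
                            models = c("erdos_renyi", "configuration",
                                       "geometric3d", "geometric_duplication",
                                       "chung_lu", "duplication_divergence"),
                            seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  graphs <- list()

  # duplication-divergence first: it seeds the configuration / Chung-Lu
  # degree sequences
  dd_spec <- match_average_degree("duplication_divergence", n, target_degree,
                                  seed = derive_seed(seed, "match_dd"))
  dd_graphs <- lapply(seq_len(replicates), function(r) {
    s <- dd_spec
    s$seed <- derive_seed(seed, paste0("duplication_divergence_", r))
    generate(s)
  })
  degseq <- igraph::degree(dd_graphs[[1]])

  for (model in models) {
    gs <- if (model == "duplication_divergence") {
      dd_graphs
    } else {
      spec <- switch(model,
        erdos_renyi = match_average_degree("erdos_renyi", n, target_degree),
        configuration = match_average_degree("configuration", n,
                                             target_degree,
                                             degree_seq = degseq),
        chung_lu = match_average_degree("chung_lu", n, target_degree,
                                        seed = derive_seed(seed, "match_cl"),
                                        weights = degseq),
        match_average_degree(model, n, target_degree,
                             seed = derive_seed(seed, paste0("match_", model)))
      )
      lapply(seq_len(replicates), function(r) {
        s <- spec
        s$seed <- derive_seed(seed, paste0(model, "_", r))
        generate(s)
      })
    }
    names(gs) <- paste0(model, "_", seq_len(replicates))
    graphs <- c(graphs, gs)
  }
  labels <- data.frame(
    name = names(graphs),
    cluster = sub("_[0-9]+$", "", names(graphs)),
    stringsAsFactors = FALSE
  )
  list(graphs = graphs, labels = labels)
}
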