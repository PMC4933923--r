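#' Specification of an ego-network sample
#'
#' @param mode `"fraction"` to sample a proportion of all nodes, or
#'   `"count"` for an absolute number of nodes.
#' @param value For fraction mode a number in (0, 1]; for count mode a
#'   positive integer.
#' @param seed Integer RNG seed; every draw from this spec is a
#'   deterministic function of `(seed, stream)`.
#' @param replacement Logical; `FALSE` (default) for plain sub-sampling.
#'   Seeds drawn with replacement belong to [bootstrap_sample()].
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(mode = c("fraction", "count"), value, seed = 1L,
                        replacement = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fraction") {
    if (!(value > 0 && value <= 1)) stop("fraction must be in (0, 1]")
  } else {
    if (!(value >= 1 && value == floor(value))) {
      stop("count must be a positive integer")
    }
  }
  structure(list(mode = mode, value = value, seed = as.integer(seed),
                 replacement = isTRUE(replacement)),
            class = "sample_spec")
}

# deterministic substream seed from (run seed, stream label); stays < 2^31
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 7919 + h + 1) %% 2147483647)
}

# run `expr` under a derived seed without disturbing the caller's RNG state
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' Uniform sample of ego identifiers
#'
#' Draws nodes uniformly without replacement. Fraction mode draws
#' `ceiling(value * |V|)` nodes, so every positive fraction samples at least
#' one ego. The draw is deterministic given the spec's seed and the stream
#' label, and the result is sorted for stable downstream iteration.
#'
#' @param g An igraph graph.
#' @param spec A [sample_spec()] with `replacement = FALSE`.
#' @param stream Label (typically the graph's name) identifying the
#'   substream, so adding a graph to a run does not perturb other graphs'
#'   samples.
#' @return Sorted character vector of node names.
#' @export
sample_ego_ids <- function(g, spec, stream = "") {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$replacement) {
    stop("sample_ego_ids draws without replacement; see bootstrap_sample()")
  }
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  n <- length(vn)
  size <- if (spec$mode == "fraction") ceiling(spec$value * n) else spec$value
  if (size > n) stop("sample size ", size, " exceeds number of nodes ", n)
  ids <- with_stream_seed(spec$seed, stream, sample(vn, size))
  sort(ids)
}

#' Seed-plus-neighbourhood bootstrap of a network
#'
#' Draws `kappa` seed nodes uniformly with replacement (multinomially); for
#' each seed the whole closed two-step neighbourhood — the node set of the
#' seed's two-step ego-network, here playing the role of the dependency
#' neighbourhood — enters the sample. Each node's mass is proportional to
#' its number of inclusions, standardised so the total mass is 1.
#'
#' @param g A non-empty igraph graph.
#' @param kappa Number of seed draws (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `empirical_measure`: list with `weights`
#'   (named vector over the sampled support, summing to 1), `kappa` and
#'   `seed_counts` (draws per seed node).
#' @export
bootstrap_sample <- function(g, kappa, seed = 1L) {
  if (kappa < 1) stop("kappa must be >= 1")
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  n <- length(vn)
  if (n == 0) stop("empty graph")
  draws <- with_stream_seed(seed, "bootstrap",
                            sample.int(n, kappa, replace = TRUE))
  mult <- table(draws)
  uniq <- as.integer(names(mult))
  hoods <- igraph::ego(g, order = 2, nodes = uniq, mode = "all")
  incl <- numeric(n)
  for (i in seq_along(uniq)) {
    members <- as.integer(hoods[[i]])
    incl[members] <- incl[members] + as.integer(mult[i])
  }
  w <- incl / sum(incl)
  structure(
    list(weights = stats::setNames(w[w > 0], vn[w > 0]), kappa = kappa,
         seed_counts = stats::setNames(as.integer(mult), vn[uniq])),
    class = "empirical_measure"
  )
}

#' @export
print.empirical_measure <- function(x, ...) {
  cat("Bootstrap empirical measure: ", length(x$weights),
      " support node(s) from kappa = ", x$kappa, " seed draws\n", sep = "")
  invisible(x)
}
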