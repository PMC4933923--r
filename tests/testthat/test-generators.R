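test_that("Erdos-Renyi specs generate the exact edge count, reproducibly", {
  spec <- model_spec("erdos_renyi", 200, list(m = 600), seed = 5)
  g <- generate(spec)
  expect_equal(igraph::vcount(g), 200)
  expect_equal(igraph::ecount(g), 600)
  expect_true(igraph::is_simple(g))
  g2 <- generate(spec)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
})

test_that("model specs validate their parameters", {
  expect_error(model_spec("nonsense", 10), "unknown model")
  expect_error(generate(model_spec("erdos_renyi", 10, list())), "requires")
  expect_error(generate(model_spec("configuration", 4,
                                   list(degree_seq = c(1, 1, 1, 2)))),
               "even")
})

test_that("geometric graphs with radius >= cube diameter are complete", {
  g <- generate(model_spec("geometric3d", 12, list(r = sqrt(3)), seed = 2))
  expect_equal(igraph::ecount(g), choose(12, 2))
})

test_that("erased configuration model keeps degrees at most the target", {
  for (seed in 1:50) {
    g <- generate(model_spec("configuration", 50,
                             list(degree_seq = rep(2L, 50)), seed = seed))
    expect_true(igraph::is_simple(g))
    expect_true(all(igraph::degree(g) <= 2))
  }
})

test_that("all six models produce simple graphs on exactly n nodes", {
  n <- 60
  specs <- list(
    model_spec("erdos_renyi", n, list(m = 150), seed = 1),
    model_spec("configuration", n, list(degree_seq = rep(4L, n)), seed = 2),
    model_spec("geometric3d", n, list(r = 0.3), seed = 3),
    model_spec("geometric_duplication", n, list(r = 0.3), seed = 4),
    model_spec("chung_lu", n, list(weights = rep(5, n)), seed = 5),
    model_spec("duplication_divergence", n, list(p = 0.4), seed = 6)
  )
  for (spec in specs) {
    g <- generate(spec)
    expect_equal(igraph::vcount(g), n)
    expect_true(igraph::is_simple(g))
    expect_identical(igraph::as_edgelist(g),
                     igraph::as_edgelist(generate(spec)))
  }
})

test_that("Chung-Lu realized degrees match their expected weights", {
  n <- 500
  set.seed(77)
  w <- pmin(sample(1:30, n, replace = TRUE), n - 1)
  draws <- sapply(1:200, function(i) {
    igraph::degree(generate(model_spec("chung_lu", n, list(weights = w),
                                       seed = i)))
  })
  avg <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(200)
  # no clipping here (max w_i w_j / S < 1), so E[deg_i] = w_i (1 - w_i/S)
  expected <- w * (1 - w / sum(w))
  idx <- order(w, decreasing = TRUE)[1:20]
  expect_true(all(abs(avg[idx] - expected[idx]) <= 3 * se[idx] + 0.05))
})

test_that("duplication-divergence degrees are heavier-tailed than ER", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  sk <- sapply(1:20, function(s) {
    dd <- generate(model_spec("duplication_divergence", 300,
                              list(p = 0.5), seed = s))
    m <- igraph::ecount(dd)
    er <- generate(model_spec("erdos_renyi", 300, list(m = max(m, 1)),
                              seed = s))
    c(dd = skew(igraph::degree(dd)), er = skew(igraph::degree(er)))
  })
  expect_gt(median(sk["dd", ]), median(sk["er", ]))
})

test_that("degree matching hits the target for closed-form and bisection
           models", {
  spec <- match_average_degree("erdos_renyi", 1000, 20)
  expect_equal(spec$params$m, 10000)
  expect_error(match_average_degree("erdos_renyi", 10, 9), "target")

  spec_geo <- match_average_degree("geometric3d", 400, 12, seed = 8)
  md <- mean(sapply(1:3, function(i) {
    s <- spec_geo
    s$seed <- i
    mean(igraph::degree(generate(s)))
  }))
  expect_gt(md, 12 * 0.9)
  expect_lt(md, 12 * 1.1)
})

test_that("benchmark suite produces labelled replicates per model", {
  suite <- benchmark_suite(n = 100, target_degree = 8, replicates = 2,
                           models = c("erdos_renyi",
                                      "duplication_divergence",
                                      "configuration"),
                           seed = 42)
  expect_length(suite$graphs, 6)
  expect_equal(nrow(suite$labels), 6)
  expect_equal(sort(unique(suite$labels$cluster)),
               sort(c("erdos_renyi", "duplication_divergence",
                      "configuration")))
  # configuration degree sequence mirrors the first duplication-divergence
  # draw (up to the evening adjustment)
  dd1 <- suite$graphs[["duplication_divergence_1"]]
  cfg <- suite$graphs[["configuration_1"]]
  stubs <- sum(igraph::degree(dd1)) - sum(igraph::degree(dd1)) %% 2
  # erasure can only lose edges relative to the stub count
  expect_lte(2 * igraph::ecount(cfg), stubs)
  expect_gte(2 * igraph::ecount(cfg), 0.7 * stubs)
  expect_equal(igraph::vcount(cfg), 100)
  # single-replicate suites have one graph per model
  s1 <- benchmark_suite(n = 50, target_degree = 4, replicates = 1,
                        models = c("erdos_renyi",
                                   "duplication_divergence"), seed = 3)
  expect_length(s1$graphs, 2)
  expect_error(benchmark_suite(50, 4, replicates = 0), "replicates")
})
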