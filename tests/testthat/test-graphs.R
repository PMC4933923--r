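test_that("edge-list parsing collapses duplicates and handles comments", {
  path <- withr::local_tempfile(lines = c("a b", "b a", "b c"))
  g <- read_edge_list(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  path2 <- withr::local_tempfile(lines = c("# comment", "u1 u2", "u2 u3",
                                           "u3 u1"))
  g2 <- read_edge_list(path2)
  expect_setequal(igraph::V(g2)$name, c("u1", "u2", "u3"))
  expect_equal(igraph::ecount(g2), 3)
  expect_equal(unname(count_induced(g2, 3)), c(0, 1))
})

test_that("self-loops are dropped with a warning; isolated nodes declared", {
  path <- withr::local_tempfile(lines = c("a a", "a b", "c"))
  expect_warning(g <- read_edge_list(path), "self-loop")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 1)
})

test_that("extra tokens are ignored with a warning; empty file errors", {
  path <- withr::local_tempfile(lines = c("a b 0.5", "b c 1.2"))
  expect_warning(g <- read_edge_list(path), "unweighted")
  expect_equal(igraph::ecount(g), 2)

  empty <- withr::local_tempfile(lines = c("# nothing", ""))
  expect_error(read_edge_list(empty), "empty graph")
  expect_error(read_edge_list(file.path(tempdir(), "no-such-file")),
               "cannot read")
})

test_that("write/read round trip preserves the graph", {
  g <- graph_from_pairs(c("a", "b", "c"), c("b", "c", "d"), isolated = "z")
  path <- withr::local_tempfile()
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_true(igraph::isomorphic(g, g2))
})

test_that("two-step ego-network is the induced depth-2 ball", {
  g <- graph_from_pairs(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  eg <- two_step_ego(g, "a")
  expect_setequal(igraph::V(eg$graph)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(eg$graph), 2)
  expect_error(two_step_ego(g, "nope"), "unknown node")

  iso <- graph_from_pairs("a", "b", isolated = "x")
  ei <- two_step_ego(iso, "x")
  expect_equal(igraph::vcount(ei$graph), 1)
  expect_equal(ei$density, 0)
})

test_that("two-step ego includes induced edges between peripheral nodes", {
  # c and d are both at distance 2 from a; the c-d edge must be induced
  g <- graph_from_pairs(c("a", "b", "b", "c"), c("b", "c", "d", "d"))
  eg <- two_step_ego(g, "a")
  expect_setequal(igraph::V(eg$graph)$name, c("a", "b", "c", "d"))
  expect_true(igraph::are_adjacent(eg$graph, "c", "d"))
})

test_that("ego extraction is idempotent on diameter-2 components and
           contains the one-step neighbourhood", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_named_gnp(15, 0.3)
    v <- sample(igraph::V(g)$name, 1)
    eg <- two_step_ego(g, v)
    one_step <- igraph::V(g)$name[as.integer(
      igraph::ego(g, 1, nodes = v)[[1]])]
    expect_true(all(one_step %in% igraph::V(eg$graph)$name))
    if (igraph::vcount(eg$graph) > 1 &&
        igraph::diameter(eg$graph, directed = FALSE) <= 2) {
      eg2 <- two_step_ego(eg$graph, v)
      expect_setequal(igraph::V(eg2$graph)$name,
                      igraph::V(eg$graph)$name)
    }
  }
})

test_that("graph density matches the closed form", {
  expect_equal(graph_density(named_graph(igraph::make_full_graph(5))), 1)
  expect_equal(graph_density(graph_from_pairs(c("a", "b"), c("b", "c"))),
               2 / 3)
  expect_equal(graph_density(graph_from_pairs("a", "b", isolated = "c")),
               1 / 3)
  g1 <- graph_from_pairs(character(0), character(0), isolated = "a")
  expect_equal(graph_density(g1), 0)
  # G(n, m) with exact edge count: density is 2m / (n (n-1)) exactly
  er <- generate(model_spec("erdos_renyi", 5000, list(m = 50000), seed = 1))
  expect_equal(graph_density(er), 50000 / choose(5000, 2))
})
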