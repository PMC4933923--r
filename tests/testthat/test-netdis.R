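test_that("expectation table from a triangle has one bin at density 1", {
  tri <- graph_from_pairs(c("a", "b", "c"), c("b", "c", "a"))
  tab <- build_expectation_table(tri, k = 3, bin_width = 0.01)
  expect_equal(nrow(tab$bins), 1)
  expect_equal(tab$bins$lower, 1.0)
  expect_equal(unname(expected_counts(tab, 1.0)[1, ]), c(0, 1))
  # any query density falls back to the single non-empty bin
  expect_equal(unname(expected_counts(tab, 0.2)[1, ]), c(0, 1))
})

test_that("degenerate references are rejected", {
  empty <- graph_from_pairs(character(0), character(0),
                            isolated = c("a", "b"))
  expect_error(build_expectation_table(empty, k = 3), "degenerate reference")
})

test_that("bin fallback prefers the lower-density bin on ties", {
  # reference with egos at densities 1.0 (triangle) and 0.5 (4-path egos)
  g <- graph_from_pairs(c("a", "b", "c", "p", "q", "r"),
                        c("b", "c", "a", "q", "r", "s"))
  tab <- build_expectation_table(g, k = 3, bin_width = 0.1)
  occupied <- tab$bins$bin
  expect_true(length(occupied) >= 2)
  lo <- occupied[1]
  hi <- occupied[length(occupied)]
  if ((hi - lo) %% 2 == 0) {
    midbin <- (lo + hi) / 2
    picked <- tab$lookup[midbin + 1]
    expect_equal(picked, lo)
  }
})

test_that("self-centering: table built from G zeroes its own sums", {
  set.seed(21)
  g <- random_named_gnm(150, 450)
  for (k in 3:4) {
    tab <- build_expectation_table(g, k = k)
    s <- centered_sums(g, tab)
    expect_equal(s$n_egos_used, 150)
    expect_lt(max(abs(s$S)), 1e-7)
  }
})

test_that("centered sums are additive over disjoint ego sets", {
  set.seed(22)
  g <- random_named_gnm(60, 150)
  ref <- random_named_gnm(60, 150)
  tab <- build_expectation_table(ref, k = 4)
  ids <- igraph::V(g)$name
  half1 <- ids[1:30]
  half2 <- ids[31:60]
  s_all <- centered_sums(g, tab)
  s1 <- centered_sums(g, tab, half1)
  s2 <- centered_sums(g, tab, half2)
  expect_equal(s_all$S, s1$S + s2$S)
  expect_error(centered_sums(g, tab, character(0)), "empty ego sample")
})

test_that("triangle against an all-zero expectation gives S = (0, 3)", {
  # single-edge reference: its egos have density 1 and zero 3-node counts
  edge_ref <- graph_from_pairs("x", "y")
  tab <- build_expectation_table(edge_ref, k = 3)
  tri <- graph_from_pairs(c("a", "b", "c"), c("b", "c", "a"))
  s <- centered_sums(tri, tab)
  expect_equal(unname(s$S), c(0, 3))
})

test_that("netd2s endpoints: identical, antipodal and orthogonal sums", {
  mk <- function(S, k = 4) {
    structure(list(k = k, S = setNames(S, subgraph_catalog(k)),
                   n_egos_used = 1), class = "centered_sums")
  }
  same <- netd2s(mk(1:6), mk(1:6))
  expect_equal(same$netd2s, 1, tolerance = 1e-12)
  expect_equal(same$netdis, 0, tolerance = 1e-12)

  anti <- netd2s(mk(1:6), mk(-(1:6)))
  expect_equal(anti$netd2s, -1, tolerance = 1e-12)
  expect_equal(anti$netdis, 1, tolerance = 1e-12)

  orth <- netd2s(mk(c(1, 0), k = 3), mk(c(0, 1), k = 3))
  expect_equal(orth$netd2s, 0)
  expect_equal(orth$netdis, 0.5)

  expect_error(netd2s(mk(c(0, 0), k = 3), mk(c(0, 0), k = 3)),
               "degenerate comparison")
  expect_error(netd2s(mk(1:6), mk(c(1, 0), k = 3)), "different subgraph")
})

test_that("zero-variance types are excluded, not propagated as 0/0", {
  mk <- function(S) {
    structure(list(k = 4, S = setNames(S, subgraph_catalog(4)),
                   n_egos_used = 1), class = "centered_sums")
  }
  r <- netd2s(mk(c(1, 2, 0, 0, 0, 0)), mk(c(2, 1, 0, 0, 0, 0)))
  expect_true(is.finite(r$netd2s))
  expect_equal(unname(r$per_type_terms[3:6]), rep(0, 4))
})

test_that("netd2s is scale-invariant and symmetric with bounded output", {
  mk <- function(S) {
    structure(list(k = 4, S = setNames(S, subgraph_catalog(4)),
                   n_egos_used = 1), class = "centered_sums")
  }
  set.seed(23)
  for (i in 1:50) {
    a <- rnorm(6) * 10^sample(0:4, 1)
    b <- rnorm(6) * 10^sample(0:4, 1)
    r <- netd2s(mk(a), mk(b))
    expect_gte(r$netd2s, -1)
    expect_lte(r$netd2s, 1)
    expect_gte(r$netdis, 0)
    expect_lte(r$netdis, 1)
    expect_equal(r$netdis, netd2s(mk(b), mk(a))$netdis)
    expect_equal(r$netd2s, netd2s(mk(7 * a), mk(7 * b))$netd2s,
                 tolerance = 1e-12)
    expect_equal(r$netdis, (1 - r$netd2s) / 2)
  }
})

test_that("pairwise matrix: identical graphs at distance ~0, symmetry,
           full-sample spec equals no sampling", {
  set.seed(24)
  g1 <- random_named_gnm(80, 240)
  g2 <- random_named_gnm(80, 240)
  ref <- random_named_gnm(120, 480)
  tab <- build_expectation_table(ref, k = 4)
  D <- pairwise_netdis(list(a = g1, b = g2, c = g1), tab)
  expect_equal(unclass(D), t(unclass(D)))
  expect_equal(unname(diag(unclass(D))), rep(0, 3))
  expect_equal(D["a", "c"], 0, tolerance = 1e-12)
  expect_gte(min(unclass(D)), 0)
  expect_lte(max(unclass(D)), 1)

  spec <- sample_spec("fraction", 1.0, seed = 5)
  D_full <- pairwise_netdis(list(a = g1, b = g2, c = g1), tab, spec)
  expect_equal(unclass(D), unclass(D_full))
})

test_that("distance matrix TSV round-trips at 6 significant digits", {
  M <- matrix(c(0, 0.123456789, 0.123456789, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  path <- withr::local_tempfile()
  write_distance_matrix(M, path)
  back <- read_distance_matrix(path)
  expect_equal(back["x", "y"], signif(0.123456789, 6))
  expect_equal(rownames(back), c("x", "y"))
})
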