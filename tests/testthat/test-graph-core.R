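test_that("edge-list loading collapses duplicates and drops self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("a b", "b c", "b a"), f)
  net <- load_edge_list(f)
  expect_equal(net$n, 3L)
  expect_equal(net$m, 2L)
  expect_equal(net$labels, c("a", "b", "c"))

  writeLines(c("1 1", "1 2"), f)
  net <- load_edge_list(f)
  expect_equal(net$n, 2L)
  expect_equal(net$m, 1L)
})

test_that("edge-list loading skips comments and reports bad lines", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "", "a b extra-token", "c d"), f)
  net <- load_edge_list(f)
  expect_equal(net$n, 4L)
  expect_equal(net$m, 2L)

  writeLines(c("a b", "lonely"), f)
  expect_error(load_edge_list(f), "line 2")
  expect_error(load_edge_list(file.path(f, "nope")), "cannot read")
})

test_that("the packaged toy fixture file loads to the 9-node network", {
  f <- system.file("extdata", "toy.edges", package = "spreadrank")
  net <- load_edge_list(f)
  expect_equal(net$n, 9L)
  expect_equal(net$m, 13L)
  expect_equal(unname(degrees(net)[as.character(1:9)]),
               c(1L, 3L, 3L, 4L, 4L, 4L, 5L, 1L, 1L))
})

test_that("bfs_distances gives the documented toy neighbourhoods", {
  net <- toy_network()
  d <- bfs_distances(net, "3", radius = 2)
  expect_equal(d[["3"]], 0L)
  expect_setequal(names(d)[d == 1], c("2", "4", "7"))
  expect_setequal(names(d)[d == 2], c("1", "5", "6"))
})

test_that("bfs_distances handles paths, radii and disconnected graphs", {
  f <- withr::local_tempfile()
  writeLines(c("a b", "b c"), f)
  path <- load_edge_list(f)
  expect_equal(bfs_distances(path, "a"), c(a = 0L, b = 1L, c = 2L))
  expect_equal(bfs_distances(path, "a", radius = 1), c(a = 0L, b = 1L))

  writeLines(c("a b", "c d"), f)
  dyads <- load_edge_list(f)
  expect_equal(sort(names(bfs_distances(dyads, "a"))), c("a", "b"))
  expect_error(bfs_distances(dyads, "zz"), "unknown node")
  expect_error(bfs_distances(dyads, 99), "out of range")
})

test_that("bfs_distances matches a Floyd-Warshall oracle on random graphs", {
  for (s in 1:10) {
    g <- random_graph("er", n = 5 + (s %% 26), p = 0.15, rng_seed = 100 + s)
    d <- fw_distances(g)
    for (src in seq_len(g$n)) {
      got <- bfs_distances(g, src)
      want <- d[src, ]
      expect_equal(unname(got[g$labels[is.finite(want)]]),
                   as.integer(want[is.finite(want)]))
    }
  }
})

test_that("network statistics hit the closed-form small cases", {
  tri <- network_from_pairs(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  s <- network_stats(tri)
  expect_equal(s$clustering, 1)
  expect_equal(s$mean_distance, 1)
  expect_equal(s$heterogeneity, 1)

  star <- network_from_pairs(cbind("hub", paste0("leaf", 1:4)))
  s <- network_stats(star)
  expect_equal(s$clustering, 0)
  expect_equal(s$assortativity, -1)

  toy <- toy_network()
  expect_equal(network_stats(toy)$mean_degree, 26 / 9)

  k5 <- random_graph("er", 5, p = 1, rng_seed = 1)
  s <- network_stats(k5)
  expect_equal(s$mean_distance, 1)
  expect_equal(s$clustering, 1)
  expect_equal(s$heterogeneity, 1)
})

test_that("statistics are invariant under node relabeling", {
  g <- random_connected(15, 0.25, seed = 7)
  set.seed(42)
  perm <- sample(g$n)
  h <- new_network(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                   g$labels)
  a <- network_stats(g); b <- network_stats(h)
  for (f in c("mean_degree", "mean_distance", "clustering", "assortativity",
              "heterogeneity", "epidemic_threshold"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12, label = f)
})

test_that("an edgeless graph yields NaN assortativity and threshold with a warning", {
  g <- new_network(matrix(integer(0), ncol = 2), c("a", "b", "c"))
  expect_warning(s <- network_stats(g), "no edges")
  expect_true(is.nan(s$assortativity))
  expect_true(is.nan(s$epidemic_threshold))
  expect_equal(s$m, 0L)
})

test_that("edge-list write/load round-trips labels and edges", {
  g <- random_connected(12, 0.3, seed = 3)
  f <- withr::local_tempfile()
  write_edge_list(g, f)
  h <- load_edge_list(f)
  expect_setequal(h$labels, g$labels)
  canon <- function(net) {
    e <- cbind(net$labels[net$edges[, 1]], net$labels[net$edges[, 2]])
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(canon(h), canon(g))
})
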