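toy <- toy_network()

test_that("toy-network decomposition reproduces shells, stages and sweep counts", {
  dec <- kshell_decompose(toy)
  expect_equal(unname(dec$shell[as.character(1:9)]),
               c(1L, 2L, 2L, 3L, 3L, 3L, 3L, 1L, 1L))
  # the 2-shell peels in two sweeps: node 2 first, then node 3
  expect_equal(dec$stage[["2"]], 1L)
  expect_equal(dec$stage[["3"]], 2L)
  # 1-shell and 3-shell each peel in a single simultaneous sweep
  expect_equal(unname(dec$stage[c("1", "8", "9")]), c(1L, 1L, 1L))
  expect_equal(unname(dec$stage[c("4", "5", "6", "7")]), rep(1L, 4))
  expect_equal(dec$stage_counts, c("1" = 1L, "2" = 2L, "3" = 1L))
  expect_equal(dec$max_stage_count, 2L)
})

test_that("decomposition handles stars, cycles, isolates and the empty graph", {
  star <- network_from_pairs(cbind("hub", paste0("l", 1:5)))
  dec <- kshell_decompose(star)
  expect_true(all(dec$shell == 1L))
  expect_equal(unname(dec$stage[paste0("l", 1:5)]), rep(1L, 5))
  expect_equal(dec$stage[["hub"]], 2L)
  expect_equal(dec$stage_counts, c("1" = 2L))

  cyc <- network_from_pairs(cbind(as.character(1:6), as.character(c(2:6, 1))))
  dec <- kshell_decompose(cyc)
  expect_true(all(dec$shell == 2L))
  expect_true(all(dec$stage == 1L))
  expect_equal(dec$stage_counts, c("2" = 1L))

  iso <- new_network(rbind(c(1, 2)), c("a", "b", "alone"))
  dec <- kshell_decompose(iso)
  expect_equal(dec$shell[["alone"]], 0L)
  expect_equal(dec$stage[["alone"]], 1L)

  empty <- new_network(matrix(integer(0), ncol = 2), character(0))
  dec <- kshell_decompose(empty)
  expect_length(dec$shell, 0)
  expect_equal(dec$max_stage_count, 0L)
})

test_that("decomposition invariants hold and shells match igraph coreness", {
  for (s in 1:8) {
    g <- random_graph("er", n = 10 + 5 * (s %% 9), p = 0.12, rng_seed = 200 + s)
    dec <- kshell_decompose(g)
    # every node gets one (shell, stage) pair within bounds
    expect_true(all(dec$stage >= 1L))
    qk <- dec$stage_counts[as.character(dec$shell)]
    expect_true(all(dec$stage <= qk))
    expect_true(all(qk <= dec$max_stage_count))
    expect_setequal(names(dec$stage_counts), as.character(unique(dec$shell)))
    # shell values are the classic k-core numbers
    expect_equal(unname(dec$shell),
                 unname(igraph::coreness(as_igraph(g))))
  }
})

test_that("improved k-shell index reproduces the printed toy values", {
  ks <- improved_kshell(toy)
  expect_equal(round(ks[["3"]], 4), 2.6667)
  expect_equal(round(unname(ks[as.character(1:9)]), 4),
               c(1.3333, 2.3333, 2.6667, 3.3333, 3.3333, 3.3333, 3.3333,
                 1.3333, 1.3333))
})

test_that("improved index keeps the shell as integer part and respects shell order", {
  cyc6 <- network_from_pairs(cbind(as.character(1:6), as.character(c(2:6, 1))))
  expect_equal(unname(improved_kshell(cyc6)), rep(2.5, 6))

  for (s in 1:6) {
    g <- random_graph("er", n = 20, p = 0.15, rng_seed = 300 + s)
    dec <- kshell_decompose(g)
    ks <- improved_kshell(dec)
    expect_equal(unname(floor(ks)), as.numeric(dec$shell))
    # lower shell never outranks a higher shell
    ord <- order(dec$shell)
    expect_true(all(diff(ks[ord][!duplicated(dec$shell[ord])]) > 0 |
                      length(unique(dec$shell)) < 2))
    for (a in unique(dec$shell)) for (b in unique(dec$shell))
      if (a < b) expect_true(max(ks[dec$shell == a]) < min(ks[dec$shell == b]))
  }
})

test_that("DK index matches the toy table and the defining identity", {
  dk <- dk_index(toy)
  expect_equal(round(unname(dk[as.character(1:9)]), 4),
               c(2.3333, 5.3333, 5.6667, 7.3333, 7.3333, 7.3333, 8.3333,
                 2.3333, 2.3333))
  # DK(i) - k(i) = k_s*(i) exactly
  expect_equal(dk - degrees(toy), improved_kshell(toy))
  # DK resolves the ties degree and plain shell cannot
  expect_false(dk[["2"]] == dk[["3"]])
  expect_false(dk[["7"]] == dk[["4"]])
  cyc6 <- network_from_pairs(cbind(as.character(1:6), as.character(c(2:6, 1))))
  expect_equal(unname(dk_index(cyc6)), rep(4.5, 6))
})
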