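test_that("walk counts match hand-enumerated examples", {
  diamond <- graph_from(c("A", "B", "C", "D"),
    data.frame(src = c("A", "A", "B", "C"),
               dst = c("B", "C", "D", "D")))
  wc <- countWalks(diamond)
  expect_equal(wc$counts, c(A = 2, B = 1, C = 1, D = 2))
  expect_equal(wc$nCompleteWalks, 2)

  chain <- graph_from(c("A", "B", "C"),
    data.frame(src = c("A", "B"), dst = c("B", "C")))
  expect_equal(countWalks(chain)$counts, c(A = 1, B = 1, C = 1))

  # cycle B<->C: the walk A-B-C-B-D would repeat B and is forbidden
  cyc <- graph_from(c("A", "B", "C", "D"),
    data.frame(src = c("A", "B", "C", "B"),
               dst = c("B", "C", "B", "D")))
  expect_equal(countWalks(cyc)$counts, c(A = 1, B = 1, C = 0, D = 1))
})

test_that("walk counting matches brute-force enumeration on random DAGs", {
  set.seed(42)
  for (i in 1:60) {
    g <- random_dag(sample(3:12, 1))
    pg <- graph_from(g$ids, g$edges)
    wc <- countWalks(pg)
    oracle <- enumerate_walks(g$ids, g$edges)
    expect_equal(wc$counts[g$ids], oracle$counts[g$ids])
    expect_equal(wc$nCompleteWalks, oracle$n)
    expect_true(all(wc$counts <= wc$nCompleteWalks))
  }
})

test_that("DP fast path and visited-set DFS agree on acyclic graphs", {
  set.seed(7)
  for (i in 1:40) {
    g <- random_dag(sample(3:10, 1))
    pg <- graph_from(g$ids, g$edges)
    adj <- ipanda:::.adjacency(pg)
    dp <- ipanda:::.count_walks_dp(adj, ipanda:::.topo_order(adj), 1e6)
    dfs <- ipanda:::.count_walks_dfs(adj, 1e6)
    expect_identical(dp$counts[g$ids], dfs$counts[g$ids])
    expect_equal(dp$n, dfs$n)
  }
})

test_that("walk-count guard trips on combinatorial blow-up", {
  # stacked diamonds double the walk count per layer
  ids <- "s0"
  edges <- data.frame(src = character(), dst = character())
  for (k in 1:25) {
    a <- paste0("a", k); b <- paste0("b", k); s <- paste0("s", k)
    edges <- rbind(edges, data.frame(
      src = c(paste0("s", k - 1), paste0("s", k - 1), a, b),
      dst = c(a, b, s, s)))
    ids <- c(ids, a, b, s)
  }
  pg <- graph_from(ids, edges)
  expect_error(countWalks(pg, maxWalks = 1000), "maxWalks")
})

test_that("topological weights are walk-count ratios with a documented fallback", {
  diamond <- graph_from(c("A", "B", "C", "D"),
    data.frame(src = c("A", "A", "B", "C"),
               dst = c("B", "C", "D", "D")))
  wt <- topologicalWeights(countWalks(diamond))
  expect_equal(wt, c(A = 1, B = 0.5, C = 0.5, D = 1))
  expect_equal(max(wt), 1)

  chain <- graph_from(c("A", "B"), data.frame(src = "A", dst = "B"))
  expect_true(all(topologicalWeights(countWalks(chain)) == 1))

  # a pure cycle has no start, hence no complete walk: all-1 fallback
  loop <- graph_from(c("A", "B"),
    data.frame(src = c("A", "B"), dst = c("B", "A")))
  expect_warning(wt0 <- topologicalWeights(countWalks(loop)),
                 "no complete")
  expect_equal(wt0, c(A = 1, B = 1))
})

test_that("module collapse contracts nodes and rewires edges", {
  ms <- GeneModuleSet(list(m1 = c("g1", "g2")))
  pg <- graph_from(c("g1", "g2", "g3"),
                   data.frame(src = "g1", dst = "g3"))
  col <- collapseModules(pg, ms)
  expect_equal(length(unitIds(col)), 2L)
  expect_setequal(unitGenes(col)[["m1"]], c("g1", "g2"))

  # chain g1 -> g2 -> g3 with module {g1, g3}: edges u->g2 and g2->u,
  # and no self-edge
  chain <- graph_from(c("g1", "g2", "g3"),
    data.frame(src = c("g1", "g2"), dst = c("g2", "g3")))
  col2 <- collapseModules(chain, GeneModuleSet(list(u = c("g1", "g3"))))
  e <- pathwayEdges(col2)
  expect_equal(nrow(e), 2L)
  expect_true(any(e$src == "u" & e$dst == "g2"))
  expect_true(any(e$src == "g2" & e$dst == "u"))
  expect_false(any(e$src == e$dst))

  # a module sharing no gene with the pathway leaves it unchanged
  col3 <- collapseModules(chain, GeneModuleSet(list(x = c("z1", "z2"))))
  expect_equal(unitIds(col3), unitIds(chain))
  expect_equal(pathwayEdges(col3), pathwayEdges(chain))
})

test_that("collapsed unit signs follow the majority, ties split per sign", {
  pg <- PathwayGraph("p",
    list(a = "g1", b = "g2", c = "g3", d = "g4"),
    signs = c(1L, 1L, -1L, 1L))
  col <- collapseModules(pg, GeneModuleSet(list(m = c("g1", "g2", "g3"))))
  expect_equal(unname(unitSigns(col)[["m"]]), 1L)
  # exact tie: split into one +1 and one -1 sub-unit
  col2 <- collapseModules(pg, GeneModuleSet(list(m = c("g1", "g3"))))
  signs <- unitSigns(col2)[c("m+", "m-")]
  expect_equal(unname(signs), c(1L, -1L))
  expect_equal(unitGenes(col2)[["m+"]], "g1")
  expect_equal(unitGenes(col2)[["m-"]], "g3")
})

test_that("contracting parallel nodes never increases complete walk counts", {
  set.seed(11)
  for (i in 1:30) {
    # layered graph with two parallel middle nodes (no path between them)
    pg <- graph_from(c("s", "m1", "m2", "e"),
      data.frame(src = c("s", "s", "m1", "m2"),
                 dst = c("m1", "m2", "e", "e")))
    extra <- random_dag(sample(3:6, 1))
    ids <- c(unitIds(pg), extra$ids)
    edges <- rbind(pathwayEdges(pg)[, c("src", "dst")], extra$edges)
    big <- graph_from(ids, edges)
    before <- countWalks(big)$nCompleteWalks
    after <- countWalks(collapseModules(
      big, GeneModuleSet(list(m = c("m1", "m2")))))$nCompleteWalks
    expect_lte(after, before)
  }
})
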