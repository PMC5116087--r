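test_that("unit contributions multiply sign, weights and fold change", {
  expect_equal(unitContribution(1.5, wS = 1, wT = 1, sign = 1), 1.5)
  expect_equal(unitContribution(1.5, wS = 1, wT = 1, sign = -1), -1.5)
  expect_equal(unitContribution(c(1, 3), wS = c(1, 1), wT = 0.5,
                                sign = 1, kind = "module"), 1)
  expect_equal(unitContribution(c(1, 3), wS = c(1, 1), wT = 0.5,
                                sign = 1, kind = "module", agg = "sum"),
               2)
})

test_that("pathway scores compose weights as in the worked examples", {
  # one activator gene, unit weights, log fc 2 -> score 2
  pair <- exact_expr_pair(c(gA = 9), c(gA = 7))
  db1 <- PathwayDatabase(list(PathwayGraph("P1", "gA")))
  sc <- ipandaScores(pair$cases, pair$normals, db1)
  expect_equal(unname(scoreMatrix(sc)[1, ]), c(2, 2))

  # activator + inhibitor with identical weights and fold change -> 0
  pair2 <- exact_expr_pair(c(gA = 9, gB = 9), c(gA = 7, gB = 7))
  db2 <- PathwayDatabase(list(
    PathwayGraph("P1", c("gA", "gB"), signs = c(1L, -1L))))
  sc2 <- ipandaScores(pair2$cases, pair2$normals, db2)
  expect_equal(unname(scoreMatrix(sc2)[1, ]), c(0, 0))

  # diamond topology, all weights from walk counts, all log fc 1:
  # contributions 1 + 0.5 + 0.5 + 1 = 3 (unnormalized)
  genes <- c(A = 8, B = 8, C = 8, D = 8)
  pair3 <- exact_expr_pair(genes, genes - 1)
  db3 <- PathwayDatabase(list(PathwayGraph("P1", names(genes),
    edges = data.frame(src = c("A", "A", "B", "C"),
                       dst = c("B", "C", "D", "D")))))
  sc3 <- ipandaScores(pair3$cases, pair3$normals, db3,
                      sizeNormalize = FALSE)
  expect_equal(unname(scoreMatrix(sc3)[1, ]), c(3, 3))
  # with size normalization the same pathway scores 3/4
  sc3n <- ipandaScores(pair3$cases, pair3$normals, db3)
  expect_equal(unname(scoreMatrix(sc3n)[1, ]), c(0.75, 0.75))
})

test_that("scores are linear in log fold change and antisymmetric", {
  base <- c(A = 8, B = 8, C = 8, D = 8, E = 8)
  ref <- base - c(2, 1, 0.5, -1, -2)      # mixed up/down regulation
  db <- PathwayDatabase(list(
    PathwayGraph("P1", names(base),
      edges = data.frame(src = c("A", "B", "C"),
                         dst = c("B", "C", "D"))),
    PathwayGraph("P2", c("D", "E"), signs = c(1L, -1L))))
  score_at <- function(scale) {
    pair <- exact_expr_pair(ref + scale * (base - ref), ref)
    scoreMatrix(ipandaScores(pair$cases, pair$normals, db))
  }
  s1 <- score_at(1)
  expect_equal(score_at(3), 3 * s1, tolerance = 1e-12)
  expect_equal(score_at(-1), -s1, tolerance = 1e-12)
})

test_that("size normalization equates small and large uniform pathways", {
  small <- sprintf("s%03d", 1:5)
  large <- sprintf("l%03d", 1:400)
  delta <- 1.7
  case_vals <- c(stats::setNames(rep(7 + delta, 5), small),
                 stats::setNames(rep(7 + delta, 400), large))
  norm_vals <- c(stats::setNames(rep(7, 5), small),
                 stats::setNames(rep(7, 400), large))
  pair <- exact_expr_pair(case_vals, norm_vals)
  db <- PathwayDatabase(list(PathwayGraph("Psmall", small),
                             PathwayGraph("Plarge", large)))
  m <- scoreMatrix(ipandaScores(pair$cases, pair$normals, db))
  expect_equal(m["Psmall", 1], delta)
  expect_equal(m["Plarge", 1], delta)
  # without normalization the large pathway dominates by its size
  m2 <- scoreMatrix(ipandaScores(pair$cases, pair$normals, db,
                                 sizeNormalize = FALSE))
  expect_equal(m2["Plarge", 1] / m2["Psmall", 1], 80)
})

test_that("two coexpressed genes score identically split or collapsed", {
  # parallel positions: s -> g1 -> e, s -> g2 -> e; g1, g2 share
  # weight and fold change
  genes <- c(s = 8, g1 = 8, g2 = 8, e = 8)
  pair <- exact_expr_pair(genes, genes - 1)
  db <- PathwayDatabase(list(PathwayGraph("P1", names(genes),
    edges = data.frame(src = c("s", "s", "g1", "g2"),
                       dst = c("g1", "g2", "e", "e")))))
  split <- scoreMatrix(ipandaScores(pair$cases, pair$normals, db))
  collapsed <- scoreMatrix(ipandaScores(
    pair$cases, pair$normals, db,
    modules = GeneModuleSet(list(m = c("g1", "g2")))))
  expect_equal(collapsed, split, tolerance = 1e-12)
})

test_that("pathways absent from the data score zero with a warning", {
  pair <- exact_expr_pair(c(gA = 9), c(gA = 7))
  db <- PathwayDatabase(list(PathwayGraph("P1", "gA"),
                             PathwayGraph("P2", c("zz1", "zz2"))))
  expect_warning(sc <- ipandaScores(pair$cases, pair$normals, db),
                 "P2")
  expect_equal(unname(scoreMatrix(sc)["P2", ]), c(0, 0))
})

test_that("Z-normalization centers and scales within each dataset", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("P1", c("s1", "s2")))
  z <- zscoreNormalize(PandaScores(m))
  expect_equal(unname(scoreMatrix(z)[1, ]), c(-1, 1))
  expect_true(isNormalized(z))

  # constant rows map to zero
  mc <- matrix(5, 1, 3, dimnames = list("P1", paste0("s", 1:3)))
  expect_equal(unname(scoreMatrix(zscoreNormalize(PandaScores(mc)))[1, ]),
               c(0, 0, 0))

  # per-dataset independence: a +10 offset dataset yields identical Z
  m2 <- matrix(c(1, 3, 2, 11, 13, 12), 1, 6,
               dimnames = list("P1", paste0("s", 1:6)))
  sc <- PandaScores(m2, datasetId = rep(c("d1", "d2"), each = 3))
  z2 <- scoreMatrix(zscoreNormalize(sc))
  expect_equal(unname(z2[1, 1:3]), unname(z2[1, 4:6]), tolerance = 1e-12)

  # balanced expectation removes class-imbalance dependence
  m3 <- matrix(c(10, 10, 10, 0), 1, 4,
               dimnames = list("P1", paste0("s", 1:4)))
  ph <- c(s1 = "responder", s2 = "responder", s3 = "responder",
          s4 = "non_responder")
  zb <- scoreMatrix(zscoreNormalize(PandaScores(m3), phenotype = ph))
  # balanced center is (10 + 0)/2 = 5, not the plain mean 7.5
  expect_equal(unname(zb[1, 4]), (0 - 5) / sqrt(75 / 4))

  expect_error(zscoreNormalize(PandaScores(
    matrix(1, 1, 1, dimnames = list("P1", "s1")))), "single sample")
})

test_that("weighted Fisher reduces to the classical combination", {
  expect_equal(weightedFisher(0.05, 1), 0.05, tolerance = 1e-12)
  expect_equal(weightedFisher(c(0.05, 0.05), c(1, 1)),
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # unit weights match Fisher's chi-squared for any N up to 20
  set.seed(13)
  for (n in c(2, 5, 11, 20)) {
    p <- runif(n)
    expect_equal(weightedFisher(p, rep(1, n)),
                 pchisq(-2 * sum(log(p)), df = 2 * n,
                        lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # zero-weight units are excluded before combination
  expect_equal(weightedFisher(c(0.05, 0.001), c(1, 0)), 0.05)
  expect_warning(res <- weightedFisher(c(0.1, 0.2), c(0, 0)),
                 "zero")
  expect_equal(res, 1)
  expect_error(weightedFisher(c(0, 0.5), c(1, 1)), "\\(0, 1\\]")
})

test_that("pathway significance reflects planted differential signal", {
  set.seed(55)
  cfg <- simulationConfig(seed = 5, nGenes = 300, nPathways = 5,
                          pathwaySizeRange = c(8, 15), nCases = 20,
                          nNormals = 20)
  db <- simulatePathwayDB(cfg)
  sim <- simulateExpression(cfg, db)
  sig <- pathwaySignificance(sim$cases, sim$normals, db)
  expect_true(all(sig$p_value > 0 & sig$p_value <= 1))
  planted <- sig$p_value[sig$pathway_id == sim$truth$planted]
  expect_lt(planted, 0.01)
  expect_lt(planted, min(sig$p_value[sig$pathway_id !=
                                       sim$truth$planted]))
})
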