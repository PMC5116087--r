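test_that("generators are fully deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 8, nGenes = 150, nPathways = 5,
                          pathwaySizeRange = c(5, 20), nCases = 5,
                          nNormals = 5)
  db1 <- simulatePathwayDB(cfg)
  db2 <- simulatePathwayDB(cfg)
  expect_equal(lapply(pathways(db1), unitGenes),
               lapply(pathways(db2), unitGenes))
  e1 <- simulateExpression(cfg, db1)
  e2 <- simulateExpression(cfg, db1)
  expect_identical(exprValues(e1$cases), exprValues(e2$cases))

  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  p1 <- simulateFixtureDir(cfg, d1); p2 <- simulateFixtureDir(cfg, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("layered DAGs always expose walk start and end points", {
  cfg <- simulationConfig(seed = 2, nGenes = 400, nPathways = 25,
                          pathwaySizeRange = c(5, 50))
  db <- simulatePathwayDB(cfg)
  for (p in pathways(db)) {
    e <- pathwayEdges(p)
    indeg <- setdiff(unitIds(p), e$dst)
    outdeg <- setdiff(unitIds(p), e$src)
    expect_gt(length(indeg), 0L)
    expect_gt(length(outdeg), 0L)
    wc <- countWalks(p, maxWalks = 1e6)   # must not trip the guard
    expect_gte(wc$nCompleteWalks, 1)
  }
  # back-edges produce cycles handled by the visited-set branch
  cfgc <- simulationConfig(seed = 3, nGenes = 200, nPathways = 10,
                           pathwaySizeRange = c(5, 15),
                           backEdgeProb = 0.5)
  dbc <- simulatePathwayDB(cfgc)
  has_cycle <- vapply(pathways(dbc), function(p)
    is.null(ipanda:::.topo_order(ipanda:::.adjacency(p))), logical(1))
  expect_true(any(has_cycle))
  for (p in pathways(dbc))
    expect_gte(countWalks(p, maxWalks = 1e6)$nCompleteWalks, 0)
})

test_that("null simulations are calibrated and planted effects recoverable", {
  # delta = 0: no planted truth, ~5% of genes below p = 0.05
  cfg0 <- simulationConfig(seed = 4, nGenes = 2000, nPathways = 5,
                           pathwaySizeRange = c(5, 20), nCases = 10,
                           nNormals = 10, effectSize = 0)
  db <- simulatePathwayDB(cfg0)
  sim0 <- simulateExpression(cfg0, db)
  expect_length(sim0$truth$planted, 0L)
  tt <- groupTTest(sim0$cases, sim0$normals)
  frac <- mean(tt$p_value < 0.05)
  half_width <- qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, 0.05 - half_width)
  expect_lt(frac, 0.05 + half_width)

  # delta = 2: the planted pathway has the largest mean |score|
  hits <- vapply(1:10, function(s) {
    cfg <- simulationConfig(seed = s, nGenes = 300, nPathways = 8,
                            pathwaySizeRange = c(10, 10), nCases = 10,
                            nNormals = 10, effectSize = 2)
    dbs <- simulatePathwayDB(cfg)
    sim <- simulateExpression(cfg, dbs)
    sc <- suppressWarnings(ipandaScores(sim$cases, sim$normals, dbs))
    means <- rowMeans(abs(scoreMatrix(sc)))
    names(which.max(means)) == sim$truth$planted
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("module-structured noise reproduces the requested correlations", {
  cfg <- simulationConfig(seed = 6, nGenes = 200, nPathways = 4,
                          pathwaySizeRange = c(10, 20), nCases = 150,
                          nNormals = 5, blockCorr = 0.8, effectSize = 0)
  db <- simulatePathwayDB(cfg)
  sim <- simulateExpression(cfg, db)
  bl <- sim$truth$blocks[[1]]
  emp <- cor(t(exprValues(sim$cases)[bl, ]))
  expect_equal(mean(emp[upper.tri(emp)]), 0.8, tolerance = 0.12)
  co <- simulateCoexpression(cfg, sim$truth$blocks, pathwayGenes(db))
  expect_silent(validateCoexpression(co))
  expect_equal(co[bl[1], bl[2]], 0.8)
})

test_that("platform pairs share biology and degrade with technical noise", {
  base <- simulationConfig(seed = 9, nGenes = 300, nPathways = 6,
                           pathwaySizeRange = c(6, 20), nCases = 6,
                           nNormals = 6, platformNoiseSd = 0)
  db <- simulatePathwayDB(base)
  p0 <- simulatePlatformPair(base, db)
  expect_identical(exprValues(p0$platform1$cases),
                   exprValues(p0$platform2$cases))

  mean_gene_corr <- function(sd, seeds = 1:6) {
    mean(vapply(seeds, function(s) {
      cfg <- simulationConfig(seed = s, nGenes = 300, nPathways = 6,
                              pathwaySizeRange = c(6, 20), nCases = 6,
                              nNormals = 6, platformNoiseSd = sd)
      pr <- simulatePlatformPair(cfg, db)
      f1 <- logFoldChanges(pr$platform1$cases, pr$platform1$normals)
      f2 <- logFoldChanges(pr$platform2$cases, pr$platform2$normals)
      mean(vapply(seq_len(ncol(f1)), function(j)
        cor(f1[, j], f2[, j]), numeric(1)))
    }, numeric(1)))
  }
  cors <- vapply(c(0.1, 0.5, 1.0), mean_gene_corr, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("scores agree across platforms better than gene fold changes", {
  agree <- vapply(1:5, function(s) {
    cfg <- simulationConfig(seed = s, nGenes = 400, nPathways = 8,
                            pathwaySizeRange = c(8, 25), nCases = 6,
                            nNormals = 6, platformNoiseSd = 1)
    db <- simulatePathwayDB(cfg)
    pc <- suppressWarnings(
      platformConcordance(simulatePlatformPair(cfg, db), db))
    pc$scoreCorr > pc$lfcCorr
  }, logical(1))
  expect_true(all(agree))
})
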