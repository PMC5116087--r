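#' @include AllClasses.R
NULL

# deterministic seed derivation; keeps values inside 32-bit integer range
.derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1000003 + salt) %% 2147483629)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' describe the reference simulation: 2000 log-normally expressed genes,
#' 20 layered-DAG pathways of 5-50 genes, 20 case and 20 normal samples,
#' a planted log2 effect of 2 units, coexpression blocks at internal
#' correlation 0.8, and platform noise of 1 log2 unit.
#'
#' @param seed integer seed; the same configuration always reproduces the
#'   same data.
#' @param nGenes size of the gene universe.
#' @param nPathways,pathwaySizeRange,dagLayers pathway database shape:
#'   number of pathways, per-pathway gene-count range, number of DAG
#'   layers (edges only run towards later layers, so graphs are acyclic
#'   unless \code{backEdgeProb > 0}).
#' @param inhibitorFrac fraction of pathway nodes with activation sign -1.
#' @param backEdgeProb probability of adding a cycle-forming back-edge per
#'   node (default 0: acyclic).
#' @param nCases,nNormals group sizes.
#' @param effectSize planted perturbation, log2 units, applied to planted
#'   pathway genes in case (or responder) samples with the sign of their
#'   node.
#' @param blockCorr within-block coexpression (correlation of block genes
#'   implied by the shared block factor).
#' @param nBlocks,blockSizeRange number and size range of coexpression
#'   blocks (drawn from pathway-covered genes).
#' @param blockNoiseSd standard deviation of an additional
#'   phenotype-independent per-sample block factor (0 disables it); used
#'   to stress module handling of correlated nuisance signal.
#' @param noiseSd per-gene residual noise SD, log2 units.
#' @param baselineMean mean baseline log2 intensity.
#' @param platformNoiseSd SD of platform-specific gene offsets and
#'   per-cell technical noise in [simulatePlatformPair()].
#' @param plantedPathways pathway ids carrying the planted effect (NULL:
#'   the first pathway).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 2000L, nPathways = 20L,
                             pathwaySizeRange = c(5L, 50L),
                             dagLayers = 4L, inhibitorFrac = 0.1,
                             backEdgeProb = 0, nCases = 20L,
                             nNormals = 20L, effectSize = 2,
                             blockCorr = 0.8, nBlocks = 10L,
                             blockSizeRange = c(4L, 8L), blockNoiseSd = 0,
                             noiseSd = 1, baselineMean = 7,
                             platformNoiseSd = 1,
                             plantedPathways = NULL) {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nPathways = as.integer(nPathways),
              pathwaySizeRange = as.integer(pathwaySizeRange),
              dagLayers = as.integer(dagLayers),
              inhibitorFrac = inhibitorFrac,
              backEdgeProb = backEdgeProb, nCases = as.integer(nCases),
              nNormals = as.integer(nNormals), effectSize = effectSize,
              blockCorr = blockCorr, nBlocks = as.integer(nBlocks),
              blockSizeRange = as.integer(blockSizeRange),
              blockNoiseSd = blockNoiseSd, noiseSd = noiseSd,
              baselineMean = baselineMean,
              platformNoiseSd = platformNoiseSd,
              plantedPathways = plantedPathways)
  stopifnot(cfg$nGenes > 0, cfg$nPathways > 0, cfg$nCases > 0,
            cfg$nNormals > 0, cfg$dagLayers >= 1,
            cfg$blockCorr >= 0, cfg$blockCorr < 1,
            cfg$platformNoiseSd >= 0, cfg$noiseSd >= 0)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a pathway-topology database
#'
#' Generates layered random DAGs: each pathway's nodes are spread over
#' \code{dagLayers} layers, every non-first-layer node receives at least
#' one parent from the previous layer, and extra forward edges are added
#' at random, so every graph has at least one zero-in-degree and one
#' zero-out-degree node and walk counting terminates. About
#' \code{inhibitorFrac} of the nodes carry sign -1; roughly 10% of edges
#' are typed \code{inhibition}. With \code{backEdgeProb > 0} a
#' back-edge may be added per node, producing cycles that exercise the
#' simple-path (visited-set) counting branch.
#'
#' @param cfg a [simulationConfig()].
#' @return A [PathwayDatabase-class] with one single-gene node per unit.
#' @export
simulatePathwayDB <- function(cfg) {
  set.seed(.derive_seed(cfg$seed, 11L))
  universe <- sprintf("G%05d", seq_len(cfg$nGenes))
  pws <- lapply(seq_len(cfg$nPathways), function(k) {
    n <- sample(seq(cfg$pathwaySizeRange[1L], cfg$pathwaySizeRange[2L]),
                1L)
    genes <- sample(universe, n)
    layers <- sort(sample(seq_len(cfg$dagLayers), n, replace = TRUE))
    layers[1L] <- 1L                       # guarantee a first layer
    src <- character(); dst <- character()
    for (i in seq_len(n)) {
      if (layers[i] > 1L) {
        prev <- which(layers == layers[i] - 1L)
        if (!length(prev)) prev <- which(layers < layers[i])
        src <- c(src, genes[sample(prev, 1L)]); dst <- c(dst, genes[i])
      }
      earlier <- which(layers < layers[i])
      extra <- earlier[stats::runif(length(earlier)) < 0.15]
      if (length(extra)) {
        src <- c(src, genes[extra]); dst <- c(dst, rep(genes[i],
                                                       length(extra)))
      }
      if (cfg$backEdgeProb > 0 && layers[i] > 1L &&
          stats::runif(1L) < cfg$backEdgeProb) {
        tgt <- which(layers < layers[i])
        src <- c(src, genes[i]); dst <- c(dst, genes[sample(tgt, 1L)])
      }
    }
    edges <- unique(data.frame(src = src, dst = dst,
                               stringsAsFactors = FALSE))
    edges$type <- ifelse(stats::runif(nrow(edges)) < 0.1, "inhibition",
                         "activation")
    signs <- ifelse(stats::runif(n) < cfg$inhibitorFrac, -1L, 1L)
    PathwayGraph(sprintf("P%02d", k), genes, signs = signs,
                 edges = edges)
  })
  PathwayDatabase(pws, name = "synthetic", version = "1")
}

# disjoint coexpression blocks drawn from pathway-covered genes
.choose_blocks <- function(cfg, db) {
  set.seed(.derive_seed(cfg$seed, 23L))
  pool <- pathwayGenes(db)
  blocks <- list()
  for (b in seq_len(cfg$nBlocks)) {
    sz <- sample(seq(cfg$blockSizeRange[1L], cfg$blockSizeRange[2L]), 1L)
    if (length(pool) < max(sz, 2L)) break
    blocks[[length(blocks) + 1L]] <- sample(pool, sz)
    pool <- setdiff(pool, blocks[[length(blocks)]])
  }
  if (length(blocks))
    names(blocks) <- sprintf("B%02d", seq_along(blocks))
  blocks
}

# log2 noise matrix with shared block factors
.noise_matrix <- function(genes, nsamp, blocks, cfg) {
  z <- matrix(stats::rnorm(length(genes) * nsamp), length(genes), nsamp,
              dimnames = list(genes, NULL))
  rho <- cfg$blockCorr
  for (b in seq_along(blocks)) {
    g <- intersect(blocks[[b]], genes)
    if (length(g) < 2L) next
    zb <- matrix(rep(stats::rnorm(nsamp), each = length(g)), length(g),
                 nsamp)
    z[g, ] <- sqrt(rho) * zb + sqrt(1 - rho) * z[g, , drop = FALSE]
    if (cfg$blockNoiseSd > 0)
      z[g, ] <- z[g, ] + (cfg$blockNoiseSd / cfg$noiseSd) *
        matrix(rep(stats::rnorm(nsamp), each = length(g)), length(g),
               nsamp)
  }
  cfg$noiseSd * z
}

# per-gene signed planted effect, taken from the planted pathways' nodes
.planted_effects <- function(db, planted, effectSize) {
  eff <- numeric(0)
  for (pid in planted) {
    p <- pathways(db)[[pid]]
    s <- unitSigns(p)
    for (u in seq_along(p@unitIds))
      for (g in p@unitGenes[[u]])
        if (!g %in% names(eff)) eff[g] <- effectSize * p@unitSigns[u]
  }
  eff
}

#' Simulate case/control expression data with planted pathway effects
#'
#' Log2 intensities are a per-gene baseline plus block-correlated
#' Gaussian noise; case samples (or, with \code{phenotype = TRUE}, only
#' responder case samples) additionally receive the planted effect
#' \code{effectSize} on every gene of the planted pathways, signed by the
#' gene's node sign. With \code{effectSize = 0} the planted truth is
#' empty and the data are pure null.
#'
#' @param cfg a [simulationConfig()].
#' @param db a [PathwayDatabase-class] (typically [simulatePathwayDB()]).
#' @param phenotype if TRUE, only the first half of case samples
#'   (responders) receive the effect; phenotype labels are attached.
#' @param blocks optional list of coexpression blocks (defaults to a
#'   seeded draw from pathway-covered genes).
#' @param caseWideGenes genes of planted pathways whose effect applies to
#'   every case sample even in phenotype mode: they model
#'   disease-responsive but phenotype-uninformative coexpressed
#'   periphery (high statistical weight, no responder signal).
#' @param effectScale optional named numeric vector of per-gene
#'   multipliers on the planted effect (e.g. topological weights, to
#'   model a perturbation propagating along the main cascade); genes not
#'   named keep multiplier 1.
#' @param seed seed override (defaults to \code{cfg$seed}); lets several
#'   datasets share a configuration while differing in noise.
#' @return list with \code{cases} and \code{normals} (see
#'   [ExpressionData()]) and a \code{truth} record (\code{planted},
#'   \code{delta}, \code{blocks}, \code{phenotype}).
#' @export
simulateExpression <- function(cfg, db, phenotype = FALSE, blocks = NULL,
                               caseWideGenes = character(0),
                               effectScale = NULL, seed = cfg$seed) {
  if (is.null(blocks)) blocks <- .choose_blocks(cfg, db)
  planted <- cfg$plantedPathways
  if (is.null(planted) && cfg$effectSize != 0)
    planted <- pathwayIds(db)[1L]
  if (cfg$effectSize == 0) planted <- character(0)
  set.seed(.derive_seed(seed, 37L))
  genes <- sprintf("G%05d", seq_len(cfg$nGenes))
  baseline <- stats::rnorm(cfg$nGenes, cfg$baselineMean, 1)
  names(baseline) <- genes
  ncase <- cfg$nCases; nnorm <- cfg$nNormals
  cases <- baseline + .noise_matrix(genes, ncase, blocks, cfg)
  normals <- baseline + .noise_matrix(genes, nnorm, blocks, cfg)
  colnames(cases) <- sprintf("case_%02d", seq_len(ncase))
  colnames(normals) <- sprintf("normal_%02d", seq_len(nnorm))
  ph <- NULL
  eff <- .planted_effects(db, planted, cfg$effectSize)
  if (length(eff)) {
    eff <- eff[names(eff) %in% genes]
    if (!is.null(effectScale)) {
      sc <- effectScale[names(eff)]
      sc[is.na(sc)] <- 1
      eff <- eff * sc
    }
    cw <- intersect(names(eff), caseWideGenes)
    ro <- setdiff(names(eff), cw)
    target <- if (phenotype) seq_len(ceiling(ncase / 2)) else
      seq_len(ncase)
    cases[ro, target] <- cases[ro, target] + eff[ro]
    if (length(cw)) cases[cw, ] <- cases[cw, ] + eff[cw]
  }
  if (phenotype)
    ph <- ifelse(seq_len(ncase) <= ceiling(ncase / 2), "responder",
                 "non_responder")
  list(
    cases = ExpressionData(cases, datasetId = sprintf("ds%d", seed),
                           scale = "log2", group = "case",
                           phenotype = ph),
    normals = ExpressionData(normals, datasetId = sprintf("ds%d", seed),
                             scale = "log2", group = "normal"),
    truth = list(planted = planted, delta = cfg$effectSize,
                 blocks = blocks, phenotype = ph))
}

#' Theoretical coexpression matrix of a simulated design
#'
#' Returns the correlation matrix implied by the generator's block
#' structure: \code{blockCorr} (raised appropriately when an extra block
#' factor is active) within blocks, 0 elsewhere, unit diagonal.
#'
#' @param cfg a [simulationConfig()].
#' @param blocks block list (from a \code{truth} record).
#' @param genes gene universe of the matrix (default: the block genes and
#'   nothing else is rarely useful, so pass e.g.
#'   \code{pathwayGenes(db)}).
#' @return A symmetric correlation matrix.
#' @export
simulateCoexpression <- function(cfg, blocks, genes) {
  rho <- cfg$blockCorr
  if (cfg$blockNoiseSd > 0) {
    v <- cfg$noiseSd^2; b <- cfg$blockNoiseSd^2
    rho <- (rho * v + b) / (v + b)
  }
  m <- diag(1, length(genes))
  dimnames(m) <- list(genes, genes)
  for (bl in blocks) {
    g <- intersect(bl, genes)
    if (length(g) < 2L) next
    m[g, g] <- rho
  }
  diag(m) <- 1
  m
}

#' Simulate a dual-platform replicate pair
#'
#' Emulates profiling the same samples on two platforms: a shared
#' biological log2 matrix (baseline, block noise, planted effects) is
#' measured twice, each platform adding its own fixed per-gene offset
#' (probe effect) and per-cell Gaussian noise, both with SD
#' \code{platformNoiseSd}. With \code{platformNoiseSd = 0} the two
#' platforms return identical matrices.
#'
#' @param cfg a [simulationConfig()].
#' @param db a [PathwayDatabase-class].
#' @param seed seed override.
#' @return list with \code{platform1}, \code{platform2} (each a
#'   \code{list(cases, normals)}) and the shared \code{truth}.
#' @export
simulatePlatformPair <- function(cfg, db, seed = cfg$seed) {
  bio <- simulateExpression(cfg, db, seed = seed)
  set.seed(.derive_seed(seed, 53L))
  sd <- cfg$platformNoiseSd
  mk <- function(tag) {
    off <- stats::rnorm(cfg$nGenes, 0, sd)
    jitter <- function(m) m + off +
      matrix(stats::rnorm(length(m), 0, sd), nrow(m), ncol(m))
    list(cases = ExpressionData(jitter(exprValues(bio$cases)),
                                datasetId = tag, scale = "log2",
                                group = "case"),
         normals = ExpressionData(jitter(exprValues(bio$normals)),
                                  datasetId = tag, scale = "log2",
                                  group = "normal"))
  }
  list(platform1 = mk(paste0("platform1_s", seed)),
       platform2 = mk(paste0("platform2_s", seed)),
       truth = bio$truth)
}

#' Cross-platform concordance of scores versus gene fold changes
#'
#' For a dual-platform pair, computes for each case sample the Pearson
#' correlation between the two platforms' pathway activation score
#' vectors, and between their gene-level log2 fold-change vectors, and
#' returns the means over samples. Pathway scores aggregating many genes
#' with statistical weighting are expected to agree across platforms
#' better than individual gene fold changes do.
#'
#' @param pair result of [simulatePlatformPair()].
#' @param db a [PathwayDatabase-class].
#' @param modules optional [GeneModuleSet-class].
#' @param ... passed to [ipandaScores()].
#' @return list with \code{scoreCorr}, \code{lfcCorr} (mean over samples)
#'   and the per-sample vectors.
#' @export
platformConcordance <- function(pair, db, modules = NULL, ...) {
  s1 <- scoreMatrix(ipandaScores(pair$platform1$cases,
                                 pair$platform1$normals, db,
                                 modules = modules, ...))
  s2 <- scoreMatrix(ipandaScores(pair$platform2$cases,
                                 pair$platform2$normals, db,
                                 modules = modules, ...))
  f1 <- logFoldChanges(pair$platform1$cases, pair$platform1$normals)
  f2 <- logFoldChanges(pair$platform2$cases, pair$platform2$normals)
  ns <- ncol(s1)
  sc <- vapply(seq_len(ns), function(j) stats::cor(s1[, j], s2[, j]),
               numeric(1))
  gc <- vapply(seq_len(ns), function(j) stats::cor(f1[, j], f2[, j]),
               numeric(1))
  list(scoreCorr = mean(sc), lfcCorr = mean(gc), perSampleScoreCorr = sc,
       perSampleLfcCorr = gc)
}

# genes of a random subset of a pathway's units, used to place a
# correlated nuisance block inside the pathway
.random_unit_block <- function(graph, maxSize) {
  ord <- sample(seq_along(graph@unitIds))
  g <- character(0)
  for (u in ord) {
    g <- union(g, graph@unitGenes[[u]])
    if (length(g) >= maxSize) break
  }
  utils::head(g, maxSize)
}

# genes of the least-travelled units (ascending walk count), excluding
# a given set, used to place topologically peripheral nuisance genes
.peripheral_genes <- function(graph, maxSize, exclude = character(0)) {
  wt <- suppressWarnings(topologicalWeights(countWalks(graph)))
  g <- character(0)
  for (u in order(wt, unitIds(graph))) {
    g <- union(g, setdiff(graph@unitGenes[[u]], exclude))
    if (length(g) >= maxSize) break
  }
  utils::head(g, maxSize)
}

#' Simulate a multi-dataset marker study
#'
#' Builds one pathway database and a set of independent datasets sharing
#' the same planted responder-specific pathway perturbations, for
#' cross-dataset marker robustness experiments. Each planted pathway
#' carries two kinds of disease-responsive but phenotype-uninformative
#' nuisance alongside its responder signal:
#' \itemize{
#'   \item a coexpression block (per-sample shared factor of SD
#'     \code{blockNoiseSd}) on a random subset of units, at most a third
#'     of the pathway's genes -- correlated noise that module collapse
#'     counts once instead of once per gene;
#'   \item scattered peripheral genes at the least-travelled (low
#'     walk-count) units, not coexpressed with anything -- strong
#'     statistical weight that only topological weighting can
#'     down-weight.
#' }
#' Both nuisance sets shift in every case sample (so they pass the
#' statistical filter), while the responder effect on the remaining core
#' genes scales with each gene's topological weight, modelling a
#' perturbation propagating along the main cascade.
#'
#' @param cfg a [simulationConfig()]; \code{plantedPathways} defaults to
#'   the first three pathways, \code{blockNoiseSd} should be positive for
#'   the design to be interesting.
#' @param nDatasets number of independent datasets.
#' @return list with \code{db}, \code{blocks}, \code{periphery},
#'   \code{coexpr} (theoretical correlation matrix over pathway genes),
#'   \code{planted} and \code{datasets} (each a \code{list(cases,
#'   normals, truth)}).
#' @export
simulateMarkerStudy <- function(cfg, nDatasets = 4L) {
  db <- simulatePathwayDB(cfg)
  planted <- cfg$plantedPathways
  if (is.null(planted))
    planted <- utils::head(pathwayIds(db), 3L)
  cfg$plantedPathways <- planted
  set.seed(.derive_seed(cfg$seed, 29L))
  blocks <- lapply(planted, function(pid) {
    p <- pathways(db)[[pid]]
    .random_unit_block(p, max(3L, pathwaySize(p) %/% 3L))
  })
  blocks <- blocks[vapply(blocks, length, integer(1)) >= 2L]
  if (length(blocks))
    names(blocks) <- sprintf("B%02d", seq_along(blocks))
  periphery <- unique(unlist(lapply(planted, function(pid) {
    p <- pathways(db)[[pid]]
    .peripheral_genes(p, max(3L, pathwaySize(p) %/% 4L),
                      exclude = unlist(blocks))
  })))
  nuisance <- union(unique(unlist(blocks)), periphery)
  # responder effect propagates along the cascade: per-gene effect scaled
  # by the gene's topological weight in its planted pathway; nuisance
  # genes shift in full in every case sample instead
  effectScale <- numeric(0)
  for (pid in planted) {
    p <- pathways(db)[[pid]]
    wt <- suppressWarnings(topologicalWeights(countWalks(p)))
    for (u in seq_along(p@unitIds))
      for (g in p@unitGenes[[u]])
        if (!g %in% names(effectScale)) effectScale[g] <- wt[u]
  }
  effectScale[nuisance] <- 1
  datasets <- lapply(seq_len(nDatasets), function(d)
    simulateExpression(cfg, db, phenotype = TRUE, blocks = blocks,
                       caseWideGenes = nuisance,
                       effectScale = effectScale,
                       seed = .derive_seed(cfg$seed, 100L + d)))
  list(db = db, blocks = blocks, periphery = periphery,
       coexpr = simulateCoexpression(cfg, blocks, pathwayGenes(db)),
       planted = planted, datasets = datasets)
}

#' Write a complete synthetic fixture directory
#'
#' Materializes one simulated study as plain-text files: pathways.json
#' (topology JSON dialect), coexpr.tsv (theoretical coexpression over
#' pathway genes), cases.tsv / normals.tsv (expression TSV) and
#' truth.json (planted pathways, blocks, phenotype labels).
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if missing).
#' @param phenotype passed to [simulateExpression()].
#' @return Invisibly, the list of written paths.
#' @export
simulateFixtureDir <- function(cfg, dir, phenotype = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  db <- simulatePathwayDB(cfg)
  sim <- simulateExpression(cfg, db, phenotype = phenotype)
  paths <- list(
    pathways = file.path(dir, "pathways.json"),
    coexpr = file.path(dir, "coexpr.tsv"),
    cases = file.path(dir, "cases.tsv"),
    normals = file.path(dir, "normals.tsv"),
    truth = file.path(dir, "truth.json"))
  writePathwayDatabase(db, paths$pathways)
  writeCoexpression(simulateCoexpression(cfg, sim$truth$blocks,
                                         pathwayGenes(db)),
                    paths$coexpr)
  writeExpression(sim$cases, paths$cases)
  writeExpression(sim$normals, paths$normals)
  jsonlite::write_json(
    list(planted = as.list(sim$truth$planted), delta = sim$truth$delta,
         blocks = lapply(sim$truth$blocks, as.list),
         phenotype = as.list(sim$truth$phenotype)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
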