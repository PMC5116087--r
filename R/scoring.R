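#' @include AllClasses.R
NULL

#' Contribution of one pathway unit to the activation score
#'
#' A unit representing a single gene contributes
#' \code{sign * w_S * w_T * logFC}; a module unit contributes its sign and
#' topological weight times the aggregate (mean by default) of
#' \code{w_S * logFC} over its member genes, so a module acts as a single
#' unit commensurate with an individual gene.
#'
#' @param logFC log2 fold change(s) of the unit's member gene(s).
#' @param wS statistical weight(s) in [0, 1], parallel to \code{logFC}.
#' @param wT the unit's topological weight in [0, 1].
#' @param sign activation sign, +1 or -1.
#' @param kind \code{"gene"} or \code{"module"}.
#' @param agg module aggregation, \code{"mean"} (default) or \code{"sum"}.
#' @return The unit's signed contribution (scalar).
#' @export
unitContribution <- function(logFC, wS, wT, sign = 1,
                             kind = c("gene", "module"),
                             agg = c("mean", "sum")) {
  kind <- match.arg(kind)
  agg <- match.arg(agg)
  stopifnot(sign %in% c(-1, 1), wT >= 0, wT <= 1, all(wS >= 0 & wS <= 1))
  v <- wS * logFC
  if (kind == "gene") {
    stopifnot(length(v) == 1L)
    return(sign * wT * v)
  }
  sign * wT * if (agg == "mean") mean(v) else sum(v)
}

# per-pathway unit bookkeeping shared by scoring and significance
.pathway_units <- function(graph, modules, useTopology, maxWalks) {
  if (!is.null(modules) && length(modules))
    graph <- collapseModules(graph, modules)
  wT <- if (useTopology) {
    suppressWarnings(topologicalWeights(countWalks(graph,
                                                   maxWalks = maxWalks)))
  } else stats::setNames(rep(1, length(graph@unitIds)), graph@unitIds)
  list(graph = graph, wT = wT)
}

#' Signed pathway activation scores
#'
#' The core scoring routine: for one dataset's case and normal groups,
#' computes per-gene statistical weights (smooth cosine transform of
#' Welch t-test P values), per-sample log2 fold changes against the
#' normal reference, per-unit topological weights on the
#' module-collapsed pathway graphs, and sums the signed unit
#' contributions into a pathway x case-sample activation score matrix.
#' Positive scores indicate pathway activation, negative inhibition.
#'
#' Weights are derived from this dataset only; to score several datasets,
#' call once per dataset and combine with [cbind] semantics or keep the
#' [PandaScores-class] objects separate (e.g. for [markerTable()]).
#'
#' @param cases,normals expression datasets ([ExpressionData()] results or
#'   log2 matrices); >= 2 samples each.
#' @param db a [PathwayDatabase-class].
#' @param modules optional [GeneModuleSet-class]; NULL scores without
#'   module collapse.
#' @param pMin,pMax smooth statistical-weight thresholds.
#' @param sizeNormalize divide each pathway score by the number of its
#'   member genes present in the data (default TRUE), so small and large
#'   pathways are treated on the same footing.
#' @param moduleAgg aggregation of member-gene terms inside a module unit,
#'   \code{"mean"} (default) or \code{"sum"}.
#' @param useTopology FALSE sets every topological weight to 1 (ablation).
#' @param maxWalks walk-count guard per pathway, see [countWalks()].
#' @return A [PandaScores-class], pathways x case samples.
#' @export
ipandaScores <- function(cases, normals, db, modules = NULL,
                         pMin = 1e-7, pMax = 1e-1, sizeNormalize = TRUE,
                         moduleAgg = c("mean", "sum"), useTopology = TRUE,
                         maxWalks = 1e6) {
  moduleAgg <- match.arg(moduleAgg)
  wtab <- statWeightTable(cases, normals, pMin = pMin, pMax = pMax)
  wS <- stats::setNames(wtab$w_S, wtab$gene)
  lfc <- logFoldChanges(cases, normals)
  lfc <- lfc[rownames(lfc) %in% names(wS), , drop = FALSE]
  nsamp <- ncol(lfc)
  scores <- matrix(0, nrow = length(db@pathways), ncol = nsamp,
                   dimnames = list(pathwayIds(db), colnames(lfc)))
  for (k in seq_along(db@pathways)) {
    pu <- .pathway_units(db@pathways[[k]], modules, useTopology, maxWalks)
    g <- pu$graph
    present <- intersect(pathwayGenes(g), rownames(lfc))
    if (!length(present)) {
      warning("pathway '", pathwayId(g),
              "' has no gene present in the expression data; score 0")
      next
    }
    total <- numeric(nsamp)
    for (u in seq_along(g@unitIds)) {
      mem <- intersect(g@unitGenes[[u]], rownames(lfc))
      if (!length(mem)) next
      x <- wS[mem] * lfc[mem, , drop = FALSE]
      v <- if (length(mem) == 1L) as.numeric(x)
           else if (moduleAgg == "mean") colMeans(x, na.rm = TRUE)
           else colSums(x, na.rm = TRUE)
      v[!is.finite(v)] <- 0
      total <- total + g@unitSigns[u] * pu$wT[g@unitIds[u]] * v
    }
    if (sizeNormalize) total <- total / length(present)
    scores[k, ] <- total
  }
  pheno <- NULL
  if (!is.matrix(cases)) {
    cd <- SummarizedExperiment::colData(cases)
    if ("phenotype" %in% names(cd))
      pheno <- cd[colnames(lfc), "phenotype"]
  }
  PandaScores(scores, datasetId = exprDataset(cases), phenotype = pheno,
              normalized = FALSE)
}

#' Z-normalize activation scores within each dataset
#'
#' Scores are centered and scaled per pathway and per dataset, so that
#' datasets profiled on different platforms become comparable. When
#' phenotype labels are available (and \code{balanceGroups} is TRUE) the
#' centering expectation is the mean of the per-phenotype means, which
#' removes the dependence of the expected score on the class balance of
#' the dataset; otherwise the plain mean is used. Scaling uses the
#' population (n-denominator) standard deviation; zero-variance rows map
#' to 0.
#'
#' @param scores a [PandaScores-class].
#' @param phenotype optional named character vector (sample -> phenotype)
#'   overriding the object's \code{colData} phenotype.
#' @param balanceGroups use the balanced expectation when labels exist.
#' @return A Z-normalized [PandaScores-class].
#' @export
zscoreNormalize <- function(scores, phenotype = NULL,
                            balanceGroups = TRUE) {
  m <- scoreMatrix(scores)
  ds <- scoreDatasets(scores)
  if (is.null(phenotype)) {
    cd <- SummarizedExperiment::colData(scores)
    if ("phenotype" %in% names(cd))
      phenotype <- stats::setNames(cd$phenotype, colnames(m))
  }
  out <- m
  for (d in unique(ds)) {
    idx <- which(ds == d)
    if (length(idx) < 2L)
      stop("dataset '", d, "' has a single sample; cannot Z-normalize")
    sub <- m[, idx, drop = FALSE]
    ph <- if (!is.null(phenotype)) phenotype[colnames(sub)] else NULL
    use_balance <- balanceGroups && !is.null(ph) &&
      length(unique(stats::na.omit(ph))) >= 2L
    center <- if (use_balance) {
      cls <- unique(stats::na.omit(ph))
      cm <- vapply(cls, function(cl)
        rowMeans(sub[, which(ph == cl), drop = FALSE]),
        numeric(nrow(sub)))
      rowMeans(matrix(cm, nrow = nrow(sub)))
    } else rowMeans(sub)
    sdv <- sqrt(rowMeans((sub - rowMeans(sub))^2))   # population SD
    z <- (sub - center) / sdv
    z[sdv == 0, ] <- 0
    out[, idx] <- z
  }
  res <- scores
  SummarizedExperiment::assay(res, "ipanda") <- out
  metadata(res)$normalized <- TRUE
  res
}

#' Weighted Fisher combined probability
#'
#' Combines per-unit P values with non-negative weights:
#' \code{X = -2 * sum(w_i * log(p_i))} referred to a Gamma null with shape
#' \code{sum(w_i)} and scale 2, which reduces exactly to Fisher's
#' chi-squared combination on 2N degrees of freedom when all weights are
#' 1. Zero-weight units are excluded before combination; if every weight
#' is zero the combined P value is 1 (with a warning), since no unit
#' carries usable evidence.
#'
#' @param p numeric vector of P values in (0, 1].
#' @param w numeric vector of weights in [0, 1], parallel to \code{p}.
#' @return Combined upper-tail P value in (0, 1].
#' @examples
#' weightedFisher(c(0.05, 0.05), c(1, 1))  # pchisq(11.98, 4, lower=FALSE)
#' @export
weightedFisher <- function(p, w = rep(1, length(p))) {
  stopifnot(length(p) == length(w))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("P values must lie in (0, 1]")
  if (any(w < 0)) stop("weights must be non-negative")
  keep <- w > 0
  if (!any(keep)) {
    warning("all unit weights are zero; combined P value set to 1")
    return(1)
  }
  p <- p[keep]; w <- w[keep]
  X <- -2 * sum(w * log(p))
  stats::pgamma(X, shape = sum(w), scale = 2, lower.tail = FALSE)
}

# Welch p for two sample vectors (used for module mean-profiles)
.welch_p <- function(x, y, zeroVarP = 1e-7) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (mean(x) != mean(y)) zeroVarP else 1)
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  max(2 * stats::pt(-abs(tt), df), 1e-300)
}

#' Statistical credibility of pathway activation scores
#'
#' Combines the unit-level differential-expression evidence of each
#' pathway into one P value with [weightedFisher()], using
#' \code{w = w_S * w_T} per unit. Single-gene units use the gene's Welch
#' t-test P value; module units use the Welch P value of the mean log2
#' expression profile of their member genes (the module treated as one
#' collective variable), with the module's \code{w_S} the cosine weight
#' of that P value.
#'
#' @inheritParams ipandaScores
#' @return data.frame with columns \code{pathway_id}, \code{p_value}.
#' @export
pathwaySignificance <- function(cases, normals, db, modules = NULL,
                                pMin = 1e-7, pMax = 1e-1,
                                useTopology = TRUE, maxWalks = 1e6) {
  x <- asLog2(cases); y <- asLog2(normals)
  tt <- groupTTest(cases, normals, zeroVarP = pMin)
  pv <- stats::setNames(tt$p_value, tt$gene)
  res <- lapply(db@pathways, function(pw) {
    pu <- .pathway_units(pw, modules, useTopology, maxWalks)
    g <- pu$graph
    ps <- numeric(0); ws <- numeric(0)
    for (u in seq_along(g@unitIds)) {
      mem <- intersect(g@unitGenes[[u]], names(pv))
      if (!length(mem)) next
      pu_p <- if (length(mem) == 1L) pv[mem]
              else .welch_p(colMeans(x[mem, , drop = FALSE]),
                            colMeans(y[mem, , drop = FALSE]),
                            zeroVarP = pMin)
      ps <- c(ps, pu_p)
      ws <- c(ws, statisticalWeight(pu_p, pMin, pMax) *
                    pu$wT[g@unitIds[u]])
    }
    if (!length(ps)) return(NA_real_)
    suppressWarnings(weightedFisher(ps, ws))
  })
  data.frame(pathway_id = pathwayIds(db),
             p_value = unlist(res, use.names = FALSE),
             stringsAsFactors = FALSE)
}
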