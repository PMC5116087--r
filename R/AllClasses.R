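#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

#' PathwayGraph: a directed signed graph of gene units
#'
#' A pathway is represented as a directed graph whose nodes ("units") are
#' either individual genes or collapsed gene modules. Each unit carries its
#' member gene symbols and an activation sign: +1 if the unit's product
#' pushes the pathway towards activation, -1 if it represses it. Edges are
#' directed biochemical interactions typed as activation or inhibition.
#'
#' @slot pathwayId single pathway identifier.
#' @slot unitIds character vector of unit identifiers, unique within the
#'   pathway.
#' @slot unitGenes list of character vectors, parallel to \code{unitIds};
#'   member gene symbols of each unit.
#' @slot unitSigns integer vector of +1/-1 activation signs, parallel to
#'   \code{unitIds}.
#' @slot edges data.frame with columns \code{src}, \code{dst}, \code{type}
#'   (\code{"activation"} or \code{"inhibition"}); \code{src}/\code{dst}
#'   reference \code{unitIds}. Self-edges are not allowed.
#'
#' @seealso [PathwayGraph()] for the user-facing constructor,
#'   [countWalks()], [collapseModules()].
#' @exportClass PathwayGraph
setClass("PathwayGraph",
  representation(
    pathwayId = "character",
    unitIds   = "character",
    unitGenes = "list",
    unitSigns = "integer",
    edges     = "data.frame"
  )
)

setValidity("PathwayGraph", function(object) {
  msg <- character()
  if (length(object@pathwayId) != 1L || is.na(object@pathwayId) ||
      !nzchar(object@pathwayId))
    msg <- c(msg, "'pathwayId' must be a single non-empty string")
  n <- length(object@unitIds)
  if (n < 1L)
    msg <- c(msg, "a pathway must contain at least one unit")
  if (anyDuplicated(object@unitIds))
    msg <- c(msg, "unit ids must be unique within a pathway")
  if (length(object@unitGenes) != n || length(object@unitSigns) != n)
    msg <- c(msg, "'unitGenes' and 'unitSigns' must be parallel to 'unitIds'")
  else {
    if (!all(vapply(object@unitGenes, function(g)
          is.character(g) && length(g) >= 1L && all(nzchar(g)), logical(1))))
      msg <- c(msg, "every unit must carry at least one member gene symbol")
    if (!all(object@unitSigns %in% c(-1L, 1L)))
      msg <- c(msg, "unit signs must be +1 or -1")
  }
  e <- object@edges
  if (!all(c("src", "dst", "type") %in% names(e)))
    msg <- c(msg, "'edges' needs columns src, dst, type")
  else if (nrow(e)) {
    bad <- setdiff(unique(c(e$src, e$dst)), object@unitIds)
    if (length(bad))
      msg <- c(msg, paste0("edge references undeclared unit id(s): ",
                           paste(bad, collapse = ", ")))
    if (any(e$src == e$dst))
      msg <- c(msg, "self-edges are not allowed")
    if (!all(e$type %in% c("activation", "inhibition")))
      msg <- c(msg, "edge type must be 'activation' or 'inhibition'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayGraph
#'
#' @param pathwayId pathway identifier.
#' @param genes named list of character vectors: member genes of each unit
#'   (names become unit ids; single-gene units may be given as a plain
#'   character vector of gene symbols, in which case unit ids equal gene
#'   symbols).
#' @param signs integer/numeric vector of +1/-1 activation signs, recycled
#'   to the number of units (default all +1).
#' @param edges data.frame with columns \code{src}, \code{dst} and
#'   optionally \code{type} (default \code{"activation"}).
#' @return A [PathwayGraph-class] object.
#' @examples
#' pg <- PathwayGraph("p1", c("A", "B"), edges = data.frame(src = "A", dst = "B"))
#' unitIds(pg)
#' @export
PathwayGraph <- function(pathwayId, genes, signs = 1L, edges = NULL) {
  if (is.character(genes)) {
    genes <- as.list(genes)
    names(genes) <- vapply(genes, `[`, character(1), 1L)
  }
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("unit list must be named (or be a plain character vector of genes)")
  if (is.null(edges))
    edges <- data.frame(src = character(), dst = character(),
                        type = character(), stringsAsFactors = FALSE)
  if (is.null(edges$type))
    edges$type <- rep("activation", nrow(edges))
  edges <- data.frame(src = as.character(edges$src),
                      dst = as.character(edges$dst),
                      type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  new("PathwayGraph",
      pathwayId = as.character(pathwayId),
      unitIds = ids,
      unitGenes = unname(lapply(genes, as.character)),
      unitSigns = rep_len(as.integer(signs), length(ids)),
      edges = edges)
}

#' PathwayDatabase: a collection of pathway graphs
#'
#' @slot dbName database name.
#' @slot dbVersion database version string.
#' @slot pathways list of [PathwayGraph-class] objects with unique ids.
#' @exportClass PathwayDatabase
setClass("PathwayDatabase",
  representation(
    dbName    = "character",
    dbVersion = "character",
    pathways  = "list"
  )
)

setValidity("PathwayDatabase", function(object) {
  msg <- character()
  if (!all(vapply(object@pathways, is, logical(1), "PathwayGraph")))
    msg <- c(msg, "'pathways' must be a list of PathwayGraph objects")
  else {
    ids <- vapply(object@pathways, function(p) p@pathwayId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "pathway identifiers must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayDatabase
#'
#' @param pathways list of [PathwayGraph-class] objects.
#' @param name,version database name and version strings.
#' @return A [PathwayDatabase-class] object.
#' @export
PathwayDatabase <- function(pathways, name = "pathwaydb", version = "0") {
  new("PathwayDatabase", dbName = as.character(name),
      dbVersion = as.character(version), pathways = unname(pathways))
}

#' GeneModuleSet: disjoint groups of coexpressed or co-regulated genes
#'
#' Gene modules are sets of genes whose expression changes are treated as a
#' single collective variable during topological weighting and scoring.
#' After merging, every gene is assigned to at most one module.
#'
#' @slot moduleIds character vector of module identifiers.
#' @slot moduleGenes list of character vectors (>= 2 genes each), parallel
#'   to \code{moduleIds}; pairwise disjoint.
#' @slot meanInternalCorr numeric vector: mean internal pairwise correlation
#'   of each module (NA when unknown, e.g. TF-target modules).
#' @slot moduleSource character vector: \code{"coexpression"},
#'   \code{"tf_targets"} or \code{"merged"}.
#' @exportClass GeneModuleSet
setClass("GeneModuleSet",
  representation(
    moduleIds        = "character",
    moduleGenes      = "list",
    meanInternalCorr = "numeric",
    moduleSource     = "character"
  )
)

setValidity("GeneModuleSet", function(object) {
  msg <- character()
  n <- length(object@moduleIds)
  if (anyDuplicated(object@moduleIds))
    msg <- c(msg, "module ids must be unique")
  if (length(object@moduleGenes) != n || length(object@meanInternalCorr) != n ||
      length(object@moduleSource) != n)
    msg <- c(msg, "all slots must be parallel to 'moduleIds'")
  else if (n) {
    if (!all(vapply(object@moduleGenes, length, integer(1)) >= 2L))
      msg <- c(msg, "every module must contain at least 2 genes")
    allg <- unlist(object@moduleGenes, use.names = FALSE)
    if (anyDuplicated(allg))
      msg <- c(msg, "modules must be pairwise disjoint")
    if (!all(object@moduleSource %in% c("coexpression", "tf_targets", "merged")))
      msg <- c(msg, "module source must be coexpression, tf_targets or merged")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModuleSet
#'
#' @param genes list of character vectors (module member genes), optionally
#'   named with module ids.
#' @param meanInternalCorr numeric vector of mean internal correlations
#'   (default NA).
#' @param source character vector of module provenance labels.
#' @return A [GeneModuleSet-class] object.
#' @export
GeneModuleSet <- function(genes = list(), meanInternalCorr = NA_real_,
                          source = "coexpression") {
  n <- length(genes)
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- if (n) sprintf("M%03d", seq_len(n)) else character()
  new("GeneModuleSet",
      moduleIds = ids,
      moduleGenes = unname(lapply(genes, as.character)),
      meanInternalCorr = rep_len(as.numeric(meanInternalCorr), n),
      moduleSource = rep_len(as.character(source), n))
}

#' PandaScores: signed pathway activation scores, pathway x sample
#'
#' Thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' the signed activation score matrix in the \code{"ipanda"} assay, with
#' per-sample \code{dataset_id} (and, when available, \code{group} /
#' \code{phenotype}) in \code{colData}. Positive scores correspond to
#' pathway activation, negative to inhibition.
#'
#' @exportClass PandaScores
setClass("PandaScores", contains = "SummarizedExperiment")

setValidity("PandaScores", function(object) {
  msg <- character()
  if (!"ipanda" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'PandaScores' object needs an 'ipanda' assay")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "ipanda"))))
    msg <- c(msg, "activation scores must be finite")
  if (!"dataset_id" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry 'dataset_id'")
  if (!is.logical(metadata(object)$normalized))
    msg <- c(msg, "metadata()$normalized flag missing")
  if (length(msg)) msg else TRUE
})

#' Construct a PandaScores object
#'
#' @param scores numeric matrix, pathways as rows, samples as columns, with
#'   dimnames set.
#' @param datasetId per-sample dataset labels (recycled).
#' @param phenotype optional per-sample phenotype labels
#'   (\code{"responder"}/\code{"non_responder"}/NA).
#' @param normalized logical flag: have the scores been Z-normalized?
#' @return A [PandaScores-class] object.
#' @export
PandaScores <- function(scores, datasetId = "dataset1", phenotype = NULL,
                        normalized = FALSE) {
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must have pathway rownames and sample colnames")
  cd <- S4Vectors::DataFrame(
    dataset_id = rep_len(as.character(datasetId), ncol(scores)),
    row.names = colnames(scores))
  if (!is.null(phenotype))
    cd$phenotype <- rep_len(as.character(phenotype), ncol(scores))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ipanda = scores), colData = cd)
  metadata(se)$normalized <- isTRUE(normalized)
  as(se, "PandaScores")
}

#' CMPResult: cross-dataset marker robustness index
#'
#' The CMP index summarizes how reproducibly pathways act as phenotype
#' markers across independent datasets: pathways whose (symmetric) AUC
#' exceeds the marker threshold in every dataset contribute
#' \code{log(N_i) * mean_j(AUC_ij - 0.5)}, where \code{N_i} is the pathway
#' gene count. CMP is zero exactly when no pathway is a marker in all
#' datasets.
#'
#' @slot cmp the index value (>= 0 in practice).
#' @slot commonMarkers ids of pathways above threshold in every dataset.
#' @slot aucThreshold marker threshold applied to the symmetric AUC.
#' @slot aucRandom AUC of a random classifier (0.5).
#' @slot contributions data.frame with one row per common marker
#'   (pathway_id, n_genes, mean_auc_excess, term).
#' @exportClass CMPResult
setClass("CMPResult",
  representation(
    cmp           = "numeric",
    commonMarkers = "character",
    aucThreshold  = "numeric",
    aucRandom     = "numeric",
    contributions = "data.frame"
  )
)

setValidity("CMPResult", function(object) {
  msg <- character()
  if (length(object@cmp) != 1L || is.na(object@cmp))
    msg <- c(msg, "'cmp' must be a single number")
  if ((length(object@commonMarkers) == 0L) != (isTRUE(object@cmp == 0)))
    msg <- c(msg, "cmp must be 0 exactly when there are no common markers")
  if (length(msg)) msg else TRUE
})
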