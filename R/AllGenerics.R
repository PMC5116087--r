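#' @include AllClasses.R
NULL

#' Accessors for pathway graphs and databases
#'
#' @param object a [PathwayGraph-class] or [PathwayDatabase-class].
#' @return \code{pathwayId}: the pathway identifier; \code{unitIds}: unit
#'   identifiers; \code{unitGenes}: named list of member gene vectors;
#'   \code{unitSigns}: named +1/-1 vector; \code{pathwayEdges}: the edge
#'   data.frame; \code{pathwaySize}: number of unique member genes;
#'   \code{pathwayGenes}: the unique member genes; \code{pathways}: the
#'   list of graphs in a database; \code{pathwayIds}: their identifiers.
#' @name pathway-accessors
NULL

#' @rdname pathway-accessors
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))
#' @rdname pathway-accessors
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))
#' @rdname pathway-accessors
#' @export
setGeneric("unitGenes", function(object) standardGeneric("unitGenes"))
#' @rdname pathway-accessors
#' @export
setGeneric("unitSigns", function(object) standardGeneric("unitSigns"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayEdges", function(object) standardGeneric("pathwayEdges"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwaySize", function(object) standardGeneric("pathwaySize"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayGenes", function(object) standardGeneric("pathwayGenes"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathways", function(object) standardGeneric("pathways"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayIds", function(object) standardGeneric("pathwayIds"))

#' @rdname pathway-accessors
setMethod("pathwayId", "PathwayGraph", function(object) object@pathwayId)
#' @rdname pathway-accessors
setMethod("unitIds", "PathwayGraph", function(object) object@unitIds)
#' @rdname pathway-accessors
setMethod("unitGenes", "PathwayGraph", function(object)
  stats::setNames(object@unitGenes, object@unitIds))
#' @rdname pathway-accessors
setMethod("unitSigns", "PathwayGraph", function(object)
  stats::setNames(object@unitSigns, object@unitIds))
#' @rdname pathway-accessors
setMethod("pathwayEdges", "PathwayGraph", function(object) object@edges)
#' @rdname pathway-accessors
setMethod("pathwaySize", "PathwayGraph", function(object)
  length(unique(unlist(object@unitGenes, use.names = FALSE))))
#' @rdname pathway-accessors
setMethod("pathwayGenes", "PathwayGraph", function(object)
  unique(unlist(object@unitGenes, use.names = FALSE)))

#' @rdname pathway-accessors
setMethod("pathways", "PathwayDatabase", function(object)
  stats::setNames(object@pathways, pathwayIds(object)))
#' @rdname pathway-accessors
setMethod("pathwayIds", "PathwayDatabase", function(object)
  vapply(object@pathways, pathwayId, character(1)))
#' @rdname pathway-accessors
setMethod("pathwayGenes", "PathwayDatabase", function(object)
  unique(unlist(lapply(object@pathways, pathwayGenes), use.names = FALSE)))

#' @describeIn PathwayDatabase number of pathways.
#' @param x a PathwayDatabase.
#' @export
setMethod("length", "PathwayDatabase", function(x) length(x@pathways))

#' @describeIn PathwayDatabase extract one pathway by position or id.
#' @param i index or pathway id.
#' @param j,... unused.
#' @export
setMethod("[[", "PathwayDatabase", function(x, i, j, ...) {
  if (is.character(i)) i <- match(i, pathwayIds(x))
  x@pathways[[i]]
})

#' Accessors for gene module sets
#'
#' @param object a [GeneModuleSet-class].
#' @return \code{moduleIds}: module identifiers; \code{moduleGenes}: named
#'   list of member gene vectors; \code{moduleAssignment}: named character
#'   vector mapping each assigned gene to its (unique) module id.
#' @name module-accessors
NULL

#' @rdname module-accessors
#' @export
setGeneric("moduleIds", function(object) standardGeneric("moduleIds"))
#' @rdname module-accessors
#' @export
setGeneric("moduleGenes", function(object) standardGeneric("moduleGenes"))
#' @rdname module-accessors
#' @export
setGeneric("moduleAssignment",
           function(object) standardGeneric("moduleAssignment"))

#' @rdname module-accessors
setMethod("moduleIds", "GeneModuleSet", function(object) object@moduleIds)
#' @rdname module-accessors
setMethod("moduleGenes", "GeneModuleSet", function(object)
  stats::setNames(object@moduleGenes, object@moduleIds))
#' @rdname module-accessors
setMethod("moduleAssignment", "GeneModuleSet", function(object) {
  g <- unlist(object@moduleGenes, use.names = FALSE)
  stats::setNames(rep(object@moduleIds,
                      vapply(object@moduleGenes, length, integer(1))), g)[g]
})

#' @describeIn GeneModuleSet number of modules.
#' @param x a GeneModuleSet.
#' @export
setMethod("length", "GeneModuleSet", function(x) length(x@moduleIds))

#' Accessors for score matrices
#'
#' @param object a [PandaScores-class].
#' @return \code{scoreMatrix}: the pathway x sample score matrix;
#'   \code{isNormalized}: logical, TRUE after Z-normalization;
#'   \code{scoreDatasets}: per-sample dataset labels.
#' @name score-accessors
NULL

#' @rdname score-accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
#' @rdname score-accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname score-accessors
#' @export
setGeneric("scoreDatasets", function(object) standardGeneric("scoreDatasets"))

#' @rdname score-accessors
setMethod("scoreMatrix", "PandaScores", function(object)
  SummarizedExperiment::assay(object, "ipanda"))
#' @rdname score-accessors
setMethod("isNormalized", "PandaScores", function(object)
  isTRUE(metadata(object)$normalized))
#' @rdname score-accessors
setMethod("scoreDatasets", "PandaScores", function(object)
  stats::setNames(SummarizedExperiment::colData(object)$dataset_id,
                  colnames(object)))

#' Accessors for CMP results
#'
#' @param object a [CMPResult-class].
#' @return \code{cmpValue}: the scalar CMP index; \code{commonMarkers}:
#'   pathway ids that are markers in every dataset.
#' @name cmp-accessors
NULL

#' @rdname cmp-accessors
#' @export
setGeneric("cmpValue", function(object) standardGeneric("cmpValue"))
#' @rdname cmp-accessors
#' @export
setGeneric("commonMarkers", function(object) standardGeneric("commonMarkers"))

#' @rdname cmp-accessors
setMethod("cmpValue", "CMPResult", function(object) object@cmp)
#' @rdname cmp-accessors
setMethod("commonMarkers", "CMPResult", function(object) object@commonMarkers)

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph '", object@pathwayId, "': ",
      length(object@unitIds), " units (",
      pathwaySize(object), " genes), ",
      nrow(object@edges), " edges, ",
      sum(object@unitSigns < 0), " inhibitory unit(s)\n", sep = "")
})

setMethod("show", "PathwayDatabase", function(object) {
  sizes <- vapply(object@pathways, pathwaySize, integer(1))
  cat("PathwayDatabase '", object@dbName, "' v", object@dbVersion, ": ",
      length(object@pathways), " pathways, gene counts ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "0",
      "\n", sep = "")
})

setMethod("show", "GeneModuleSet", function(object) {
  cat("GeneModuleSet: ", length(object@moduleIds), " disjoint modules, ",
      length(unlist(object@moduleGenes, use.names = FALSE)),
      " genes assigned\n", sep = "")
})

setMethod("show", "PandaScores", function(object) {
  cat("PandaScores: ", nrow(object), " pathways x ", ncol(object),
      " samples (", length(unique(scoreDatasets(object))), " dataset(s)), ",
      if (isNormalized(object)) "Z-normalized" else "raw", " scores\n",
      sep = "")
})

setMethod("show", "CMPResult", function(object) {
  cat("CMP index: ", format(object@cmp, digits = 6), " (",
      length(object@commonMarkers), " common marker(s), symmetric AUC > ",
      object@aucThreshold, " in every dataset)\n", sep = "")
  if (length(object@commonMarkers))
    cat("  markers:", paste(object@commonMarkers, collapse = ", "), "\n")
})
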