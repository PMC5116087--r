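#' @include AllClasses.R
NULL

#' Rank-based ROC AUC of a pathway score against a binary phenotype
#'
#' Mann-Whitney formulation: the probability that a random positive-class
#' sample scores higher than a random negative-class one, with half
#' credit for ties. An AUC of 1 means perfect separation, 0.5 is chance
#' level (the random-classifier reference).
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels logical (or coercible) vector, TRUE for the positive
#'   class (e.g. responders); both classes must be present.
#' @return AUC in [0, 1].
#' @examples
#' pathwayAUC(c(0.9, 0.3, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
pathwayAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both phenotype classes must be present to compute an AUC")
  r <- rank(scores)          # midranks give the 0.5 tie credit
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pathway marker table across datasets
#'
#' Computes the per-dataset AUC of every pathway's activation score
#' against the responder phenotype, ranks pathways by their mean AUC over
#' datasets, and reports the top markers. Because activated and
#' repressed pathways are equally valid markers, the symmetric AUC
#' \code{max(AUC, 1 - AUC)} is used for ranking and for the marker rule;
#' the raw (responder-oriented) AUC is also kept.
#'
#' @param scoresList a [PandaScores-class] or list of them (one per
#'   dataset); each must carry a \code{phenotype} column in its
#'   \code{colData}, or be covered by \code{phenotype}.
#' @param phenotype optional named character vector (sample ->
#'   \code{"responder"}/\code{"non_responder"}) overriding \code{colData}.
#' @param db optional [PathwayDatabase-class] supplying pathway gene
#'   counts (needed later by [cmpIndex()]).
#' @param top how many top-ranked pathways to flag (default 30).
#' @return An object of class \code{"AUCTable"}: list with \code{auc} and
#'   \code{aucSym} (pathway x dataset matrices), \code{nGenes} (named
#'   vector or NA), and \code{ranking} (data.frame with
#'   \code{pathway_id}, \code{mean_auc}, \code{rank}, \code{top}).
#'   Mean-AUC ties are broken by larger pathway, then lexicographic id,
#'   so the ranking is deterministic.
#' @export
markerTable <- function(scoresList, phenotype = NULL, db = NULL,
                        top = 30L) {
  if (is(scoresList, "PandaScores")) scoresList <- list(scoresList)
  mats <- lapply(scoresList, scoreMatrix)
  pids <- rownames(mats[[1L]])
  stopifnot(all(vapply(mats, function(m)
    identical(rownames(m), pids), logical(1))))
  dsids <- vapply(seq_along(scoresList), function(i) {
    d <- unique(scoreDatasets(scoresList[[i]]))
    if (length(d) == 1L) d else paste0("dataset", i)
  }, character(1))
  if (anyDuplicated(dsids)) dsids <- make.unique(dsids)
  auc <- matrix(NA_real_, length(pids), length(mats),
                dimnames = list(pids, dsids))
  for (j in seq_along(mats)) {
    ph <- phenotype
    if (is.null(ph)) {
      cd <- SummarizedExperiment::colData(scoresList[[j]])
      if (!"phenotype" %in% names(cd))
        stop("no phenotype labels for dataset '", dsids[j], "'")
      ph <- stats::setNames(cd$phenotype, colnames(mats[[j]]))
    }
    lab <- ph[colnames(mats[[j]])] == "responder"
    keep <- !is.na(lab)
    for (i in seq_along(pids))
      auc[i, j] <- pathwayAUC(mats[[j]][i, keep], lab[keep])
  }
  aucSym <- pmax(auc, 1 - auc)
  ng <- if (is.null(db)) stats::setNames(rep(NA_integer_, length(pids)),
                                         pids)
        else vapply(pathways(db)[pids], pathwaySize, integer(1))
  mean_auc <- rowMeans(aucSym)
  ord <- order(-mean_auc, -ifelse(is.na(ng), 0L, ng), pids)
  ranking <- data.frame(pathway_id = pids[ord],
                        mean_auc = mean_auc[ord],
                        n_genes = as.integer(ng[ord]),
                        rank = seq_along(ord),
                        top = seq_along(ord) <= top,
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(auc = auc, aucSym = aucSym, nGenes = ng,
                 ranking = ranking), class = "AUCTable")
}

#' @export
print.AUCTable <- function(x, ...) {
  cat("AUCTable:", nrow(x$auc), "pathways x", ncol(x$auc), "datasets\n")
  print(utils::head(x$ranking, sum(x$ranking$top)))
  invisible(x)
}

#' Cross-dataset marker robustness (CMP index)
#'
#' A pathway is a common marker when its symmetric AUC exceeds
#' \code{threshold} in every dataset. Each common marker contributes
#' \code{log(N_i) * mean_j(AUC_ij - aucRandom)}; the log pathway-size
#' term up-weights large pathways, which are less likely to reach a high
#' AUC by chance. The index is 0 exactly when the per-dataset marker
#' lists have an empty intersection, and grows with both the number of
#' common markers and the margin by which they beat a random classifier.
#'
#' @param aucTable an \code{"AUCTable"} from [markerTable()], or a
#'   pathway x dataset AUC matrix.
#' @param nGenes named vector of pathway gene counts (taken from the
#'   AUCTable when available).
#' @param threshold marker threshold on the symmetric AUC (default 0.75,
#'   strict inequality, required in all datasets).
#' @param aucRandom AUC of a random classifier (0.5).
#' @return A [CMPResult-class].
#' @export
cmpIndex <- function(aucTable, nGenes = NULL, threshold = 0.75,
                     aucRandom = 0.5) {
  if (inherits(aucTable, "AUCTable")) {
    m <- aucTable$aucSym
    if (is.null(nGenes)) nGenes <- aucTable$nGenes
  } else {
    m <- pmax(as.matrix(aucTable), 1 - as.matrix(aucTable))
  }
  if (ncol(m) < 2L)
    stop("the CMP index needs at least 2 datasets")
  if (is.null(nGenes) || anyNA(nGenes[rownames(m)]))
    stop("pathway gene counts are required (pass 'db' to markerTable()",
         " or supply 'nGenes')")
  common <- rownames(m)[apply(m > threshold, 1L, all)]
  if (!length(common)) {
    return(new("CMPResult", cmp = 0, commonMarkers = character(),
               aucThreshold = threshold, aucRandom = aucRandom,
               contributions = data.frame(pathway_id = character(),
                                          n_genes = integer(),
                                          mean_auc_excess = numeric(),
                                          term = numeric())))
  }
  excess <- rowMeans(m[common, , drop = FALSE] - aucRandom)
  terms <- log(as.numeric(nGenes[common])) * excess
  new("CMPResult", cmp = sum(terms), commonMarkers = common,
      aucThreshold = threshold, aucRandom = aucRandom,
      contributions = data.frame(pathway_id = common,
                                 n_genes = as.integer(nGenes[common]),
                                 mean_auc_excess = unname(excess),
                                 term = unname(terms),
                                 stringsAsFactors = FALSE))
}
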