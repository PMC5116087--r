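#' @include AllClasses.R
NULL

.log_stage <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[%s] done in %.2fs", stage,
                    as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full activation-scoring pipeline on files
#'
#' Orchestrates the four pipeline stages for one dataset: (1) per-gene
#' statistical weights from the case/normal t-tests, (2) coexpression
#' module construction, (3) topological weights on the module-collapsed
#' pathway graphs, (4) signed activation scores plus the weighted Fisher
#' significance table. Inputs and outputs are files; all options can be
#' supplied via a YAML config (see [readRunConfig()]) with explicit
#' arguments taking precedence. A JSON metadata sidecar
#' (\code{<out_scores>.meta.json}) records every option so a run can be
#' reproduced from its outputs.
#'
#' @param cases,normals expression file paths (TSV or GCT 1.2).
#' @param pathways pathway database path (topology JSON or GMT).
#' @param coexpression optional coexpression TSV for module building.
#' @param modules optional precomputed module TSV (overrides
#'   \code{coexpression}).
#' @param tf_targets optional GMT of TF target sets.
#' @param out_scores,out_significance,out_modules output paths (NULL
#'   skips the file).
#' @param config optional YAML config path.
#' @param pmin,pmax,size_normalize,module_agg,use_topology scoring
#'   options, see [ipandaScores()].
#' @param scale declared expression scale (\code{"auto"}/\code{"log2"}/
#'   \code{"linear"}).
#' @param dataset_id dataset label.
#' @param hier_cut,dbscan_eps,dbscan_min_pts,min_corr,min_overlap,
#'   overlap_metric module-building options, see [buildModules()].
#' @param verbose log per-stage timing to stderr.
#' @return Invisibly, a list with the \code{scores}
#'   ([PandaScores-class]), \code{significance} data.frame and
#'   \code{modules} ([GeneModuleSet-class]).
#' @export
runPipeline <- function(cases, normals, pathways, coexpression = NULL,
                        modules = NULL, tf_targets = NULL,
                        out_scores = NULL, out_significance = NULL,
                        out_modules = NULL, config = NULL, pmin = 1e-7,
                        pmax = 1e-1, size_normalize = TRUE,
                        module_agg = "mean", use_topology = TRUE,
                        scale = "auto", dataset_id = "dataset1",
                        hier_cut = 1.0, dbscan_eps = 1.0,
                        dbscan_min_pts = 3L, min_corr = 0.3,
                        min_overlap = 0.7, overlap_metric = "jaccard",
                        verbose = FALSE) {
  if (!is.null(config)) {
    cfg <- readRunConfig(config)
    supplied <- names(match.call())[-1L]
    for (k in setdiff(names(cfg), supplied))
      assign(k, cfg[[k]])
  }
  t0 <- as.numeric(proc.time()["elapsed"])
  ca <- readExpression(cases, scale = scale, datasetId = dataset_id)
  no <- readExpression(normals, scale = scale, datasetId = dataset_id)
  db <- readPathwayDatabase(pathways)
  .log_stage(verbose, "read inputs", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  ms <- NULL
  if (!is.null(modules)) {
    ms <- readModules(modules)
  } else if (!is.null(coexpression)) {
    tf <- if (!is.null(tf_targets)) readGMT(tf_targets) else NULL
    ms <- buildModules(readCoexpression(coexpression), tfTargets = tf,
                       restrictTo = pathwayGenes(db),
                       cutHeight = hier_cut, eps = dbscan_eps,
                       minPts = dbscan_min_pts, minCorr = min_corr,
                       minOverlap = min_overlap, metric = overlap_metric)
  }
  .log_stage(verbose, "modules", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  sc <- ipandaScores(ca, no, db, modules = ms, pMin = pmin, pMax = pmax,
                     sizeNormalize = isTRUE(size_normalize),
                     moduleAgg = module_agg,
                     useTopology = isTRUE(use_topology))
  .log_stage(verbose, "scores", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  sig <- pathwaySignificance(ca, no, db, modules = ms, pMin = pmin,
                             pMax = pmax,
                             useTopology = isTRUE(use_topology))
  .log_stage(verbose, "significance", t0)

  if (!is.null(out_scores)) {
    writeScores(sc, out_scores)
    meta <- list(cases = cases, normals = normals, pathways = pathways,
                 coexpression = coexpression, modules = modules,
                 tf_targets = tf_targets, pmin = pmin, pmax = pmax,
                 size_normalize = isTRUE(size_normalize),
                 module_agg = module_agg,
                 use_topology = isTRUE(use_topology), scale = scale,
                 dataset_id = dataset_id, hier_cut = hier_cut,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_pts = dbscan_min_pts, min_corr = min_corr,
                 min_overlap = min_overlap,
                 overlap_metric = overlap_metric,
                 package_version = as.character(utils::packageVersion("ipanda")))
    jsonlite::write_json(meta, paste0(out_scores, ".meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  if (!is.null(out_significance))
    utils::write.table(sig, out_significance, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(out_modules) && !is.null(ms))
    writeModules(ms, out_modules)
  invisible(list(scores = sc, significance = sig, modules = ms))
}
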