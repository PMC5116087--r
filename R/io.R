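#' @include AllClasses.R
NULL

#' Build an expression dataset object
#'
#' Wraps a genes x samples intensity matrix in a
#' \code{SummarizedExperiment}, recording the intensity scale
#' (\code{"linear"} or \code{"log2"}) and a dataset label in its metadata.
#' Gene and sample identifiers must be unique; values must be finite where
#' present (missing entries are explicit \code{NA}s), and linear-scale
#' values must be non-negative.
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param datasetId dataset label (weights are always computed per dataset).
#' @param scale \code{"log2"} or \code{"linear"}.
#' @param group optional per-sample group label (\code{"case"}/\code{"normal"}).
#' @param phenotype optional per-sample phenotype
#'   (\code{"responder"}/\code{"non_responder"}).
#' @return A \code{SummarizedExperiment} with an \code{"exprs"} assay.
#' @export
ExpressionData <- function(values, datasetId = "dataset1",
                           scale = c("log2", "linear"),
                           group = NULL, phenotype = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (ncol(values) == 0L)
    stop("empty input: no samples")
  if (any(!is.finite(values) & !is.na(values)))
    stop("expression values must be finite or NA")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("linear-scale intensities must be non-negative")
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(group)) cd$group <- rep_len(as.character(group), ncol(values))
  if (!is.null(phenotype))
    cd$phenotype <- rep_len(as.character(phenotype), ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  metadata(se)$scale <- scale
  metadata(se)$dataset_id <- as.character(datasetId)
  se
}

#' @rdname ExpressionData
#' @param x a \code{SummarizedExperiment} built by [ExpressionData()] (a
#'   plain numeric matrix is accepted and treated as log2 scale).
#' @export
exprValues <- function(x) {
  if (is.matrix(x)) return(x)
  SummarizedExperiment::assay(x, "exprs")
}

#' @rdname ExpressionData
#' @export
exprScale <- function(x) {
  if (is.matrix(x)) return("log2")
  sc <- metadata(x)$scale
  if (is.null(sc)) "log2" else sc
}

#' @rdname ExpressionData
#' @export
exprDataset <- function(x) {
  if (is.matrix(x)) return("dataset1")
  ds <- metadata(x)$dataset_id
  if (is.null(ds)) "dataset1" else ds
}

#' Convert an expression dataset to log2 scale
#'
#' Linear-scale data containing zeros receive a pseudo-count of half the
#' smallest positive value in the matrix before taking logs; strictly
#' negative linear intensities are an error.
#'
#' @param x expression dataset ([ExpressionData()] result or matrix).
#' @return A numeric genes x samples matrix on log2 scale.
#' @export
asLog2 <- function(x) {
  v <- exprValues(x)
  if (exprScale(x) == "log2") return(v)
  if (any(v < 0, na.rm = TRUE))
    stop("negative linear intensities cannot be log-transformed")
  if (any(v == 0, na.rm = TRUE)) {
    eps <- min(v[v > 0], na.rm = TRUE) / 2
    if (!is.finite(eps)) eps <- 0.5
    v <- v + eps
  }
  log2(v)
}

.collapse_duplicates <- function(values, genes) {
  if (!anyDuplicated(genes)) {
    rownames(values) <- genes
    return(list(values = values, n_collapsed = 0L))
  }
  means <- rowMeans(values, na.rm = TRUE)
  ord <- order(genes, -means)
  keep <- ord[!duplicated(genes[ord])]
  n_dropped <- nrow(values) - length(keep)
  keep <- sort(keep)
  values <- values[keep, , drop = FALSE]
  rownames(values) <- genes[keep]
  list(values = values, n_collapsed = n_dropped)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect is tab-separated UTF-8 with a first column headed
#' \code{gene} and one column per sample. GCT files must declare version
#' \code{#1.2}. Duplicate gene rows are collapsed to the row with the
#' highest mean intensity; the number of dropped duplicates is reported via
#' \code{message()}.
#'
#' @param path file path.
#' @param scale declared intensity scale; \code{"auto"} treats matrices
#'   whose maximum exceeds 50 as linear, otherwise log2.
#' @param datasetId dataset label attached to the result.
#' @return A \code{SummarizedExperiment}; see [ExpressionData()].
#' @export
readExpression <- function(path, scale = c("auto", "log2", "linear"),
                           datasetId = "dataset1") {
  scale <- match.arg(scale)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.")) {
    if (!identical(trimws(first), "#1.2"))
      stop("unsupported GCT version (only 1.2): ", first)
    dims <- strsplit(readLines(path, n = 2L)[2L], "\t", fixed = TRUE)[[1L]]
    nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) != nr || ncol(tab) - 2L != nc)
      stop("GCT declared dimensions ", nr, "x", nc,
           " do not match file content")
    genes <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (tolower(names(tab)[1L]) != "gene")
      stop("malformed expression TSV: first column header must be 'gene'")
    if (ncol(tab) < 2L)
      stop("empty input: no sample columns")
    genes <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -1L, drop = FALSE])
  }
  storage.mode(values) <- "double"
  cl <- .collapse_duplicates(values, genes)
  if (cl$n_collapsed > 0L)
    message("collapsed ", cl$n_collapsed,
            " duplicate gene row(s) by maximum mean intensity")
  if (scale == "auto")
    scale <- if (max(cl$values, na.rm = TRUE) > 50) "linear" else "log2"
  ExpressionData(cl$values, datasetId = datasetId, scale = scale)
}

#' Write an expression dataset to the TSV dialect
#'
#' @param x expression dataset.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
  .write_gene_tsv(exprValues(x), path, key = "gene")
}

.write_gene_tsv <- function(m, path, key) {
  df <- data.frame(rownames(m),
                   apply(m, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(key, colnames(m))
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write to '", path, "'")
  invisible(path)
}

#' Read / write pathway databases
#'
#' \code{readPathwayDatabase} accepts either the pathway-topology JSON
#' dialect (\code{\{"name", "version", "pathways": [\{"id", "nodes":
#' [\{"id", "genes", "sign"\}], "edges": [\{"src", "dst", "type"\}]\}]\}})
#' or GMT. GMT is a topology-free fallback: every gene becomes an isolated
#' node with sign +1 (such nodes are each a complete walk of their own, so
#' all topological weights come out 1).
#'
#' @param path file path (\code{.json} or \code{.gmt}; content sniffed when
#'   the extension is ambiguous).
#' @return A [PathwayDatabase-class].
#' @export
readPathwayDatabase <- function(path) {
  first <- readLines(path, n = 1L)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE) ||
    startsWith(trimws(first), "{")
  if (!is_json) return(.read_gmt_db(path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$pathways))
    stop("pathway JSON lacks a 'pathways' array")
  pws <- lapply(obj$pathways, function(p) {
    ids <- vapply(p$nodes, function(n) as.character(n$id), character(1))
    signs <- vapply(p$nodes, function(n) as.numeric(n$sign), numeric(1))
    if (!all(signs %in% c(-1, 1)))
      stop("schema error in pathway '", p$id,
           "': node sign must be +1 or -1")
    genes <- lapply(p$nodes, function(n) unlist(n$genes, use.names = FALSE))
    names(genes) <- ids
    edges <- if (length(p$edges)) {
      src <- vapply(p$edges, function(e) as.character(e$src), character(1))
      dst <- vapply(p$edges, function(e) as.character(e$dst), character(1))
      typ <- vapply(p$edges, function(e)
        if (is.null(e$type)) "activation" else as.character(e$type),
        character(1))
      miss <- setdiff(unique(c(src, dst)), ids)
      if (length(miss))
        stop("schema error in pathway '", p$id,
             "': edge references undeclared node '",
             paste(miss, collapse = "', '"), "'")
      data.frame(src = src, dst = dst, type = typ, stringsAsFactors = FALSE)
    } else NULL
    PathwayGraph(p$id, genes, signs = as.integer(signs), edges = edges)
  })
  PathwayDatabase(pws,
                  name = if (is.null(obj$name)) "pathwaydb" else obj$name,
                  version = if (is.null(obj$version)) "0" else obj$version)
}

.read_gmt_db <- function(path) {
  sets <- readGMT(path)
  pws <- lapply(names(sets), function(id)
    PathwayGraph(id, sets[[id]], signs = 1L))
  PathwayDatabase(pws, name = basename(path), version = "gmt")
}

#' Read a GMT file into a named list of gene sets
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in attribute
#'   \code{"description"}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("malformed GMT: line(s) with fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname readPathwayDatabase
#' @param db a [PathwayDatabase-class].
#' @export
writePathwayDatabase <- function(db, path) {
  obj <- list(
    name = db@dbName, version = db@dbVersion,
    pathways = lapply(db@pathways, function(p) {
      list(
        id = pathwayId(p),
        nodes = unname(Map(function(id, g, s)
          list(id = id, genes = as.list(g), sign = s),
          p@unitIds, p@unitGenes, p@unitSigns)),
        edges = if (nrow(p@edges)) unname(lapply(seq_len(nrow(p@edges)),
          function(i) list(src = p@edges$src[i], dst = p@edges$dst[i],
                           type = p@edges$type[i]))) else list())
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write pathway activation score matrices
#'
#' Scores are stored as TSV with pathways as rows (first column header
#' \code{pathway}) and samples as columns, at full double precision, so a
#' write/read round trip preserves values to better than 1e-12.
#'
#' @param scores a [PandaScores-class].
#' @param path file path.
#' @return \code{writeScores} invisibly returns \code{path};
#'   \code{readScores} returns a [PandaScores-class].
#' @export
writeScores <- function(scores, path) {
  m <- scoreMatrix(scores)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("refusing to write an empty score matrix")
  .write_gene_tsv(m, path, key = "pathway")
}

#' @rdname writeScores
#' @param datasetId per-sample dataset labels for the reread matrix.
#' @param normalized logical flag recorded on the reread object.
#' @export
readScores <- function(path, datasetId = "dataset1", normalized = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (tolower(names(tab)[1L]) != "pathway")
    stop("malformed score TSV: first column header must be 'pathway'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  PandaScores(m, datasetId = datasetId, normalized = normalized)
}

#' Read / write gene-gene coexpression matrices
#'
#' Square TSV with gene identifiers on both axes. On read the matrix is
#' validated: values in [-1, 1], symmetric within 1e-12, unit diagonal.
#'
#' @param path file path.
#' @return \code{readCoexpression}: a validated symmetric correlation
#'   matrix.
#' @export
readCoexpression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  validateCoexpression(m)
  m
}

#' @rdname readCoexpression
#' @param corr symmetric correlation matrix with gene dimnames.
#' @export
writeCoexpression <- function(corr, path) {
  validateCoexpression(corr)
  .write_gene_tsv(corr, path, key = "gene")
}

#' @rdname readCoexpression
#' @export
validateCoexpression <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("coexpression matrix must be square")
  if (is.null(rownames(corr)) ||
      !identical(rownames(corr), colnames(corr)))
    stop("coexpression matrix needs matching gene dimnames on both axes")
  if (any(corr < -1 - 1e-12 | corr > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  if (max(abs(corr - t(corr))) > 1e-12)
    stop("coexpression matrix must be symmetric (within 1e-12)")
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("coexpression matrix must have a unit diagonal")
  invisible(corr)
}

#' Write a module table
#'
#' TSV with one row per (module, gene): \code{module_id}, \code{gene},
#' \code{mean_internal_corr}, \code{source}.
#'
#' @param modules a [GeneModuleSet-class].
#' @param path output path.
#' @export
writeModules <- function(modules, path) {
  sizes <- vapply(modules@moduleGenes, length, integer(1))
  df <- data.frame(
    module_id = rep(modules@moduleIds, sizes),
    gene = unlist(modules@moduleGenes, use.names = FALSE),
    mean_internal_corr = rep(modules@meanInternalCorr, sizes),
    source = rep(modules@moduleSource, sizes),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModules
#' @export
readModules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ids <- unique(df$module_id)
  genes <- lapply(ids, function(i) df$gene[df$module_id == i])
  names(genes) <- ids
  GeneModuleSet(genes,
    meanInternalCorr = df$mean_internal_corr[match(ids, df$module_id)],
    source = df$source[match(ids, df$module_id)])
}

#' Load a YAML run configuration
#'
#' Keys mirror the arguments of [runPipeline()]; unknown keys are an error
#' so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("cases", "normals", "pathways", "coexpression", "modules",
             "tf_targets", "out_scores", "out_significance", "out_modules",
             "pmin", "pmax", "size_normalize", "module_agg", "use_topology",
             "scale", "dataset_id", "seed", "hier_cut", "dbscan_eps",
             "dbscan_min_pts", "min_corr", "min_overlap", "overlap_metric")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
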