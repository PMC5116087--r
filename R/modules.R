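#' @include AllClasses.R
NULL

#' Correlation-to-distance transform for coexpression clustering
#'
#' Maps a correlation matrix to the Euclidean distance between
#' standardized expression vectors, \code{d = sqrt(2 * (1 - corr))}:
#' perfectly coexpressed genes are at distance 0, uncorrelated genes at
#' \code{sqrt(2)}, perfectly anti-correlated genes at 2.
#'
#' @param corr symmetric correlation matrix (values in [-1, 1], unit
#'   diagonal, gene dimnames).
#' @return Symmetric distance matrix with zero diagonal, range [0, 2].
#' @export
coexpressionDistance <- function(corr) {
  validateCoexpression(corr)
  d <- sqrt(pmax(2 * (1 - corr), 0))
  diag(d) <- 0
  d
}

# DBSCAN on a precomputed distance matrix. minPts counts the point itself;
# border points join the cluster of the first core point that reaches them.
.dbscan_dist <- function(d, eps, minPts) {
  n <- nrow(d)
  if (n < 2L) return(list())
  labels <- rep(0L, n)      # 0 = unvisited/noise
  cluster <- 0L
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= minPts
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    seeds <- setdiff(neighbors[[i]], i)
    while (length(seeds)) {
      j <- seeds[1L]; seeds <- seeds[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (core[j])
          seeds <- union(seeds, setdiff(neighbors[[j]],
                                        which(labels != 0L)))
      }
    }
  }
  ids <- rownames(d)
  out <- lapply(seq_len(cluster), function(k) ids[labels == k])
  out[vapply(out, length, integer(1)) >= 2L]
}

#' Detect candidate coexpression clusters
#'
#' Two complementary detectors are supported and are typically pooled:
#' average-linkage hierarchical clustering with a fixed-height tree cut,
#' and density-based DBSCAN on the same distance matrix.
#'
#' @param dist square distance matrix from [coexpressionDistance()].
#' @param method \code{"hierarchical_average"} or \code{"dbscan"}.
#' @param cutHeight tree-cut height for hierarchical clustering (distance
#'   units; the default 1.0 corresponds to correlation 0.5).
#' @param eps,minPts DBSCAN neighbourhood radius and minimum neighbourhood
#'   size (the point itself counts).
#' @return List of candidate gene sets (character vectors of size >= 2);
#'   empty when fewer than 2 genes are supplied.
#' @export
detectClusters <- function(dist,
                           method = c("hierarchical_average", "dbscan"),
                           cutHeight = 1.0, eps = 1.0, minPts = 3L) {
  method <- match.arg(method)
  if (nrow(dist) < 2L) return(list())
  if (method == "hierarchical_average") {
    hc <- stats::hclust(stats::as.dist(dist), method = "average")
    # average-linkage heights are monotone in exact arithmetic; guard
    # against floating-point jitter that trips cutree
    if (is.unsorted(hc$height)) hc$height <- sort(hc$height)
    grp <- stats::cutree(hc, h = cutHeight)
    out <- split(rownames(dist), grp)
    out <- unname(out[vapply(out, length, integer(1)) >= 2L])
    return(out)
  }
  .dbscan_dist(dist, eps = eps, minPts = minPts)
}

.mean_internal_corr <- function(genes, corr) {
  g <- intersect(genes, rownames(corr))
  if (length(g) < 2L) return(NA_real_)
  sub <- corr[g, g, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Keep clusters with sufficient internal coexpression
#'
#' A candidate cluster is retained only if the mean over all internal
#' unordered gene pairs of their correlation strictly exceeds
#' \code{minCorr}.
#'
#' @param clusters list of candidate gene sets (size >= 2).
#' @param corr correlation matrix covering the clustered genes.
#' @param minCorr retention threshold (default 0.3, strict inequality).
#' @return List of retained gene sets with their mean internal correlation
#'   in attribute \code{"mean_corr"}.
#' @export
filterClusters <- function(clusters, corr, minCorr = 0.3) {
  mc <- vapply(clusters, .mean_internal_corr, numeric(1), corr = corr)
  keep <- !is.na(mc) & mc > minCorr
  structure(clusters[keep], mean_corr = mc[keep])
}

.overlap_level <- function(a, b, metric) {
  i <- length(intersect(a, b))
  if (metric == "jaccard") i / length(union(a, b)) else i / min(length(a),
                                                                length(b))
}

#' Merge two collections of gene sets into disjoint modules
#'
#' Pools both collections and repeatedly unions any pair of sets whose
#' intersection level exceeds \code{minOverlap} until a fixpoint is
#' reached; products of a merge are tagged \code{source = "merged"}. The
#' intersection level is Jaccard (\code{|A∩B| / |A∪B|}) by default, or
#' the overlap coefficient \code{|A∩B| / min(|A|, |B|)}. Any gene left in
#' more than one surviving set is then assigned to the set with the
#' higher mean internal correlation (ties: larger set, then lexicographic
#' id), and sets shrunk below 2 genes are dropped, so the result is a
#' disjoint [GeneModuleSet-class].
#'
#' @param setA,setB lists of gene sets (size >= 2); \code{setB} may be
#'   empty.
#' @param minOverlap merge threshold on the intersection level (strict).
#' @param metric \code{"jaccard"} or \code{"min"}.
#' @param corr optional correlation matrix used to score mean internal
#'   correlation of merged sets (without it ties fall through to size).
#' @param sourceA,sourceB provenance tags for unmerged survivors.
#' @return A [GeneModuleSet-class].
#' @export
mergeClusterSets <- function(setA, setB = list(), minOverlap = 0.7,
                             metric = c("jaccard", "min"), corr = NULL,
                             sourceA = "coexpression",
                             sourceB = "tf_targets") {
  metric <- match.arg(metric)
  sets <- c(lapply(setA, unique), lapply(setB, unique))
  src <- c(rep(sourceA, length(setA)), rep(sourceB, length(setB)))
  # recursive pairwise merging to a fixpoint
  repeat {
    merged <- FALSE
    n <- length(sets)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          if (.overlap_level(sets[[i]], sets[[j]], metric) > minOverlap) {
            sets[[i]] <- union(sets[[i]], sets[[j]])
            src[i] <- "merged"
            sets[[j]] <- NULL
            src <- src[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  if (!length(sets)) return(GeneModuleSet())
  ids <- sprintf("M%03d", seq_along(sets))
  mc <- if (is.null(corr)) rep(NA_real_, length(sets))
        else vapply(sets, .mean_internal_corr, numeric(1), corr = corr)
  # disjointness: each gene goes to its best module
  allg <- unique(unlist(sets, use.names = FALSE))
  pick <- function(g) {
    cand <- which(vapply(sets, function(s) g %in% s, logical(1)))
    if (length(cand) == 1L) return(cand)
    key <- order(-ifelse(is.na(mc[cand]), -Inf, mc[cand]),
                 -vapply(sets[cand], length, integer(1)), ids[cand])
    cand[key[1L]]
  }
  owner <- vapply(allg, pick, integer(1))
  sets <- lapply(seq_along(sets), function(k) allg[owner == k])
  keep <- vapply(sets, length, integer(1)) >= 2L
  sets <- sets[keep]; src <- src[keep]; mc <- mc[keep]
  if (!length(sets)) return(GeneModuleSet())
  # recompute internal correlation on the final membership
  if (!is.null(corr))
    mc <- vapply(sets, .mean_internal_corr, numeric(1), corr = corr)
  names(sets) <- sprintf("M%03d", seq_along(sets))
  GeneModuleSet(sets, meanInternalCorr = mc, source = src)
}

#' Build gene modules from coexpression data and TF target lists
#'
#' Full module-construction pipeline: correlation-to-distance transform,
#' cluster detection by both average-linkage hierarchical clustering and
#' DBSCAN, internal-correlation filtering, and recursive merging with
#' optional transcription-factor target sets (which are first intersected
#' with \code{restrictTo}, typically the pathway database's gene
#' universe).
#'
#' @param corr gene-gene correlation matrix.
#' @param tfTargets optional named list of TF target gene sets (e.g. from
#'   [readGMT()]).
#' @param restrictTo optional gene universe for TF target sets.
#' @param cutHeight,eps,minPts clustering parameters, see
#'   [detectClusters()].
#' @param minCorr internal-correlation retention threshold (strict).
#' @param minOverlap,metric merge parameters, see [mergeClusterSets()].
#' @return A disjoint [GeneModuleSet-class].
#' @export
buildModules <- function(corr, tfTargets = NULL, restrictTo = NULL,
                         cutHeight = 1.0, eps = 1.0, minPts = 3L,
                         minCorr = 0.3, minOverlap = 0.7,
                         metric = c("jaccard", "min")) {
  metric <- match.arg(metric)
  d <- coexpressionDistance(corr)
  cands <- c(detectClusters(d, "hierarchical_average", cutHeight = cutHeight),
             detectClusters(d, "dbscan", eps = eps, minPts = minPts))
  coex <- filterClusters(cands, corr, minCorr = minCorr)
  tf <- list()
  if (!is.null(tfTargets)) {
    tf <- lapply(tfTargets, function(g)
      if (is.null(restrictTo)) unique(g) else intersect(g, restrictTo))
    tf <- tf[vapply(tf, length, integer(1)) >= 2L]
  }
  mergeClusterSets(coex, tf, minOverlap = minOverlap, metric = metric,
                   corr = corr)
}
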