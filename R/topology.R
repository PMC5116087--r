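#' @include AllClasses.R
NULL

# adjacency lists keyed by unit id; edges deduplicated by (src, dst)
.adjacency <- function(graph) {
  ids <- graph@unitIds
  e <- unique(graph@edges[, c("src", "dst")])
  out <- lapply(stats::setNames(ids, ids), function(i) e$dst[e$src == i])
  inn <- lapply(stats::setNames(ids, ids), function(i) e$src[e$dst == i])
  list(ids = ids, out = out, inn = inn)
}

# Kahn's algorithm: returns the topological order, or NULL if cyclic
.topo_order <- function(adj) {
  indeg <- vapply(adj$inn, length, integer(1))
  queue <- adj$ids[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in adj$out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) == length(adj$ids)) order else NULL
}

#' Collapse gene modules into single pathway units
#'
#' All nodes of a pathway graph whose member genes intersect the same gene
#' module are contracted into one unit that inherits the union of the
#' contracted nodes' in- and out-edges (self-edges produced by the
#' contraction are dropped) and the union of their member genes. The
#' contracted unit's activation sign is the majority sign of the
#' contracted nodes; on an exact tie the module is split into one
#' per-sign sub-unit within that pathway, since a tied module genuinely
#' contains two opposing units. A node whose genes intersect more than one
#' module is attached to the module sharing the most genes with it (ties
#' broken by lexicographic module id).
#'
#' @param graph a [PathwayGraph-class].
#' @param modules a [GeneModuleSet-class] (pairwise disjoint).
#' @return A [PathwayGraph-class] with module members contracted; graphs
#'   sharing no genes with any module are returned unchanged.
#' @examples
#' pg <- PathwayGraph("p", c("g1", "g2", "g3"),
#'                    edges = data.frame(src = c("g1", "g2"),
#'                                       dst = c("g2", "g3")))
#' ms <- GeneModuleSet(list(m1 = c("g1", "g3")))
#' collapseModules(pg, ms)
#' @export
collapseModules <- function(graph, modules) {
  if (length(modules) == 0L) return(graph)
  mgenes <- moduleGenes(modules)
  # unit -> module with the largest gene overlap
  unit2mod <- rep(NA_character_, length(graph@unitIds))
  for (k in seq_along(graph@unitIds)) {
    ov <- vapply(mgenes, function(g)
      length(intersect(g, graph@unitGenes[[k]])), integer(1))
    if (any(ov > 0L)) {
      best <- which(ov == max(ov))
      unit2mod[k] <- names(mgenes)[best[order(names(mgenes)[best])[1L]]]
    }
  }
  if (all(is.na(unit2mod))) return(graph)

  newid <- graph@unitIds            # map old unit id -> new unit id
  names(newid) <- graph@unitIds
  keep_ids <- character(); keep_genes <- list(); keep_signs <- integer()
  # untouched units pass through
  for (k in seq_along(graph@unitIds)) {
    if (is.na(unit2mod[k])) {
      keep_ids <- c(keep_ids, graph@unitIds[k])
      keep_genes <- c(keep_genes, graph@unitGenes[k])
      keep_signs <- c(keep_signs, graph@unitSigns[k])
    }
  }
  for (m in unique(stats::na.omit(unit2mod))) {
    idx <- which(unit2mod == m)
    signs <- graph@unitSigns[idx]
    npos <- sum(signs > 0L); nneg <- sum(signs < 0L)
    if (npos != nneg) {
      uid <- m
      if (uid %in% keep_ids) uid <- paste0("mod:", m)
      keep_ids <- c(keep_ids, uid)
      keep_genes <- c(keep_genes,
        list(unique(unlist(graph@unitGenes[idx], use.names = FALSE))))
      keep_signs <- c(keep_signs, if (npos > nneg) 1L else -1L)
      newid[graph@unitIds[idx]] <- uid
    } else {
      # exact sign tie: split into per-sign sub-units
      for (s in c(1L, -1L)) {
        sub <- idx[signs == s]
        uid <- paste0(m, if (s > 0L) "+" else "-")
        keep_ids <- c(keep_ids, uid)
        keep_genes <- c(keep_genes,
          list(unique(unlist(graph@unitGenes[sub], use.names = FALSE))))
        keep_signs <- c(keep_signs, s)
        newid[graph@unitIds[sub]] <- uid
      }
    }
  }
  e <- graph@edges
  if (nrow(e)) {
    e$src <- unname(newid[e$src])
    e$dst <- unname(newid[e$dst])
    e <- unique(e[e$src != e$dst, , drop = FALSE])
    rownames(e) <- NULL
  }
  names(keep_genes) <- keep_ids
  PathwayGraph(graph@pathwayId, keep_genes, signs = keep_signs, edges = e)
}

#' Count start-to-end walks through a pathway graph
#'
#' All simple walks (no node visited twice) from every zero-in-degree unit
#' to every zero-out-degree unit are counted; \code{counts} gives the
#' number of complete walks passing through each unit. An isolated unit is
#' both a start and an end and lies on exactly one walk (itself). On
#' acyclic graphs the counts are obtained by dynamic programming
#' (walks-into times walks-out-of each unit); graphs with cycles fall back
#' to an explicit depth-first enumeration with a visited set, honouring
#' the rule that loops are forbidden.
#'
#' @param graph a [PathwayGraph-class] (module-collapsed if desired).
#' @param maxWalks guard on the total number of complete walks; counting
#'   is exponential in the worst case, so exceeding the guard raises an
#'   error suggesting graph simplification.
#' @return A list with elements \code{pathwayId}, \code{counts} (named
#'   numeric, one entry per unit) and \code{nCompleteWalks}.
#' @examples
#' diamond <- PathwayGraph("d", c("A", "B", "C", "D"),
#'   edges = data.frame(src = c("A", "A", "B", "C"),
#'                      dst = c("B", "C", "D", "D")))
#' countWalks(diamond)$counts  # A:2 B:1 C:1 D:2
#' @export
countWalks <- function(graph, maxWalks = 1e6) {
  stopifnot(is(graph, "PathwayGraph"), maxWalks >= 1)
  adj <- .adjacency(graph)
  order <- .topo_order(adj)
  res <- if (is.null(order)) .count_walks_dfs(adj, maxWalks)
         else .count_walks_dp(adj, order, maxWalks)
  structure(list(pathwayId = graph@pathwayId, counts = res$counts,
                 nCompleteWalks = res$n), class = "WalkCounts")
}

.count_walks_dp <- function(adj, order, maxWalks) {
  ids <- adj$ids
  win <- stats::setNames(numeric(length(ids)), ids)
  wout <- win
  for (v in order) {
    preds <- adj$inn[[v]]
    win[v] <- if (length(preds)) sum(win[preds]) else 1
  }
  for (v in rev(order)) {
    succ <- adj$out[[v]]
    wout[v] <- if (length(succ)) sum(wout[succ]) else 1
  }
  n <- sum(wout[ids[vapply(adj$inn, length, integer(1)) == 0L]])
  if (n > maxWalks)
    stop("walk count ", n, " exceeds maxWalks = ", maxWalks,
         "; consider simplifying the pathway graph or collapsing modules")
  list(counts = win * wout, n = n)
}

.count_walks_dfs <- function(adj, maxWalks) {
  ids <- adj$ids
  counts <- stats::setNames(numeric(length(ids)), ids)
  starts <- ids[vapply(adj$inn, length, integer(1)) == 0L]
  env <- new.env(parent = emptyenv())
  env$counts <- counts; env$n <- 0
  visit <- function(v, path) {
    path <- c(path, v)
    succ <- adj$out[[v]]
    if (!length(succ)) {               # reached an end unit
      env$n <- env$n + 1
      if (env$n > maxWalks)
        stop("walk count exceeds maxWalks = ", maxWalks,
             "; consider simplifying the pathway graph or collapsing",
             " modules")
      env$counts[path] <- env$counts[path] + 1
      return(invisible())
    }
    for (w in succ)
      if (!w %in% path) visit(w, path)  # loops are forbidden
    invisible()
  }
  for (s in starts) visit(s, character(0))
  list(counts = env$counts, n = env$n)
}

#' Topological weights from walk counts
#'
#' Each unit's weight is its walk count divided by the maximum walk count
#' in the pathway, so weights lie in [0, 1] and the best-travelled unit
#' gets weight 1. When no complete start-to-end walk exists (all counts
#' zero, possible only in cyclic graphs) all weights are set to 1 and a
#' warning is emitted.
#'
#' @param counts result of [countWalks()].
#' @return Named numeric vector of weights in [0, 1], one per unit.
#' @export
topologicalWeights <- function(counts) {
  cc <- counts$counts
  mx <- max(cc)
  if (mx <= 0) {
    warning("pathway '", counts$pathwayId,
            "' has no complete start-to-end walk; topological weights",
            " set to 1")
    return(stats::setNames(rep(1, length(cc)), names(cc)))
  }
  cc / mx
}

#' Precompute topological weights for a whole database
#'
#' Collapses modules into units, counts walks and derives topological
#' weights for every pathway; the result can be cached to TSV since it
#' depends only on the pathway database and module set, not on the
#' expression data.
#'
#' @param db a [PathwayDatabase-class].
#' @param modules optional [GeneModuleSet-class]; NULL disables module
#'   collapse.
#' @param maxWalks per-pathway walk-count guard, see [countWalks()].
#' @return data.frame with columns \code{pathway_id}, \code{unit_id},
#'   \code{n_walks}, \code{w_T}.
#' @export
topologyTable <- function(db, modules = NULL, maxWalks = 1e6) {
  rows <- lapply(db@pathways, function(p) {
    if (!is.null(modules)) p <- collapseModules(p, modules)
    wc <- countWalks(p, maxWalks = maxWalks)
    wt <- topologicalWeights(wc)
    data.frame(pathway_id = pathwayId(p), unit_id = names(wt),
               n_walks = unname(wc$counts[names(wt)]), w_T = unname(wt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
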