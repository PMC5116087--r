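# Independent oracles and fixture builders used across the test files.

# Brute-force enumeration of all simple start->end paths in a directed
# graph given as an edge data.frame over node ids. Collects every path
# explicitly, then counts how many contain each node. Deliberately
# written in a different style from the package internals.
enumerate_walks <- function(nodes, edges) {
  succ <- lapply(stats::setNames(nodes, nodes),
                 function(v) edges$dst[edges$src == v])
  indeg <- vapply(nodes, function(v) sum(edges$dst == v), integer(1))
  outdeg <- vapply(nodes, function(v) sum(edges$src == v), integer(1))
  starts <- nodes[indeg == 0L]
  paths <- list()
  grow <- function(path) {
    v <- path[length(path)]
    nxt <- setdiff(succ[[v]], path)
    if (outdeg[v] == 0L) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in nxt) grow(c(path, w))
    invisible()
  }
  for (s in starts) grow(s)
  counts <- vapply(nodes, function(v)
    sum(vapply(paths, function(p) v %in% p, logical(1))), numeric(1))
  list(counts = counts, n = length(paths))
}

# random DAG on n nodes: edges respect a random node order
random_dag <- function(n, p = 0.25) {
  ids <- sprintf("n%02d", sample(n))
  src <- character(); dst <- character()
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      if (stats::runif(1) < p) {
        src <- c(src, ids[i]); dst <- c(dst, ids[j])
      }
  list(ids = sort(ids),
       edges = data.frame(src = src, dst = dst,
                          stringsAsFactors = FALSE))
}

graph_from <- function(ids, edges, pathwayId = "test", signs = 1L) {
  PathwayGraph(pathwayId, ids, signs = signs, edges = edges)
}

# block-structured correlation matrix: rho within listed blocks, 0 out
block_corr <- function(blocks, extra = 0L, rho = 0.8) {
  genes <- c(unlist(blocks, use.names = FALSE),
             if (extra > 0L) sprintf("noise%02d", seq_len(extra)))
  m <- diag(1, length(genes))
  dimnames(m) <- list(genes, genes)
  for (b in blocks) m[b, b] <- rho
  diag(m) <- 1
  m
}

# tiny expression pair with exact values and zero within-group variance,
# so every gene gets statistical weight 1 and log fold change
# case_value - normal_value (log2 scale)
exact_expr_pair <- function(case_vals, normal_vals, datasetId = "toy") {
  genes <- names(case_vals)
  ca <- matrix(rep(case_vals, 2L), ncol = 2L,
               dimnames = list(genes, c("c1", "c2")))
  no <- matrix(rep(normal_vals, 2L), ncol = 2L,
               dimnames = list(genes, c("n1", "n2")))
  list(cases = ExpressionData(ca, datasetId = datasetId, scale = "log2"),
       normals = ExpressionData(no, datasetId = datasetId,
                                scale = "log2"))
}

# exhaustive pair-counting AUC (Mann-Whitney oracle)
auc_by_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
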