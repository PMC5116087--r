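#' @include AllClasses.R
NULL

.row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

#' Per-gene group t-test between case and normal samples
#'
#' Two-sided Welch (unequal-variance) t-test for every gene shared by the
#' two groups, computed on log2 intensities (linear data are converted
#' first). Genes absent from either group, or carrying a missing value in
#' either group, are excluded and reported via \code{message()}. Genes
#' with zero variance in both groups get \code{p = zeroVarP} when the
#' group means differ (unmistakable signal, weight 1 under the default
#' thresholds) and \code{p = 1} when they are equal.
#'
#' @param cases,normals expression datasets ([ExpressionData()] results or
#'   plain log2 matrices) with >= 2 samples each.
#' @param zeroVarP p-value assigned to zero-variance genes with differing
#'   means (default 1e-7, the lower weighting threshold).
#' @return data.frame with columns \code{gene}, \code{t}, \code{p_value}.
#' @export
groupTTest <- function(cases, normals, zeroVarP = 1e-7) {
  x <- asLog2(cases); y <- asLog2(normals)
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("each group needs at least 2 samples for the t-test")
  shared <- intersect(rownames(x), rownames(y))
  dropped <- length(union(rownames(x), rownames(y))) - length(shared)
  x <- x[shared, , drop = FALSE]; y <- y[shared, , drop = FALSE]
  ok <- !(rowSums(is.na(x)) > 0L | rowSums(is.na(y)) > 0L)
  if (any(!ok) || dropped > 0L)
    message("t-test: excluded ", sum(!ok) + dropped,
            " gene(s) absent from a group or with missing values")
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .row_vars(x); v2 <- .row_vars(y)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- pmax(2 * stats::pt(-abs(tt), df), 1e-300)
  zero <- se2 == 0
  if (any(zero)) {
    diffm <- m1[zero] != m2[zero]
    p[zero] <- ifelse(diffm, zeroVarP, 1)
    tt[zero] <- ifelse(diffm, sign(m1[zero] - m2[zero]) * Inf, 0)
  }
  data.frame(gene = rownames(x), t = unname(tt), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Per-sample log2 fold changes against the normal reference
#'
#' For each case sample and gene, the log2 intensity minus the mean log2
#' intensity over the normal group (a geometric-mean reference on the
#' linear scale, matching the log-normal view of expression levels).
#' Genes with missing values in the normal group get an \code{NA}
#' reference and are skipped downstream.
#'
#' @param cases,normals expression datasets or log2 matrices sharing a
#'   gene universe.
#' @return Numeric matrix, shared genes x case samples, of log2 fold
#'   changes.
#' @export
logFoldChanges <- function(cases, normals) {
  x <- asLog2(cases); y <- asLog2(normals)
  shared <- intersect(rownames(x), rownames(y))
  x <- x[shared, , drop = FALSE]; y <- y[shared, , drop = FALSE]
  ref <- rowMeans(y)                    # NA if any normal value missing
  x - ref
}

#' Smooth cosine statistical weight of a differential-expression P value
#'
#' A smooth alternative to hard P-value thresholding: weight 1 at or below
#' \code{pMin}, 0 at or beyond \code{pMax}, and a half-cosine on the log10
#' scale in between, so pathway scores vary continuously with the
#' evidence instead of jumping as genes cross an arbitrary cutoff.
#'
#' @param p numeric vector of P values in (0, 1].
#' @param pMin,pMax lower and upper thresholds (defaults 1e-7 and 1e-1).
#' @return Numeric vector of weights in [0, 1].
#' @examples
#' statisticalWeight(c(1e-8, 1e-4, 0.5))  # 1, 0.5, 0
#' @export
statisticalWeight <- function(p, pMin = 1e-7, pMax = 1e-1) {
  if (!(pMin > 0 && pMin < pMax && pMax <= 1))
    stop("need 0 < pMin < pMax <= 1")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("P values must lie in (0, 1]")
  w <- 0.5 * (1 + cos(pi * (log(p) - log(pMin)) / (log(pMax) - log(pMin))))
  w[p <= pMin] <- 1
  w[p >= pMax] <- 0
  w
}

#' Per-dataset statistical weight table
#'
#' Convenience wrapper running [groupTTest()] and [statisticalWeight()]
#' for one dataset. Weight tables are always computed per dataset,
#' independently of any other dataset's content.
#'
#' @inheritParams groupTTest
#' @param pMin,pMax smooth-threshold P value bounds.
#' @return data.frame with columns \code{dataset_id}, \code{gene},
#'   \code{p_value}, \code{w_S}.
#' @export
statWeightTable <- function(cases, normals, pMin = 1e-7, pMax = 1e-1) {
  tt <- groupTTest(cases, normals, zeroVarP = pMin)
  data.frame(dataset_id = exprDataset(cases), gene = tt$gene,
             p_value = tt$p_value,
             w_S = statisticalWeight(tt$p_value, pMin, pMax),
             stringsAsFactors = FALSE)
}
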