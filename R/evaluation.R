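#' Build a 2x2 confusion matrix
#'
#' Cross-tabulates predicted against true binary labels, with the positive
#' class being the inflamed / T-cell-infiltrated call. Inputs may be
#' logical vectors or character/factor labels with \code{positive} naming
#' the positive level; when both vectors carry sample-id names they are
#' aligned by name and any mismatch is an error.
#'
#' @param pred,truth Predicted and true labels.
#' @param positive Positive-class value used when the labels are not
#'   logical.
#' @return Integer matrix with dimnames \code{pred} x \code{truth}, levels
#'   \code{c("positive", "negative")}; cells are tp, fn, fp, tn.
#' @examples
#' confusion2x2(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion2x2 <- function(pred, truth, positive = "inflamed") {
  toLogical <- function(v) {
    if (is.logical(v)) return(v)
    as.character(v) == positive
  }
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth)))
      stop("prediction and truth sample ids do not match")
    truth <- truth[names(pred)]
  } else if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' must have the same length")
  }
  p <- toLogical(pred)
  t <- toLogical(truth)
  if (anyNA(p) || anyNA(t)) stop("labels must not contain missing values")
  m <- matrix(c(sum(p & t), sum(!p & t), sum(p & !t), sum(!p & !t)),
              nrow = 2,
              dimnames = list(pred = c("positive", "negative"),
                              truth = c("positive", "negative")))
  storage.mode(m) <- "integer"
  m
}

#' Diagnostic classification metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp), negative predictive value tn/(tn+fn) and accuracy
#' (tp+tn)/n. A metric whose denominator is zero is returned as \code{NA}
#' and listed in the \code{undefined} element rather than silently set to
#' zero.
#'
#' @param cm 2x2 confusion matrix from [confusion2x2()], or \code{tp} given
#'   with \code{fn}, \code{fp}, \code{tn}.
#' @param tp,fn,fp,tn Cell counts, used when \code{cm} is missing.
#' @return List with elements \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, \code{accuracy}, \code{n} and
#'   \code{undefined} (character vector of metrics with a zero
#'   denominator).
#' @examples
#' classificationMetrics(tp = 21, fn = 4, fp = 6, tn = 46)
#' @export
classificationMetrics <- function(cm = NULL, tp = NULL, fn = NULL,
                                  fp = NULL, tn = NULL) {
  if (!is.null(cm)) {
    stopifnot(identical(dim(cm), c(2L, 2L)))
    tp <- cm[1, 1]; fn <- cm[2, 1]; fp <- cm[1, 2]; tn <- cm[2, 2]
  }
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion-matrix cells must be non-negative integers")
  n <- sum(cells)
  if (n == 0L) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp),
              npv = ratio(tn, tn + fn),
              accuracy = (tp + tn) / n,
              n = as.integer(n))
  out$undefined <- names(out)[vapply(out[1:5], is.na, logical(1))]
  out
}

#' Round a proportion to a whole percentage (half-up)
#'
#' Matches the conventional presentation of diagnostic metrics as whole
#' percentages, rounding halves upward (0.885 -> 89 would be banker's
#' rounding territory; here 88.5 -> 89).
#'
#' @param p Proportion in [0, 1] (vectorised).
#' @return Integer percentage(s).
#' @examples
#' wholePercent(c(21 / 27, 46 / 52, 0.84, 46 / 50))  # 78 88 84 92
#' @export
wholePercent <- function(p) {
  as.integer(floor(p * 100 + 0.5))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Tests association in a 2x2 contingency table, e.g. IHC classification
#' against IPASS immune designation. Two-sided p-values follow the
#' probability-mass convention: the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("'table' must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must contain non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return List with elements \code{r} and \code{p}.
#' @examples
#' pearsonR(1:4, c(2, 4, 5, 9))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-group comparison with a normality/variance decision flow
#'
#' Implements the common parametric-or-rank decision flow for comparing a
#' continuous marker between two groups: Shapiro-Wilk normality test on
#' each group and an F-test for equality of variances; if normality is
#' rejected in either group (at \code{alpha}) or the variances differ, the
#' Wilcoxon rank-sum test is used, otherwise a two-sample t-test with
#' pooled variance. The returned object records which test fired and the
#' gating p-values.
#'
#' @param a,b Numeric vectors, each of length >= 3 and not constant.
#' @param alpha Significance level for the gating tests, default 0.05.
#' @return List with elements \code{test} ("t" or "wilcoxon"),
#'   \code{statistic}, \code{p}, \code{shapiro_p} (length 2) and
#'   \code{var_p}.
#' @examples
#' set.seed(1)
#' twoGroupCompare(rnorm(20), rnorm(20, 1))
#' @export
twoGroupCompare <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate group: all values identical")
  sw <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
  vp <- stats::var.test(a, b)$p.value
  if (any(sw < alpha) || vp < alpha) {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "wilcoxon"
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       shapiro_p = sw, var_p = vp)
}

#' K-means clustering of immune genes against a per-sample score
#'
#' Standardises each gene (z-score of log2(TPM+1) across samples), runs
#' k-means on the gene profiles with a seeded initialisation and multiple
#' restarts, computes each cluster's mean Pearson correlation with the
#' per-sample scores, and reports the most score-correlated cluster — the
#' grouping of immune genes whose expression most tracks the infiltration
#' score.
#'
#' @param x \linkS4class{SummarizedExperiment} or genes x samples TPM
#'   matrix.
#' @param genes Genes to cluster (must be present in the matrix).
#' @param scores Named numeric per-sample scores (e.g. normalised IPASS).
#' @param k Number of clusters, 2 <= k <= length(genes).
#' @param seed Integer RNG seed.
#' @param nstart Number of k-means restarts, default 10.
#' @return List with \code{assignments} (named integer cluster per gene),
#'   \code{clusterCor} (mean per-cluster correlation with the scores),
#'   \code{bestCluster} (index of the max-correlation cluster) and
#'   \code{bestGenes} (its members).
#' @export
clusterGenesVsScore <- function(x, genes, scores, k, seed = 1,
                                nstart = 10) {
  mat <- .tpmMatrix(x)
  miss <- setdiff(genes, rownames(mat))
  if (length(miss))
    stop("genes missing from matrix: ", paste(miss, collapse = ", "))
  if (k < 2 || k > length(genes))
    stop("'k' must lie between 2 and the number of genes")
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), colnames(mat)))
      stop("score sample ids do not match the matrix")
    scores <- scores[colnames(mat)]
  } else if (length(scores) != ncol(mat)) {
    stop("one score per sample required")
  }
  lg <- log2(mat[genes, , drop = FALSE] + 1)
  z <- t(scale(t(lg)))
  if (anyNA(z))
    stop("cannot standardise: some gene(s) are constant across samples")
  set.seed(as.integer(seed))
  if (k == nrow(z)) {
    # singleton clusters: k-means is the identity partition
    cluster <- stats::setNames(seq_len(k), rownames(z))
  } else {
    cluster <- stats::kmeans(z, centers = k, nstart = nstart)$cluster
  }
  geneCor <- apply(lg, 1L, function(g) stats::cor(g, scores))
  clusterCor <- vapply(seq_len(k),
                       function(cl) mean(geneCor[cluster == cl]),
                       numeric(1))
  best <- which.max(clusterCor)
  list(assignments = cluster, clusterCor = clusterCor,
       bestCluster = best,
       bestGenes = names(cluster)[cluster == best])
}
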