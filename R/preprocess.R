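#' Log2 transformation
#'
#' Elementwise base-2 logarithm of an expression matrix; the usual first step
#' for microarray intensities before normalization.
#'
#' @param X numeric matrix with strictly positive entries.
#' @return the transformed matrix.
#' @examples
#' log2Transform(matrix(c(1, 2, 1024, 8), 2))
#' @export
log2Transform <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  bad <- which(!is.finite(X) | X <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(X))
    stop(sprintf(
      "nonpositive or non-finite entry at row %d ('%s'), column %d ('%s')",
      rc[1], rownames(X)[rc[1]] %||% rc[1],
      rc[2], colnames(X)[rc[2]] %||% rc[2]))
  }
  log2(X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score normalization
#'
#' Rescales every variable (column) to sample mean 0 and sample variance 1
#' (n - 1 denominator). The clustering model assumes its input in this form.
#'
#' @param X numeric matrix, observations in rows.
#' @return the normalized matrix.
#' @examples
#' zscoreNormalize(matrix(c(1, 2, 3, 10, 20, 30), 3))
#' @export
zscoreNormalize <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  if (any(!is.finite(X))) stop("non-finite values in 'X'")
  if (nrow(X) < 2L) stop("need at least two observations to normalize")
  v <- apply(X, 2, stats::var)
  zero <- which(v < .Machine$double.eps)
  if (length(zero))
    stop("zero-variance column(s), drop before normalizing: ",
         paste(colnames(X)[zero] %||% zero, collapse = ", "))
  scale(X, center = TRUE, scale = sqrt(v))[, , drop = FALSE]
}

#' Wilcoxon rank-sum feature filtering
#'
#' Retains the variables (columns) whose two-sided Wilcoxon rank-sum p-value
#' between the two observation groups falls below the significance level —
#' the feature-selection step used ahead of clustering when phenotype labels
#' are available. The exact null distribution is enumerated when both groups
#' have at most 15 observations and no ties; otherwise the tie-corrected
#' normal approximation is used.
#'
#' @param X numeric matrix, observations in rows.
#' @param groups vector with exactly two non-empty levels, one entry per row
#'   of \code{X}.
#' @param alphaLevel significance level; the protocol value is 0.001.
#' @return \code{X} restricted to the retained columns, with the p-values in
#'   attribute \code{"p.values"} (all columns, in input order).
#' @examples
#' X <- cbind(sig = c(rnorm(12), rnorm(12, 8)), noise = rnorm(24))
#' g <- rep(c("a", "b"), each = 12)
#' ncol(wilcoxonFilter(X, g, 0.001))
#' @export
wilcoxonFilter <- function(X, groups, alphaLevel = 0.001) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  groups <- as.factor(groups)
  if (length(groups) != nrow(X))
    stop("'groups' must have one entry per observation (row)")
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("need exactly two non-empty groups, got ", nlevels(groups))
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  stopifnot(alphaLevel > 0, alphaLevel < 1)
  p <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[g1, j]; y <- X[!g1, j]
    exact <- n1 <= 15 && n2 <= 15 && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                        exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  keep <- p < alphaLevel
  out <- X[, keep, drop = FALSE]
  attr(out, "p.values") <- stats::setNames(
    p, colnames(X) %||% seq_len(ncol(X)))
  out
}

#' Expression preprocessing pipeline
#'
#' Applies, in this fixed order: log2 transformation, Wilcoxon rank-sum
#' filtering (when group labels are supplied), and z-score normalization.
#' Filtering precedes normalization so retained columns end up exactly
#' normalized.
#'
#' @param X numeric matrix, observations in rows.
#' @param groups optional two-level vector over rows for the Wilcoxon filter.
#' @param log2 apply the log2 transform first.
#' @param alphaLevel significance level for the filter.
#' @return the preprocessed matrix.
#' @examples
#' X <- matrix(2^rnorm(60, 5), 10)
#' dim(preprocessExpression(X))
#' @export
preprocessExpression <- function(X, groups = NULL, log2 = TRUE,
                                 alphaLevel = 0.001) {
  if (log2) X <- log2Transform(X)
  if (!is.null(groups)) X <- wilcoxonFilter(X, groups, alphaLevel)
  if (ncol(X) == 0L) stop("no variables retained by the filter")
  zscoreNormalize(X)
}
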