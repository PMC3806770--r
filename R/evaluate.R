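.alignPartitions <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("partitions are over different observation sets")
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("partitions are over different observation sets")
  }
  list(x = as.factor(x), y = as.factor(y))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same
#' observations (Hubert-Arabie form): the pair-counting Rand index minus its
#' expectation under random partitions with the same margins, rescaled so
#' identical partitions score 1. Values near 0 indicate chance-level
#' agreement and slightly negative values are possible (they are not
#' clamped).
#'
#' @param x,y partitions: factors or vectors of cluster labels; when both are
#'   named they are aligned by name.
#' @return the index, a number <= 1.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' adjustedRandIndex(c(1, 2, 1, 2), c(1, 1, 2, 2))          # negative
#' @export
adjustedRandIndex <- function(x, y) {
  p <- .alignPartitions(x, y)
  tab <- table(p$x, p$y)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (abs(maxidx - expected) < .Machine$double.eps * max(1, maxidx))
    return(1)  # both partitions degenerate and identical
  (sumij - expected) / (maxidx - expected)
}

#' Biological homogeneity index
#'
#' Mean, over clusters with at least two annotated members, of the fraction
#' of annotated within-cluster pairs that share at least one functional
#' class. Items with an empty class set are treated as unannotated and
#' excluded from pair counts.
#'
#' @param partition named factor or vector of cluster labels.
#' @param annotations named list mapping observation ids to character vectors
#'   of functional-class identifiers (possibly empty), e.g. from
#'   \code{\link{readAnnotations}}.
#' @return a value in [0, 1].
#' @examples
#' p <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)
#' ann <- list(g1 = "GO:1", g2 = "GO:1", g3 = "GO:2", g4 = "GO:3")
#' bhi(p, ann)
#' @export
bhi <- function(partition, annotations) {
  if (is.null(names(partition)))
    stop("'partition' must be named by observation id")
  if (!is.list(annotations) || is.null(names(annotations)))
    stop("'annotations' must be a named list of class vectors")
  partition <- as.factor(partition)
  ann <- annotations[lengths(annotations) > 0]
  scores <- numeric(0)
  for (cl in levels(partition)) {
    ids <- intersect(names(partition)[partition == cl], names(ann))
    if (length(ids) < 2L) next  # nothing to average over
    pairs <- utils::combn(ids, 2)
    share <- apply(pairs, 2, function(p)
      length(intersect(ann[[p[1]]], ann[[p[2]]])) > 0)
    scores <- c(scores, mean(share))
  }
  if (!length(scores))
    stop("no cluster has two or more annotated members; BHI is undefined")
  mean(scores)
}

#' Number of clusters in a partition
#'
#' @param partition factor or vector of cluster labels.
#' @return the count of distinct labels.
#' @examples
#' clusterCount(c(1, 1, 2, 7))
#' @export
clusterCount <- function(partition) {
  length(unique(as.vector(partition)))
}
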