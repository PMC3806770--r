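#' Per-dimension sufficient statistics of a cluster
#'
#' All the data the conjugate normal-gamma marginal needs: the observation
#' count and, per dimension, the sample mean and the sum of squared
#' deviations from the mean. Statistics of merged clusters combine exactly
#' (pooled mean plus the between-cluster correction to the ssd), so the
#' agglomeration never revisits raw data.
#'
#' @param X numeric matrix (observations x dimensions) or vector (one
#'   dimension).
#' @return a list of class \code{ClusterStats} with elements \code{n},
#'   \code{mean}, \code{ssd}.
#' @examples
#' clusterStats(matrix(rnorm(20), 10, 2))
#' @export
clusterStats <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (!is.numeric(X)) stop("'X' must be numeric")
  if (any(!is.finite(X))) stop("non-finite values in 'X'")
  n <- nrow(X)
  if (n == 0L) {
    s <- list(n = 0, mean = numeric(ncol(X)), ssd = numeric(ncol(X)))
  } else {
    m <- colMeans(X)
    s <- list(n = n, mean = m,
              ssd = colSums((X - rep(m, each = n))^2))
  }
  class(s) <- "ClusterStats"
  s
}

#' Merge two sets of cluster sufficient statistics
#'
#' @param x,y \code{ClusterStats} over the same dimensions.
#' @return the \code{ClusterStats} of the pooled cluster, identical (to
#'   numerical tolerance) to recomputation from the raw data.
#' @examples
#' a <- clusterStats(matrix(1:4, 2))
#' b <- clusterStats(matrix(5:8, 2))
#' mergeClusterStats(a, b)
#' @export
mergeClusterStats <- function(x, y) {
  stopifnot(length(x$mean) == length(y$mean))
  if (x$n == 0) return(y)
  if (y$n == 0) return(x)
  n <- x$n + y$n
  m <- (x$n * x$mean + y$n * y$mean) / n
  delta <- x$mean - y$mean
  s <- list(n = n, mean = m,
            ssd = x$ssd + y$ssd + x$n * y$n * delta^2 / n)
  class(s) <- "ClusterStats"
  s
}

.checkHp <- function(hp) {
  if (!methods::is(hp, "NGHyperParams")) stop("'hp' must be an NGHyperParams")
  methods::validObject(hp)
  invisible(hp)
}

.checkStats <- function(stats) {
  if (!inherits(stats, "ClusterStats"))
    stop("'stats' must be a ClusterStats object (see clusterStats())")
  if (!is.finite(stats$n) || stats$n < 0)
    stop("invalid observation count")
  if (any(!is.finite(stats$mean)) || any(!is.finite(stats$ssd)))
    stop("non-finite cluster statistics")
  if (any(stats$ssd < 0)) stop("negative sum of squared deviations")
  invisible(stats)
}

#' Normal-gamma posterior update
#'
#' Conjugate posterior hyperparameters of a Gaussian dimension with unknown
#' mean and precision, given the cluster's sufficient statistics and a
#' normal-gamma prior with mean location fixed at zero:
#' \deqn{c_n = c + n, \quad a_n = a + n/2, \quad
#'       b_n = b + ssd/2 + c\,n\,\bar{x}^2 / (2 (c + n)).}
#'
#' @param stats \code{\link{clusterStats}} (one or more dimensions).
#' @param hp an \code{\link{NGHyperParams}}.
#' @return list with elements \code{c}, \code{a} (scalars) and \code{b}
#'   (one entry per dimension).
#' @examples
#' ngPosteriorUpdate(clusterStats(c(1, -1)), ngHyperParams(1, 1, 1))
#' @export
ngPosteriorUpdate <- function(stats, hp) {
  .checkHp(hp)
  .checkStats(stats)
  n <- stats$n
  if (n == 0)
    return(list(c = hp@c, a = hp@a, b = rep(hp@b, length(stats$mean))))
  list(c = hp@c + n,
       a = hp@a + n / 2,
       b = hp@b + stats$ssd / 2 +
         hp@c * n * stats$mean^2 / (2 * (hp@c + n)))
}

#' Log marginal likelihood of one Gaussian dimension
#'
#' Closed-form marginal likelihood of the values in one dimension under a
#' Gaussian likelihood with unknown mean and precision and a normal-gamma
#' prior (mean location fixed at zero):
#' \deqn{\log p(x) = \log\Gamma(a_n) - \log\Gamma(a) + a \log b
#'   - a_n \log b_n + \tfrac12(\log c - \log c_n)
#'   - \tfrac{n}{2}\log 2\pi.}
#' An empty vector yields 0 (the log of an empty product).
#'
#' @param values numeric vector of observations in one dimension.
#' @param hp an \code{\link{NGHyperParams}}.
#' @return a finite log-probability.
#' @examples
#' ngMarginalLogLik(0, ngHyperParams(1, 1, 1))  # -log(4)
#' @export
ngMarginalLogLik <- function(values, hp) {
  .checkHp(hp)
  if (length(values) == 0L) return(0)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric")
  s <- clusterStats(values)
  post <- ngPosteriorUpdate(s, hp)
  lgamma(post$a) - lgamma(hp@a) + hp@a * log(hp@b) - post$a * log(post$b) +
    0.5 * (log(hp@c) - log(post$c)) - 0.5 * s$n * log(2 * pi)
}

#' Log marginal likelihood of a cluster
#'
#' Dimensions are modelled as independent Gaussians, so the cluster marginal
#' is the sum of the per-dimension marginals, all under one shared
#' hyperparameter triple.
#'
#' @param X numeric matrix, observations x dimensions.
#' @param hp an \code{\link{NGHyperParams}} shared across dimensions, or a
#'   list of one \code{NGHyperParams} per dimension.
#' @return a finite log-probability; 0 for a zero-row matrix.
#' @examples
#' clusterMarginalLogLik(matrix(rnorm(20), 10, 2), ngHyperParams())
#' @export
clusterMarginalLogLik <- function(X, hp) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (!is.numeric(X)) stop("'X' must be numeric")
  if (any(!is.finite(X))) stop("non-finite values in 'X'")
  if (is.list(hp) && !methods::is(hp, "NGHyperParams")) {
    if (length(hp) != ncol(X))
      stop("need one NGHyperParams per dimension")
    return(sum(vapply(seq_len(ncol(X)),
                      function(j) ngMarginalLogLik(X[, j], hp[[j]]),
                      numeric(1))))
  }
  sum(vapply(seq_len(ncol(X)), function(j) ngMarginalLogLik(X[, j], hp),
             numeric(1)))
}

# stats-based marginal used by the hyperparameter layer (shared hp)
.marginalFromStats <- function(stats, hp) {
  .cppMargLogLik(stats$n, stats$mean, stats$ssd, hp@c, hp@a, hp@b)
}
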