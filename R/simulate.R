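#' Synthetic benchmark generators
#'
#' Three mixture scenarios with ground-truth labels, for probing the
#' clustering model where its assumptions hold and where they break:
#' \describe{
#'   \item{Scenario 1}{mixture of \code{k} multivariate Gaussians with
#'     diagonal (identity) covariance — every model assumption holds.}
#'   \item{Scenario 2}{the same mixture but with exchangeable within-component
#'     correlation \code{rho} between dimensions — violates the
#'     independent-dimensions assumption and provokes over-segmentation.}
#'   \item{Scenario 3}{a mixture of seven heterogeneous components — Gaussian,
#'     gamma(2, 1), uniform, Student's t (5 df), Weibull (shape 1.5),
#'     chi-squared (4 df), each with independent dimensions, plus one
#'     correlated Gaussian — probes robustness to non-Gaussian marginals.}
#' }
#' Component assignments are drawn first, then coordinates; every component
#' sits at a distinct coordinate axis at distance \code{separation} in raw
#' space with unit marginal variances (well separated), and the matrix is
#' z-score normalized before it is returned, so the generator output always
#' satisfies the model's normalization assumption. Ground-truth labels are
#' returned separately and are never consumed by the clustering code.
#'
#' @param n observations (default 1000).
#' @param d dimensions (default 10); must be >= \code{k}.
#' @param k mixture components (default 7).
#' @param separation distance of each component mean from the origin in raw
#'   space, in units of the component standard deviation (default 8).
#' @param weights mixing weights, default equal.
#' @param rho exchangeable within-component correlation (scenarios 2 and the
#'   correlated component of scenario 3); must keep the correlation matrix
#'   positive definite, i.e. \code{rho} in (-1/(d-1), 1).
#' @param seed optional integer seed for reproducible draws.
#' @return list with \code{data} (normalized n x d matrix with row names),
#'   \code{labels} (factor of generating components) and, for scenario 3,
#'   \code{families} (the component distribution families in label order).
#' @examples
#' sim <- simulateScenario1(n = 100, seed = 1)
#' dim(sim$data)
#' table(sim$labels)
#' @name simulateScenarios
NULL

.scenarioCheck <- function(n, d, k, separation, weights) {
  stopifnot(n >= 2, d >= 1, k >= 1, k <= n, separation >= 0)
  if (k > d)
    stop("default mean placement needs k <= d components")
  if (length(weights) != k || any(weights <= 0))
    stop("'weights' must be ", k, " positive values")
  weights / sum(weights)
}

.componentMeans <- function(d, k, separation) {
  mu <- matrix(0, k, d)
  mu[cbind(seq_len(k), seq_len(k))] <- separation
  mu
}

.exchangeableChol <- function(d, rho) {
  if (rho <= -1 / (d - 1) || rho >= 1)
    stop("'rho' must keep the exchangeable correlation positive definite")
  R <- matrix(rho, d, d)
  diag(R) <- 1
  chol(R)
}

.finishScenario <- function(X, labels, families = NULL) {
  rownames(X) <- sprintf("obs%d", seq_len(nrow(X)))
  colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  out <- list(data = zscoreNormalize(X), labels = factor(labels))
  if (!is.null(families)) out$families <- families
  out
}

#' @rdname simulateScenarios
#' @export
simulateScenario1 <- function(n = 1000, d = 10, k = 7, separation = 8,
                              weights = rep(1 / k, k), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights <- .scenarioCheck(n, d, k, separation, weights)
  labels <- sample.int(k, n, replace = TRUE, prob = weights)
  mu <- .componentMeans(d, k, separation)
  X <- matrix(stats::rnorm(n * d), n, d) + mu[labels, , drop = FALSE]
  .finishScenario(X, labels)
}

#' @rdname simulateScenarios
#' @export
simulateScenario2 <- function(n = 1000, d = 10, k = 7, separation = 8,
                              rho = 0.5, weights = rep(1 / k, k),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights <- .scenarioCheck(n, d, k, separation, weights)
  L <- .exchangeableChol(d, rho)
  labels <- sample.int(k, n, replace = TRUE, prob = weights)
  mu <- .componentMeans(d, k, separation)
  X <- matrix(stats::rnorm(n * d), n, d) %*% L + mu[labels, , drop = FALSE]
  .finishScenario(X, labels)
}

# standardized (zero-mean, unit-variance) draws per family
.familyDraw <- function(family, m) {
  switch(family,
    "gaussian" = stats::rnorm(m),
    "gamma" = (stats::rgamma(m, shape = 2, rate = 1) - 2) / sqrt(2),
    "uniform" = stats::runif(m, -sqrt(3), sqrt(3)),
    "t" = stats::rt(m, df = 5) / sqrt(5 / 3),
    "weibull" = {
      mu <- gamma(1 + 1 / 1.5)
      sd <- sqrt(gamma(1 + 2 / 1.5) - mu^2)
      (stats::rweibull(m, shape = 1.5, scale = 1) - mu) / sd
    },
    "chisq" = (stats::rchisq(m, df = 4) - 4) / sqrt(8),
    stop("unknown family: ", family))
}

#' @rdname simulateScenarios
#' @export
simulateScenario3 <- function(n = 1000, d = 10, separation = 8, rho = 0.5,
                              weights = rep(1 / 7, 7), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- 7L
  families <- c("gaussian", "gamma", "uniform", "t", "weibull", "chisq",
                "gaussian-correlated")
  weights <- .scenarioCheck(n, d, k, separation, weights)
  labels <- sample.int(k, n, replace = TRUE, prob = weights)
  mu <- .componentMeans(d, k, separation)
  X <- matrix(0, n, d)
  L <- .exchangeableChol(d, rho)
  for (comp in seq_len(k)) {
    idx <- which(labels == comp)
    if (!length(idx)) next
    m <- length(idx) * d
    Z <- if (comp == k)
      matrix(stats::rnorm(m), length(idx), d) %*% L
    else
      matrix(.familyDraw(families[comp], m), length(idx), d)
    X[idx, ] <- Z + matrix(mu[comp, ], length(idx), d, byrow = TRUE)
  }
  .finishScenario(X, labels, families)
}
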