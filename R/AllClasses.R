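#' Normal-gamma hyperparameters
#'
#' Hyperparameters of the conjugate normal-gamma prior placed on the unknown
#' mean and precision of each Gaussian dimension. The prior mean location
#' \code{m} is fixed at zero, reflecting the assumption that input data are
#' z-score normalized; \code{c} scales the prior precision of the mean, and
#' \code{a}, \code{b} are the shape and rate of the gamma prior on the
#' precision.
#'
#' @slot m prior mean location, always 0.
#' @slot c prior precision scaling, positive.
#' @slot a gamma shape on the precision, positive.
#' @slot b gamma rate on the precision, positive.
#'
#' @export
setClass("NGHyperParams",
  representation(m = "numeric", c = "numeric", a = "numeric", b = "numeric"),
  prototype(m = 0, c = 1, a = 1, b = 1))

setValidity("NGHyperParams", function(object) {
  msg <- NULL
  for (s in c("m", "c", "a", "b")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (is.null(msg)) {
    if (object@m != 0)
      msg <- c(msg, "'m' is fixed at 0 (data are assumed normalized)")
    for (s in c("c", "a", "b"))
      if (slot(object, s) <= 0)
        msg <- c(msg, sprintf("'%s' must be positive", s))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param c,a,b positive hyperparameters (see slots).
#' @return \code{ngHyperParams} returns an \code{NGHyperParams} object.
#' @examples
#' ngHyperParams(c = 1, a = 1, b = 1)
#' @rdname NGHyperParams-class
#' @export
ngHyperParams <- function(c = 1, a = 1, b = 1) {
  new("NGHyperParams", m = 0, c = as.numeric(c), a = as.numeric(a),
      b = as.numeric(b))
}

setMethod("show", "NGHyperParams", function(object) {
  cat(sprintf("NGHyperParams (m = 0): c = %.6g, a = %.6g, b = %.6g\n",
              object@c, object@a, object@b))
})

#' Gamma hyper-priors and optimizer settings
#'
#' Configuration of the empirical-Bayes layer: independent gamma hyper-priors
#' on each of the normal-gamma hyperparameters (c, a, b) and the settings of
#' the conjugate-gradient ascent used to maximize the per-merger
#' hyperparameter posterior. The default Gamma(shape = 2, rate = 2) priors
#' (mode 1/2, mean 1) are weakly informative on the unit scale of normalized
#' data.
#'
#' @slot shape,rate positive length-3 vectors, one gamma hyper-prior per
#'   hyperparameter, in the order (c, a, b).
#' @slot init initialization triple for (c, a, b).
#' @slot maxIter maximum conjugate-gradient iterations.
#' @slot gradTol gradient-norm convergence tolerance.
#' @slot objTol objective-change convergence tolerance.
#'
#' @export
setClass("HyperPrior",
  representation(shape = "numeric", rate = "numeric", init = "numeric",
                 maxIter = "integer", gradTol = "numeric", objTol = "numeric"),
  prototype(shape = c(2, 2, 2), rate = c(2, 2, 2), init = c(1, 1, 1),
            maxIter = 200L, gradTol = 1e-6, objTol = 1e-8))

setValidity("HyperPrior", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L || any(!is.finite(object@shape)) ||
      any(object@shape <= 0))
    msg <- c(msg, "'shape' must be 3 positive numbers")
  if (length(object@rate) != 3L || any(!is.finite(object@rate)) ||
      any(object@rate <= 0))
    msg <- c(msg, "'rate' must be 3 positive numbers")
  if (length(object@init) != 3L || any(!is.finite(object@init)) ||
      any(object@init <= 0))
    msg <- c(msg, "'init' must be 3 positive numbers")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be >= 1")
  if (object@gradTol <= 0 || object@objTol <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param shape,rate,init,maxIter,gradTol,objTol see slots.
#' @return \code{hyperPrior} returns a \code{HyperPrior} object.
#' @examples
#' hyperPrior()
#' @rdname HyperPrior-class
#' @export
hyperPrior <- function(shape = c(2, 2, 2), rate = c(2, 2, 2),
                       init = c(1, 1, 1), maxIter = 200L,
                       gradTol = 1e-6, objTol = 1e-8) {
  new("HyperPrior", shape = as.numeric(shape), rate = as.numeric(rate),
      init = as.numeric(init), maxIter = as.integer(maxIter),
      gradTol = gradTol, objTol = objTol)
}

setMethod("show", "HyperPrior", function(object) {
  cat("HyperPrior: gamma hyper-priors on (c, a, b)\n")
  cat(sprintf("  shapes: %s   rates: %s\n",
              paste(signif(object@shape, 4), collapse = ", "),
              paste(signif(object@rate, 4), collapse = ", ")))
  cat(sprintf("  init: (%s); maxIter = %d, gradTol = %g, objTol = %g\n",
              paste(signif(object@init, 4), collapse = ", "),
              object@maxIter, object@gradTol, object@objTol))
})

#' Fitted Bayesian hierarchical clustering
#'
#' The result of \code{\link{gbhc}}: the full binary dendrogram over the
#' observations with every node's Dirichlet-process weight, marginal
#' likelihoods and posterior merge probability, the hyperparameters in force,
#' and the flat partition obtained by cutting the dendrogram at the merge
#' probability threshold.
#'
#' Nodes are numbered 1..n for the leaf observations and n+t for the cluster
#' created at merge t; the last node is the root. \code{left}/\code{right}
#' are 0 for leaves.
#'
#' @slot scheme "tree" or "node".
#' @slot alpha Dirichlet process concentration used.
#' @slot cutThreshold merge-probability cut level.
#' @slot nodes data.frame with one row per node: \code{left}, \code{right},
#'   \code{nK}, \code{logD}, \code{logPi}, \code{logMlH1}, \code{logMlTree},
#'   \code{r}.
#' @slot hyperParams the shared hyperparameters (TREE) or the root node's
#'   optimized hyperparameters (NODE).
#' @slot nodeHyperParams matrix of per-node (c, a, b) (NODE scheme; under
#'   TREE all rows equal \code{hyperParams}).
#' @slot partition factor of cluster labels, named by observation.
#' @slot labels observation labels.
#' @slot rootLogLik log marginal likelihood of the full tree at the root.
#' @slot trace root log marginal likelihood per outer round (TREE) or the
#'   final value (NODE).
#'
#' @export
setClass("GBHCFit",
  representation(scheme = "character", alpha = "numeric",
                 cutThreshold = "numeric", nodes = "data.frame",
                 hyperParams = "NGHyperParams", nodeHyperParams = "matrix",
                 partition = "factor", labels = "character",
                 rootLogLik = "numeric", trace = "numeric"))

setValidity("GBHCFit", function(object) {
  msg <- NULL
  n <- length(object@labels)
  if (nrow(object@nodes) != max(2L * n - 1L, 1L))
    msg <- c(msg, "node table must have 2n-1 rows")
  if (length(object@partition) != n)
    msg <- c(msg, "partition must cover all observations")
  if (any(object@nodes$r < 0 | object@nodes$r > 1))
    msg <- c(msg, "merge probabilities must lie in [0, 1]")
  if (!object@scheme %in% c("tree", "node"))
    msg <- c(msg, "scheme must be 'tree' or 'node'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GBHCFit", function(object) {
  n <- length(object@labels)
  cat(sprintf("GBHCFit: %d observations, scheme = %s, alpha = %g\n",
              n, toupper(object@scheme), object@alpha))
  cat(sprintf("  root log marginal likelihood: %.4f\n", object@rootLogLik))
  cat(sprintf("  cut at r <= %g: %d clusters\n", object@cutThreshold,
              nlevels(object@partition)))
  cat(sprintf("  hyperparameters: c = %.4g, a = %.4g, b = %.4g\n",
              object@hyperParams@c, object@hyperParams@a,
              object@hyperParams@b))
})
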