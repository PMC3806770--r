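#' @rdname partition
#' @export
setGeneric("partition", function(object, ...) standardGeneric("partition"))

#' @rdname partition
#' @export
setGeneric("nClusters", function(object, ...) standardGeneric("nClusters"))

#' @rdname partition
#' @export
setGeneric("mergeProbabilities",
           function(object, ...) standardGeneric("mergeProbabilities"))

#' @rdname partition
#' @export
setGeneric("hyperParams", function(object, ...) standardGeneric("hyperParams"))

#' @rdname partition
#' @export
setGeneric("rootLogLik", function(object, ...) standardGeneric("rootLogLik"))

#' @rdname cutTree
#' @export
setGeneric("cutTree",
           function(object, threshold = 0.5, ...) standardGeneric("cutTree"))

#' Accessors for GBHCFit objects
#'
#' \code{partition} returns the flat cluster assignment (a named factor)
#' obtained by cutting the dendrogram at the stored threshold;
#' \code{nClusters} its number of clusters; \code{mergeProbabilities} the
#' posterior merge probability of every internal node in merge order;
#' \code{hyperParams} the fitted hyperparameters; \code{rootLogLik} the log
#' marginal likelihood of the whole tree.
#'
#' @param object a \code{\link{GBHCFit}}.
#' @param ... unused.
#' @return see description.
#' @examples
#' sim <- simulateScenario1(n = 40, d = 4, k = 2, seed = 1)
#' fit <- gbhc(sim$data, scheme = "node")
#' partition(fit)
#' nClusters(fit)
#' @name partition
#' @aliases partition,GBHCFit-method nClusters,GBHCFit-method
#'   mergeProbabilities,GBHCFit-method hyperParams,GBHCFit-method
#'   rootLogLik,GBHCFit-method
NULL

setMethod("partition", "GBHCFit", function(object, ...) object@partition)

setMethod("nClusters", "GBHCFit",
          function(object, ...) nlevels(object@partition))

setMethod("mergeProbabilities", "GBHCFit", function(object, ...) {
  internal <- object@nodes$left != 0L
  object@nodes$r[internal]
})

setMethod("hyperParams", "GBHCFit", function(object, ...) object@hyperParams)

setMethod("rootLogLik", "GBHCFit", function(object, ...) object@rootLogLik)
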