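#' @import methods
NULL

#' Gene identifiers of an object
#'
#' @param x a \linkS4class{BinaryExpressionMatrix} or
#'   \linkS4class{LogicNetwork}.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Number of genes
#' @param x a \linkS4class{BinaryExpressionMatrix} or
#'   \linkS4class{LogicNetwork}.
#' @return Integer count.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Number of samples
#' @param x a \linkS4class{BinaryExpressionMatrix}.
#' @return Integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Binary expression values
#' @param x a \linkS4class{BinaryExpressionMatrix}.
#' @return Integer 0/1 matrix, genes in rows, samples in columns.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' First-order edges of a logic network
#' @param x a \linkS4class{LogicNetwork}.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{logic}, \code{weight}.
#' @export
setGeneric("firstOrderEdges", function(x) standardGeneric("firstOrderEdges"))

#' Second-order triplets of a logic network
#' @param x a \linkS4class{LogicNetwork}.
#' @return data.frame with columns \code{inputA}, \code{inputB},
#'   \code{target}, \code{logic}, \code{weight}, \code{splitA},
#'   \code{splitB}.
#' @export
setGeneric("secondOrderTriplets",
           function(x) standardGeneric("secondOrderTriplets"))

#' Detection thresholds of a logic network
#' @param x a \linkS4class{LogicNetwork}.
#' @return Numeric vector \code{c(t1, t2)}; \code{NA} for directly
#'   constructed (unthresholded) networks.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' Trigger node of a cascade outcome
#' @param x a \linkS4class{CascadeOutcome}.
#' @return Gene identifier of the initially deleted node.
#' @export
setGeneric("trigger", function(x) standardGeneric("trigger"))

#' Failed nodes of a cascade outcome
#' @param x a \linkS4class{CascadeOutcome}.
#' @return Character vector of failed gene identifiers, trigger first,
#'   then in order of failure round.
#' @export
setGeneric("failedNodes", function(x) standardGeneric("failedNodes"))

#' Cascade size (number of failed nodes, including the trigger)
#' @param x a \linkS4class{CascadeOutcome}.
#' @return Integer failure count \eqn{s_i}.
#' @export
setGeneric("cascadeSize", function(x) standardGeneric("cascadeSize"))

#' Per-round failure lists of a cascade
#' @param x a \linkS4class{CascadeOutcome}.
#' @return List of character vectors; element 1 is the trigger, later
#'   elements are the synchronous failure rounds.
#' @export
setGeneric("cascadeRounds", function(x) standardGeneric("cascadeRounds"))
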