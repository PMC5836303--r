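#' @include AllGenerics.R
#' @import methods
NULL

.emptyEdgeFrame <- function() {
  data.frame(source = character(), target = character(),
             logic = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

.emptyTripletFrame <- function() {
  data.frame(inputA = character(), inputB = character(),
             target = character(), logic = character(),
             weight = numeric(), splitA = numeric(), splitB = numeric(),
             stringsAsFactors = FALSE)
}

#' BinaryExpressionMatrix: binarized presence/absence expression profiles
#'
#' Container for a genes x samples matrix with entries in \{0, 1\}, where 1
#' denotes presence (expression) of the gene in a sample and 0 absence.
#' This is the substrate for uncertainty-coefficient network inference.
#'
#' @slot values integer matrix of 0/1 values; rownames are the unique gene
#'   identifiers, columns are samples.
#' @seealso [BinaryExpressionMatrix()], [buildLogicNetwork()]
#' @export
setClass("BinaryExpressionMatrix",
         representation(values = "matrix"))

setValidity("BinaryExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) && !is.integer(v))
    msg <- c(msg, "'values' must be a numeric 0/1 matrix")
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "need at least 1 gene and 1 sample")
  else if (anyNA(v) || !all(v == 0L | v == 1L))
    msg <- c(msg, "all entries must be 0 or 1")
  rn <- rownames(v)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    msg <- c(msg, "gene identifiers (rownames) are required")
  else if (anyDuplicated(rn))
    msg <- c(msg, "gene identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryExpressionMatrix
#'
#' @param values matrix of 0/1 values with gene identifiers as rownames
#'   (genes in rows, samples in columns). Sample names default to
#'   \code{S1..Sn} when absent.
#' @return A \linkS4class{BinaryExpressionMatrix}.
#' @examples
#' m <- BinaryExpressionMatrix(rbind(gA = c(1, 1, 0, 0),
#'                                   gB = c(1, 0, 1, 0)))
#' nSamples(m)
#' @export
BinaryExpressionMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  new("BinaryExpressionMatrix", values = values)
}

#' LogicNetwork: a directed, weighted gene logic network
#'
#' Nodes are genes; relationships are first-order edges (one regulator, one
#' target, weight = uncertainty coefficient U) and second-order triplets
#' (two inputs combined by a Boolean function regulating one target, weight
#' = U of the composite input). Isolated nodes are retained in the node
#' set; cascade size ratios are always relative to the full node count.
#'
#' @slot geneIds character vector of all node identifiers (isolated nodes
#'   included).
#' @slot firstOrder data.frame: source, target, logic (DIRECT/INVERTED),
#'   weight.
#' @slot secondOrder data.frame: inputA, inputB, target, logic (one of the
#'   ten two-input types, see [logicFunctions()]), weight, splitA, splitB
#'   (contribution fractions of the two inputs; sum to 1).
#' @slot thresholds numeric c(t1, t2) used at inference time; NA for
#'   directly constructed networks.
#' @seealso [buildLogicNetwork()], [generateToyNetwork()],
#'   [strengthTable()], [runCascade()]
#' @export
setClass("LogicNetwork",
         representation(geneIds = "character",
                        firstOrder = "data.frame",
                        secondOrder = "data.frame",
                        thresholds = "numeric"))

setValidity("LogicNetwork", function(object) {
  msg <- character()
  ids <- object@geneIds
  if (length(ids) < 1L || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "geneIds must be non-empty identifiers")
  if (anyDuplicated(ids))
    msg <- c(msg, "geneIds must be unique")
  e <- object@firstOrder
  needE <- c("source", "target", "logic", "weight")
  if (!all(needE %in% names(e))) {
    msg <- c(msg, "firstOrder must have columns source, target, logic, weight")
  } else if (nrow(e)) {
    if (!all(c(e$source, e$target) %in% ids))
      msg <- c(msg, "first-order edges reference unknown genes")
    if (any(e$source == e$target))
      msg <- c(msg, "self-loops are not allowed")
    if (!all(e$logic %in% .LOGIC1$name))
      msg <- c(msg, "unknown first-order logic type")
    if (any(e$weight <= 0 | e$weight > 1))
      msg <- c(msg, "edge weights must lie in (0, 1]")
    if (anyDuplicated(e[c("source", "target", "logic")]))
      msg <- c(msg, "duplicate (source, target, logic) edges")
  }
  tr <- object@secondOrder
  needT <- c("inputA", "inputB", "target", "logic", "weight",
             "splitA", "splitB")
  if (!all(needT %in% names(tr))) {
    msg <- c(msg, paste("secondOrder must have columns",
                        paste(needT, collapse = ", ")))
  } else if (nrow(tr)) {
    if (!all(c(tr$inputA, tr$inputB, tr$target) %in% ids))
      msg <- c(msg, "triplets reference unknown genes")
    distinct <- tr$inputA != tr$inputB & tr$inputA != tr$target &
      tr$inputB != tr$target
    if (!all(distinct))
      msg <- c(msg, "the three genes of a triplet must be distinct")
    if (!all(tr$logic %in% .LOGIC2$name))
      msg <- c(msg, "unknown second-order logic type")
    if (any(tr$weight <= 0 | tr$weight > 1))
      msg <- c(msg, "triplet weights must lie in (0, 1]")
    if (any(tr$splitA < 0 | tr$splitB < 0) ||
        any(abs(tr$splitA + tr$splitB - 1) > 1e-9))
      msg <- c(msg, "splitA + splitB must equal 1 with both nonnegative")
    if (anyDuplicated(tr[c("inputA", "inputB", "target", "logic")]))
      msg <- c(msg, "duplicate (inputA, inputB, target, logic) triplets")
  }
  th <- object@thresholds
  if (length(th) != 2L)
    msg <- c(msg, "thresholds must have length 2")
  else if (!all(is.na(th)) &&
           (anyNA(th) || th[1] <= 0 || th[2] < th[1] || th[2] >= 1))
    msg <- c(msg, "thresholds must satisfy 0 < t1 <= t2 < 1 (or both NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a LogicNetwork directly
#'
#' Low-level constructor used by [buildLogicNetwork()] and
#' [generateToyNetwork()]; validates all network invariants.
#'
#' @param geneIds character vector of node identifiers.
#' @param firstOrder data.frame of first-order edges (may be empty).
#' @param secondOrder data.frame of second-order triplets (may be empty).
#' @param thresholds numeric c(t1, t2) or c(NA, NA).
#' @return A \linkS4class{LogicNetwork}.
#' @export
LogicNetwork <- function(geneIds,
                         firstOrder = .emptyEdgeFrame(),
                         secondOrder = .emptyTripletFrame(),
                         thresholds = c(NA_real_, NA_real_)) {
  firstOrder <- as.data.frame(firstOrder, stringsAsFactors = FALSE)
  secondOrder <- as.data.frame(secondOrder, stringsAsFactors = FALSE)
  if (!nrow(firstOrder)) firstOrder <- .emptyEdgeFrame()
  if (!nrow(secondOrder)) secondOrder <- .emptyTripletFrame()
  rownames(firstOrder) <- NULL
  rownames(secondOrder) <- NULL
  new("LogicNetwork", geneIds = as.character(geneIds),
      firstOrder = firstOrder, secondOrder = secondOrder,
      thresholds = as.numeric(thresholds))
}

#' CascadeOutcome: result of one single-trigger cascading failure
#'
#' @slot trigger gene id of the initially deleted node.
#' @slot failed character vector of all failed nodes (trigger included).
#' @slot rounds list of character vectors: element 1 is the trigger, each
#'   later element one synchronous failure round.
#' @slot s integer failure count.
#' @slot d numeric size ratio s/N.
#' @slot N integer node count of the intact network.
#' @seealso [runCascade()], [sweepAllTriggers()]
#' @export
setClass("CascadeOutcome",
         representation(trigger = "character", failed = "character",
                        rounds = "list", s = "integer", d = "numeric",
                        N = "integer"))

setValidity("CascadeOutcome", function(object) {
  msg <- character()
  if (!(object@trigger %in% object@failed))
    msg <- c(msg, "trigger must be among the failed nodes")
  if (object@s != length(object@failed))
    msg <- c(msg, "s must equal the number of failed nodes")
  if (object@d < 1 / object@N - 1e-12 || object@d > 1 + 1e-12)
    msg <- c(msg, "size ratio must lie in [1/N, 1]")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname geneIds
#' @export
setMethod("geneIds", "BinaryExpressionMatrix",
          function(x) rownames(x@values))

#' @rdname geneIds
#' @export
setMethod("geneIds", "LogicNetwork", function(x) x@geneIds)

#' @rdname nGenes
#' @export
setMethod("nGenes", "BinaryExpressionMatrix", function(x) nrow(x@values))

#' @rdname nGenes
#' @export
setMethod("nGenes", "LogicNetwork", function(x) length(x@geneIds))

#' @rdname nSamples
#' @export
setMethod("nSamples", "BinaryExpressionMatrix", function(x) ncol(x@values))

#' @rdname exprValues
#' @export
setMethod("exprValues", "BinaryExpressionMatrix", function(x) x@values)

#' @rdname firstOrderEdges
#' @export
setMethod("firstOrderEdges", "LogicNetwork", function(x) x@firstOrder)

#' @rdname secondOrderTriplets
#' @export
setMethod("secondOrderTriplets", "LogicNetwork", function(x) x@secondOrder)

#' @rdname thresholds
#' @export
setMethod("thresholds", "LogicNetwork", function(x) x@thresholds)

#' @rdname trigger
#' @export
setMethod("trigger", "CascadeOutcome", function(x) x@trigger)

#' @rdname failedNodes
#' @export
setMethod("failedNodes", "CascadeOutcome", function(x) x@failed)

#' @rdname cascadeSize
#' @export
setMethod("cascadeSize", "CascadeOutcome", function(x) x@s)

#' @rdname cascadeRounds
#' @export
setMethod("cascadeRounds", "CascadeOutcome", function(x) x@rounds)

## ---- show methods ----

setMethod("show", "BinaryExpressionMatrix", function(object) {
  cat("BinaryExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples\n")
  cat("  presence rate:",
      format(mean(object@values), digits = 3), "\n")
})

setMethod("show", "LogicNetwork", function(object) {
  th <- object@thresholds
  cat("LogicNetwork:", length(object@geneIds), "nodes,",
      nrow(object@firstOrder), "first-order edges,",
      nrow(object@secondOrder), "second-order triplets\n")
  if (!all(is.na(th)))
    cat("  thresholds: t1 =", th[1], ", t2 =", th[2], "\n")
})

setMethod("show", "CascadeOutcome", function(object) {
  cat("CascadeOutcome: trigger", object@trigger, "->", object@s,
      "failed of", object@N,
      sprintf("(d = %.4f, %d round(s))\n", object@d,
              length(object@rounds) - 1L))
})
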