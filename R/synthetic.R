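#' Design for a synthetic binary expression matrix with planted logic
#'
#' Describes a seeded generative model that emulates binarized
#' presence/absence expression profiles: background genes are i.i.d.
#' Bernoulli(p) across samples, and each planted relationship computes
#' its target from the realized input profiles through a Boolean logic
#' truth table, after which each target entry is flipped independently
#' with probability \code{noise} (measurement-noise reading: inputs are
#' left untouched unless \code{noiseOn = "inputs"}).
#'
#' @param nGenes total number of genes; identifiers are \code{g01},
#'   \code{g02}, ... unless \code{geneIds} is given.
#' @param nSamples number of samples.
#' @param p background activation probability in (0, 1).
#' @param relationships list of planted relationships, each a list with
#'   \code{inputs} (1 or 2 gene ids), \code{target} (gene id, distinct
#'   from its inputs, planted at most once), and \code{logic} (a type
#'   name from [logicFunctions()] matching the arity).
#' @param noise per-entry flip probability in [0, 0.5).
#' @param noiseOn \code{"target"} (default) or \code{"inputs"}.
#' @param seed integer seed; the same design always generates the same
#'   matrix.
#' @param geneIds optional explicit gene identifiers.
#' @return List of class \code{PlantedDesign}.
#' @seealso [generateMatrix()]
#' @export
plantedDesign <- function(nGenes, nSamples, p = 0.5,
                          relationships = list(), noise = 0,
                          noiseOn = c("target", "inputs"),
                          seed = 1L, geneIds = NULL) {
  noiseOn <- match.arg(noiseOn)
  if (nGenes < 1 || nSamples < 1) stop("need at least 1 gene and 1 sample")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)")
  if (is.null(geneIds))
    geneIds <- sprintf("g%02d", seq_len(nGenes))
  if (length(geneIds) != nGenes || anyDuplicated(geneIds))
    stop("geneIds must be ", nGenes, " unique identifiers")
  targets <- character()
  for (r in relationships) {
    if (!all(c("inputs", "target", "logic") %in% names(r)))
      stop("each relationship needs inputs, target and logic")
    if (!all(c(r$inputs, r$target) %in% geneIds))
      stop("relationship references unknown gene")
    if (r$target %in% r$inputs)
      stop("target must be distinct from its inputs")
    if (length(r$inputs) != .logicArity(r$logic))
      stop("logic '", r$logic, "' arity does not match inputs")
    if (r$target %in% targets)
      stop("target '", r$target, "' planted twice")
    targets <- c(targets, r$target)
  }
  structure(list(nGenes = nGenes, nSamples = nSamples, p = p,
                 relationships = relationships, noise = noise,
                 noiseOn = noiseOn, seed = as.integer(seed),
                 geneIds = geneIds),
            class = "PlantedDesign")
}

#' @export
print.PlantedDesign <- function(x, ...) {
  cat("PlantedDesign:", x$nGenes, "genes x", x$nSamples,
      "samples, p =", x$p, ", noise =", x$noise, ", seed =", x$seed,
      "\n  planted relationships:", length(x$relationships), "\n")
  invisible(x)
}

#' Generate a binary expression matrix from a planted design
#'
#' @param design a [plantedDesign()].
#' @return List with \code{matrix} (a
#'   \linkS4class{BinaryExpressionMatrix}) and \code{truth}, a data.frame
#'   of the planted relationships (\code{inputA}, \code{inputB} (NA for
#'   single-input), \code{target}, \code{logic}).
#' @examples
#' des <- plantedDesign(4, 32, relationships = list(
#'   list(inputs = c("g01", "g02"), target = "g03", logic = "OR")))
#' gm <- generateMatrix(des)
#' gm$truth
#' @export
generateMatrix <- function(design) {
  stopifnot(inherits(design, "PlantedDesign"))
  set.seed(design$seed)
  M <- matrix(rbinom(design$nGenes * design$nSamples, 1L, design$p),
              nrow = design$nGenes,
              dimnames = list(design$geneIds, NULL))
  flip <- function(v) {
    f <- stats::rbinom(length(v), 1L, design$noise)
    (v + f) %% 2L
  }
  for (r in design$relationships) {
    ins <- M[r$inputs, , drop = FALSE]
    if (design$noiseOn == "inputs" && design$noise > 0)
      ins <- t(apply(ins, 1, flip))
    w <- if (nrow(ins) == 1L) evaluateLogic(r$logic, ins[1, ])
         else evaluateLogic(r$logic, ins[1, ], ins[2, ])
    if (design$noiseOn == "target" && design$noise > 0)
      w <- flip(w)
    M[r$target, ] <- w
  }
  truth <- data.frame(
    inputA = vapply(design$relationships, function(r) r$inputs[1],
                    character(1)),
    inputB = vapply(design$relationships, function(r)
      if (length(r$inputs) == 2L) r$inputs[2] else NA_character_,
      character(1)),
    target = vapply(design$relationships, function(r) r$target,
                    character(1)),
    logic = vapply(design$relationships, function(r) r$logic,
                   character(1)),
    stringsAsFactors = FALSE)
  list(matrix = BinaryExpressionMatrix(M), truth = truth)
}

#' Construct a toy logic network directly
#'
#' Builds a \linkS4class{LogicNetwork} from explicit edge and triplet
#' tables, bypassing inference — the workhorse for cascade unit tests
#' and worked examples. Contribution splits default to (1/2, 1/2) when
#' not supplied.
#'
#' @param nodes character vector of node ids (isolated nodes allowed).
#' @param edges optional data.frame with \code{source}, \code{target},
#'   \code{weight} and optionally \code{logic} (default DIRECT).
#' @param triplets optional data.frame with \code{inputA}, \code{inputB},
#'   \code{target}, \code{logic}, \code{weight} and optionally
#'   \code{splitA}, \code{splitB}.
#' @return A \linkS4class{LogicNetwork} with NA thresholds.
#' @examples
#' generateToyNetwork(c("A", "B", "C"),
#'   triplets = data.frame(inputA = "A", inputB = "B", target = "C",
#'                         logic = "OR", weight = 0.6))
#' @export
generateToyNetwork <- function(nodes, edges = NULL, triplets = NULL) {
  e <- .emptyEdgeFrame()
  if (!is.null(edges) && nrow(edges)) {
    if (is.null(edges$logic)) edges$logic <- "DIRECT"
    e <- data.frame(source = as.character(edges$source),
                    target = as.character(edges$target),
                    logic = as.character(edges$logic),
                    weight = as.numeric(edges$weight),
                    stringsAsFactors = FALSE)
  }
  tr <- .emptyTripletFrame()
  if (!is.null(triplets) && nrow(triplets)) {
    if (is.null(triplets$splitA)) triplets$splitA <- 0.5
    if (is.null(triplets$splitB)) triplets$splitB <- 1 - triplets$splitA
    tr <- data.frame(inputA = as.character(triplets$inputA),
                     inputB = as.character(triplets$inputB),
                     target = as.character(triplets$target),
                     logic = as.character(triplets$logic),
                     weight = as.numeric(triplets$weight),
                     splitA = as.numeric(triplets$splitA),
                     splitB = as.numeric(triplets$splitB),
                     stringsAsFactors = FALSE)
  }
  LogicNetwork(nodes, e, tr)
}

#' Random logic network fixture
#'
#' Seeded generator of structurally valid random
#' \linkS4class{LogicNetwork}s for property tests and robustness
#' ensembles: relationship endpoints are sampled uniformly without
#' duplicates, weights uniformly on [wmin, 1], logic types uniformly
#' from the catalogue, and OR-family contribution splits uniformly on
#' (0, 1) (other families get the fixed (1/2, 1/2)).
#'
#' @param nNodes number of nodes.
#' @param nEdges number of first-order edges (capped at the number of
#'   distinct ordered pairs).
#' @param nTriplets number of second-order triplets.
#' @param seed integer seed.
#' @param wmin minimum relationship weight (default 0.1).
#' @return A \linkS4class{LogicNetwork}.
#' @export
randomLogicNetwork <- function(nNodes, nEdges, nTriplets, seed,
                               wmin = 0.1) {
  if (nNodes < 3) stop("need at least 3 nodes")
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nNodes))
  e <- .emptyEdgeFrame()
  if (nEdges > 0) {
    pairs <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pick <- pairs[sample(nrow(pairs), min(nEdges, nrow(pairs))), ]
    e <- data.frame(source = pick$source, target = pick$target,
                    logic = sample(.LOGIC1$name, nrow(pick),
                                   replace = TRUE),
                    weight = stats::runif(nrow(pick), wmin, 1),
                    stringsAsFactors = FALSE)
  }
  tr <- .emptyTripletFrame()
  if (nTriplets > 0) {
    seen <- character()
    rows <- vector("list", nTriplets)
    nkeep <- 0L
    for (i in seq_len(nTriplets * 4L)) {
      g <- sample(ids, 3L)
      ab <- sort(g[1:2])
      key <- paste(ab[1], ab[2], g[3])
      if (key %in% seen) next
      seen <- c(seen, key)
      lg <- sample(.LOGIC2$name, 1L)
      sa <- if (.onesCount(lg) == 3L) stats::runif(1) else 0.5
      nkeep <- nkeep + 1L
      rows[[nkeep]] <- data.frame(inputA = ab[1], inputB = ab[2],
                                  target = g[3], logic = lg,
                                  weight = stats::runif(1, wmin, 1),
                                  splitA = sa, splitB = 1 - sa,
                                  stringsAsFactors = FALSE)
      if (nkeep == nTriplets) break
    }
    if (nkeep) tr <- do.call(rbind, rows[seq_len(nkeep)])
  }
  LogicNetwork(ids, e, tr)
}
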