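#' Cascade size ratio
#'
#' d = s/N: the fraction of all network nodes (trigger included) that
#' fail in one cascade; an approximate indicator of network damage.
#'
#' @param s failure count, 1 <= s <= N.
#' @param N node count of the intact network.
#' @return d in [1/N, 1].
#' @examples
#' sizeRatio(3, 10)  # 0.3
#' @export
sizeRatio <- function(s, N) {
  if (s < 1 || N < 1 || s > N) stop("need 1 <= s <= N")
  s / N
}

#' Largest cascade size ratio
#'
#' R_max = max over triggers of the size ratio d_i: the worst-case damage
#' a single-node deletion can cause.
#'
#' @param d non-empty numeric vector of size ratios.
#' @return Maximum element.
#' @export
rMax <- function(d) {
  if (!length(d)) stop("d must be non-empty")
  max(d)
}

#' Cumulative cascade probability curve
#'
#' For each grid value d, the fraction of triggers whose cascade size
#' ratio d_i is at least d: the empirical survival function
#' P(d' >= d). It equals 1 at d = 0, is non-increasing, and drops to 0
#' beyond R_max.
#'
#' @param d numeric vector of per-trigger size ratios.
#' @param grid ascending grid of d values; default the sorted unique
#'   ratios plus 0 (the exact empirical survival function).
#' @return data.frame with columns \code{d} and \code{p}.
#' @examples
#' cumulativeProbability(c(0.1, 0.1, 0.5, 1))
#' @export
cumulativeProbability <- function(d, grid = NULL) {
  if (!length(d)) stop("d must be non-empty")
  if (is.null(grid)) grid <- sort(unique(c(0, d)))
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  p <- vapply(grid, function(g) mean(d >= g - 1e-12), numeric(1))
  data.frame(d = grid, p = p)
}

#' Summarize a trigger sweep
#'
#' Collects the per-trigger size ratios of a [sweepAllTriggers()] run
#' into the standard damage statistics: the d vector, R_max, and the
#' cumulative cascade probability curve.
#'
#' @param sweep list of \linkS4class{CascadeOutcome} from
#'   [sweepAllTriggers()].
#' @param grid optional grid for [cumulativeProbability()].
#' @return List of class \code{CascadeSweepSummary}: \code{N}, \code{d}
#'   (named by trigger), \code{RMax}, \code{curve}.
#' @export
cascadeSummary <- function(sweep, grid = NULL) {
  if (!length(sweep)) stop("sweep must be non-empty")
  d <- vapply(sweep, function(x) x@d, numeric(1))
  names(d) <- vapply(sweep, function(x) x@trigger, character(1))
  out <- list(N = sweep[[1]]@N, d = d, RMax = rMax(d),
              curve = cumulativeProbability(d, grid))
  class(out) <- "CascadeSweepSummary"
  out
}

#' @export
print.CascadeSweepSummary <- function(x, ...) {
  cat("CascadeSweepSummary:", length(x$d), "triggers over", x$N,
      "nodes; R_max =", format(x$RMax, digits = 4), "\n")
  invisible(x)
}

## All relationships a center node participates in, with its role.
.centerRelationships <- function(net, center) {
  e <- net@firstOrder
  tr <- net@secondOrder
  rel <- character()
  role <- character()
  if (nrow(e)) {
    hit <- which(e$source == center | e$target == center)
    for (i in hit) {
      rel <- c(rel, sprintf("%s->%s [%s]", e$source[i], e$target[i],
                            e$logic[i]))
      role <- c(role, if (e$target[i] == center) "in" else "out")
    }
  }
  if (nrow(tr)) {
    hit <- which(tr$inputA == center | tr$inputB == center |
                   tr$target == center)
    for (i in hit) {
      rel <- c(rel, sprintf("(%s,%s)->%s [%s]", tr$inputA[i],
                            tr$inputB[i], tr$target[i], tr$logic[i]))
      role <- c(role, if (tr$target[i] == center) "in" else "out")
    }
  }
  data.frame(rel = rel, role = role, stringsAsFactors = FALSE)
}

#' Logic doublets centered on a node
#'
#' A logic doublet is an unordered pair of relationships (first- or
#' second-order) sharing a common center node. Doublets are classed by
#' the center's position: \code{both-in} when it is the target of both
#' (within the doublet subgraph its load is +Inf), \code{both-out} when
#' it is an input/source of both (load 0), and \code{in-out} otherwise
#' (positive load). Hubs embedded in many doublets are the nodes whose
#' deletion tends to cause large cascades.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @param center gene id.
#' @return data.frame with one row per doublet: \code{center},
#'   \code{rel1}, \code{rel2} (human-readable relationship labels),
#'   \code{klass}.
#' @export
classifyDoublets <- function(net, center) {
  stopifnot(is(net, "LogicNetwork"))
  if (!(center %in% net@geneIds)) stop("unknown center node: ", center)
  cr <- .centerRelationships(net, center)
  n <- nrow(cr)
  empty <- data.frame(center = character(), rel1 = character(),
                      rel2 = character(), klass = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  pairs <- utils::combn(n, 2)
  klass <- apply(pairs, 2, function(ij) {
    r <- cr$role[ij]
    if (all(r == "in")) "both-in"
    else if (all(r == "out")) "both-out"
    else "in-out"
  })
  data.frame(center = center, rel1 = cr$rel[pairs[1, ]],
             rel2 = cr$rel[pairs[2, ]], klass = klass,
             stringsAsFactors = FALSE)
}

#' Ranked report of the most damaging triggers
#'
#' The top-k triggers by cascade size ratio, with their degree, strength
#' and doublet-motif profile: the structural context the damage is
#' usually attributed to (hubs with large in- or out-degree embedded in
#' logic doublets). Ties in d are broken lexicographically by gene id.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @param sweep list of \linkS4class{CascadeOutcome} from
#'   [sweepAllTriggers()] on the same network.
#' @param k number of triggers to report (k >= 1; capped at N).
#' @return data.frame: \code{gene}, \code{s}, \code{d}, \code{inDegree},
#'   \code{outDegree}, \code{inStrength}, \code{outStrength},
#'   \code{bothIn}, \code{bothOut}, \code{inOut} (doublet counts).
#' @export
hubReport <- function(net, sweep, k = 5L) {
  stopifnot(is(net, "LogicNetwork"))
  if (k < 1) stop("k must be >= 1")
  d <- vapply(sweep, function(x) x@d, numeric(1))
  s <- vapply(sweep, function(x) x@s, integer(1))
  gene <- vapply(sweep, function(x) x@trigger, character(1))
  deg <- degreeTable(net)
  st <- strengthTable(net)
  cnt <- t(vapply(gene, function(g) {
    kl <- classifyDoublets(net, g)$klass
    c(bothIn = sum(kl == "both-in"), bothOut = sum(kl == "both-out"),
      inOut = sum(kl == "in-out"))
  }, numeric(3)))
  tab <- data.frame(gene = gene, s = s, d = d, stringsAsFactors = FALSE)
  tab <- merge(tab, deg, by = "gene", sort = FALSE)
  tab <- merge(tab, st[c("gene", "inStrength", "outStrength")],
               by = "gene", sort = FALSE)
  tab <- cbind(tab, cnt[match(tab$gene, gene), , drop = FALSE])
  tab <- tab[order(-tab$d, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, n = min(k, nrow(tab)))
}
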