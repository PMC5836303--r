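#' Structural summary of a logic network
#'
#' Node and relationship counts plus the average degree, computed as the
#' total of all per-node in- and out-degrees (with the catalogue degree
#' increments) divided by the node count.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @return One-row data.frame: \code{nodes}, \code{relationships},
#'   \code{firstOrder}, \code{secondOrder}, \code{averageDegree}.
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "LogicNetwork"))
  deg <- degreeTable(net)
  data.frame(nodes = length(net@geneIds),
             relationships = nrow(net@firstOrder) + nrow(net@secondOrder),
             firstOrder = nrow(net@firstOrder),
             secondOrder = nrow(net@secondOrder),
             averageDegree = sum(deg$inDegree + deg$outDegree) /
               length(net@geneIds))
}

#' Robustness across the capacity parameter grid
#'
#' Sweeps all triggers at each capacity parameter value and records the
#' largest cascade size ratio R_max and the mean size ratio. Smaller
#' alpha means narrower capacity intervals, hence larger cascades.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @param alphas grid of capacity parameters (default 0.1 to 0.9 by
#'   0.1).
#' @param isolatedPolicy passed to [runCascade()].
#' @return data.frame with columns \code{alpha}, \code{RMax},
#'   \code{meanD}.
#' @export
alphaSweep <- function(net, alphas = seq(0.1, 0.9, by = 0.1),
                       isolatedPolicy = c("fail", "inert")) {
  isolatedPolicy <- match.arg(isolatedPolicy)
  rows <- lapply(alphas, function(a) {
    sm <- cascadeSummary(sweepAllTriggers(net, a, isolatedPolicy))
    data.frame(alpha = a, RMax = sm$RMax, meanD = mean(sm$d))
  })
  do.call(rbind, rows)
}

#' Full pipeline across detection-threshold pairs
#'
#' For each (t1, t2) pair, infers the network from the matrix, sweeps
#' all triggers at the given capacity parameter, and collects structure
#' and damage summaries. The default grid is the four standard pairs
#' (0.15, 0.30), (0.20, 0.35), (0.25, 0.40), (0.30, 0.45).
#'
#' @param m a \linkS4class{BinaryExpressionMatrix}.
#' @param thresholdPairs two-column matrix or data.frame of (t1, t2)
#'   pairs.
#' @param alpha capacity parameter (default 0.5).
#' @param redundancyFilter passed to [buildLogicNetwork()].
#' @return List with \code{summary} (one row per pair: t1, t2, the
#'   [networkSummary()] columns, RMax, meanD), \code{networks} (list of
#'   \linkS4class{LogicNetwork}) and \code{sweeps} (list of outcome
#'   lists), both named "t1_t2".
#' @export
thresholdSweep <- function(m,
                           thresholdPairs = cbind(
                             t1 = c(0.15, 0.20, 0.25, 0.30),
                             t2 = c(0.30, 0.35, 0.40, 0.45)),
                           alpha = 0.5, redundancyFilter = TRUE) {
  thresholdPairs <- as.matrix(thresholdPairs)
  nets <- list()
  sweeps <- list()
  rows <- list()
  for (i in seq_len(nrow(thresholdPairs))) {
    t1 <- thresholdPairs[i, 1]
    t2 <- thresholdPairs[i, 2]
    key <- paste0(t1, "_", t2)
    net <- buildLogicNetwork(m, t1, t2, redundancyFilter)
    sw <- sweepAllTriggers(net, alpha)
    sm <- cascadeSummary(sw)
    nets[[key]] <- net
    sweeps[[key]] <- sw
    rows[[key]] <- cbind(data.frame(t1 = t1, t2 = t2),
                         networkSummary(net),
                         data.frame(RMax = sm$RMax, meanD = mean(sm$d)))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       networks = nets, sweeps = sweeps)
}
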