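#' Data-driven contribution split of a second-order relationship
#'
#' For OR-family logics the two inputs can act independently, so their
#' shares of the relationship's total out-degree are estimated from the
#' expression profiles. Writing la, lb for the input literals after the
#' logic's negations (e.g. for !A|B the literals are !A and B), the counts
#' over samples where the target is present are
#' \itemize{
#'   \item n0: both literals active (joint activation),
#'   \item n1: only the A-literal active,
#'   \item n2: only the B-literal active,
#' }
#' and the shares are \eqn{(n_0 + 2n_1)/2(n_0+n_1+n_2)} for A and
#' \eqn{(n_0 + 2n_2)/2(n_0+n_1+n_2)} for B; they always sum to 1. For
#' AND-family logics both inputs act jointly, and for XOR/XNOR the data
#' cannot apportion the regulation, so the split is (1/2, 1/2).
#'
#' @param a,b,target binary vectors of equal length.
#' @param logic two-input logic type name.
#' @return Numeric c(splitA, splitB), summing to 1. OR-family triplets
#'   with no supporting samples (n0 + n1 + n2 = 0) fall back to
#'   (1/2, 1/2) with a warning.
#' @examples
#' a <- c(1, 0, 0, 1); b <- c(1, 1, 0, 0)
#' contributionSplit(a, b, evaluateLogic("OR", a, b), "OR")
#' @export
contributionSplit <- function(a, b, target, logic) {
  i <- .logic2Row(logic)
  if (.LOGIC2$onesCount[i] != 3L) return(c(0.5, 0.5))
  a <- .checkBinary(a, "a")
  b <- .checkBinary(b, "b")
  target <- .checkBinary(target, "target")
  if (length(a) != length(b) || length(a) != length(target))
    stop("a, b and target must have equal length")
  la <- if (.LOGIC2$negA[i]) 1L - a else a
  lb <- if (.LOGIC2$negB[i]) 1L - b else b
  n0 <- sum(la & lb & target)
  n1 <- sum(la & !lb & target)
  n2 <- sum(!la & lb & target)
  tot <- n0 + n1 + n2
  if (tot == 0) {
    warning("no supporting samples for OR-family split; using (1/2, 1/2)")
    return(c(0.5, 0.5))
  }
  c((n0 + 2 * n1) / (2 * tot), (n0 + 2 * n2) / (2 * tot))
}

#' Degree increments of a logic relationship
#'
#' A two-input relationship with k satisfying assignments adds k/2 to the
#' in-degree of its target (1/2 for AND-family, 1 for XOR/XNOR, 3/2 for
#' OR-family); the total out-degree added equals that in-degree increment
#' and is divided between the inputs by their contribution split. A
#' single-input relationship adds 1 to both sides. Out- and in-degree
#' totals are therefore conserved across the network.
#'
#' @param logic logic type name (any arity).
#' @param splitA,splitB contribution fractions (ignored for single-input
#'   logics; default equal split).
#' @return Named numeric: \code{outA}, \code{outB} (NA for single-input),
#'   \code{inTarget}.
#' @examples
#' degreeIncrements("AND")  # 1/4, 1/4, 1/2
#' degreeIncrements("OR")   # 3/4, 3/4, 3/2
#' degreeIncrements("XOR")  # 1/2, 1/2, 1
#' @export
degreeIncrements <- function(logic, splitA = 0.5, splitB = 0.5) {
  arity <- .logicArity(logic)
  if (is.na(arity)) stop("unknown logic type: ", logic)
  if (arity == 1L)
    return(c(outA = 1, outB = NA_real_, inTarget = 1))
  if (abs(splitA + splitB - 1) > 1e-9)
    stop("splitA + splitB must equal 1")
  inc <- .onesCount(logic) / 2
  c(outA = splitA * inc, outB = splitB * inc, inTarget = inc)
}

## Vectorized first-order U for all ordered gene pairs.
## Returns list(U = genes x genes matrix with U[j, i] = U(target i | source j),
##              agree = co-occurrence agreement counts, H = marginal entropies).
.pairwiseU <- function(M) {
  n <- ncol(M)
  G <- nrow(M)
  R <- rowSums(M)
  H <- .H2(R / n)
  N11 <- tcrossprod(M)                       # joint presence counts
  N10 <- matrix(R, G, G) - N11               # source 1, target 0
  N01 <- matrix(R, G, G, byrow = TRUE) - N11 # source 0, target 1
  N00 <- n - N11 - N10 - N01
  Hj <- .jointH4(N11, N10, N01, N00, n)
  num <- matrix(H, G, G) + matrix(H, G, G, byrow = TRUE) - Hj
  U <- num / matrix(H, G, G, byrow = TRUE)   # denominator H(target)
  U[, H == 0] <- 0
  U <- pmin(pmax(U, 0), 1)
  diag(U) <- 0
  list(U = U, agree = N11 + N00, H = H)
}

## U of one composite vector w against all rows of M (targets).
.compositeU <- function(M, w, H) {
  n <- ncol(M)
  sw <- sum(w)
  Hw <- .H2(sw / n)
  R <- rowSums(M)
  n11 <- as.vector(M %*% w)
  n10 <- R - n11
  n01 <- sw - n11
  n00 <- n - n11 - n10 - n01
  Hj <- .jointH4(n11, n10, n01, n00, n)
  U <- (H + Hw - Hj) / H
  U[H == 0] <- 0
  pmin(pmax(U, 0), 1)
}

#' Infer a logic network from a binary expression matrix
#'
#' Scores every ordered gene pair with the first-order uncertainty
#' coefficient and every gene triplet with the second-order coefficient
#' under all ten two-input Boolean logic types, then thresholds: pairs are
#' kept at \code{U >= t1}, triplets at \code{U >= t2}. Constant genes
#' (zero entropy) carry no regulatory signal and are excluded as targets
#' with a warning.
#'
#' First-order edges are labelled DIRECT when the profiles agree on at
#' least half the samples and INVERTED otherwise (complementing a profile
#' leaves U unchanged, so orientation of the input literal is recovered
#' from the sign of association, not from U). For each (input pair,
#' target) at most one logic type is retained: the one with maximal U,
#' ties broken by the fixed catalogue row order. With
#' \code{redundancyFilter = TRUE} (default) a triplet is kept only when
#' its U strictly exceeds both constituent first-order coefficients
#' U(C|A) and U(C|B), so second-order relationships are non-redundant
#' with pairwise ones.
#'
#' Output ordering is deterministic: edges sorted by (source, target),
#' triplets by (inputA, inputB, target) with inputA < inputB
#' lexicographically.
#'
#' @param m a \linkS4class{BinaryExpressionMatrix}.
#' @param t1 first-order threshold, 0 < t1 <= t2.
#' @param t2 second-order threshold, t1 <= t2 < 1.
#' @param redundancyFilter keep only triplets stronger than both of their
#'   first-order margins (default TRUE).
#' @return A \linkS4class{LogicNetwork} over all genes of \code{m}.
#' @examples
#' set.seed(1)
#' A <- rbinom(40, 1, 0.5); B <- rbinom(40, 1, 0.5)
#' m <- BinaryExpressionMatrix(rbind(gA = A, gB = B,
#'                                   gC = evaluateLogic("OR", A, B)))
#' net <- buildLogicNetwork(m, 0.20, 0.35)
#' secondOrderTriplets(net)
#' @export
buildLogicNetwork <- function(m, t1, t2, redundancyFilter = TRUE) {
  stopifnot(is(m, "BinaryExpressionMatrix"))
  if (!is.numeric(t1) || !is.numeric(t2) || t1 <= 0 || t2 < t1 || t2 >= 1)
    stop("thresholds must satisfy 0 < t1 <= t2 < 1")
  M <- m@values
  ids <- rownames(M)
  G <- nrow(M)
  if (G < 3L) stop("triplet enumeration requires at least 3 genes")
  pw <- .pairwiseU(M)
  H <- pw$H
  if (any(H == 0))
    warning("constant gene(s) excluded as regulatory targets: ",
            paste(ids[H == 0], collapse = ", "))

  ## ---- first-order edges ----
  keep <- which(pw$U >= t1 & row(pw$U) != col(pw$U), arr.ind = TRUE)
  edges <- .emptyEdgeFrame()
  if (nrow(keep)) {
    agree <- pw$agree[keep]
    edges <- data.frame(
      source = ids[keep[, 1]], target = ids[keep[, 2]],
      logic = ifelse(agree >= ncol(M) - agree, "DIRECT", "INVERTED"),
      weight = pw$U[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  }

  ## ---- second-order triplets ----
  ## Unordered input pairs in lexicographic id order; asymmetric types are
  ## evaluated once on that canonical orientation (the ten types on the
  ## ordered pair already cover all distinct two-input functions).
  ord <- order(ids)
  res <- vector("list", 64L)
  nres <- 0L
  for (ii in seq_len(G - 1L)) {
    for (jj in seq.int(ii + 1L, G)) {
      gi <- ord[ii]; gj <- ord[jj]
      a <- M[gi, ]; b <- M[gj, ]
      Umat <- vapply(.LOGIC2$name, function(lg)
        .compositeU(M, evaluateLogic(lg, a, b), H), numeric(G))
      Umat[c(gi, gj), ] <- 0        # targets must differ from inputs
      Umat[H == 0, ] <- 0           # constant targets excluded
      if (redundancyFilter) {
        margin <- pmax(pw$U[gi, ], pw$U[gj, ])
        Umat[Umat <= margin] <- 0
      }
      best <- max.col(Umat, ties.method = "first")  # catalogue row order
      bestU <- Umat[cbind(seq_len(G), best)]
      hit <- which(bestU >= t2)
      if (length(hit)) {
        nres <- nres + 1L
        if (nres > length(res)) res <- c(res, vector("list", length(res)))
        res[[nres]] <- data.frame(
          inputA = ids[gi], inputB = ids[gj], target = ids[hit],
          logic = .LOGIC2$name[best[hit]], weight = bestU[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  triplets <- .emptyTripletFrame()
  if (nres) {
    triplets <- do.call(rbind, res[seq_len(nres)])
    sp <- t(mapply(function(ai, bi, ti, lg)
      contributionSplit(M[ai, ], M[bi, ], M[ti, ], lg),
      triplets$inputA, triplets$inputB, triplets$target, triplets$logic))
    triplets$splitA <- sp[, 1]
    triplets$splitB <- sp[, 2]
    triplets <- triplets[order(triplets$inputA, triplets$inputB,
                               triplets$target), , drop = FALSE]
  }
  LogicNetwork(ids, edges, triplets, thresholds = c(t1, t2))
}

## Accumulate a named vector of per-node sums: base for strengths/degrees.
.accumulate <- function(ids, keys, vals) {
  out <- numeric(length(ids))
  names(out) <- ids
  if (length(keys)) {
    s <- rowsum(vals, keys)
    out[rownames(s)] <- out[rownames(s)] + s[, 1]
  }
  out
}

## Strengths over raw relationship frames (used per cascade round without
## paying S4 construction costs).
.strengths <- function(ids, edges, triplets) {
  inS <- .accumulate(ids, edges$target, edges$weight)
  outS <- .accumulate(ids, edges$source, edges$weight)
  if (nrow(triplets)) {
    inc <- .onesCount(triplets$logic) / 2
    inS <- inS + .accumulate(ids, triplets$target, triplets$weight * inc)
    outS <- outS +
      .accumulate(ids, triplets$inputA,
                  triplets$weight * triplets$splitA * inc) +
      .accumulate(ids, triplets$inputB,
                  triplets$weight * triplets$splitB * inc)
  }
  list(inS = inS, outS = outS)
}

#' Degree strengths and loads of all nodes
#'
#' In-degree strength of a node is the U-weighted sum over relationships
#' targeting it (each second-order relationship weighted by its in-degree
#' increment k/2); out-degree strength is the U-weighted sum over
#' relationships it feeds, weighted by its out-degree increment
#' (contribution split times k/2). Totals are conserved:
#' sum of in-strengths = sum of out-strengths.
#'
#' The load of a non-isolated node is the ratio in-strength/out-strength:
#' 0 when the in-strength is 0, \code{Inf} when the out-strength is 0, a
#' positive real otherwise. Isolated nodes (both strengths 0) have no
#' load (\code{NA}) and are flagged.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @return data.frame with one row per gene: \code{gene},
#'   \code{inStrength}, \code{outStrength}, \code{load},
#'   \code{isolated}.
#' @examples
#' net <- generateToyNetwork(c("A", "C"),
#'   edges = data.frame(source = "A", target = "C",
#'                      logic = "DIRECT", weight = 0.4))
#' strengthTable(net)
#' @export
strengthTable <- function(net) {
  stopifnot(is(net, "LogicNetwork"))
  st <- .strengths(net@geneIds, net@firstOrder, net@secondOrder)
  .loadFrame(net@geneIds, st$inS, st$outS)
}

.loadFrame <- function(ids, inS, outS) {
  isolated <- inS == 0 & outS == 0
  load <- ifelse(inS == 0, 0, ifelse(outS == 0, Inf, inS / outS))
  load[isolated] <- NA_real_
  data.frame(gene = ids, inStrength = unname(inS),
             outStrength = unname(outS), load = unname(load),
             isolated = unname(isolated), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Unweighted in-/out-degrees of all nodes
#'
#' Degree accounting with the per-relationship increments of
#' [degreeIncrements()]: a single-input edge adds 1 to both endpoints; a
#' two-input relationship adds k/2 to its target's in-degree, divided
#' between the inputs' out-degrees by the contribution split. Totals are
#' conserved.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @return data.frame with columns \code{gene}, \code{inDegree},
#'   \code{outDegree}.
#' @export
degreeTable <- function(net) {
  stopifnot(is(net, "LogicNetwork"))
  ids <- net@geneIds
  e <- net@firstOrder
  tr <- net@secondOrder
  inD <- .accumulate(ids, e$target, rep(1, nrow(e)))
  outD <- .accumulate(ids, e$source, rep(1, nrow(e)))
  if (nrow(tr)) {
    inc <- .onesCount(tr$logic) / 2
    inD <- inD + .accumulate(ids, tr$target, inc)
    outD <- outD + .accumulate(ids, tr$inputA, tr$splitA * inc) +
      .accumulate(ids, tr$inputB, tr$splitB * inc)
  }
  data.frame(gene = ids, inDegree = unname(inD), outDegree = unname(outD),
             stringsAsFactors = FALSE, row.names = NULL)
}
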