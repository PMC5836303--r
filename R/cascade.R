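#' Load at a node
#'
#' The load of a non-isolated node is the ratio of its in-degree strength
#' to its out-degree strength: 0 when the in-strength is 0 (pure
#' regulator), \code{Inf} when the out-strength is 0 (pure target), and a
#' positive real otherwise. A node with both strengths zero is isolated
#' and carries no load: the distinct sentinel \code{NA} is returned.
#'
#' @param inStrength,outStrength nonnegative degree strengths.
#' @return Load: 0, positive real, \code{Inf}, or \code{NA} (isolated).
#' @examples
#' nodeLoad(0, 2.5)   # 0
#' nodeLoad(1.2, 0)   # Inf
#' nodeLoad(2, 4)     # 0.5
#' @export
nodeLoad <- function(inStrength, outStrength) {
  if (inStrength < 0 || outStrength < 0)
    stop("strengths must be nonnegative")
  if (inStrength == 0 && outStrength == 0) return(NA_real_)
  if (inStrength == 0) return(0)
  if (outStrength == 0) return(Inf)
  inStrength / outStrength
}

#' Initial capacity interval of a node
#'
#' The capacity of a node with initial load l is the load interval it
#' tolerates: \eqn{[(1-\alpha)l, (1+\alpha)l]} for finite positive l,
#' the point \{0\} for l = 0, and \{+Inf\} for l = Inf. The capacity
#' parameter alpha in (0, 1) is the relative half-width: larger alpha
#' means a more tolerant node.
#'
#' @param load initial load (from [nodeLoad()]).
#' @param alpha capacity parameter in (0, 1).
#' @return Numeric c(C, D), the lower and upper capacity limits.
#' @examples
#' capacityInterval(2, 0.5)   # 1 3
#' capacityInterval(0, 0.5)   # 0 0
#' capacityInterval(Inf, 0.2) # Inf Inf
#' @export
capacityInterval <- function(load, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (is.na(load)) stop("isolated nodes have no capacity interval")
  if (load == 0) return(c(0, 0))
  if (is.infinite(load)) return(c(Inf, Inf))
  c((1 - alpha) * load, (1 + alpha) * load)
}

#' Is a redistributed load within a capacity interval?
#'
#' Membership conventions: the point interval \{0\} contains only load 0;
#' the interval \{+Inf\} contains only load +Inf; the isolated sentinel
#' (\code{NA}) is never within any interval; finite intervals use a
#' relative tolerance of 1e-9 at the boundaries so that summation
#' round-off does not fail a node spuriously.
#'
#' @param newLoad recomputed load (0, positive, Inf, or NA).
#' @param interval numeric c(C, D) from [capacityInterval()].
#' @return TRUE iff the load lies within the interval.
#' @examples
#' withinCapacity(0, c(0, 0))    # TRUE
#' withinCapacity(0, c(1, 3))    # FALSE
#' withinCapacity(Inf, c(1, 3))  # FALSE
#' @export
withinCapacity <- function(newLoad, interval) {
  tol <- 1e-9
  if (is.na(newLoad)) return(FALSE)
  C <- interval[1]; D <- interval[2]
  if (C == 0 && D == 0) return(newLoad == 0)
  if (is.infinite(C)) return(is.infinite(newLoad))
  if (newLoad == 0 || is.infinite(newLoad)) return(FALSE)
  newLoad >= C * (1 - tol) && newLoad <= D * (1 + tol)
}

## Internal cascade core over raw frames. Returns list(failed, rounds).
.cascadeCore <- function(ids, edges, triplets, trig, alpha,
                         isolatedPolicy = "fail", tol = 1e-9) {
  st0 <- .strengths(ids, edges, triplets)
  inS0 <- st0$inS; outS0 <- st0$outS
  initIsolated <- ids[inS0 == 0 & outS0 == 0]
  ## initial load class and finite capacity limits, per node
  load0 <- ifelse(inS0 == 0, 0, ifelse(outS0 == 0, Inf, inS0 / outS0))
  cls0 <- ifelse(inS0 == 0 & outS0 == 0, "isolated",
                 ifelse(inS0 == 0, "zero",
                        ifelse(outS0 == 0, "inf", "finite")))
  Cl <- (1 - alpha) * load0
  Dl <- (1 + alpha) * load0
  names(cls0) <- names(Cl) <- names(Dl) <- ids

  alive <- setdiff(ids, trig)
  failed <- trig
  rounds <- list(trig)
  e <- edges; tr <- triplets
  repeat {
    if (nrow(e))
      e <- e[e$source %in% alive & e$target %in% alive, , drop = FALSE]
    if (nrow(tr))
      tr <- tr[tr$inputA %in% alive & tr$inputB %in% alive &
                 tr$target %in% alive, , drop = FALSE]
    st <- .strengths(alive, e, tr)
    inS <- st$inS; outS <- st$outS
    ## nodes isolated in the intact network never fail (they have no
    ## capacity to violate); everything else is checked against its
    ## initial interval
    check <- alive[cls0[alive] != "isolated"]
    if (!length(check)) break
    ci <- inS[check]; co <- outS[check]
    nowIso <- ci == 0 & co == 0
    nowLoad <- ifelse(ci == 0, 0, ifelse(co == 0, Inf, ci / co))
    cls <- cls0[check]
    ok <- logical(length(check))
    ok[cls == "zero"] <- !nowIso[cls == "zero"] &
      nowLoad[cls == "zero"] == 0
    ok[cls == "inf"] <- !nowIso[cls == "inf"] &
      is.infinite(nowLoad[cls == "inf"])
    fin <- cls == "finite"
    ok[fin] <- !nowIso[fin] & nowLoad[fin] > 0 &
      is.finite(nowLoad[fin]) &
      nowLoad[fin] >= Cl[check][fin] * (1 - tol) &
      nowLoad[fin] <= Dl[check][fin] * (1 + tol)
    if (isolatedPolicy == "inert") {
      ## newly isolated nodes persist instead of failing
      ok[nowIso] <- TRUE
    }
    newFailed <- check[!ok]
    if (!length(newFailed)) break
    failed <- c(failed, newFailed)
    rounds <- c(rounds, list(newFailed))
    alive <- setdiff(alive, newFailed)
  }
  list(failed = failed, rounds = rounds)
}

#' Run one single-trigger cascading failure
#'
#' Implements the degree-strength cascading failure model (D-SCFM).
#' Loads and capacity intervals of all nodes are fixed once from the
#' intact network; the trigger node and all its relationships are then
#' deleted (a triplet is removed entirely when any of its three genes is
#' removed), and failure propagates in synchronous rounds: the loads of
#' all surviving nodes are recomputed on the current network and every
#' node whose load has left its initial capacity interval fails, together
#' (by default) with every newly isolated node. Failed nodes and their
#' relationships are removed and the round repeats until no further
#' failure occurs. Termination is guaranteed because the failed set grows
#' strictly each round.
#'
#' Nodes that are isolated in the intact network have no load and never
#' fail, but still count in N for size ratios.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @param trigger gene id of the node deleted initially.
#' @param alpha capacity parameter in (0, 1).
#' @param isolatedPolicy \code{"fail"} (default): nodes isolated by the
#'   cascade fail and are removed; \code{"inert"}: they persist, for
#'   sensitivity analysis.
#' @return A \linkS4class{CascadeOutcome}.
#' @examples
#' net <- generateToyNetwork(c("A", "B", "C", "D"),
#'   edges = data.frame(source = c("A", "A", "C"),
#'                      target = c("B", "C", "D"),
#'                      logic = "DIRECT", weight = 0.5))
#' runCascade(net, "A", alpha = 0.5)  # full collapse: s = 4
#' @export
runCascade <- function(net, trigger, alpha,
                       isolatedPolicy = c("fail", "inert")) {
  stopifnot(is(net, "LogicNetwork"))
  isolatedPolicy <- match.arg(isolatedPolicy)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!(trigger %in% net@geneIds))
    stop("unknown trigger node: ", trigger)
  res <- .cascadeCore(net@geneIds, net@firstOrder, net@secondOrder,
                      trigger, alpha, isolatedPolicy)
  N <- length(net@geneIds)
  s <- length(res$failed)
  new("CascadeOutcome", trigger = trigger, failed = res$failed,
      rounds = res$rounds, s = as.integer(s), d = s / N,
      N = as.integer(N))
}

#' Cascade outcomes for every trigger node
#'
#' Runs [runCascade()] once per node of the network, each from the same
#' intact state, in \code{geneIds} order.
#'
#' @inheritParams runCascade
#' @return List of \linkS4class{CascadeOutcome}, named by trigger.
#' @seealso [cascadeSummary()] for R_max and the cumulative cascade
#'   probability curve.
#' @export
sweepAllTriggers <- function(net, alpha,
                             isolatedPolicy = c("fail", "inert")) {
  stopifnot(is(net, "LogicNetwork"))
  isolatedPolicy <- match.arg(isolatedPolicy)
  out <- lapply(net@geneIds, function(g)
    runCascade(net, g, alpha, isolatedPolicy))
  names(out) <- net@geneIds
  out
}
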