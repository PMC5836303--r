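# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: entropies are tabulated from the full empirical
# joint distribution with table(), and the cascade oracle rebuilds the
# surviving network from scratch every round with plain loops.

oracle_entropy <- function(...) {
  states <- do.call(paste, list(...))
  p <- as.vector(table(states)) / length(states)
  -sum(p * log2(p))
}

oracle_U <- function(pred, targ, base = 2) {
  H <- function(...) {
    states <- do.call(paste, list(...))
    p <- as.vector(table(states)) / length(states)
    -sum(p * log(p, base = base))
  }
  (H(pred) + H(targ) - H(pred, targ)) / H(targ)
}

# Strengths by explicit iteration over relationship rows.
oracle_strengths <- function(ids, edges, triplets) {
  inS <- stats::setNames(numeric(length(ids)), ids)
  outS <- inS
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      outS[edges$source[i]] <- outS[edges$source[i]] + edges$weight[i]
      inS[edges$target[i]] <- inS[edges$target[i]] + edges$weight[i]
    }
  }
  if (nrow(triplets)) {
    k <- c(AND = 1, NAND = 3, OR = 3, NOR = 1, A_AND_NOTB = 1,
           NOTA_AND_B = 1, NOTA_OR_B = 3, A_OR_NOTB = 3, XNOR = 2,
           XOR = 2)
    for (i in seq_len(nrow(triplets))) {
      inc <- k[[triplets$logic[i]]] / 2
      w <- triplets$weight[i]
      inS[triplets$target[i]] <- inS[triplets$target[i]] + w * inc
      outS[triplets$inputA[i]] <- outS[triplets$inputA[i]] +
        w * triplets$splitA[i] * inc
      outS[triplets$inputB[i]] <- outS[triplets$inputB[i]] +
        w * triplets$splitB[i] * inc
    }
  }
  list(inS = inS, outS = outS)
}

# Fixpoint cascade rebuilt from scratch each round.
oracle_cascade <- function(net, trig, alpha) {
  ids <- geneIds(net)
  edges <- firstOrderEdges(net)
  triplets <- secondOrderTriplets(net)
  st0 <- oracle_strengths(ids, edges, triplets)
  initIso <- ids[st0$inS == 0 & st0$outS == 0]
  load0 <- ifelse(st0$inS == 0, 0,
                  ifelse(st0$outS == 0, Inf, st0$inS / st0$outS))
  names(load0) <- ids
  removed <- trig
  rounds <- list(trig)
  repeat {
    alive <- setdiff(ids, removed)
    e <- edges[edges$source %in% alive & edges$target %in% alive, ,
               drop = FALSE]
    tr <- triplets[triplets$inputA %in% alive &
                     triplets$inputB %in% alive &
                     triplets$target %in% alive, , drop = FALSE]
    st <- oracle_strengths(alive, e, tr)
    fails <- character()
    for (g in alive) {
      if (g %in% initIso) next
      ci <- st$inS[[g]]; co <- st$outS[[g]]
      l0 <- load0[[g]]
      if (ci == 0 && co == 0) { fails <- c(fails, g); next }
      l <- if (ci == 0) 0 else if (co == 0) Inf else ci / co
      ok <- if (l0 == 0) l == 0
            else if (is.infinite(l0)) is.infinite(l)
            else is.finite(l) && l > 0 &&
              l >= (1 - alpha) * l0 * (1 - 1e-9) &&
              l <= (1 + alpha) * l0 * (1 + 1e-9)
      if (!ok) fails <- c(fails, g)
    }
    if (!length(fails)) break
    removed <- c(removed, fails)
    rounds <- c(rounds, list(fails))
  }
  list(failed = removed, rounds = rounds)
}

# Small random graph for exhaustive cascade comparisons.
random_small_network <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  randomLogicNetwork(nNodes = n,
                     nEdges = sample(0:4, 1),
                     nTriplets = sample(0:3, 1),
                     seed = seed + 10000L)
}
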