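## Registry of supported Boolean regulation types.
## Two-input types in the canonical row order of the degree-accounting
## table: AND-family rows have one satisfying assignment (onesCount 1),
## OR-family three, equivalence/exclusive-or two. That count k drives the
## in-degree increment k/2 of the target.
.LOGIC2 <- data.frame(
  name      = c("AND", "NAND", "OR", "NOR",
                "A_AND_NOTB", "NOTA_AND_B", "NOTA_OR_B", "A_OR_NOTB",
                "XNOR", "XOR"),
  display   = c("A&B", "!A|!B", "A|B", "!A&!B",
                "A&!B", "!A&B", "!A|B", "A|!B",
                "A<->B", "A<->!B"),
  op        = c("and", "or", "or", "and",
                "and", "and", "or", "or",
                "xnor", "xor"),
  negA      = c(FALSE, TRUE, FALSE, TRUE,
                FALSE, TRUE, TRUE, FALSE,
                FALSE, FALSE),
  negB      = c(FALSE, TRUE, FALSE, TRUE,
                TRUE, FALSE, FALSE, TRUE,
                FALSE, FALSE),
  onesCount = c(1L, 3L, 3L, 1L, 1L, 1L, 3L, 3L, 2L, 2L),
  symmetric = c(TRUE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE),
  row       = 1:10,
  stringsAsFactors = FALSE)

.LOGIC1 <- data.frame(
  name      = c("DIRECT", "INVERTED"),
  display   = c("A", "!A"),
  onesCount = c(1L, 1L),
  row       = 1:2,
  stringsAsFactors = FALSE)

.logic2Row <- function(logic) {
  i <- match(logic, .LOGIC2$name)
  if (anyNA(i)) stop("unknown second-order logic type: ",
                     paste(logic[is.na(i)], collapse = ", "))
  i
}

.checkBinary <- function(v, what = "vector") {
  if (length(v) == 0L) stop(what, " must be non-empty")
  if (anyNA(v) || !all(v == 0 | v == 1))
    stop(what, " must contain only 0/1 values")
  as.integer(v)
}

## Binary entropy of a Bernoulli(p) source, in bits; vectorized over p.
.H2 <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  h
}

## Joint entropy (bits) from 2x2 cell counts; vectorized over cells.
.jointH4 <- function(n11, n10, n01, n00, n) {
  term <- function(k) {
    t <- numeric(length(k))
    pos <- k > 0
    p <- k[pos] / n
    t[pos] <- -p * log2(p)
    t
  }
  term(n11) + term(n10) + term(n01) + term(n00)
}

#' Shannon entropy of a binary vector
#'
#' Entropy in bits of the empirical distribution of a presence/absence
#' profile: \eqn{H = -\sum_x p(x) \log_2 p(x)} with \eqn{0 \log 0 = 0}.
#' For a binary vector the result lies in [0, 1].
#'
#' @param v binary vector (entries 0/1, non-empty).
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(c(1, 1, 0, 0))  # 1
#' shannonEntropy(c(1, 0, 0, 0))  # 0.8113
#' @export
shannonEntropy <- function(v) {
  v <- .checkBinary(v, "v")
  .H2(mean(v))
}

#' Joint Shannon entropy of two binary vectors
#'
#' Entropy in bits of the empirical joint distribution over the paired
#' states of \code{u} and \code{v}. Always at least the larger marginal
#' entropy and at most their sum.
#'
#' @param u,v binary vectors of equal length.
#' @return Joint entropy in bits.
#' @examples
#' jointEntropy(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 1.5
#' @export
jointEntropy <- function(u, v) {
  u <- .checkBinary(u, "u")
  v <- .checkBinary(v, "v")
  if (length(u) != length(v)) stop("u and v must have equal length")
  n <- length(u)
  n11 <- sum(u & v)
  n10 <- sum(u) - n11
  n01 <- sum(v) - n11
  n00 <- n - n11 - n10 - n01
  .jointH4(n11, n10, n01, n00, n)
}

## Core of the uncertainty coefficient from 2x2 counts; returns 0 for a
## constant target when constantTarget = "zero". Hw and Hc cancel base,
## so U is invariant to the entropy log base.
.Ucounts <- function(n11, n10, n01, n00, n, constantTarget = "zero") {
  pc <- (n11 + n01) / n          # target presence rate
  Hc <- .H2(pc)
  if (Hc == 0) {
    if (identical(constantTarget, "error"))
      stop("target vector is constant: uncertainty coefficient undefined")
    return(0)
  }
  Hw <- .H2((n11 + n10) / n)
  Hcw <- .jointH4(n11, n10, n01, n00, n)
  u <- (Hc + Hw - Hcw) / Hc
  ## clamp summation round-off into [0, 1]
  min(max(u, 0), 1)
}

#' First-order uncertainty coefficient U(C | A)
#'
#' Normalized mutual information
#' \deqn{U(C|A) = \frac{H(A) + H(C) - H(A, C)}{H(C)}}
#' interpreted as the probability that the regulator explains the target:
#' the fraction of the target's entropy removed by knowing the source.
#' Lies in [0, 1]; 1 iff the target is a deterministic function of the
#' source, 0 iff their empirical distributions are independent.
#'
#' @param source,target binary vectors of equal length (source = candidate
#'   regulator A, target = regulated gene C).
#' @param constantTarget \code{"zero"} (default) returns 0 with a warning
#'   when the target is constant (H(C) = 0, no regulatory signal);
#'   \code{"error"} raises an error instead.
#' @return U in [0, 1].
#' @examples
#' firstOrderU(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.3837
#' @export
firstOrderU <- function(source, target, constantTarget = c("zero", "error")) {
  constantTarget <- match.arg(constantTarget)
  source <- .checkBinary(source, "source")
  target <- .checkBinary(target, "target")
  if (length(source) != length(target))
    stop("source and target must have equal length")
  n <- length(source)
  if (all(target == target[1]) && constantTarget == "zero")
    warning("constant target vector: U defined as 0")
  n11 <- sum(source & target)
  n10 <- sum(source) - n11
  n01 <- sum(target) - n11
  .Ucounts(n11, n10, n01, n - n11 - n10 - n01, n, constantTarget)
}

#' Second-order uncertainty coefficient U(C | f2(A, B))
#'
#' Evaluates the composite regulator \eqn{w = f_2(A, B)} elementwise with
#' one of the ten two-input Boolean functions, then scores
#' \deqn{U(C | f_2(A,B)) = \frac{H(C) + H(w) - H(C, w)}{H(C)},}
#' the probability that the pair (A, B), combined by that logic, regulates
#' target C.
#'
#' @param a,b,target binary vectors of equal length.
#' @param logic name of a two-input logic type; see [logicFunctions()].
#' @param constantTarget as in [firstOrderU()].
#' @return U in [0, 1].
#' @examples
#' a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
#' secondOrderU(a, b, evaluateLogic("OR", a, b), "OR")  # 1: C = A|B exactly
#' @export
secondOrderU <- function(a, b, target, logic,
                         constantTarget = c("zero", "error")) {
  constantTarget <- match.arg(constantTarget)
  a <- .checkBinary(a, "a")
  b <- .checkBinary(b, "b")
  target <- .checkBinary(target, "target")
  if (length(a) != length(b) || length(a) != length(target))
    stop("a, b and target must have equal length")
  w <- evaluateLogic(logic, a, b)
  if (all(target == target[1]) && constantTarget == "zero")
    warning("constant target vector: U defined as 0")
  n <- length(a)
  n11 <- sum(w & target)
  n10 <- sum(w) - n11
  n01 <- sum(target) - n11
  .Ucounts(n11, n10, n01, n - n11 - n10 - n01, n, constantTarget)
}

#' Evaluate a Boolean regulation function
#'
#' Applies one of the supported logic types elementwise to 0/1 input
#' vectors (or single bits): the two first-order types DIRECT (A) and
#' INVERTED (!A), and the ten two-input types of [logicFunctions()].
#'
#' @param logic logic type name.
#' @param a first input (0/1 vector).
#' @param b second input, required for the two-input types.
#' @return Integer 0/1 vector of the same length as the inputs.
#' @examples
#' evaluateLogic("AND", 1, 1)        # 1
#' evaluateLogic("INVERTED", 1)      # 0
#' evaluateLogic("NOTA_OR_B", c(1, 0), c(0, 0))  # 0 1
#' @export
evaluateLogic <- function(logic, a, b = NULL) {
  a <- .checkBinary(a, "a")
  if (logic %in% .LOGIC1$name) {
    if (!is.null(b)) stop("logic '", logic, "' takes a single input")
    return(if (logic == "DIRECT") a else 1L - a)
  }
  i <- .logic2Row(logic)
  if (is.null(b)) stop("logic '", logic, "' requires two inputs")
  b <- .checkBinary(b, "b")
  if (length(a) != length(b)) stop("a and b must have equal length")
  la <- if (.LOGIC2$negA[i]) 1L - a else a
  lb <- if (.LOGIC2$negB[i]) 1L - b else b
  switch(.LOGIC2$op[i],
         and  = la * lb,
         or   = 1L - (1L - la) * (1L - lb),
         xor  = (a + b) %% 2L,
         xnor = 1L - (a + b) %% 2L)
}

#' Catalogue of supported logic types
#'
#' The ten two-input Boolean regulation types (in the canonical row order
#' used for tie-breaking) and the two single-input types. \code{onesCount}
#' is the number of satisfying input assignments k; the in-degree
#' increment contributed to the target is k/2 for two-input types and 1
#' for single-input types.
#'
#' @return data.frame with columns \code{name}, \code{display},
#'   \code{arity}, \code{onesCount}, \code{symmetric}, \code{row}.
#' @examples
#' logicFunctions()
#' @export
logicFunctions <- function() {
  rbind(
    data.frame(name = .LOGIC2$name, display = .LOGIC2$display, arity = 2L,
               onesCount = .LOGIC2$onesCount,
               symmetric = .LOGIC2$symmetric, row = .LOGIC2$row,
               stringsAsFactors = FALSE),
    data.frame(name = .LOGIC1$name, display = .LOGIC1$display, arity = 1L,
               onesCount = .LOGIC1$onesCount, symmetric = NA,
               row = .LOGIC1$row, stringsAsFactors = FALSE))
}

## onesCount lookup for any logic name (1st or 2nd order)
.onesCount <- function(logic) {
  i2 <- match(logic, .LOGIC2$name)
  out <- .LOGIC2$onesCount[i2]
  i1 <- match(logic, .LOGIC1$name)
  out[is.na(i2)] <- .LOGIC1$onesCount[i1[is.na(i2)]]
  if (anyNA(out)) stop("unknown logic type")
  out
}

## arity lookup
.logicArity <- function(logic) {
  ifelse(logic %in% .LOGIC2$name, 2L,
         ifelse(logic %in% .LOGIC1$name, 1L, NA_integer_))
}
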