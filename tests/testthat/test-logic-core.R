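test_that("shannonEntropy matches closed forms and validates input", {
  expect_equal(shannonEntropy(c(0, 0, 0, 0)), 0)
  expect_equal(shannonEntropy(c(1, 1, 0, 0)), 1)
  expect_equal(shannonEntropy(c(1, 0, 0, 0)),
               -(1 / 4) * log2(1 / 4) - (3 / 4) * log2(3 / 4))
  expect_error(shannonEntropy(integer(0)), "non-empty")
  expect_error(shannonEntropy(c(0, 2)), "0/1")
})

test_that("jointEntropy matches the tabulated joint distribution", {
  expect_equal(jointEntropy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(jointEntropy(c(1, 1, 0, 0), c(1, 0, 0, 0)), 1.5)
  expect_equal(jointEntropy(c(1, 0), c(0, 1)), 1)
  expect_error(jointEntropy(c(1, 0), c(1, 0, 0)), "equal length")
  # bounds: max marginal <= joint <= sum of marginals, on random draws
  set.seed(42)
  for (i in 1:25) {
    u <- rbinom(8, 1, 0.5); v <- rbinom(8, 1, 0.5)
    h <- jointEntropy(u, v)
    expect_gte(h, max(shannonEntropy(u), shannonEntropy(v)) - 1e-12)
    expect_lte(h, shannonEntropy(u) + shannonEntropy(v) + 1e-12)
    expect_equal(h, oracle_entropy(u, v))
  }
})

test_that("first-order uncertainty coefficient matches the brute-force oracle", {
  expect_equal(firstOrderU(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(firstOrderU(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0)
  expect_equal(firstOrderU(c(1, 1, 0, 0), c(1, 0, 0, 0)),
               (1 + shannonEntropy(c(1, 0, 0, 0)) - 1.5) /
                 shannonEntropy(c(1, 0, 0, 0)))
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    a <- rbinom(n, 1, 0.5); c_ <- rbinom(n, 1, 0.5)
    if (all(c_ == c_[1])) next
    u <- firstOrderU(a, c_)
    expect_equal(u, oracle_U(a, c_), tolerance = 1e-12)
    expect_gte(u, 0); expect_lte(u, 1)
    # base invariance: the ratio cancels the entropy log base
    expect_equal(u, oracle_U(a, c_, base = exp(1)), tolerance = 1e-12)
  }
})

test_that("constant-target handling is configurable", {
  expect_warning(u <- firstOrderU(c(1, 0), c(1, 1)), "constant")
  expect_equal(u, 0)
  expect_error(firstOrderU(c(1, 0), c(1, 1), constantTarget = "error"),
               "constant")
})

test_that("second-order U is 1 for deterministic targets and 0 for constant composites", {
  # inputs covering all four assignments
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  for (lg in subset(logicFunctions(), arity == 2)$name) {
    w <- evaluateLogic(lg, a, b)
    if (all(w == w[1])) next
    expect_equal(secondOrderU(a, b, w, lg), 1)
  }
  # constant composite: A AND B over samples where it never fires
  expect_equal(secondOrderU(c(1, 0, 0), c(0, 1, 0), c(1, 0, 1), "AND"), 0)
})

test_that("second-order U matches the oracle and reduces to first order", {
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0); targ <- c(1, 0, 0, 1)
  w <- evaluateLogic("AND", a, b)
  expect_equal(w, c(1L, 0L, 0L, 0L))
  expect_equal(secondOrderU(a, b, targ, "AND"), oracle_U(w, targ),
               tolerance = 1e-12)
  expect_equal(oracle_U(w, targ), 0.3112781, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    targ <- rbinom(n, 1, 0.5)
    if (all(targ == targ[1])) next
    for (lg in c("OR", "NAND", "XOR", "A_AND_NOTB")) {
      expect_equal(secondOrderU(a, b, targ, lg),
                   oracle_U(evaluateLogic(lg, a, b), targ),
                   tolerance = 1e-12)
    }
    # a composite that just projects input a reproduces first-order U:
    # A OR A-literal is not in the catalogue, but A_AND_NOTB with b = 0
    # evaluates to a elementwise
    expect_equal(secondOrderU(a, rep(0, n), targ, "A_AND_NOTB"),
                 firstOrderU(a, targ), tolerance = 1e-12)
  }
})

test_that("logic truth tables agree with base R Boolean operators", {
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  ref <- list(
    AND = a & b, NAND = !(a & b), OR = a | b, NOR = !(a | b),
    A_AND_NOTB = a & !b, NOTA_AND_B = !a & b,
    NOTA_OR_B = !a | b, A_OR_NOTB = a | !b,
    XNOR = !xor(a, b), XOR = xor(a, b))
  for (lg in names(ref))
    expect_equal(evaluateLogic(lg, a, b), as.integer(ref[[lg]]),
                 info = lg)
  expect_equal(evaluateLogic("DIRECT", c(1, 0)), c(1L, 0L))
  expect_equal(evaluateLogic("INVERTED", c(1, 0)), c(0L, 1L))
  expect_error(evaluateLogic("NOPE", a, b), "unknown")
  expect_error(evaluateLogic("AND", a), "two inputs")
  expect_error(evaluateLogic("DIRECT", a, b), "single input")
})

test_that("onesCount follows the logic family", {
  lf <- subset(logicFunctions(), arity == 2)
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  for (i in seq_len(nrow(lf))) {
    expect_equal(sum(evaluateLogic(lf$name[i], a, b)), lf$onesCount[i],
                 info = lf$name[i])
  }
  expect_setequal(lf$onesCount[lf$name %in% c("AND", "NOR", "A_AND_NOTB",
                                              "NOTA_AND_B")], 1)
  expect_setequal(lf$onesCount[lf$name %in% c("XOR", "XNOR")], 2)
  expect_setequal(lf$onesCount[lf$name %in% c("OR", "NAND", "NOTA_OR_B",
                                              "A_OR_NOTB")], 3)
})
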