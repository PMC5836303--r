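test_that("contribution split follows the support counts for OR-family logic", {
  # n1 = n2 = 1, n0 = 0: balanced independent activation
  expect_equal(contributionSplit(c(1, 0), c(0, 1), c(1, 1), "OR"),
               c(0.5, 0.5))
  # n0 = 1, n1 = 1, n2 = 0
  expect_equal(contributionSplit(c(1, 1), c(1, 0), c(1, 1), "OR"),
               c(3 / 4, 1 / 4))
  # negated literals: !A|B counts rows where !A is active
  # row 1: !A and B both active with C on (n0); row 2: only !A (n1)
  expect_equal(contributionSplit(c(0, 0), c(1, 0), c(1, 1), "NOTA_OR_B"),
               c(3 / 4, 1 / 4))
  # XOR and AND-family: the data cannot apportion the regulation
  expect_equal(contributionSplit(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0),
                                 "XOR"), c(0.5, 0.5))
  expect_equal(contributionSplit(c(1, 0), c(1, 0), c(1, 0), "AND"),
               c(0.5, 0.5))
  # no supporting samples: fall back with a warning
  expect_warning(sp <- contributionSplit(c(0, 0), c(0, 0), c(1, 1), "OR"),
                 "supporting")
  expect_equal(sp, c(0.5, 0.5))
  # splits always sum to 1 on random inputs
  set.seed(3)
  for (i in 1:20) {
    a <- rbinom(10, 1, 0.5); b <- rbinom(10, 1, 0.5)
    targ <- rbinom(10, 1, 0.7)
    sp <- suppressWarnings(contributionSplit(a, b, targ, "A_OR_NOTB"))
    expect_equal(sum(sp), 1)
  }
})

test_that("degree increments match the accounting table and conserve totals", {
  expect_equal(degreeIncrements("AND"),
               c(outA = 1 / 4, outB = 1 / 4, inTarget = 1 / 2))
  expect_equal(degreeIncrements("OR"),
               c(outA = 3 / 4, outB = 3 / 4, inTarget = 3 / 2))
  expect_equal(degreeIncrements("XOR"),
               c(outA = 1 / 2, outB = 1 / 2, inTarget = 1))
  expect_equal(degreeIncrements("DIRECT"),
               c(outA = 1, outB = NA, inTarget = 1))
  # uneven splits still conserve out = in
  inc <- degreeIncrements("NOTA_OR_B", 0.8, 0.2)
  expect_equal(inc[["outA"]] + inc[["outB"]], inc[["inTarget"]])
  # a second-order relationship carried by a single effective input
  # reproduces the first-order accounting
  inc <- degreeIncrements("XOR", 1, 0)
  expect_equal(unname(inc), c(1, 0, 1))
  expect_error(degreeIncrements("XOR", 0.7, 0.7), "equal 1")
  expect_error(degreeIncrements("BOGUS"), "unknown")
})

test_that("a deterministic OR target is recovered with weight 1", {
  set.seed(5)
  A <- rbinom(40, 1, 0.5); B <- rbinom(40, 1, 0.5)
  m <- BinaryExpressionMatrix(rbind(gA = A, gB = B,
                                    gC = evaluateLogic("OR", A, B)))
  net <- buildLogicNetwork(m, 0.20, 0.35)
  tr <- secondOrderTriplets(net)
  hit <- tr[tr$target == "gC", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$logic, "OR")
  expect_equal(hit$weight, 1)
  expect_gte(min(firstOrderEdges(net)$weight, Inf), 0.20)
})

test_that("independent genes at large n produce an empty network", {
  set.seed(9)
  m <- BinaryExpressionMatrix(
    matrix(rbinom(5 * 400, 1, 0.5), nrow = 5,
           dimnames = list(paste0("g", 1:5), NULL)))
  net <- buildLogicNetwork(m, 0.30, 0.45)
  expect_equal(nrow(firstOrderEdges(net)), 0)
  expect_equal(nrow(secondOrderTriplets(net)), 0)
  expect_equal(geneIds(net), paste0("g", 1:5))  # nodes retained
})

test_that("threshold validation and small-matrix errors", {
  m <- BinaryExpressionMatrix(rbind(a = c(1, 0), b = c(0, 1)))
  expect_error(buildLogicNetwork(m, 0.2, 0.35), "at least 3 genes")
  m3 <- BinaryExpressionMatrix(rbind(a = c(1, 0), b = c(0, 1),
                                     c = c(1, 1)))
  expect_error(buildLogicNetwork(m3, 0, 0.3), "thresholds")
  expect_error(buildLogicNetwork(m3, 0.4, 0.3), "thresholds")
  expect_error(buildLogicNetwork(m3, 0.2, 1), "thresholds")
})

test_that("constant genes are excluded as targets with a warning", {
  set.seed(13)
  A <- rbinom(30, 1, 0.5); B <- rbinom(30, 1, 0.5)
  m <- BinaryExpressionMatrix(rbind(gA = A, gB = B,
                                    gK = rep(1L, 30)))
  expect_warning(net <- buildLogicNetwork(m, 0.2, 0.35), "gK")
  expect_false("gK" %in% firstOrderEdges(net)$target)
  expect_false("gK" %in% secondOrderTriplets(net)$target)
})

test_that("raising thresholds never adds relationships (nesting)", {
  gm <- generateMatrix(planted_family_design(seed = 21, noise = 0.05))
  pairs <- cbind(t1 = c(0.15, 0.20, 0.25, 0.30),
                 t2 = c(0.30, 0.35, 0.40, 0.45))
  key_e <- function(net) {
    e <- firstOrderEdges(net); paste(e$source, e$target)
  }
  key_t <- function(net) {
    tr <- secondOrderTriplets(net)
    paste(tr$inputA, tr$inputB, tr$target, tr$logic)
  }
  nets <- lapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(buildLogicNetwork(gm$matrix, pairs[i, 1],
                                       pairs[i, 2])))
  for (i in 2:4) {
    expect_true(all(key_e(nets[[i]]) %in% key_e(nets[[i - 1]])))
    expect_true(all(key_t(nets[[i]]) %in% key_t(nets[[i - 1]])))
  }
})

test_that("the redundancy filter removes triplets weaker than their margins", {
  set.seed(17)
  A <- rbinom(60, 1, 0.5)
  C <- A  # C is a deterministic copy: every (A, x) triplet is redundant
  B <- rbinom(60, 1, 0.5)
  m <- BinaryExpressionMatrix(rbind(gA = A, gB = B, gC = C))
  net <- buildLogicNetwork(m, 0.2, 0.35, redundancyFilter = TRUE)
  tr <- secondOrderTriplets(net)
  expect_equal(nrow(tr[tr$target == "gC", ]), 0)
  netOff <- buildLogicNetwork(m, 0.2, 0.35, redundancyFilter = FALSE)
  expect_gt(nrow(secondOrderTriplets(netOff)), 0)
})

test_that("strength accounting matches worked single-relationship cases", {
  net1 <- generateToyNetwork(c("A", "C"),
    edges = data.frame(source = "A", target = "C", logic = "DIRECT",
                       weight = 0.4))
  st <- strengthTable(net1)
  expect_equal(st$outStrength[st$gene == "A"], 0.4)
  expect_equal(st$inStrength[st$gene == "C"], 0.4)
  net2 <- generateToyNetwork(c("A", "B", "C"),
    triplets = data.frame(inputA = "A", inputB = "B", target = "C",
                          logic = "OR", weight = 0.6))
  st <- strengthTable(net2)
  expect_equal(st$inStrength[st$gene == "C"], 0.9)
  expect_equal(st$outStrength[st$gene %in% c("A", "B")], c(0.45, 0.45))
  st0 <- strengthTable(generateToyNetwork(c("A", "B", "C")))
  expect_true(all(st0$inStrength == 0 & st0$outStrength == 0))
  expect_true(all(st0$isolated))
})

test_that("in/out degree and strength totals are conserved on random networks", {
  for (seed in c(2, 23, 57)) {
    net <- randomLogicNetwork(12, 15, 10, seed = seed)
    st <- strengthTable(net)
    expect_equal(sum(st$inStrength), sum(st$outStrength),
                 tolerance = 1e-12)
    deg <- degreeTable(net)
    expect_equal(sum(deg$inDegree), sum(deg$outDegree),
                 tolerance = 1e-12)
    # cross-check against the loop-based oracle
    os <- oracle_strengths(geneIds(net), firstOrderEdges(net),
                           secondOrderTriplets(net))
    expect_equal(unname(os$inS), st$inStrength, tolerance = 1e-12)
    expect_equal(unname(os$outS), st$outStrength, tolerance = 1e-12)
  }
})

test_that("network inference is deterministic", {
  gm <- generateMatrix(planted_family_design(seed = 31, noise = 0.05))
  n1 <- suppressWarnings(buildLogicNetwork(gm$matrix, 0.2, 0.35))
  n2 <- suppressWarnings(buildLogicNetwork(gm$matrix, 0.2, 0.35))
  expect_identical(firstOrderEdges(n1), firstOrderEdges(n2))
  expect_identical(secondOrderTriplets(n1), secondOrderTriplets(n2))
})

test_that("matrix and network class validity catches malformed objects", {
  expect_error(BinaryExpressionMatrix(rbind(a = c(1, 2))), "0 or 1")
  expect_error(BinaryExpressionMatrix(matrix(c(1, 0), 1)), "identifiers")
  expect_error(BinaryExpressionMatrix(rbind(a = 1, a = 0)), "unique")
  expect_error(LogicNetwork("A",
    firstOrder = data.frame(source = "A", target = "A",
                            logic = "DIRECT", weight = 0.5)),
    "self-loops")
  expect_error(LogicNetwork(c("A", "B"),
    firstOrder = data.frame(source = "A", target = "B",
                            logic = "DIRECT", weight = 1.5)),
    "weights")
  expect_error(LogicNetwork(c("A", "B", "C"),
    secondOrder = data.frame(inputA = "A", inputB = "B", target = "C",
                             logic = "OR", weight = 0.5, splitA = 0.9,
                             splitB = 0.4)),
    "splitA")
})
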