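test_that("discretization recovers a planted bimodal pattern", {
  set.seed(5)
  n <- 200
  planted <- runif(n) < 0.4
  x <- ifelse(planted,
              rlnorm(n, meanlog = log(64), sdlog = 0.5),
              rlnorm(n, meanlog = 0, sdlog = 0.5))
  X <- matrix(x, ncol = 1, dimnames = list(paste0("g", 1:n), "s1"))
  calls <- discretizeExpression(X)
  # at least 95% of planted-expressed genes called +1
  expect_gte(mean(calls[planted, 1] == 1L), 0.95)
  # silent genes essentially never called expressed
  expect_lte(mean(calls[!planted, 1] == 1L), 0.02)
})

test_that("discretization edge cases: degenerate, zero and duplicated samples", {
  X <- matrix(3, nrow = 10, ncol = 1,
              dimnames = list(paste0("g", 1:10), "flat"))
  expect_warning(calls <- discretizeExpression(X), "degenerate")
  expect_true(all(calls == 0L))

  # zero-expression genes are inactive
  set.seed(6)
  x <- c(rep(0, 30), rlnorm(70, log(64), 0.5))
  X2 <- matrix(x, ncol = 1, dimnames = list(paste0("g", 1:100), "s"))
  calls2 <- discretizeExpression(X2)
  expect_true(all(calls2[1:30, 1] == -1L))

  # identical samples give identical call columns (determinism)
  X3 <- cbind(s1 = x, s2 = x)
  rownames(X3) <- paste0("g", 1:100)
  calls3 <- discretizeExpression(X3)
  expect_identical(calls3[, 1], calls3[, 2])

  expect_error(discretizeExpression(-X2), "non-negative")
})

test_that("calls map to reactions with AND -> min, OR -> max", {
  net <- mkNetwork(list(
    rxn("r_or", c(A = 1), gpr = "g1 or g2"),
    rxn("r_and", c(A = -1, B = 1), gpr = "g1 and g2"),
    rxn("r_none", c(B = -1)),
    rxn("r_unk", c(B = -1), gpr = "g3")
  ), objective = "r_none")
  calls <- c(g1 = 1L, g2 = -1L)   # g3 has no call -> unknown
  asg <- mapCallsToReactions(net, calls)
  expect_identical(asg$core, "r_or")        # max(+1, -1) = +1
  expect_identical(asg$inactive, "r_and")   # min(+1, -1) = -1
  expect_setequal(asg$unknown, c("r_none", "r_unk"))
})

test_that("fastcore picks the short route of a two-route toy", {
  # biomass core; route 1 = 2 reactions, route 2 = 4 reactions
  net <- mkNetwork(list(
    rxn("src", c(A = 1), ub = 10),
    rxn("s1", c(A = -1, P = 1)),                    # short route
    rxn("l1", c(A = -1, X1 = 1)),                   # long route
    rxn("l2", c(X1 = -1, X2 = 1)),
    rxn("l3", c(X2 = -1, P = 1)),
    rxn("bio", c(P = -1))
  ), objective = "bio")
  A <- fastcoreExtract(net, core = c("src", "bio"))
  expect_true(all(c("src", "bio") %in% A))
  expect_true("s1" %in% A)
  expect_false(any(c("l1", "l2", "l3") %in% A))
})

test_that("fastcore boundary behaviour: full core, empty core, superset law", {
  net <- randomNetwork(n_extra = 5, seed = 42)
  cons <- findConsistentSubnetwork(net)
  consNet <- subsetNetwork(net, cons)
  # core = all consistent reactions -> A = consistent set
  expect_setequal(fastcoreExtract(consNet, cons), cons)
  # empty core -> empty extraction
  expect_identical(fastcoreExtract(consNet, character(0)), character(0))
  # A always contains the core
  for (i in 1:5) {
    core <- sample(cons, 3)
    A <- fastcoreExtract(consNet, core)
    expect_true(all(core %in% A), label = paste(core, collapse = ","))
  }
})

test_that("a core reaction that cannot carry flux is an error naming it", {
  net <- mkNetwork(list(
    rxn("in", c(A = 1), ub = 10),
    rxn("out", c(A = -1), ub = 10),
    rxn("dead", c(A = -1, D = 1))
  ), objective = "out")
  expect_error(fastcoreExtract(net, c("out", "dead")), "dead")
})

test_that("consensus model: identical samples reproduce the single-sample model", {
  sc <- generateScenario(seed = 3)
  net <- applyMedium(sc$network, sc$medium)
  calls <- setNames(ifelse(sc$geneActivity[, "subtype1"], 1L, -1L),
                    rownames(sc$geneActivity))
  asg <- mapCallsToReactions(sc$network, calls)
  m1 <- buildConsensusModel(net, list(asg), q = 0.5, id = "one")
  m3 <- buildConsensusModel(net, list(asg, asg, asg), q = 0.5, id = "three")
  expect_identical(reactions(m1), reactions(m3))
  expect_identical(m1@lb, m3@lb)
})

test_that("consensus threshold excludes minority-core reactions", {
  sc <- generateScenario(seed = 3)
  net <- applyMedium(sc$network, sc$medium)
  act <- sc$geneActivity
  mkAsg <- function(extraGene = NULL) {
    a <- act[, "subtype1"]
    if (!is.null(extraGene)) a[extraGene] <- TRUE
    mapCallsToReactions(sc$network, setNames(ifelse(a, 1L, -1L), names(a)))
  }
  # gAlt (R_alt) core in only 2 of 4 samples; q = 0.9 keeps it out
  asgs <- list(mkAsg("gAlt"), mkAsg("gAlt"), mkAsg(), mkAsg())
  m <- buildConsensusModel(net, asgs, q = 0.9, id = "strict")
  expect_false("R_alt" %in% reactions(m))
  # with q = 0.5 it is core and survives
  m2 <- buildConsensusModel(net, asgs, q = 0.5, id = "loose")
  expect_true("R_alt" %in% reactions(m2))
})

test_that("subtype-specific planted pathways end up in the right consensus models", {
  sc <- generateScenario(seed = 4)
  X <- SummarizedExperiment::assay(sc$expression, 1)
  calls <- discretizeExpression(X)
  net <- applyMedium(sc$network, sc$medium)
  grp <- SummarizedExperiment::colData(sc$expression)$subtype
  build <- function(st) {
    smp <- colnames(X)[grp == st]
    asg <- lapply(smp, function(s) mapCallsToReactions(sc$network, calls, s))
    buildConsensusModel(net, asg, q = 0.9, id = st)
  }
  mA <- build("subtype1"); mB <- build("subtype2")
  # the amino-acid synthesis bypass is planted outside subtype1
  expect_false("R_alt" %in% reactions(mA))
  expect_true("R_alt" %in% reactions(mB))
  # both are strict functional subnetworks that grow
  for (m in list(mA, mB)) {
    expect_lt(length(reactions(m)), length(reactions(sc$network)))
    expect_gt(fba(m)@objval, 0)
    cons <- findConsistentSubnetwork(m)
    expect_setequal(cons, reactions(m))
  }
})

test_that("pooled gene calls take the majority and tie to unknown", {
  calls <- matrix(c( 1,  1, -1,
                     1, -1, -1,
                     0,  1, -1), nrow = 3, byrow = TRUE,
                  dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
  pooled <- poolGeneCalls(calls)
  expect_identical(unname(pooled["gA"]), 1L)    # 2 expressed vs 1 inactive
  expect_identical(unname(pooled["gB"]), -1L)
  expect_identical(unname(pooled["gC"]), 0L)    # 1 vs 1 tie
  # pooled mode feeds the same consensus machinery
  sc <- generateScenario(seed = 3)
  X <- SummarizedExperiment::assay(sc$expression, 1)
  allCalls <- discretizeExpression(X)
  grp <- SummarizedExperiment::colData(sc$expression)$subtype
  pooled1 <- poolGeneCalls(allCalls, colnames(X)[grp == "subtype1"])
  m <- buildConsensusModel(applyMedium(sc$network, sc$medium),
                           list(mapCallsToReactions(sc$network, pooled1)),
                           id = "pooled")
  expect_gt(fba(m)@objval, 0)
  expect_false("R_alt" %in% reactions(m))
})
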