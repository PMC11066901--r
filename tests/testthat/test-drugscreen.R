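mkCatalog <- function(...) {
  rows <- list(...)
  data.frame(drug_id = vapply(rows, `[[`, character(1), 1),
             name = vapply(rows, `[[`, character(1), 1),
             category = I(lapply(rows, `[[`, 2)),
             targets = I(lapply(rows, `[[`, 3)),
             cofactor_of_target = FALSE, induces_proliferation = FALSE,
             stringsAsFactors = FALSE)
}

test_that("single-drug screen: joint target deletion semantics", {
  net <- parallelNetwork(gprs = c("g1", "g2"))  # two half-capacity branches
  net@ub[match("r_bio", net@rxns)] <- 10
  cat <- mkCatalog(list("dBoth", "FDA", c("g1", "g2")),
                   list("dOne", "FDA", "g1"),
                   list("dNone", "FDA", "gZZZ"))
  res <- screenSingleDrugs(net, catalog = cat)
  E <- setNames(res$E, res$drug_id)
  # joint deletion kills both branches although each alone halves growth
  expect_equal(unname(E["dBoth"]), 1, tolerance = 1e-9)
  expect_equal(unname(E["dOne"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(E["dNone"]), 0, tolerance = 1e-12)
  expect_true(res$lethal[res$drug_id == "dBoth"])
  expect_identical(res$hit, c(TRUE, TRUE, FALSE))   # 0.5 hit is inclusive
  # empty catalog -> empty table, not an error
  expect_identical(nrow(screenSingleDrugs(net, catalog = cat[0, ])), 0L)
})

test_that("adding a target never decreases the drug effect", {
  set.seed(77)
  for (i in 1:5) {
    net <- randomNetwork(n_extra = 6, seed = 4000 + i)
    gs <- paste0("g", 1:5)
    for (k in seq_along(net@rxns)[-c(1, 2)])
      net@gpr[k] <- sample(c("", gs[sample(5, 1)]), 1)
    net@gprTrees <- lapply(net@gpr, parseGpr)
    if (fba(net)@objval <= 1e-6) next
    zwt <- fba(net)@objval
    for (j in 1:4) {
      tset <- sample(gs, 2)
      E1 <- 1 - gemscreen:::.jointDeletionRatio(net, tset[1], zwt)
      E2 <- 1 - gemscreen:::.jointDeletionRatio(net, tset, zwt)
      expect_gte(E2, E1 - 1e-9)
    }
  }
})

test_that("Bliss classification matches the closed form and is symmetric", {
  expect_equal(classifyBliss(0.5, 0.5, 0.9)$E_exp, 0.75)
  expect_identical(classifyBliss(0, 0.4, 0.4, delta = 0.05)$class, "additive")
  expect_identical(classifyBliss(0, 0, 1, delta = 0.5)$class, "synergistic")
  expect_identical(classifyBliss(0.8, 0.8, 0.5)$class, "antagonistic")
  for (i in 1:20) {
    e <- runif(3)
    a <- classifyBliss(e[1], e[2], e[3])
    b <- classifyBliss(e[2], e[1], e[3])
    expect_equal(a$E_exp, b$E_exp)
    expect_identical(a$class, b$class)
    # E_exp lies in [max(E_A, E_B), 1]
    expect_gte(a$E_exp, max(e[1], e[2]) - 1e-12)
    expect_lte(a$E_exp, 1)
  }
})

test_that("combination screen finds redundant-route synergy and drops lethal singles", {
  # two fully redundant routes to biomass, each gated by one gene
  net <- parallelNetwork(branch_ub = 1000, gprs = c("g1", "g2"))
  cat <- mkCatalog(list("fdaA", "FDA", "g1"),
                   list("antiB", "AntiBC", "g2"),
                   list("fdaLethal", "FDA", "gSrc"),
                   list("fdaIdle", "FDA", "gZZZ"))
  net@gpr[1] <- "gSrc"   # src gated: its deletion is lethal
  net@gprTrees <- lapply(net@gpr, parseGpr)
  res <- screenCombinations(list(m1 = net), catalog = cat)
  expect_true(nrow(res) > 0)
  key <- paste(res$drugA, res$drugB)
  expect_true("fdaA antiB" %in% key)
  row <- res[key == "fdaA antiB", ]
  expect_equal(row$E_A, 0, tolerance = 1e-9)
  expect_equal(row$E_AB, 1, tolerance = 1e-9)
  expect_identical(row$class, "synergistic")
  # a lethal single FDA drug appears in no pair
  expect_false("fdaLethal" %in% res$drugA)
  # an irrelevant pair is not reported at cutoff 0.5
  expect_false("fdaIdle" %in% res$drugA)
})

test_that("safety check passes bypassed targets and fails sole ATP routes", {
  ctl <- mkNetwork(list(
    rxn("src", c(A = 1), ub = 10, gpr = ""),
    rxn("r_bio", c(A = -1), ub = 100),
    rxn("r_atp", c(A = -1, atp = 1), ub = 10, gpr = "gAtp"),
    rxn("dm_atp", c(atp = -1), ub = 10)
  ), objective = "r_bio", atpDemand = "dm_atp")
  ok <- safetyCheck(ctl, targets = c("gNope1", "gNope2"))
  expect_true(ok$pass)
  expect_equal(ok$biomass_ratio, 1)
  expect_equal(ok$atp_ratio, 1)
  bad <- safetyCheck(ctl, targets = "gAtp")
  expect_false(bad$pass)
  expect_equal(bad$atp_ratio, 0, tolerance = 1e-9)
  # control without ATP demand is a configuration error
  noAtp <- mkNetwork(list(rxn("src", c(A = 1), ub = 10),
                          rxn("r_bio", c(A = -1))), objective = "r_bio")
  expect_error(safetyCheck(noAtp, targets = "g"), "ATP-demand")
})

test_that("specificity labels: pan, specific, and partial hits", {
  res <- data.frame(
    drug_id = rep(c("dPan", "dOne", "dTwo"), each = 3),
    model = rep(c("m1", "m2", "m3"), 3),
    hit = c(TRUE, TRUE, TRUE,  TRUE, FALSE, FALSE,  TRUE, TRUE, FALSE))
  sp <- subtypeSpecificity(res)
  lab <- setNames(sp$specificity, sp$drug_id)
  expect_identical(unname(lab["dPan"]), "pan")
  expect_identical(unname(lab["dOne"]), "specific to m1")
  expect_identical(unname(lab["dTwo"]), "m1,m2")
})

test_that("planted scenario: pan and subtype-specific combinations recovered with safety", {
  sc <- generateScenario(seed = 6)
  subtypes <- c("subtype1", "subtype2", "subtype3")
  models <- setNames(lapply(subtypes, intendedModel, scenario = sc), subtypes)
  combos <- screenCombinations(models, catalog = sc$catalog)
  sp <- subtypeSpecificity(combos)
  lab <- setNames(sp$specificity, paste(sp$drugA, sp$drugB))
  gtp <- sc$groundTruth$synergy_pairs
  for (i in seq_len(nrow(gtp)))
    expect_identical(unname(lab[paste(gtp$drugA[i], gtp$drugB[i])]),
                     gtp$specificity[i])
  # the specific pair passes the healthy-control check
  ctl <- intendedModel(sc, "control")
  tu <- c("gC1", "gC2")
  expect_true(safetyCheck(ctl, targets = tu)$pass)
})

test_that("ratio-form Bliss index agrees on clear cases and handles E_exp = 0", {
  expect_identical(classifyBliss(0, 0, 1, method = "ratio")$class,
                   "synergistic")
  expect_identical(classifyBliss(0, 0, 0, method = "ratio")$class, "additive")
  expect_identical(classifyBliss(0.5, 0.5, 0.75, method = "ratio")$class,
                   "additive")
  expect_identical(classifyBliss(0.8, 0.8, 0.3, method = "ratio")$class,
                   "antagonistic")
})
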