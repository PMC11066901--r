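test_that("a hand-written 3-reaction JSON toy loads with all fields", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "toy",
    "metabolites": [{"id": "A"}, {"id": "B"}],
    "reactions": [
      {"id": "r_in", "metabolites": {"A": 1}, "lower_bound": 0,
       "upper_bound": 10, "gene_reaction_rule": ""},
      {"id": "r_bio", "metabolites": {"A": -1, "B": 1}, "lower_bound": 0,
       "upper_bound": 1000, "gene_reaction_rule": "g1",
       "objective_coefficient": 1},
      {"id": "r_out", "metabolites": {"B": -1}, "lower_bound": 0,
       "upper_bound": 1000}
    ]
  }', tmp)
  net <- readNetwork(tmp)
  expect_s4_class(net, "MetabolicNetwork")
  expect_length(metabolites(net), 2)
  expect_length(reactions(net), 3)
  expect_identical(objectiveReaction(net), "r_bio")
  expect_identical(unname(gprRules(net)["r_bio"]), "g1")
  expect_setequal(exchangeReactions(net), c("r_in", "r_out"))
})

test_that("write-then-read is the identity in both dialects", {
  skip_if_not_installed("withr")
  set.seed(11)
  for (dialect in c("json", "sbml-fbc")) {
    for (i in 1:5) {
      net <- randomNetwork(n_extra = sample(3:8, 1), seed = 100 + i)
      # give some reactions GPRs to exercise rule round-trips
      net@gpr[3] <- "(g1 and g2) or g3"
      net@gpr[4] <- "gA and (gB or gC)"
      net@gprTrees <- lapply(net@gpr, parseGpr)
      ext <- if (dialect == "json") ".json" else ".xml"
      tmp <- withr::local_tempfile(fileext = ext)
      writeNetwork(net, tmp, dialect = dialect)
      back <- readNetwork(tmp, dialect = dialect)
      expect_identical(reactions(back), reactions(net))
      expect_identical(metabolites(back), metabolites(net))
      expect_identical(unname(lowerBounds(back)), net@lb)
      expect_identical(unname(upperBounds(back)), net@ub)
      expect_equal(as.matrix(stoichiometry(back)),
                   as.matrix(stoichiometry(net)), ignore_attr = TRUE)
      expect_identical(objectiveReaction(back), objectiveReaction(net))
      # GPR text round-trips up to its parse tree
      expect_identical(lapply(back@gpr, parseGpr), lapply(net@gpr, parseGpr))
    }
  }
})

test_that("a reaction citing an undeclared metabolite is a parse error", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [
      {"id": "r1", "metabolites": {"A": 1, "GHOST": -1},
       "lower_bound": 0, "upper_bound": 10, "objective_coefficient": 1}
    ]
  }', tmp)
  expect_error(readNetwork(tmp), "GHOST")
})

test_that("a model without an objective is a configuration error", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [{"id": "r1", "metabolites": {"A": 1},
                   "lower_bound": 0, "upper_bound": 10}]
  }', tmp)
  expect_error(readNetwork(tmp), "objective")
})

test_that("GPR evaluation follows boolean semantics and the empty-rule convention", {
  tr <- parseGpr("(g1 AND g2) OR g3")
  expect_true(evaluateGpr(tr, deleted = "g1"))          # g3 branch survives
  expect_false(evaluateGpr(tr, deleted = c("g1", "g3")))
  expect_true(evaluateGpr(tr, deleted = character(0)))
  # empty rule: unaffected by any deletion
  expect_true(evaluateGpr(parseGpr(""), deleted = paste0("g", 1:100)))
  # malformed rules fail at parse time, not evaluation time
  expect_error(parseGpr("g1 and (g2"), "GPR")
  expect_error(parseGpr("and g1"), "GPR")
})

test_that("GPR text form round-trips through parse and render", {
  for (txt in c("g1", "g1 and g2", "(g1 and g2) or g3",
                "gA and (gB or gC or gD)", "((a or b) and (c or d)) or e")) {
    tr <- parseGpr(txt)
    expect_identical(parseGpr(gprToString(tr)), tr, label = txt)
  }
})

test_that("applyMedium sets uptake bounds and only uptake bounds", {
  net <- mkNetwork(list(
    rxn("EX_glc", c(glc_e = -1)),
    rxn("EX_gln", c(gln_e = -1)),
    rxn("t_glc", c(glc_e = -1, x = 1)),
    rxn("t_gln", c(gln_e = -1, x = 1)),
    rxn("bio", c(x = -1))
  ), objective = "bio")
  out <- applyMedium(net, newMedium(c(glc_e = 10)))
  expect_equal(unname(lowerBounds(out)["EX_glc"]), -10)
  expect_equal(unname(lowerBounds(out)["EX_gln"]), 0)
  expect_equal(unname(upperBounds(out)), net@ub)      # secretion untouched
  expect_equal(unname(lowerBounds(out)["t_glc"]), 0)  # non-exchange untouched
  # input not mutated
  expect_equal(unname(lowerBounds(net)["EX_glc"]), 0)

  # empty medium closes all uptake
  closed <- applyMedium(net, newMedium())
  expect_true(all(lowerBounds(closed)[exchangeReactions(net)] == 0))

  # a metabolite listed with rate 0 is closed, not open
  zero <- applyMedium(net, newMedium(c(glc_e = 0)))
  expect_equal(unname(lowerBounds(zero)["EX_glc"]), 0)
})

test_that("applyMedium is idempotent and warns on unmatched metabolites", {
  net <- mkNetwork(list(
    rxn("EX_glc", c(glc_e = -1)),
    rxn("bio", c(glc_e = -1))
  ), objective = "bio")
  med <- newMedium(c(glc_e = 7))
  once <- applyMedium(net, med)
  twice <- applyMedium(once, med)
  expect_identical(once@lb, twice@lb)
  expect_identical(once@ub, twice@ub)
  expect_warning(applyMedium(net, newMedium(c(nope_e = 1))), "nope_e")
})

test_that("medium CSV round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  med <- newMedium(c(glc_e = 10, gln_e = 2.5))
  writeMedium(med, tmp)
  expect_equal(uptakeRates(readMedium(tmp)), uptakeRates(med))
})
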