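# The forced-uptake toy used below couples glutamate uptake to biomass:
# biomass drains 1 glu per unit, z* is capped at 2 by the carbon source, and
# glutamate has no other source or sink, so its uptake is exactly 2 at the
# optimum.

test_that("a biomass-coupled uptake is narrow and uptake-only", {
  net <- mkNetwork(list(
    rxn("EX_c", c(c_e = -1), lb = -2),
    rxn("EX_glu", c(glu_e = -1), lb = -10),
    rxn("t_c", c(c_e = -1, x_c = 1)),
    rxn("t_glu", c(glu_e = -1, glu_c = 1)),
    rxn("bio", c(x_c = -1, glu_c = -1))
  ), objective = "bio", id = "forced")
  prof <- classifyNarrowBounded(profileExchanges(net, fraction = 1.0))
  glu <- prof[prof$reaction == "EX_glu", ]
  expect_equal(glu$min, -2, tolerance = 1e-5)
  expect_equal(glu$max, -2, tolerance = 1e-5)
  expect_identical(glu$directionality, "uptake-only")
  expect_true(glu$narrow)
  # the carbon source is pinned at its cap as well
  expect_true(prof$narrow[prof$reaction == "EX_c"])
})

test_that("an exchange of an unused metabolite is blocked", {
  net <- mkNetwork(list(
    rxn("EX_c", c(c_e = -1), lb = -2),
    rxn("EX_ghost", c(ghost_e = -1), lb = -5),
    rxn("t_c", c(c_e = -1, x_c = 1)),
    rxn("bio", c(x_c = -1))
  ), objective = "bio")
  prof <- profileExchanges(net)
  expect_identical(prof$directionality[prof$reaction == "EX_ghost"],
                   "blocked")
})

test_that("lowering the optimality fraction widens or preserves every range", {
  net <- mkNetwork(list(
    rxn("EX_c", c(c_e = -1), lb = -2),
    rxn("EX_glu", c(glu_e = -1), lb = -10),
    rxn("t_c", c(c_e = -1, x_c = 1)),
    rxn("t_glu", c(glu_e = -1, glu_c = 1)),
    rxn("bio", c(x_c = -1, glu_c = -1))
  ), objective = "bio")
  p100 <- profileExchanges(net, fraction = 1.0)
  p90 <- profileExchanges(net, fraction = 0.9)
  expect_true(all(p90$min <= p100$min + 1e-6))
  expect_true(all(p90$max >= p100$max - 1e-6))
  # the forced uptake strictly widens once 10% slack is allowed
  expect_gt(p90$max[p90$reaction == "EX_glu"] -
            p100$max[p100$reaction == "EX_glu"], 0.1)
})

test_that("narrow classification is inclusive at the cutoff and monotone", {
  prof <- data.frame(reaction = c("a", "b", "c", "d"),
                     r = c(0, 0.10, 0.100001, 1))
  out10 <- classifyNarrowBounded(prof, 0.10)
  expect_identical(out10$narrow, c(TRUE, TRUE, FALSE, FALSE))
  # monotone: narrow set at c1 <= c2 is nested
  for (c1 in c(0.05, 0.1, 0.2)) for (c2 in c(0.3, 0.6, 1)) {
    n1 <- classifyNarrowBounded(prof, c1)$narrow
    n2 <- classifyNarrowBounded(prof, c2)$narrow
    expect_true(all(!n1 | n2))
  }
  expect_error(classifyNarrowBounded(prof, 0), "ratio_cutoff")
})

test_that("a fully fixed reaction (zero maximal range) is narrow, not an error", {
  prof <- data.frame(reaction = "pinned", metabolite = "m", min = -2, max = -2,
                     rmax_min = -2, rmax_max = -2, r = 0,
                     directionality = "uptake-only", model = "m1")
  expect_true(classifyNarrowBounded(prof)$narrow)
})

test_that("profile is independent of exchange enumeration order", {
  sc <- generateScenario(seed = 9)
  m <- intendedModel(sc, "subtype1")
  p1 <- profileExchanges(m)
  pr <- match(rev(reactions(m)), reactions(m))
  flipped <- newMetabolicNetwork(
    rxns = m@rxns[pr], mets = m@mets, S = as.matrix(m@S)[, pr],
    lb = m@lb[pr], ub = m@ub[pr], gpr = m@gpr[pr],
    objective = m@objective, atpDemand = m@atpDemand, id = m@id)
  p2 <- profileExchanges(flipped)
  p2 <- p2[match(p1$reaction, p2$reaction), ]
  expect_equal(p1$min, p2$min, tolerance = 1e-6)
  expect_equal(p1$max, p2$max, tolerance = 1e-6)
})

test_that("cross-model comparison flags planted subtype-specific narrow uptake", {
  sc <- generateScenario(seed = 2)
  profs <- lapply(c("subtype1", "subtype2", "subtype3"), function(st)
    classifyNarrowBounded(profileExchanges(intendedModel(sc, st))))
  names(profs) <- c("subtype1", "subtype2", "subtype3")
  cmp <- compareExchangeProfiles(profs)
  # the amino-acid uptake is forced (narrow) only in subtype1
  aa <- cmp[cmp$metabolite == "aa_e", ]
  expect_identical(unique(aa$specificity), "subtype1")
  # the limiting nutrient is narrow everywhere
  nut <- cmp[cmp$metabolite == "nut1_e", ]
  expect_identical(unique(nut$specificity), "pan")
  # identical models produce identical rows with pan/none flags only
  cmp2 <- compareExchangeProfiles(list(a = profs[[1]], b = profs[[1]]))
  expect_true(all(cmp2$specificity %in% c("pan", "none")))
})

test_that("metabolites absent from one model are recorded as absent", {
  sc <- generateScenario(seed = 2)
  p1 <- classifyNarrowBounded(profileExchanges(intendedModel(sc, "subtype1")))
  p2 <- classifyNarrowBounded(profileExchanges(intendedModel(sc, "subtype2")))
  # drop one metabolite from the second profile to simulate model absence
  p2 <- p2[p2$metabolite != "free1_e", ]
  cmp <- compareExchangeProfiles(list(m1 = p1, m2 = p2))
  row <- cmp[cmp$metabolite == "free1_e" & cmp$model == "m2", ]
  expect_identical(row$directionality, "absent")
  expect_true(is.na(row$min))
})
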