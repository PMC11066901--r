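test_that("potency: median, single record, dedup-then-median", {
  ic <- data.frame(drug_id = "d1", cell_line = c("l1", "l2", "l3"),
                   ic50_uM = c(1, 2, 10))
  expect_equal(unname(computePotency(ic)["d1"]), 2)

  one <- data.frame(drug_id = "d2", cell_line = "l1", ic50_uM = 5)
  expect_equal(unname(computePotency(one)["d2"]), 5)

  dup <- data.frame(drug_id = "d3",
                    cell_line = c("lineX", "lineX", "lineY"),
                    ic50_uM = c(2, 4, 10))
  expect_equal(unname(computePotency(dup)["d3"]), 6.5)  # median(3, 10)

  # non-positive records are rejected, not averaged in
  neg <- rbind(dup, data.frame(drug_id = "d3", cell_line = "lineZ",
                               ic50_uM = -1))
  expect_message(p <- computePotency(neg), "non-positive")
  expect_equal(unname(p["d3"]), 6.5)
})

test_that("potency ranking is invariant to uniform unit rescaling", {
  ic <- data.frame(drug_id = c("a", "a", "b"), cell_line = c("l1", "l2", "l1"),
                   ic50_uM = c(2, 4, 9))
  p1 <- computePotency(ic)
  ic2 <- ic; ic2$ic50_uM <- ic2$ic50_uM * 1000
  p2 <- computePotency(ic2)
  expect_identical(order(p1), order(p2))
})

test_that("exclusion rules drop flagged drugs with logged reasons", {
  flags <- data.frame(drug_id = c("dCof", "dPro", "dBoth"),
                      cofactor_of_target = c(TRUE, FALSE, TRUE),
                      induces_proliferation = c(FALSE, TRUE, TRUE))
  expect_message(
    out <- applyExclusions(c("dCof", "dPro", "dBoth", "dOk"), flags),
    "excluded")
  expect_identical(out$retained, "dOk")
  expect_identical(nrow(out$excluded), 3L)
  expect_identical(out$excluded$reasons[out$excluded$drug_id == "dCof"],
                   "cofactor_of_target")
  # both flags -> excluded once, both reasons listed
  expect_identical(out$excluded$reasons[out$excluded$drug_id == "dBoth"],
                   "cofactor_of_target;induces_proliferation")
})

test_that("tier calls: thresholds inclusive, missing records untested", {
  ev <- list(
    ic50 = data.frame(drug_id = character(0), cell_line = character(0),
                      ic50_uM = numeric(0)),
    viability = data.frame(drug_id = "dx", reduction_pct = 55),
    xenograft = data.frame(drug_id = c("dx", "dy", "dz"),
                           growth_reduction_pct = c(30, 25, 24)),
    clinical = data.frame(drug_id = "dy", phase = "II", arms = 2L,
                          outcome = "improved"))
  expect_identical(unname(classifyTiers("dx", ev)),
                   c("effective", "effective", "untested"))
  # xenograft exactly 25% is effective (inclusive); 24% is not
  expect_identical(unname(classifyTiers("dy", ev)["xenograft"]), "effective")
  expect_identical(unname(classifyTiers("dz", ev)["xenograft"]), "ineffective")
  expect_identical(unname(classifyTiers("dy", ev)["clinical"]), "effective")
  # single-arm or low-phase records never make a clinical call
  ev$clinical <- data.frame(drug_id = "dy", phase = "I", arms = 1L,
                            outcome = "improved")
  expect_identical(unname(classifyTiers("dy", ev)["clinical"]), "untested")
})

test_that("contradictory clinical records resolve by majority, ties ineffective", {
  ev <- list(ic50 = data.frame(drug_id = character(0),
                               cell_line = character(0), ic50_uM = numeric(0)),
             viability = data.frame(drug_id = character(0),
                                    reduction_pct = numeric(0)),
             xenograft = data.frame(drug_id = character(0),
                                    growth_reduction_pct = numeric(0)),
             clinical = data.frame(drug_id = "d",
                                   phase = c("II", "II"), arms = 2L,
                                   outcome = c("improved", "worse")))
  expect_identical(unname(classifyTiers("d", ev)["clinical"]), "ineffective")
})

test_that("ranking follows the lexicographic criteria", {
  tiers <- rbind(
    dFast = c(in_vitro = "effective", xenograft = "effective",
              clinical = "untested"),
    dSlow = c(in_vitro = "effective", xenograft = "effective",
              clinical = "untested"),
    dNone = c(in_vitro = "untested", xenograft = "untested",
              clinical = "untested"))
  # equal tiers: potency 2 beats 6.5
  r <- rankCandidates(c("dFast", "dSlow", "dNone"), tiers,
                      potency = c(dFast = 2, dSlow = 6.5))
  expect_identical(r$drug_id, c("dFast", "dSlow", "dNone"))
  expect_true(r$untested_overall[3])

  # equal tiers: minor DDI beats major
  tiers2 <- rbind(
    cMajor = c(in_vitro = "effective", xenograft = "untested",
               clinical = "untested"),
    cMinor = c(in_vitro = "effective", xenograft = "untested",
               clinical = "untested"))
  r2 <- rankCandidates(c("cMajor", "cMinor"), tiers2,
                       ddi = c(cMajor = "major", cMinor = "minor"))
  expect_identical(r2$drug_id, c("cMinor", "cMajor"))

  # LogBB breaks remaining ties, higher first
  r3 <- rankCandidates(c("a", "b"), tiers2[c(1, 2), , drop = FALSE] |>
                         `rownames<-`(c("a", "b")),
                       logbb = c(a = -2, b = -0.5))
  expect_identical(r3$drug_id, c("b", "a"))
})

test_that("ranking is a stable total order under record shuffling", {
  set.seed(8)
  drugs <- paste0("d", 1:8)
  tiers <- matrix(sample(c("effective", "ineffective", "untested"), 24, TRUE),
                  nrow = 8, dimnames = list(drugs,
                                            c("in_vitro", "xenograft",
                                              "clinical")))
  pot <- setNames(round(runif(8, 1, 10), 2), drugs)
  r1 <- rankCandidates(drugs, tiers, potency = pot)
  r2 <- rankCandidates(rev(drugs), tiers[rev(drugs), ], potency = rev(pot))
  expect_identical(r1$drug_id, r2$drug_id)
  expect_identical(r1$rank, seq_along(drugs))           # total order
  expect_identical(anyDuplicated(r1$drug_id), 0L)
})

test_that("an extra untested tier record does not reorder other drugs", {
  tiers <- rbind(a = c("effective", "untested", "untested"),
                 b = c("ineffective", "untested", "untested"))
  colnames(tiers) <- c("in_vitro", "xenograft", "clinical")
  r1 <- rankCandidates(c("a", "b"), tiers)
  tiers2 <- tiers; tiers2["b", "xenograft"] <- "untested"  # no-op record
  r2 <- rankCandidates(c("a", "b"), tiers2)
  expect_identical(r1$drug_id, r2$drug_id)
})
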