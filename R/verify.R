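# Brute-force re-derivation of every GroundTruth claim of a synthetic
# scenario. This is deliberately an independent code path from the screening
# functions: GPR rules are evaluated by textual substitution into an R
# boolean expression (not via the package's parse trees), knockouts are
# exhaustive per-gene / per-pair LP re-solves, and exchange ranges come from
# hand-assembled LPs with an explicit optimality row.

# text-substitution GPR evaluation: independent of parseGpr()/evaluateGpr()
.gprEvalText <- function(rule, deleted) {
  if (!nzchar(trimws(rule))) return(TRUE)
  toks <- .gprTokenize(rule)
  expr <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (lt == "and") "&&" else if (lt == "or") "||"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% deleted) "FALSE" else "TRUE"
  }, character(1))
  eval(parse(text = paste(expr, collapse = " ")))
}

# maximal objective after closing every reaction whose rule dies under the
# deletion; plain LP assembled here, no fba() involved
.bruteKnockoutOptimum <- function(model, deleted, objective = model@objective) {
  lb <- model@lb; ub <- model@ub
  dead <- vapply(model@gpr, .gprEvalText, logical(1), deleted = deleted)
  lb[!dead] <- 0; ub[!dead] <- 0
  obj <- numeric(length(model@rxns))
  obj[match(objective, model@rxns)] <- 1
  r <- solveLP(obj, model@S, numeric(length(model@mets)), lb, ub)
  if (r$status != "optimal") 0 else max(r$objval, 0)
}

# min and max flux of one reaction subject to objective >= frac * z*
.bruteFluxRange <- function(model, reaction, frac = 1) {
  n <- length(model@rxns); m <- length(model@mets)
  jobj <- match(model@objective, model@rxns)
  jrx <- match(reaction, model@rxns)
  obj0 <- numeric(n); obj0[jobj] <- 1
  z <- solveLP(obj0, model@S, numeric(m), model@lb, model@ub)$objval
  row <- numeric(n); row[jobj] <- 1
  A <- rbind(as.matrix(model@S), row)
  rhs <- c(numeric(m), frac * (1 - 1e-6) * z)
  sense <- c(rep("=", m), ">=")
  obj <- numeric(n); obj[jrx] <- 1
  c(min = solveLP(obj, A, rhs, model@lb, model@ub, sense, FALSE)$objval,
    max = solveLP(obj, A, rhs, model@lb, model@ub, sense, TRUE)$objval)
}

#' Verify every planted claim of a synthetic scenario by brute force
#'
#' Re-derives the GroundTruth record of [generateScenario()] with exhaustive
#' LP checks on the intended context models: per-gene knockout optima
#' (essential genes), flux ranges of all exchanges at optimal growth
#' (narrow-bounded set, 10% rule), exhaustive drug-pair knockouts with the
#' Bliss closed form (synergy pairs, classes, subtype specificity), the
#' lethal single drug, single-drug hits and the control-model safety of the
#' planted pairs. Mismatches are report rows, not exceptions.
#'
#' @param scenario a `SyntheticScenario`.
#' @param cutoff growth-reduction cutoff (default 0.5).
#' @param ratio_cutoff narrow-bounded relative-range cutoff (default 0.10).
#' @param delta Bliss tolerance (default 0.05).
#' @return data.frame with columns `check`, `context`, `item`, `expected`,
#'   `observed`, `ok`; attribute `"n_mismatch"`.
#' @export
verifyScenario <- function(scenario, cutoff = 0.5, ratio_cutoff = 0.10,
                           delta = 0.05) {
  gt <- scenario$groundTruth
  subtypes <- c("subtype1", "subtype2", "subtype3")
  rows <- list()
  note <- function(check, context, item, expected, observed)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, context = context, item = item,
      expected = as.character(expected), observed = as.character(observed),
      ok = identical(as.character(expected), as.character(observed)),
      stringsAsFactors = FALSE)

  models <- setNames(lapply(c(subtypes, "control"), intendedModel,
                            scenario = scenario), c(subtypes, "control"))

  # --- essential genes: exhaustive single-gene KO per subtype model ---
  for (st in subtypes) {
    mod <- models[[st]]
    zwt <- .bruteKnockoutOptimum(mod, character(0))
    ess <- character(0)
    for (g in sort(genes(mod))) {
      z <- .bruteKnockoutOptimum(mod, g)
      if (z / zwt <= 1 - cutoff + 1e-9) ess <- c(ess, g)
    }
    note("essential_genes", st, "set",
         paste(gt$essential_genes[[st]], collapse = ","),
         paste(sort(ess), collapse = ","))
  }

  # --- narrow-bounded exchanges at f = 1 and the 10% rule ---
  for (st in subtypes) {
    mod <- models[[st]]
    ex <- exchangeReactions(mod)
    open <- ex[mod@lb[match(ex, mod@rxns)] < 0 |
               mod@ub[match(ex, mod@rxns)] > 0]
    narrow <- character(0)
    for (e in open) {
      rng <- .bruteFluxRange(mod, e, frac = 1)
      full <- .bruteFluxRange(mod, e, frac = 0)
      span <- full["max"] - full["min"]
      r <- if (span <= 1e-6) 0 else (rng["max"] - rng["min"]) / span
      if (r <= ratio_cutoff + 1e-9) narrow <- c(narrow, e)
    }
    note("narrow_exchanges", st, "set",
         paste(gt$narrow_exchanges[[st]], collapse = ","),
         paste(sort(narrow), collapse = ","))
    free <- gt$free_exchange
    if (free %in% open) {
      rng <- .bruteFluxRange(mod, free, frac = 1)
      full <- .bruteFluxRange(mod, free, frac = 0)
      r <- (rng["max"] - rng["min"]) / (full["max"] - full["min"])
      note("free_exchange", st, free, "wide", if (r > ratio_cutoff) "wide" else "narrow")
    }
  }

  # --- blocked reactions stay out of every intended model ---
  for (b in gt$blocked_reactions)
    note("blocked", "all", b, "absent",
         if (any(vapply(models, function(m) b %in% m@rxns, logical(1))))
           "present" else "absent")

  # --- single drugs: hits and the lethal single ---
  targetsOf <- function(d)
    scenario$catalog$targets[[match(d, scenario$catalog$drug_id)]]
  effectOf <- function(mod, targets, zwt)
    1 - min(max(.bruteKnockoutOptimum(mod, targets) / zwt, 0), 1)
  for (st in names(gt$single_hits)) {
    mod <- models[[st]]
    zwt <- .bruteKnockoutOptimum(mod, character(0))
    hits <- character(0)
    for (d in scenario$catalog$drug_id) {
      E <- effectOf(mod, targetsOf(d), zwt)
      if (E >= cutoff - 1e-9) hits <- c(hits, d)
    }
    note("single_hits", st, "set",
         paste(sort(gt$single_hits[[st]]), collapse = ","),
         paste(sort(hits), collapse = ","))
  }
  # lethal single: complete shutdown in every tumour model
  lethalAll <- all(vapply(subtypes, function(st) {
    mod <- models[[st]]
    zwt <- .bruteKnockoutOptimum(mod, character(0))
    effectOf(mod, targetsOf(gt$lethal_single), zwt) >= 1 - 1e-6
  }, logical(1)))
  note("lethal_single", "all", gt$lethal_single, TRUE, lethalAll)

  # --- synergy pairs: exhaustive pair KO + Bliss closed form ---
  for (i in seq_len(nrow(gt$synergy_pairs))) {
    pr <- gt$synergy_pairs[i, ]
    tA <- targetsOf(pr$drugA); tB <- targetsOf(pr$drugB)
    hitIn <- character(0); classIn <- character(0)
    for (st in subtypes) {
      mod <- models[[st]]
      zwt <- .bruteKnockoutOptimum(mod, character(0))
      EA <- effectOf(mod, tA, zwt); EB <- effectOf(mod, tB, zwt)
      EAB <- effectOf(mod, union(tA, tB), zwt)
      Eexp <- EA + EB - EA * EB
      cls <- if (EAB - Eexp > delta) "synergistic"
             else if (EAB - Eexp < -delta) "antagonistic" else "additive"
      if (EAB >= cutoff - 1e-9) {
        hitIn <- c(hitIn, st); classIn <- c(classIn, cls)
      }
    }
    spec <- if (length(hitIn) == 3) "pan"
            else if (length(hitIn) == 1) paste("specific to", hitIn)
            else paste(hitIn, collapse = ",")
    note("synergy_specificity", "pairwise",
         paste(pr$drugA, pr$drugB, sep = "+"), pr$specificity, spec)
    note("synergy_class", "pairwise", paste(pr$drugA, pr$drugB, sep = "+"),
         pr$class, paste(unique(classIn), collapse = ","))

    # control safety: biomass and ATP demand both retained
    ctl <- models[["control"]]
    zb <- .bruteKnockoutOptimum(ctl, character(0))
    za <- .bruteKnockoutOptimum(ctl, character(0),
                                objective = atpDemandReaction(ctl))
    rb <- .bruteKnockoutOptimum(ctl, union(tA, tB)) / zb
    ra <- .bruteKnockoutOptimum(ctl, union(tA, tB),
                                objective = atpDemandReaction(ctl)) / za
    note("safety_pass", "control", paste(pr$drugA, pr$drugB, sep = "+"),
         pr$safety_pass, rb >= 0.95 && ra >= 0.95)
  }

  out <- do.call(rbind, rows)
  attr(out, "n_mismatch") <- sum(!out$ok)
  out
}
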