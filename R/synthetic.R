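# Synthetic scenario generator.
#
# Emits every input the pipeline consumes -- a generic toy network, a medium,
# subtype-structured expression, a drug catalog and evidence tables -- with
# planted, LP-verifiable ground truth:
#   * planted essential genes per subtype (sole-route genes),
#   * planted narrow-bounded exchanges (metabolites whose uptake is forced
#     exactly at the optimum), one of them subtype-specific,
#   * planted synergistic target pairs (two fully redundant biosynthesis
#     routes to one biomass precursor; each drug closes one route), one pan
#     and one subtype-specific,
#   * a planted lethal single drug (targets the sole-route gene),
#   * a healthy control context in which the tumour-specific targets are
#     bypassed, so the specific pair passes the safety check.

#' Build the synthetic generic toy network
#'
#' Hand-designed skeleton (see the package vignette for the wiring) plus
#' seeded decoy chains and an optional dead-end reaction that exercises the
#' consistency filter. All internal reactions carry a single-gene GPR;
#' boundary reactions (exchanges, biomass, ATP demand) have none.
#'
#' @param n_decoy_chains number of uptake-transport-sink decoy chains.
#' @param include_dead_end add a planted dead-end (blocked) reaction.
#' @return list: `network` ([MetabolicNetwork-class]), `medium`,
#'   `geneActivity` (gene x context logical matrix of intended activity over
#'   contexts subtype1..3 + control), `blocked` (planted blocked reactions).
#' @export
syntheticGenericNetwork <- function(n_decoy_chains = 3,
                                    include_dead_end = TRUE) {
  rx <- list()  # id, mets (named coefs), lb, ub, gpr
  addR <- function(id, mets, lb, ub, gpr = "")
    rx[[length(rx) + 1L]] <<- list(id = id, mets = mets, lb = lb, ub = ub,
                                   gpr = gpr)
  UB <- 1000

  # exchanges (export positive; uptake bound set by the medium); all
  # intracellular sinks drain into a shared waste metabolite so that the
  # single-metabolite (exchange) reactions are exactly the EX_* boundary set
  for (m in c("glc_e", "nut1_e", "aa_e", "free1_e", "unused_e", "waste_e"))
    addR(paste0("EX_", m), setNames(-1, m), 0, UB)

  addR("T_glc",   c(glc_e = -1, glc_c = 1),    0, UB, "tg1")
  addR("T_nut1",  c(nut1_e = -1, nut1_c = 1),  0, UB, "tgn")
  addR("T_aa",    c(aa_e = -1, aa_c = 1),      0, UB, "tga")
  addR("T_free1", c(free1_e = -1, free1_c = 1), -UB, UB, "tgf")
  addR("DM_free1", c(free1_c = -1, waste_e = 1), 0, UB, "tgf2")

  # precursor 1: two redundant routes everywhere (pan synergy plant) plus a
  # third route expressed only in the healthy control context
  addR("R_B1", c(glc_c = -1, prec1_c = 1), 0, UB, "gB1")
  addR("R_B2", c(glc_c = -1, prec1_c = 1), 0, UB, "gB2")
  addR("R_B3", c(glc_c = -1, prec1_c = 1), 0, UB, "gB3")
  # precursor 2: redundant pair everywhere, bypass route in subtypes 2, 3
  # and control (subtype-specific synergy plant)
  addR("R_C1", c(glc_c = -1, prec2_c = 1), 0, UB, "gC1")
  addR("R_C2", c(glc_c = -1, prec2_c = 1), 0, UB, "gC2")
  addR("R_C3", c(glc_c = -1, prec2_c = 1), 0, UB, "gC3")
  # precursor 3: sole route (pan essential + lethal-single plant)
  addR("R_D", c(glc_c = -1, prec3_c = 1), 0, UB, "gE")
  # precursor 4: route pair with subtype-restricted expression
  # (subtype-specific essential plant)
  addR("R_F1", c(glc_c = -1, prec4_c = 1), 0, UB, "gF1")
  addR("R_F2", c(glc_c = -1, prec4_c = 1), 0, UB, "gF2")
  # amino-acid precursor: uptake everywhere, internal synthesis only outside
  # subtype 1 (subtype-specific narrow-bounded exchange plant)
  addR("R_alt", c(glc_c = -1, aa_c = 1), 0, UB, "gAlt")
  # ATP route and demand (safety-check metric); the route capacity is kept
  # small so the ATP drain cannot blur the forced-uptake exchange plants
  addR("R_atp", c(glc_c = -1, atp_c = 1), 0, 0.5, "tA")
  addR("DM_atp", c(atp_c = -1, waste_e = 1), 0, UB)

  if (include_dead_end)
    addR("R_dead", c(glc_c = -1, dead_c = 1), 0, UB, "gDead")

  decoyGenes <- character(0)
  for (i in seq_len(n_decoy_chains)) {
    me <- paste0("dec", i, "_e"); mc <- paste0("dec", i, "_c")
    g1 <- paste0("gD", i, "a"); g2 <- paste0("gD", i, "b")
    addR(paste0("EX_", me), setNames(-1, me), 0, UB)
    addR(paste0("T_dec", i), setNames(c(-1, 1), c(me, mc)), 0, UB, g1)
    addR(paste0("DM_dec", i), setNames(c(-1, 1), c(mc, "waste_e")), 0, UB, g2)
    decoyGenes <- c(decoyGenes, g1, g2)
  }

  addR("BIOMASS",
       c(prec1_c = -1, prec2_c = -1, prec3_c = -1, prec4_c = -1,
         nut1_c = -1, aa_c = -1), 0, UB)

  ids <- vapply(rx, `[[`, character(1), "id")
  mets <- unique(unlist(lapply(rx, function(r) names(r$mets))))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (k in seq_along(rx)) S[names(rx[[k]]$mets), k] <- rx[[k]]$mets
  net <- newMetabolicNetwork(
    rxns = ids, mets = mets, S = S,
    lb = vapply(rx, `[[`, numeric(1), "lb"),
    ub = vapply(rx, `[[`, numeric(1), "ub"),
    gpr = vapply(rx, `[[`, character(1), "gpr"),
    objective = "BIOMASS", atpDemand = "DM_atp", id = "generic_toy")

  # nut1 is the growth-limiting nutrient (z* = 2), leaving glucose slack in
  # contexts where the internal amino-acid route can substitute for uptake
  med <- c(glc_e = 10, nut1_e = 2, aa_e = 10, free1_e = 5, unused_e = 1)
  if (n_decoy_chains > 0)
    med <- c(med, setNames(rep(1, n_decoy_chains),
                           paste0("dec", seq_len(n_decoy_chains), "_e")))

  contexts <- c("subtype1", "subtype2", "subtype3", "control")
  allGenes <- sort(unique(c(unlist(lapply(net@gprTrees, gprGenes)))))
  act <- matrix(FALSE, length(allGenes), length(contexts),
                dimnames = list(allGenes, contexts))
  common <- c("tg1", "tgn", "tga", "tgf", "tgf2", "tA",
              "gB1", "gB2", "gC1", "gC2", "gE",
              if (include_dead_end) "gDead")
  act[common, ] <- TRUE
  act["gC3", c("subtype2", "subtype3", "control")] <- TRUE
  act["gAlt", c("subtype2", "subtype3", "control")] <- TRUE
  act["gB3", "control"] <- TRUE
  act["gF1", c("subtype1", "subtype2", "control")] <- TRUE
  act["gF2", c("subtype1", "subtype3", "control")] <- TRUE
  # decoy chains: active in a seeded random, non-empty subset of contexts
  for (g in decoyGenes) {
    on <- runif(length(contexts)) < 0.6
    if (!any(on)) on[sample.int(length(contexts), 1)] <- TRUE
    act[g, ] <- on
  }

  list(network = net, medium = newMedium(med), geneActivity = act,
       blocked = c(if (include_dead_end) "R_dead", "EX_unused_e"))
}

.syntheticCatalog <- function() {
  mk <- function(drug_id, name, category, targets, cof = FALSE, pro = FALSE)
    data.frame(drug_id = drug_id, name = name, category = I(list(category)),
               targets = I(list(targets)), cofactor_of_target = cof,
               induces_proliferation = pro, stringsAsFactors = FALSE)
  rbind(
    mk("dB1",  "panroutine",   "FDA",    "gB1"),
    mk("bB2",  "blockamide",   "AntiBC", "gB2"),
    mk("dC1",  "subroutine",   "FDA",    "gC1"),
    mk("iC2",  "investigatol", "IAG",    "gC2"),
    mk("dE",   "lethalin",     "FDA",    "gE"),
    mk("dF1",  "forkanib",     "FDA",    "gF1"),
    mk("dTga", "uptakol",      "FDA",    "tga"),
    mk("dX1",  "decoymycin",   "FDA",    "gX_offnet"),
    mk("dX2",  "sinkastat",    "FDA",    "tgf2"),
    mk("dCof", "cofactorin",   "FDA",    "gB2", cof = TRUE),
    mk("dPro", "prolifex",     "FDA",    "gC3", pro = TRUE),
    mk("abcRef1", "refchemo1", "AntiBC", "gRefA"),
    mk("abcRef2", "refchemo2", "AntiBC", "gRefB")
  )
}

.syntheticEvidence <- function() {
  list(
    ic50 = data.frame(
      drug_id  = c("abcRef1", "abcRef1", "abcRef2", "dB1", "dE", "iC2"),
      cell_line = c("BT1", "BT2", "BT1", "BT1", "BT1", "BT2"),
      ic50_uM  = c(4, 6, 8, 2, 10, 12), stringsAsFactors = FALSE),
    viability = data.frame(
      drug_id = c("dC1", "iC2"), reduction_pct = c(60, 20),
      stringsAsFactors = FALSE),
    pk = data.frame(
      drug_id = c("dB1", "dC1", "iC2", "dE", "abcRef1"),
      logbb = c(-0.5, -1.2, 0.1, -2.0, -1.0),
      bbb_permeable = c(TRUE, FALSE, TRUE, FALSE, TRUE),
      abc_transporter = c("none", "substrate", "inhibitor", "unknown", "none"),
      stringsAsFactors = FALSE),
    xenograft = data.frame(
      drug_id = c("dB1", "dE", "dC1"),
      growth_reduction_pct = c(30, 10, 25), stringsAsFactors = FALSE),
    clinical = data.frame(
      drug_id = c("dB1", "dE"), phase = c("II", "II"), arms = c(2L, 1L),
      outcome = c("improved", "improved"), stringsAsFactors = FALSE),
    flags = data.frame(
      drug_id = c("dCof", "dPro"),
      cofactor_of_target = c(TRUE, FALSE),
      induces_proliferation = c(FALSE, TRUE), stringsAsFactors = FALSE),
    ddi = data.frame(
      drugA = c("dB1", "dC1"), drugB = c("bB2", "iC2"),
      severity = c("minor", "none"), stringsAsFactors = FALSE)
  )
}

#' Generate a complete synthetic scenario with planted ground truth
#'
#' Draws subtype-structured expression from a two-component log-normal
#' mixture (silent ~ LogNormal(log 1, 0.5), expressed ~ LogNormal(log 64,
#' 0.5)) aligned to the GPR rules of the synthetic generic network, and
#' assembles medium, drug catalog, evidence tables and the GroundTruth
#' record. Regeneration with the same seed is bit-identical; generation
#' fails (rather than silently emitting a broken scenario) when biomass is
#' not reachable in some intended context.
#'
#' @param n_samples samples per tumour subtype (default 8).
#' @param n_control control samples (default 4).
#' @param n_decoy_chains decoy chains in the network (default 3).
#' @param n_extra_genes off-network genes added to the expression matrix
#'   (one third expressed everywhere, the rest silent; default 42).
#' @param seed integer seed (required).
#' @return object of class `SyntheticScenario`: list with `network`,
#'   `medium`, `expression` (SummarizedExperiment, colData column
#'   `subtype`), `catalog`, `evidence`, `groundTruth`, `params`.
#' @export
generateScenario <- function(n_samples = 8, n_control = 4,
                             n_decoy_chains = 3, n_extra_genes = 42,
                             seed) {
  if (missing(seed)) stop("'seed' is required for reproducible generation")
  stopifnot(n_samples >= 1, n_control >= 1, n_decoy_chains >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  gen <- syntheticGenericNetwork(n_decoy_chains = n_decoy_chains)
  net <- gen$network
  act <- gen$geneActivity
  subtypes <- c("subtype1", "subtype2", "subtype3")

  # expression: genes x samples, log-normal mixture tied to intended activity
  nExtraHi <- ceiling(n_extra_genes / 3)
  extra <- c(sprintf("hk%02d", seq_len(nExtraHi)),
             sprintf("sil%02d", seq_len(n_extra_genes - nExtraHi)))
  genesAll <- c(rownames(act), "gX_offnet", extra)
  groups <- c(rep(subtypes, each = n_samples), rep("control", n_control))
  samples <- sprintf("%s_s%02d", groups, c(
    rep(seq_len(n_samples), 3), seq_len(n_control)))
  X <- matrix(0, length(genesAll), length(samples),
              dimnames = list(genesAll, samples))
  for (j in seq_along(samples)) {
    ctx <- groups[j]
    onExtra <- setNames(c(rep(TRUE, nExtraHi),
                          rep(FALSE, n_extra_genes - nExtraHi)), extra)
    on <- c(act[, ctx], c(gX_offnet = FALSE), onExtra)[genesAll]
    X[, j] <- ifelse(on,
                     rlnorm(length(genesAll), meanlog = log(64), sdlog = 0.5),
                     rlnorm(length(genesAll), meanlog = log(1), sdlog = 0.5))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = X),
    colData = S4Vectors::DataFrame(subtype = groups, row.names = samples))

  # planted ground truth (re-derivable by brute force; see verifyScenario)
  gt <- list(
    essential_genes = list(
      subtype1 = sort(c("tg1", "tgn", "tga", "gE")),
      subtype2 = sort(c("tg1", "tgn", "gE", "gF1")),
      subtype3 = sort(c("tg1", "tgn", "gE", "gF2"))),
    narrow_exchanges = list(
      subtype1 = sort(c("EX_glc_e", "EX_nut1_e", "EX_aa_e")),
      subtype2 = "EX_nut1_e",
      subtype3 = "EX_nut1_e"),
    free_exchange = "EX_free1_e",
    blocked_reactions = gen$blocked,
    synergy_pairs = data.frame(
      drugA = c("dB1", "dC1"), drugB = c("bB2", "iC2"),
      class = "synergistic",
      specificity = c("pan", "specific to subtype1"),
      safety_pass = TRUE, stringsAsFactors = FALSE),
    lethal_single = "dE",
    single_hits = list(
      subtype1 = sort(c("dE", "dTga")),
      subtype2 = sort(c("dE", "dF1")),
      subtype3 = sort(c("dE")),
      control  = "dE"),
    excluded_drugs = c("dCof", "dPro"),
    evidence_labels = list(
      in_vitro = c(dB1 = "effective", dC1 = "effective", iC2 = "ineffective",
                   dE = "ineffective", dF1 = "untested"),
      xenograft = c(dB1 = "effective", dC1 = "effective", dE = "ineffective",
                    dF1 = "untested"),
      clinical = c(dB1 = "effective", dE = "untested", dF1 = "untested"))
  )

  scenario <- structure(
    list(network = net, medium = gen$medium, expression = se,
         geneActivity = act, catalog = .syntheticCatalog(),
         evidence = .syntheticEvidence(), groundTruth = gt,
         params = list(n_samples = n_samples, n_control = n_control,
                       n_decoy_chains = n_decoy_chains,
                       n_extra_genes = n_extra_genes, seed = seed)),
    class = "SyntheticScenario")

  # construction check: biomass reachable in every intended context
  for (ctx in c(subtypes, "control")) {
    m <- intendedModel(scenario, ctx)
    z <- fba(m)
    if (z@status != "optimal" || z@objval <= 1e-6)
      stop("scenario generation error: context '", ctx,
           "' cannot produce biomass (z* = ",
           if (z@status == "optimal") z@objval else z@status, ")")
  }
  scenario
}

#' @exportS3Method base::print
print.SyntheticScenario <- function(x, ...) {
  cat("SyntheticScenario (seed ", x$params$seed, ")\n", sep = "")
  cat("  network:   ", length(x$network@rxns), " reactions, ",
      length(x$network@mets), " metabolites\n", sep = "")
  cat("  expression:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("  catalog:   ", nrow(x$catalog), "drugs |",
      nrow(x$groundTruth$synergy_pairs), "planted synergy pairs\n")
  invisible(x)
}

#' Intended context-specific model of a scenario
#'
#' Deterministic reference model for one context (subtype or control):
#' reactions whose GPR is satisfied by the intended gene-activity table,
#' plus the GPR-less boundary reactions, reduced to the flux-consistent
#' part under the medium. This is what consensus extraction should
#' reproduce from the noisy expression.
#'
#' @param scenario a `SyntheticScenario`.
#' @param context one of `"subtype1"`, `"subtype2"`, `"subtype3"`,
#'   `"control"`.
#' @return a [MetabolicNetwork-class].
#' @export
intendedModel <- function(scenario, context) {
  act <- scenario$geneActivity
  net <- applyMedium(scenario$network, scenario$medium)
  calls <- setNames(ifelse(act[, context], 1L, -1L), rownames(act))
  keep <- vapply(seq_along(net@rxns), function(k) {
    tr <- net@gprTrees[[k]]
    if (is.null(tr)) return(TRUE)            # boundary reactions stay
    scoreGpr(tr, calls) == 1L
  }, logical(1))
  inact <- which(!keep)
  net@lb[inact] <- 0; net@ub[inact] <- 0
  cons <- findConsistentSubnetwork(net)
  m <- subsetNetwork(net, cons)
  m@id <- paste0("intended_", context)
  m
}

#' Write all scenario files to a directory
#'
#' Emits exactly the formats the pipeline reads: `model.json`, `model.xml`
#' (SBML-FBC), `expression.tsv`, `labels.csv`, `medium.csv`, `catalog.tsv`,
#' `evidence/*.tsv` and `ground_truth.json`.
#'
#' @param scenario a `SyntheticScenario`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeNetwork(scenario$network, file.path(dir, "model.json"))
  writeNetwork(scenario$network, file.path(dir, "model.xml"))
  writeMedium(scenario$medium, file.path(dir, "medium.csv"))

  X <- SummarizedExperiment::assay(scenario$expression, 1)
  write.table(data.frame(gene = rownames(X), X, check.names = FALSE),
              file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(
    sample = colnames(scenario$expression),
    subtype = SummarizedExperiment::colData(scenario$expression)$subtype),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)

  cat0 <- scenario$catalog
  cat0$targets <- vapply(cat0$targets, paste, character(1), collapse = ";")
  cat0$category <- vapply(cat0$category, paste, character(1), collapse = ";")
  write.table(cat0, file.path(dir, "catalog.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  evdir <- file.path(dir, "evidence")
  dir.create(evdir, showWarnings = FALSE)
  for (nm in names(scenario$evidence))
    write.table(scenario$evidence[[nm]], file.path(evdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(scenario$groundTruth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
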