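#' Read and validate a pipeline configuration
#'
#' YAML key-value file with input paths, the subtype/control grouping and
#' the analysis thresholds. Threshold defaults (all overridable):
#' `fraction = 1.0` (FVA optimality fraction), `epsilon = 1e-4`
#' (flux-consistency threshold), `q = 0.9` (consensus threshold),
#' `cutoff = 0.5` (growth-reduction cutoff for essentiality and drug hits),
#' `delta = 0.05` (Bliss tolerance), `eta = 0.05` (safety-check tolerated
#' loss), `ratio_cutoff = 0.10` (narrow-bounded rule), `p_hi = 0.9`,
#' `p_lo = 0.1` (discretization posteriors). Validation happens before any
#' computation.
#'
#' @param config path to a YAML file, or a named list with the same keys.
#' @return validated config list (class `PipelineConfig`).
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(fraction = 1.0, epsilon = 1e-4, q = 0.9, cutoff = 0.5,
                   delta = 0.05, eta = 0.05, ratio_cutoff = 0.10,
                   p_hi = 0.9, p_lo = 0.1, control_label = "control",
                   seed = 1L, reference_essentials = NULL)
  cfg <- modifyList(defaults, config)
  need <- c("network", "medium", "expression", "labels", "catalog",
            "evidence_dir", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("pipeline config missing key(s): ", paste(miss, collapse = ", "))
  chk <- function(nm, lo, hi, loOpen = TRUE) {
    v <- cfg[[nm]]
    ok <- is.numeric(v) && length(v) == 1L &&
      (if (loOpen) v > lo else v >= lo) && v <= hi
    if (!ok) stop("config validation error: '", nm, "' = ", v,
                  " outside (", lo, ", ", hi, "]")
  }
  chk("fraction", 0, 1); chk("epsilon", 0, 1); chk("q", 0, 1)
  chk("cutoff", 0, 1); chk("delta", 0, 1); chk("eta", 0, 1)
  chk("ratio_cutoff", 0, 1); chk("p_hi", 0, 1); chk("p_lo", 0, 1, FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Run the full prediction pipeline
#'
#' Per subtype: discretize expression, build the consensus context-specific
#' model, profile exchanges, screen gene essentiality and single drugs.
#' Across subtypes: combination screen with Bliss classification, subtype
#' specificity, control-model safety checks of hit pairs, and evidence-based
#' prioritization. Every output table is written as TSV under
#' `cfg$out_dir` together with a manifest (input MD5 hashes, thresholds,
#' seed, package version); re-running the same config reproduces identical
#' bytes.
#'
#' @param config a config list or YAML path (see [readPipelineConfig()]).
#' @return invisible list with all stage results.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  set.seed(cfg$seed)
  stage <- "load inputs"
  res <- tryCatch({
    network <- readNetwork(cfg$network)
    medium <- readMedium(cfg$medium)
    exprTab <- utils::read.delim(cfg$expression, check.names = FALSE)
    X <- as.matrix(exprTab[, -1, drop = FALSE])
    rownames(X) <- exprTab[[1]]
    labels <- utils::read.csv(cfg$labels, stringsAsFactors = FALSE)
    catalog <- readDrugCatalog(cfg$catalog)
    evidence <- readEvidence(cfg$evidence_dir)
    grp <- setNames(labels$subtype, labels$sample)[colnames(X)]
    if (anyNA(grp)) stop("samples without subtype label: ",
                         paste(colnames(X)[is.na(grp)], collapse = ", "))
    subtypes <- setdiff(sort(unique(grp)), cfg$control_label)
    hasControl <- cfg$control_label %in% grp

    stage <- "discretization"
    calls <- discretizeExpression(X, p_hi = cfg$p_hi, p_lo = cfg$p_lo)

    stage <- "consensus model building"
    constrained <- applyMedium(network, medium)
    buildFor <- function(label) {
      smp <- colnames(X)[grp == label]
      asg <- lapply(smp, function(s)
        mapCallsToReactions(network, calls, sample = s))
      buildConsensusModel(constrained, asg, q = cfg$q,
                          epsilon = cfg$epsilon, id = label)
    }
    models <- setNames(lapply(subtypes, buildFor), subtypes)
    control <- if (hasControl) buildFor(cfg$control_label) else NULL

    stage <- "exchange profiling"
    profiles <- lapply(models, function(m)
      classifyNarrowBounded(
        profileExchanges(m, fraction = cfg$fraction),
        ratio_cutoff = cfg$ratio_cutoff))
    exchangeComparison <- if (length(profiles) >= 2)
      compareExchangeProfiles(profiles) else NULL

    stage <- "gene essentiality"
    essentiality <- lapply(names(models), function(nm) {
      r <- classifyEssential(singleGeneDeletion(models[[nm]]),
                             cutoff = cfg$cutoff)
      r$model <- nm
      r
    })
    essentiality <- do.call(rbind, essentiality)
    commonEss <- if (!is.null(cfg$reference_essentials))
      annotateCommonEssentials(unique(essentiality$gene[essentiality$essential]),
                               cfg$reference_essentials) else NULL

    stage <- "single-drug screen"
    singles <- lapply(models, screenSingleDrugs, catalog = catalog,
                      cutoff = cfg$cutoff)
    singlesTab <- do.call(rbind, singles)
    singleSpec <- subtypeSpecificity(singlesTab)

    stage <- "combination screen"
    combos <- screenCombinations(models, catalog = catalog,
                                 cutoff = cfg$cutoff, delta = cfg$delta,
                                 singles = singles)
    comboSpec <- if (nrow(combos)) subtypeSpecificity(combos) else NULL

    stage <- "safety check"
    safety <- NULL
    if (!is.null(control) && !is.null(combos) && nrow(combos)) {
      pairs <- unique(combos[, c("drugA", "drugB")])
      safety <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        tu <- union(catalog$targets[[match(pairs$drugA[i], catalog$drug_id)]],
                    catalog$targets[[match(pairs$drugB[i], catalog$drug_id)]])
        s <- safetyCheck(control, targets = tu, eta = cfg$eta)
        data.frame(drugA = pairs$drugA[i], drugB = pairs$drugB[i],
                   pass = s$pass, biomass_ratio = s$biomass_ratio,
                   atp_ratio = s$atp_ratio, stringsAsFactors = FALSE)
      }))
    }

    stage <- "prioritization"
    predicted <- sort(unique(singlesTab$drug_id[singlesTab$hit]))
    refDrugs <- catalog$drug_id[.hasCategory(catalog, "AntiBC")]
    prior <- if (length(predicted) || (!is.null(combos) && nrow(combos)))
      prioritizeDrugs(predicted,
                      if (!is.null(combos) && nrow(combos))
                        unique(combos[combos$hit, c("drugA", "drugB")])
                      else NULL,
                      evidence, reference_drugs = refDrugs)
    else NULL

    list(config = cfg, models = models, control = control,
         summaries = do.call(rbind, c(
           lapply(names(models), function(nm)
             modelSummary(models[[nm]], sum(grp == nm))),
           if (!is.null(control))
             list(modelSummary(control, sum(grp == cfg$control_label))))),
         calls = calls, profiles = profiles,
         exchangeComparison = exchangeComparison,
         essentiality = essentiality, commonEssentials = commonEss,
         singles = singlesTab, singleSpecificity = singleSpec,
         combinations = combos, comboSpecificity = comboSpec,
         safety = safety, prioritization = prior)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         "\nhint: check the inputs this stage consumes, then re-run",
         call. = FALSE)
  })

  .writePipelineOutputs(res, cfg)
  invisible(res)
}

.writePipelineOutputs <- function(res, cfg) {
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x) && NROW(x))
    write.table(x, file.path(out, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  for (nm in names(res$models))
    writeNetwork(res$models[[nm]], file.path(out, paste0("model_", nm, ".json")))
  if (!is.null(res$control))
    writeNetwork(res$control, file.path(out, "model_control.json"))
  wt(res$summaries, "model_summary.tsv")
  wt(do.call(rbind, res$profiles), "exchange_profiles.tsv")
  wt(res$exchangeComparison, "exchange_comparison.tsv")
  wt(res$essentiality, "essentiality.tsv")
  wt(res$commonEssentials, "common_essentials.tsv")
  wt(res$singles, "single_drugs.tsv")
  wt(res$singleSpecificity, "single_drug_specificity.tsv")
  wt(res$combinations, "combinations.tsv")
  wt(res$comboSpecificity, "combination_specificity.tsv")
  wt(res$safety, "safety.tsv")
  if (!is.null(res$prioritization)) {
    wt(res$prioritization$ranking, "drug_ranking.tsv")
    wt(res$prioritization$excluded, "excluded_drugs.tsv")
  }
  inputs <- unlist(cfg[c("network", "medium", "expression", "labels",
                         "catalog")])
  manifest <- list(
    package = "gemscreen",
    version = as.character(utils::packageVersion("gemscreen")),
    seed = cfg$seed,
    thresholds = cfg[c("fraction", "epsilon", "q", "cutoff", "delta", "eta",
                       "ratio_cutoff", "p_hi", "p_lo")],
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
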