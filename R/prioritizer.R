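# Evidence aggregation and drug ranking.
#
# Evidence arrives as curated TSVs, one per tier:
#   ic50:      drug_id, cell_line, ic50_uM
#   viability: drug_id, reduction_pct
#   pk:        drug_id, logbb, bbb_permeable, abc_transporter
#   xenograft: drug_id, growth_reduction_pct
#   clinical:  drug_id, phase, arms, outcome (improved/none/worse)
#   flags:     drug_id, cofactor_of_target, induces_proliferation
#   ddi:       drugA, drugB, severity (none/minor/major/unknown)

#' Read evidence tables from a directory
#'
#' Expects files `ic50.tsv`, `viability.tsv`, `pk.tsv`, `xenograft.tsv`,
#' `clinical.tsv`, `flags.tsv`, `ddi.tsv` (each optional; missing tables are
#' empty).
#'
#' @param dir directory containing the TSVs.
#' @return named list of data.frames.
#' @export
readEvidence <- function(dir) {
  rd <- function(f, cols) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  list(ic50 = rd("ic50.tsv", c("drug_id", "cell_line", "ic50_uM")),
       viability = rd("viability.tsv", c("drug_id", "reduction_pct")),
       pk = rd("pk.tsv", c("drug_id", "logbb", "bbb_permeable",
                           "abc_transporter")),
       xenograft = rd("xenograft.tsv", c("drug_id", "growth_reduction_pct")),
       clinical = rd("clinical.tsv", c("drug_id", "phase", "arms", "outcome")),
       flags = rd("flags.tsv", c("drug_id", "cofactor_of_target",
                                 "induces_proliferation")),
       ddi = rd("ddi.tsv", c("drugA", "drugB", "severity")))
}

#' Median IC50 potency per drug
#'
#' Duplicate (drug, cell line) records are averaged first, then the median
#' across cell lines is taken as the potency measure (µM; lower is more
#' potent). Non-positive IC50 records are rejected with a log note. Drugs
#' without records get NA.
#'
#' @param ic50 data.frame `drug_id`, `cell_line`, `ic50_uM`.
#' @param drugs drug ids to report (default: those with records).
#' @return named numeric vector of median IC50s (µM).
#' @export
computePotency <- function(ic50, drugs = NULL) {
  bad <- !is.finite(ic50$ic50_uM) | ic50$ic50_uM <= 0
  if (any(bad)) {
    message("rejected ", sum(bad), " non-positive IC50 record(s)")
    ic50 <- ic50[!bad, , drop = FALSE]
  }
  if (is.null(drugs)) drugs <- sort(unique(ic50$drug_id))
  out <- setNames(rep(NA_real_, length(drugs)), drugs)
  if (nrow(ic50)) {
    perLine <- stats::aggregate(ic50_uM ~ drug_id + cell_line, data = ic50,
                                FUN = mean)
    med <- tapply(perLine$ic50_uM, perLine$drug_id, median)
    out[names(med)] <- med
  }
  out
}

#' Apply exclusion rules to predicted drugs
#'
#' Drops drugs flagged as inducing proliferation in vitro or as cofactors of
#' their target genes; every drop is logged with its reason(s).
#'
#' @param drugs character vector of predicted drug ids.
#' @param flags data.frame `drug_id`, `cofactor_of_target`,
#'   `induces_proliferation` (catalog flags work too).
#' @return list: `retained` (character), `excluded` (data.frame `drug_id`,
#'   `reasons`).
#' @export
applyExclusions <- function(drugs, flags) {
  if ("drug_id" %in% names(flags)) {
    idx <- match(drugs, flags$drug_id)
    cof <- as.logical(flags$cofactor_of_target[idx]) %in% TRUE
    pro <- as.logical(flags$induces_proliferation[idx]) %in% TRUE
  } else cof <- pro <- rep(FALSE, length(drugs))
  drop <- cof | pro
  reasons <- vapply(seq_along(drugs), function(i)
    paste(c(if (cof[i]) "cofactor_of_target",
            if (pro[i]) "induces_proliferation"), collapse = ";"),
    character(1))
  excluded <- data.frame(drug_id = drugs[drop], reasons = reasons[drop],
                         stringsAsFactors = FALSE)
  if (nrow(excluded))
    message("excluded: ",
            paste(paste0(excluded$drug_id, " (", excluded$reasons, ")"),
                  collapse = ", "))
  list(retained = drugs[!drop], excluded = excluded)
}

.TIER_RULES_DEFAULT <- list(
  viability_min = 50,      # % median viability reduction for in-vitro call
  xenograft_min = 25,      # % median growth reduction (PDX tier), inclusive
  clinical_min_arms = 2,   # two-arm trials only
  clinical_phases = c("I/II", "II", "II/III", "III", "IV")
)

#' Per-tier effectiveness calls for one drug
#'
#' Tiers: `in_vitro` — effective when the median viability reduction is at
#' least `viability_min` (default 50%) or the potency is at or below the
#' reference (AntiBC) median potency; `xenograft` — effective when the
#' median growth reduction is at least `xenograft_min` (default 25%,
#' inclusive); `clinical` — effective when any two-arm record of phase I/II
#' or higher reports an improved primary survival outcome. A tier without
#' records is `untested`. Contradictory clinical records resolve by majority
#' with ties called ineffective (conservative).
#'
#' @param drug drug id.
#' @param evidence evidence list from [readEvidence()].
#' @param rules rule thresholds (see `.TIER_RULES_DEFAULT`).
#' @param reference_potency median potency of the reference drug class (µM),
#'   NA to skip the potency route.
#' @return named character vector with entries `in_vitro`, `xenograft`,
#'   `clinical` in \{"effective", "ineffective", "untested"\}.
#' @export
classifyTiers <- function(drug, evidence, rules = .TIER_RULES_DEFAULT,
                          reference_potency = NA_real_) {
  rules <- modifyList(.TIER_RULES_DEFAULT, rules)

  ic <- evidence$ic50[evidence$ic50$drug_id == drug, , drop = FALSE]
  vi <- evidence$viability[evidence$viability$drug_id == drug, , drop = FALSE]
  inv <- if (!nrow(ic) && !nrow(vi)) "untested" else {
    pot <- if (nrow(ic)) unname(computePotency(ic)[drug]) else NA_real_
    viaOk <- nrow(vi) > 0 && median(vi$reduction_pct) >= rules$viability_min
    potOk <- is.finite(pot) && is.finite(reference_potency) &&
             pot <= reference_potency
    if (viaOk || potOk) "effective" else "ineffective"
  }

  xg <- evidence$xenograft[evidence$xenograft$drug_id == drug, , drop = FALSE]
  xen <- if (!nrow(xg)) "untested"
         else if (median(xg$growth_reduction_pct) >= rules$xenograft_min)
           "effective" else "ineffective"

  cl <- evidence$clinical[evidence$clinical$drug_id == drug, , drop = FALSE]
  cl <- cl[cl$arms >= rules$clinical_min_arms &
           cl$phase %in% rules$clinical_phases, , drop = FALSE]
  cli <- if (!nrow(cl)) "untested" else {
    nImp <- sum(cl$outcome == "improved")
    nNot <- sum(cl$outcome != "improved")
    if (nImp > nNot) "effective" else "ineffective"
  }

  c(in_vitro = inv, xenograft = xen, clinical = cli)
}

.DDI_ORDER <- c(none = 0, minor = 1, unknown = 2, major = 3)

#' Rank drug candidates
#'
#' Lexicographic ranking of retained candidates: (1) number of effective
#' tiers, descending; (2) drug-drug interaction severity, ascending
#' (none < minor < unknown < major; singles count as none); (3) potency
#' (median IC50, µM) ascending with missing last; (4) LogBB descending with
#' missing last; ties broken by drug id. Excluded drugs carry no rank.
#' Candidates with no tested tier are listed last and flagged.
#'
#' @param drugs character vector of candidate ids (drugs, or combination ids
#'   like `"a+b"`).
#' @param tiers matrix/data.frame of per-tier calls, rows named by drug
#'   (from [classifyTiers()]).
#' @param potency named numeric vector (µM) from [computePotency()].
#' @param logbb named numeric vector of LogBB values.
#' @param ddi named character vector of DDI severities (combinations only;
#'   missing = none).
#' @return data.frame sorted by rank: `drug_id`, `rank`,
#'   `effective_tiers`, `ddi`, `potency_uM`, `logbb`, tier columns,
#'   `untested_overall`.
#' @export
rankCandidates <- function(drugs, tiers, potency = NULL, logbb = NULL,
                           ddi = NULL) {
  tiers <- as.matrix(tiers)
  get <- function(v, d, default) {
    if (is.null(v) || !(d %in% names(v)) || is.na(v[d])) default else v[[d]]
  }
  eff <- vapply(drugs, function(d)
    sum(tiers[d, ] == "effective"), numeric(1))
  tested <- vapply(drugs, function(d)
    any(tiers[d, ] != "untested"), logical(1))
  ddiRank <- vapply(drugs, function(d)
    .DDI_ORDER[[get(ddi, d, "none")]], numeric(1))
  pot <- vapply(drugs, function(d) get(potency, d, NA_real_), numeric(1))
  lb <- vapply(drugs, function(d) get(logbb, d, NA_real_), numeric(1))

  ord <- order(!tested,                       # untested-overall last
               -eff, ddiRank,
               ifelse(is.na(pot), Inf, pot),
               ifelse(is.na(lb), -Inf, -lb),
               drugs)
  out <- data.frame(drug_id = drugs[ord], rank = seq_along(drugs),
                    effective_tiers = eff[ord],
                    ddi = names(.DDI_ORDER)[ddiRank[ord] + 1],
                    potency_uM = pot[ord], logbb = lb[ord],
                    stringsAsFactors = FALSE)
  out <- cbind(out, tiers[drugs[ord], , drop = FALSE])
  out$untested_overall <- !tested[ord]
  rownames(out) <- NULL
  out
}

#' Full prioritization of predicted drugs and combinations
#'
#' Convenience wrapper: applies exclusions, computes potency (CSF LogBB is
#' preferred over the binary BBB flag when both are present), classifies
#' tiers against the reference class and ranks. For combinations the pair
#' potency is the stronger (lower) of the two partners and the tier calls
#' are taken from the pair's FDA partner unless pair-level records exist
#' under the combined id `"a+b"`.
#'
#' @param predicted character vector of predicted single-drug ids.
#' @param combinations optional data.frame with `drugA`, `drugB`.
#' @param evidence evidence list from [readEvidence()].
#' @param reference_drugs ids whose median potency anchors the in-vitro
#'   potency route (e.g. the approved anti-brain-tumour chemotherapies).
#' @param rules tier rules overriding the defaults.
#' @return list: `ranking` (data.frame), `excluded` (data.frame),
#'   `potency`, `logbb` (named vectors).
#' @export
prioritizeDrugs <- function(predicted, combinations = NULL, evidence,
                            reference_drugs = character(0),
                            rules = list()) {
  exq <- applyExclusions(predicted, evidence$flags)
  potAll <- computePotency(evidence$ic50)
  refPot <- if (length(reference_drugs))
    median(potAll[intersect(reference_drugs, names(potAll))], na.rm = TRUE)
  else NA_real_

  ids <- exq$retained
  comboIds <- character(0)
  comboDdi <- character(0)
  if (!is.null(combinations) && nrow(combinations)) {
    pairs <- unique(combinations[, c("drugA", "drugB")])
    comboIds <- paste0(pairs$drugA, "+", pairs$drugB)
    dd <- evidence$ddi
    comboDdi <- vapply(seq_len(nrow(pairs)), function(i) {
      hit <- dd[(dd$drugA == pairs$drugA[i] & dd$drugB == pairs$drugB[i]) |
                (dd$drugA == pairs$drugB[i] & dd$drugB == pairs$drugA[i]), ,
                drop = FALSE]
      if (nrow(hit)) hit$severity[1] else "unknown"
    }, character(1))
    names(comboDdi) <- comboIds
  }
  all_ids <- c(ids, comboIds)
  if (!length(all_ids)) stop("no candidates left to rank")

  tierOf <- function(id) {
    if (grepl("+", id, fixed = TRUE)) {
      parts <- strsplit(id, "+", fixed = TRUE)[[1]]
      if (id %in% evidence$clinical$drug_id ||
          id %in% evidence$ic50$drug_id ||
          id %in% evidence$xenograft$drug_id)
        classifyTiers(id, evidence, rules, refPot)
      else classifyTiers(parts[1], evidence, rules, refPot)
    } else classifyTiers(id, evidence, rules, refPot)
  }
  tiers <- t(vapply(all_ids, tierOf, character(3)))

  pk <- evidence$pk
  logbb <- setNames(rep(NA_real_, length(all_ids)), all_ids)
  if (nrow(pk)) {
    idx <- match(all_ids, pk$drug_id)
    logbb[!is.na(idx)] <- pk$logbb[idx[!is.na(idx)]]
  }
  potency <- setNames(rep(NA_real_, length(all_ids)), all_ids)
  potency[names(potAll)[names(potAll) %in% all_ids]] <-
    potAll[names(potAll) %in% all_ids]
  for (i in seq_along(comboIds)) {
    parts <- strsplit(comboIds[i], "+", fixed = TRUE)[[1]]
    if (is.na(potency[comboIds[i]]))
      potency[comboIds[i]] <- suppressWarnings(min(potAll[parts], na.rm = TRUE))
    if (!is.finite(potency[comboIds[i]])) potency[comboIds[i]] <- NA_real_
    if (is.na(logbb[comboIds[i]]) && nrow(pk)) {
      pl <- pk$logbb[match(parts, pk$drug_id)]
      if (any(is.finite(pl))) logbb[comboIds[i]] <- min(pl, na.rm = TRUE)
    }
  }
  ddi <- setNames(rep("none", length(all_ids)), all_ids)
  ddi[names(comboDdi)] <- comboDdi

  list(ranking = rankCandidates(all_ids, tiers, potency, logbb, ddi),
       excluded = exq$excluded, potency = potency, logbb = logbb)
}
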