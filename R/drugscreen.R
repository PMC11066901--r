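#' Read a drug catalog
#'
#' TSV with columns `drug_id`, `name`, `category` (semicolon-joined subset of
#' FDA / AntiBC / IAG), `targets` (semicolon-joined gene ids), and optional
#' logical flag columns `cofactor_of_target`, `induces_proliferation`.
#'
#' @param path TSV file path.
#' @return data.frame with list-columns `targets` and `category`.
#' @export
readDrugCatalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "name", "category", "targets")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("drug catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$targets <- strsplit(tab$targets, ";", fixed = TRUE)
  tab$category <- strsplit(tab$category, ";", fixed = TRUE)
  badcat <- setdiff(unlist(tab$category), c("FDA", "AntiBC", "IAG"))
  if (length(badcat)) stop("unknown drug category: ",
                           paste(badcat, collapse = ", "))
  if (any(lengths(tab$targets) == 0))
    stop("drug(s) with empty target set")
  for (fl in c("cofactor_of_target", "induces_proliferation"))
    tab[[fl]] <- if (is.null(tab[[fl]])) FALSE else as.logical(tab[[fl]])
  tab
}

.hasCategory <- function(catalog, cat)
  vapply(catalog$category, function(cs) cat %in% cs, logical(1))

# growth ratio after jointly closing every reaction disabled by deleting
# `targets`; targets absent from the model are ignored.
.jointDeletionRatio <- function(model, targets, zwt) {
  targets <- intersect(targets, genes(model))
  if (!length(targets)) return(1)
  hit <- which(vapply(seq_along(model@gprTrees), function(k) {
    tr <- model@gprTrees[[k]]
    if (is.null(tr)) return(FALSE)
    length(intersect(gprGenes(tr), targets)) > 0 && !.gprEval(tr, targets)
  }, logical(1)))
  if (!length(hit)) return(1)
  ko <- model
  ko@lb[hit] <- 0; ko@ub[hit] <- 0
  s <- fba(ko)
  z <- if (s@status != "optimal") 0 else s@objval
  min(max(z / zwt, 0), 1)
}

#' Screen single drugs by joint knockout of their targets
#'
#' For every drug, all mapped target genes are deleted jointly (GPR
#' semantics) and the drug effect `E = 1 - grRatio` recorded. A drug is a
#' hit when `E >= cutoff` (inclusive, default 0.5) and lethal when it shuts
#' growth down completely (`E >= 1 - lethal_tol`). Targets absent from the
#' model are ignored (logged via message); a drug with no mapped target has
#' `E = 0`.
#'
#' @param model a growing [MetabolicNetwork-class].
#' @param medium optional [MediumDefinition-class].
#' @param catalog drug catalog (see [readDrugCatalog()]).
#' @param cutoff hit cutoff on E, default 0.5.
#' @param lethal_tol tolerance for the lethal call.
#' @return data.frame: `drug_id`, `name`, `model`, `n_targets_mapped`,
#'   `grRatio`, `E`, `hit`, `lethal`.
#' @export
screenSingleDrugs <- function(model, medium = NULL, catalog, cutoff = 0.5,
                              lethal_tol = 1e-6) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  if (!nrow(catalog))
    return(data.frame(drug_id = character(0), name = character(0),
                      model = character(0), n_targets_mapped = integer(0),
                      grRatio = numeric(0), E = numeric(0),
                      hit = logical(0), lethal = logical(0)))
  wt <- fba(model)
  if (wt@status != "optimal" || wt@objval <= .TOL_FEAS * 10)
    stop("model does not grow; drug effects are undefined")
  mg <- genes(model)
  orphan <- setdiff(unique(unlist(catalog$targets)), mg)
  if (length(orphan))
    message("drug targets not in model '", model@id, "' (ignored): ",
            paste(orphan, collapse = ", "))
  gr <- vapply(catalog$targets, .jointDeletionRatio, numeric(1),
               model = model, zwt = wt@objval)
  E <- 1 - gr
  data.frame(drug_id = catalog$drug_id, name = catalog$name, model = model@id,
             n_targets_mapped = vapply(catalog$targets,
                                       function(t) length(intersect(t, mg)),
                                       integer(1)),
             grRatio = gr, E = E,
             hit = E >= cutoff - .TOL_FEAS,
             lethal = E >= 1 - lethal_tol,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bliss-independence classification of a drug pair
#'
#' Under Bliss independence the expected joint effect of two drugs with
#' independent targets is `E_exp = E_A + E_B - E_A * E_B`. The pair is
#' synergistic when the observed joint effect exceeds `E_exp` by more than
#' `delta`, antagonistic when it falls short by more than `delta`, additive
#' otherwise. Symmetric in (E_A, E_B).
#'
#' @param E_A,E_B,E_AB effects in \[0, 1\] (growth reduction 1 - grRatio).
#' @param delta synergy tolerance, default 0.05.
#' @param method `"excess"` (default; classify on `E_AB - E_exp`) or
#'   `"ratio"` (classify on the combination index `E_AB / E_exp`, with
#'   `1 +/- delta` as the band; a zero expectation with a positive observed
#'   effect is synergistic).
#' @return list with `E_exp`, `excess` (E_AB - E_exp) and `class`.
#' @export
classifyBliss <- function(E_A, E_B, E_AB, delta = 0.05,
                          method = c("excess", "ratio")) {
  method <- match.arg(method)
  stopifnot(all(c(E_A, E_B, E_AB) >= -1e-9), all(c(E_A, E_B, E_AB) <= 1 + 1e-9))
  E_exp <- E_A + E_B - E_A * E_B
  excess <- E_AB - E_exp
  cls <- if (method == "excess") {
    if (excess > delta) "synergistic"
    else if (excess < -delta) "antagonistic"
    else "additive"
  } else {
    if (E_exp <= .TOL_FEAS) {
      if (E_AB > delta) "synergistic" else "additive"
    } else {
      ci <- E_AB / E_exp
      if (ci > 1 + delta) "synergistic"
      else if (ci < 1 - delta) "antagonistic"
      else "additive"
    }
  }
  list(E_exp = E_exp, excess = excess, class = cls)
}

#' Screen drug combinations with Bliss classification
#'
#' Candidate pairs are (FDA drugs that are not lethal as singles in any
#' tumour model) x (AntiBC or IAG drugs); drugs already predicted to shut
#' down biomass on their own are not tested further in combination. The
#' joint effect `E_AB` comes from deleting the union of both target sets.
#' Pairs are reported when `E_AB >= cutoff` in at least one model
#' (per-model hit flags retained), with the Bliss class per model. Pair
#' ordering is deterministic: drugA is always the FDA partner, pairs sorted
#' by id.
#'
#' @param models named list of [MetabolicNetwork-class] tumour models.
#' @param medium optional [MediumDefinition-class].
#' @param catalog drug catalog.
#' @param cutoff combination hit cutoff on `E_AB`, default 0.5.
#' @param delta Bliss tolerance, default 0.05.
#' @param singles optional precomputed single-drug screens (named list of
#'   data.frames per model); computed when missing.
#' @param lethal_tol lethal-single tolerance.
#' @return data.frame: `drugA`, `drugB`, `model`, `E_A`, `E_B`, `E_AB`,
#'   `E_exp`, `excess`, `class`, `hit`. Only pairs hitting in >= 1 model are
#'   returned (all models' rows for those pairs).
#' @export
screenCombinations <- function(models, medium = NULL, catalog, cutoff = 0.5,
                               delta = 0.05, singles = NULL,
                               lethal_tol = 1e-6) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a named list")
  if (!is.null(medium))
    models <- lapply(models, applyMedium, medium = medium)
  if (is.null(singles))
    singles <- lapply(models, screenSingleDrugs, catalog = catalog,
                      cutoff = cutoff, lethal_tol = lethal_tol)

  fda <- catalog[.hasCategory(catalog, "FDA"), , drop = FALSE]
  partner <- catalog[.hasCategory(catalog, "AntiBC") |
                     .hasCategory(catalog, "IAG"), , drop = FALSE]
  lethalAny <- unique(unlist(lapply(singles, function(s)
    s$drug_id[s$lethal])))
  fda <- fda[!(fda$drug_id %in% lethalAny), , drop = FALSE]
  fda <- fda[order(fda$drug_id), , drop = FALSE]
  partner <- partner[order(partner$drug_id), , drop = FALSE]

  zwt <- lapply(models, function(m) fba(m)@objval)
  rows <- list()
  for (a in seq_len(nrow(fda))) for (b in seq_len(nrow(partner))) {
    if (fda$drug_id[a] == partner$drug_id[b]) next
    tA <- fda$targets[[a]]; tB <- partner$targets[[b]]
    if (length(intersect(tA, tB)))
      message("pair ", fda$drug_id[a], "/", partner$drug_id[b],
              " has overlapping targets (union semantics)")
    for (mn in names(models)) {
      sg <- singles[[mn]]
      EA <- sg$E[sg$drug_id == fda$drug_id[a]]
      EB <- sg$E[sg$drug_id == partner$drug_id[b]]
      EAB <- 1 - .jointDeletionRatio(models[[mn]], union(tA, tB), zwt[[mn]])
      bl <- classifyBliss(EA, EB, EAB, delta = delta)
      rows[[length(rows) + 1L]] <- data.frame(
        drugA = fda$drug_id[a], drugB = partner$drug_id[b], model = mn,
        E_A = EA, E_B = EB, E_AB = EAB, E_exp = bl$E_exp,
        excess = bl$excess, class = bl$class,
        hit = EAB >= cutoff - .TOL_FEAS, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  keep <- unique(out[out$hit, c("drugA", "drugB")])
  out <- merge(keep, out, by = c("drugA", "drugB"), sort = TRUE)
  out[order(out$drugA, out$drugB, out$model), , drop = FALSE]
}

#' Healthy-control safety check of a joint target deletion
#'
#' Applies the joint deletion of a drug (or pair) target union to the
#' healthy control model and requires that both the maximal ATP-demand flux
#' and the maximal biomass flux retain at least `1 - eta` of their
#' wild-type optima.
#'
#' @param control the healthy [MetabolicNetwork-class]; must carry an
#'   ATP-demand reaction.
#' @param medium optional [MediumDefinition-class].
#' @param targets character vector: union of target genes to delete.
#' @param eta tolerated fractional loss, default 0.05.
#' @return list with `pass`, `biomass_ratio`, `atp_ratio`.
#' @export
safetyCheck <- function(control, medium = NULL, targets, eta = 0.05) {
  if (!length(atpDemandReaction(control)))
    stop("configuration error: control model has no ATP-demand reaction")
  if (!is.null(medium)) control <- applyMedium(control, medium)
  wtB <- fba(control)
  wtA <- fba(control, objective = atpDemandReaction(control))
  if (wtB@status != "optimal" || wtA@status != "optimal" ||
      wtB@objval <= .TOL_FEAS || wtA@objval <= .TOL_FEAS)
    stop("control model cannot produce biomass and ATP in the wild type")
  rB <- .jointDeletionRatio(control, targets, wtB@objval)
  ctlA <- control
  ctlA@objective <- atpDemandReaction(control)
  rA <- .jointDeletionRatio(ctlA, targets, wtA@objval)
  list(pass = rB >= 1 - eta && rA >= 1 - eta,
       biomass_ratio = rB, atp_ratio = rA)
}

#' Subtype specificity of screened drugs or combinations
#'
#' Labels each drug (or pair) `"pan"` when it is a hit in every model,
#' `"specific to <M>"` when a hit in exactly one, otherwise the
#' comma-joined list of models where it hits (or `"none"`).
#'
#' @param results data.frame from [screenSingleDrugs()] (stacked over
#'   models) or [screenCombinations()]; needs columns `model`, `hit` and
#'   either `drug_id` or `drugA`/`drugB`.
#' @return data.frame: one row per drug/pair with `hit_models`,
#'   `specificity`.
#' @export
subtypeSpecificity <- function(results) {
  key <- if ("drug_id" %in% names(results)) "drug_id" else c("drugA", "drugB")
  models <- sort(unique(results$model))
  ids <- unique(results[, key, drop = FALSE])
  out <- lapply(seq_len(nrow(ids)), function(i) {
    sel <- rep(TRUE, nrow(results))
    for (k in key) sel <- sel & results[[k]] == ids[[k]][i]
    hitIn <- sort(unique(results$model[sel & results$hit]))
    spec <- if (length(hitIn) == length(models)) "pan"
            else if (length(hitIn) == 1L) paste("specific to", hitIn)
            else if (!length(hitIn)) "none"
            else paste(hitIn, collapse = ",")
    cbind(ids[i, , drop = FALSE],
          data.frame(hit_models = paste(hitIn, collapse = ","),
                     specificity = spec, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
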