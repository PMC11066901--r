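#' MetabolicNetwork: a constraint-based metabolic model
#'
#' Holds the stoichiometric matrix, reaction bounds (mmol/gDW/h), parsed
#' gene-protein-reaction (GPR) rules, the biomass objective and an optional
#' ATP-demand reaction. Exchange reactions are defined structurally as the
#' reactions with exactly one nonzero stoichiometric entry, written in the
#' export-positive convention (`met_e ->`): uptake is negative flux.
#'
#' @slot id model identifier.
#' @slot mets metabolite identifiers (compartment-tagged, e.g. `glc_e`).
#' @slot rxns reaction identifiers.
#' @slot S sparse stoichiometric matrix, metabolites x reactions.
#' @slot lb,ub flux bounds per reaction; `lb <= ub`, `lb < 0` marks a
#'   reversible reaction.
#' @slot gpr GPR rule text per reaction (`""` = no rule).
#' @slot gprTrees parsed GPR boolean trees (cached at construction).
#' @slot objective identifier of the biomass (objective) reaction.
#' @slot atpDemand identifier of the ATP-demand reaction, or `character(0)`.
#'
#' @seealso [newMetabolicNetwork()], [readNetwork()], [exchangeReactions()]
#' @export
setClass("MetabolicNetwork",
  representation(
    id        = "character",
    mets      = "character",
    rxns      = "character",
    S         = "Matrix",
    lb        = "numeric",
    ub        = "numeric",
    gpr       = "character",
    gprTrees  = "list",
    objective = "character",
    atpDemand = "character"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character(0)
  n <- length(object@rxns)
  m <- length(object@mets)
  if (anyDuplicated(object@rxns)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(object@mets)) msg <- c(msg, "duplicated metabolite ids")
  if (!all(dim(object@S) == c(m, n)))
    msg <- c(msg, sprintf("S is %dx%d, expected %dx%d",
                          nrow(object@S), ncol(object@S), m, n))
  if (length(object@lb) != n || length(object@ub) != n)
    msg <- c(msg, "bounds length must equal number of reactions")
  else if (any(object@lb > object@ub))
    msg <- c(msg, paste0("lb > ub for: ",
                         paste(object@rxns[object@lb > object@ub], collapse = ", ")))
  if (length(object@gpr) != n)
    msg <- c(msg, "gpr length must equal number of reactions")
  if (length(object@objective) != 1L || !(object@objective %in% object@rxns))
    msg <- c(msg, "objective reaction missing from the network")
  if (length(object@atpDemand) > 1L ||
      (length(object@atpDemand) == 1L && !(object@atpDemand %in% object@rxns)))
    msg <- c(msg, "atpDemand must name an existing reaction (or be empty)")
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicNetwork
#'
#' @param rxns data.frame-free constructor: reaction ids.
#' @param mets metabolite ids.
#' @param S stoichiometric matrix (metabolites x reactions), dense or sparse;
#'   every nonzero entry must reference a declared metabolite.
#' @param lb,ub numeric bounds per reaction.
#' @param gpr character GPR rules per reaction ("" for none); parsed at
#'   construction so malformed rules fail here, never during evaluation.
#' @param objective reaction id of the biomass objective.
#' @param atpDemand optional reaction id of an ATP-demand reaction.
#' @param id model id.
#' @return a validated [MetabolicNetwork-class] object.
#' @export
newMetabolicNetwork <- function(rxns, mets, S, lb, ub,
                                gpr = rep("", length(rxns)),
                                objective, atpDemand = character(0),
                                id = "model") {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(S) <- list(mets, rxns)
  trees <- lapply(gpr, parseGpr)
  new("MetabolicNetwork",
      id = id, mets = as.character(mets), rxns = as.character(rxns),
      S = S, lb = as.numeric(lb), ub = as.numeric(ub),
      gpr = as.character(gpr), gprTrees = trees,
      objective = objective, atpDemand = atpDemand)
}

#' MediumDefinition: extracellular medium composition
#'
#' Maps extracellular metabolite ids to maximum uptake rates
#' (non-negative, mmol/gDW/h). Metabolites not listed get uptake 0. Rates are
#' used directly as uptake-rate bounds; no concentration-to-rate conversion is
#' performed.
#'
#' @slot uptake named non-negative numeric vector of maximum uptake rates.
#' @export
setClass("MediumDefinition", representation(uptake = "numeric"))

setValidity("MediumDefinition", function(object) {
  msg <- character(0)
  if (length(object@uptake) &&
      (is.null(names(object@uptake)) || any(!nzchar(names(object@uptake)))))
    msg <- c(msg, "uptake rates must be named by metabolite id")
  if (any(object@uptake < 0)) msg <- c(msg, "uptake rates must be >= 0")
  if (anyDuplicated(names(object@uptake)))
    msg <- c(msg, "duplicated metabolite ids in medium")
  if (length(msg)) msg else TRUE
})

#' @param uptake named non-negative numeric vector (metabolite id -> max
#'   uptake rate).
#' @rdname MediumDefinition-class
#' @export
newMedium <- function(uptake = numeric(0)) {
  new("MediumDefinition", uptake = uptake)
}

#' FluxSolution: result of one flux balance analysis
#'
#' @slot objval objective value `z*` (NA unless status is "optimal").
#' @slot fluxes named flux vector over reactions (length 0 unless optimal).
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxSolution",
  representation(objval = "numeric", fluxes = "numeric", status = "character"))

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution |", object@status)
  if (object@status == "optimal")
    cat(sprintf(" | z* = %.6g over %d reactions", object@objval,
                length(object@fluxes)))
  cat("\n")
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork '%s': %d reactions, %d metabolites, %d genes\n",
              object@id, length(object@rxns), length(object@mets),
              length(genes(object))))
  cat(sprintf("  objective: %s", object@objective))
  if (length(object@atpDemand)) cat(sprintf(" | ATP demand: %s", object@atpDemand))
  cat(sprintf("\n  exchanges: %d | reversible: %d\n",
              length(exchangeReactions(object)), sum(object@lb < 0)))
})

setMethod("show", "MediumDefinition", function(object) {
  cat(sprintf("MediumDefinition: %d metabolites with uptake > 0 allowed\n",
              sum(object@uptake > 0)))
})
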