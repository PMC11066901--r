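#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))

#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))

#' @export
setGeneric("genes", function(object, ...) standardGeneric("genes"))

#' @export
setGeneric("stoichiometry", function(object, ...) standardGeneric("stoichiometry"))

#' @export
setGeneric("lowerBounds", function(object, ...) standardGeneric("lowerBounds"))

#' @export
setGeneric("upperBounds", function(object, ...) standardGeneric("upperBounds"))

#' @export
setGeneric("gprRules", function(object, ...) standardGeneric("gprRules"))

#' @export
setGeneric("objectiveReaction", function(object, ...) standardGeneric("objectiveReaction"))

#' @export
setGeneric("atpDemandReaction", function(object, ...) standardGeneric("atpDemandReaction"))

#' @export
setGeneric("exchangeReactions", function(object, ...) standardGeneric("exchangeReactions"))

#' @export
setGeneric("uptakeRates", function(object, ...) standardGeneric("uptakeRates"))

#' Accessors for MetabolicNetwork and MediumDefinition
#'
#' `reactions()`, `metabolites()` and `genes()` return identifier vectors;
#' `stoichiometry()` the sparse S matrix; `lowerBounds()`/`upperBounds()`
#' named bound vectors; `gprRules()` the GPR rule strings;
#' `objectiveReaction()`/`atpDemandReaction()` the special reaction ids;
#' `exchangeReactions()` the ids of the single-metabolite boundary reactions;
#' `uptakeRates()` the named uptake vector of a medium.
#'
#' @param object a [MetabolicNetwork-class] or [MediumDefinition-class].
#' @param ... unused.
#' @name network-accessors
#' @aliases reactions metabolites genes stoichiometry lowerBounds upperBounds
#'   gprRules objectiveReaction atpDemandReaction exchangeReactions uptakeRates
NULL

#' @rdname network-accessors
setMethod("reactions", "MetabolicNetwork", function(object, ...) object@rxns)

#' @rdname network-accessors
setMethod("metabolites", "MetabolicNetwork", function(object, ...) object@mets)

#' @rdname network-accessors
setMethod("genes", "MetabolicNetwork", function(object, ...) {
  sort(unique(unlist(lapply(object@gprTrees, gprGenes))))
})

#' @rdname network-accessors
setMethod("stoichiometry", "MetabolicNetwork", function(object, ...) object@S)

#' @rdname network-accessors
setMethod("lowerBounds", "MetabolicNetwork", function(object, ...)
  setNames(object@lb, object@rxns))

#' @rdname network-accessors
setMethod("upperBounds", "MetabolicNetwork", function(object, ...)
  setNames(object@ub, object@rxns))

#' @rdname network-accessors
setMethod("gprRules", "MetabolicNetwork", function(object, ...)
  setNames(object@gpr, object@rxns))

#' @rdname network-accessors
setMethod("objectiveReaction", "MetabolicNetwork", function(object, ...)
  object@objective)

#' @rdname network-accessors
setMethod("atpDemandReaction", "MetabolicNetwork", function(object, ...)
  object@atpDemand)

#' @rdname network-accessors
setMethod("exchangeReactions", "MetabolicNetwork", function(object, ...) {
  nz <- Matrix::colSums(object@S != 0)
  object@rxns[nz == 1L]
})

#' @rdname network-accessors
setMethod("uptakeRates", "MediumDefinition", function(object, ...) object@uptake)
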