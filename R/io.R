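#' Read a metabolic network from file
#'
#' Two dialects are supported: a JSON model dialect compatible with the
#' COBRA-community JSON schema (canonical format of this package) and SBML
#' Level 3 with the FBC version 2 package. Bounds and GPR strings are
#' preserved bit-exactly, so `writeNetwork()` then `readNetwork()` is the
#' identity on (stoichiometry, bounds, gpr, objective).
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml-fbc"`; `"auto"` (default) decides by
#'   file extension (`.json` vs `.xml`/`.sbml`).
#' @return a [MetabolicNetwork-class].
#' @seealso [writeNetwork()]
#' @export
readNetwork <- function(path, dialect = c("auto", "json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
               else "sbml-fbc"
  }
  if (dialect == "json") .readNetworkJson(path) else .readNetworkSbml(path)
}

#' Write a metabolic network to file
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output file path.
#' @param dialect `"json"` or `"sbml-fbc"`; `"auto"` decides by extension.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, dialect = c("auto", "json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
               else "sbml-fbc"
  }
  if (dialect == "json") .writeNetworkJson(network, path)
  else .writeNetworkSbml(network, path)
  invisible(path)
}

.readNetworkJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("malformed model JSON: missing 'reactions' or 'metabolites' in ", path)
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  n <- length(doc$reactions)
  rxns <- character(n); lb <- ub <- numeric(n); gpr <- character(n)
  objcoef <- numeric(n)
  trip <- list()
  for (k in seq_len(n)) {
    r <- doc$reactions[[k]]
    if (is.null(r$id)) stop("malformed model JSON: reaction ", k, " has no id")
    rxns[k] <- r$id
    lb[k] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[k] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    gpr[k] <- if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule
    objcoef[k] <- if (is.null(r$objective_coefficient)) 0
                  else as.numeric(r$objective_coefficient)
    sm <- r$metabolites
    if (length(sm)) {
      bad <- setdiff(names(sm), mets)
      if (length(bad))
        stop("reaction '", r$id, "' references undeclared metabolite(s): ",
             paste(bad, collapse = ", "))
      trip[[k]] <- data.frame(i = match(names(sm), mets), j = k,
                              x = as.numeric(unlist(sm)))
    }
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(mets), n))
  obj <- rxns[objcoef != 0]
  if (length(obj) != 1L)
    stop("configuration error: model must declare exactly one objective ",
         "reaction (found ", length(obj), ") in ", path)
  atp <- if (!is.null(doc$atp_demand)) as.character(doc$atp_demand) else character(0)
  newMetabolicNetwork(rxns = rxns, mets = mets, S = S, lb = lb, ub = ub,
                      gpr = gpr, objective = obj, atpDemand = atp,
                      id = if (is.null(doc$id)) "model" else doc$id)
}

.writeNetworkJson <- function(network, path) {
  mets <- lapply(metabolites(network), function(m) list(id = m))
  S <- network@S
  doc <- list(
    id = network@id,
    metabolites = mets,
    reactions = lapply(seq_along(network@rxns), function(k) {
      col <- S[, k]
      nz <- which(col != 0)
      list(id = network@rxns[k],
           metabolites = as.list(setNames(as.numeric(col[nz]),
                                          network@mets[nz])),
           lower_bound = network@lb[k],
           upper_bound = network@ub[k],
           gene_reaction_rule = network@gpr[k],
           objective_coefficient = if (network@rxns[k] == network@objective) 1 else 0)
    }),
    genes = lapply(genes(network), function(g) list(id = g))
  )
  if (length(network@atpDemand)) doc$atp_demand <- network@atpDemand
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a medium composition table
#'
#' Two-column CSV `metabolite_id,max_uptake` with a header row. Rates are
#' maximum uptake rates in mmol/gDW/h, used directly as uptake bounds.
#'
#' @param path CSV file path.
#' @return a [MediumDefinition-class].
#' @export
readMedium <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("medium CSV must have columns metabolite_id, max_uptake")
  newMedium(setNames(as.numeric(tab[[2]]), as.character(tab[[1]])))
}

#' Write a medium composition table
#' @param medium a [MediumDefinition-class].
#' @param path output CSV path.
#' @export
writeMedium <- function(medium, path) {
  up <- uptakeRates(medium)
  utils::write.csv(data.frame(metabolite_id = names(up), max_uptake = up,
                              row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Constrain a network's exchange reactions to a medium
#'
#' For every exchange reaction (export-positive convention) the uptake bound
#' becomes `-rate` if its metabolite is listed in the medium and 0 otherwise;
#' secretion bounds and all non-exchange reactions are untouched. The input
#' network is not modified. Applying the same medium twice is a no-op.
#'
#' Medium metabolites with no matching exchange reaction trigger a warning
#' (they cannot constrain anything) but are not fatal.
#'
#' @param network a [MetabolicNetwork-class].
#' @param medium a [MediumDefinition-class].
#' @return a new [MetabolicNetwork-class] with medium-constrained uptake
#'   bounds.
#' @export
applyMedium <- function(network, medium) {
  stopifnot(is(network, "MetabolicNetwork"), is(medium, "MediumDefinition"))
  ex <- exchangeReactions(network)
  exIdx <- match(ex, network@rxns)
  exMet <- vapply(exIdx, function(j) {
    network@mets[which(network@S[, j] != 0)]
  }, character(1))
  up <- uptakeRates(medium)
  unmatched <- setdiff(names(up), exMet)
  if (length(unmatched))
    warning("medium metabolite(s) without exchange reaction: ",
            paste(unmatched, collapse = ", "))
  out <- network
  rate <- up[exMet]
  rate[is.na(rate)] <- 0
  out@lb[exIdx] <- -as.numeric(rate)
  validObject(out)
  out
}
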