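# SBML Level 3 Version 1 + FBC version 2 reader/writer (xml2-based),
# covering the constraint-based subset: compartments, species, reactions
# with speciesReferences, flux bounds via global parameters,
# geneProductAssociations and the active objective. Identifiers follow the
# community prefix convention (R_/M_/G_) and are stripped on read. Bounds
# are serialized with full double precision ("%.17g") so a write/read
# round-trip is bit-exact.

.sbmlId <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))
.sbmlUnId <- function(x, prefix) sub(paste0("^", prefix), "", x)

.writeNetworkSbml <- function(network, path) {
  fmt <- function(x) sprintf("%.17g", x)
  ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

  # unique parameter per distinct bound value
  vals <- sort(unique(c(network@lb, network@ub)))
  pid <- setNames(paste0("par_", seq_along(vals)), fmt(vals))

  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = ns_fbc, level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = .sbmlId(network@id, ""),
                             "fbc:strict" = "true")

  cmp <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")

  sp <- xml2::xml_add_child(mod, "listOfSpecies")
  for (m in network@mets)
    xml2::xml_add_child(sp, "species", id = .sbmlId(m, "M_"), compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(mod, "listOfParameters")
  for (v in vals)
    xml2::xml_add_child(pars, "parameter", id = pid[[fmt(v)]], value = fmt(v),
                        constant = "true")

  gp <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
  for (g in genes(network))
    xml2::xml_add_child(gp, "fbc:geneProduct", "fbc:id" = .sbmlId(g, "G_"),
                        "fbc:label" = g)

  objs <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = .sbmlId(network@objective, "R_"),
                      "fbc:coefficient" = "1")

  rl <- xml2::xml_add_child(mod, "listOfReactions")
  for (k in seq_along(network@rxns)) {
    rx <- xml2::xml_add_child(rl, "reaction",
      id = .sbmlId(network@rxns[k], "R_"),
      reversible = if (network@lb[k] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[fmt(network@lb[k])]],
      "fbc:upperFluxBound" = pid[[fmt(network@ub[k])]])
    col <- network@S[, k]
    nzi <- which(col != 0)
    reac <- nzi[col[nzi] < 0]
    prod <- nzi[col[nzi] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lr, "speciesReference",
                            species = .sbmlId(network@mets[i], "M_"),
                            stoichiometry = fmt(-col[i]), constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lp, "speciesReference",
                            species = .sbmlId(network@mets[i], "M_"),
                            stoichiometry = fmt(col[i]), constant = "true")
    }
    if (nzchar(network@gpr[k])) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .sbmlWriteGpa(ga, network@gprTrees[[k]])
    }
    if (length(network@atpDemand) && network@rxns[k] == network@atpDemand)
      xml2::xml_set_attr(rx, "sboTerm", "SBO:0000628") # demand reaction marker
  }
  xml2::write_xml(doc, path)
}

.sbmlWriteGpa <- function(node, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = .sbmlId(tree, "G_"))
  } else {
    sub <- xml2::xml_add_child(node, paste0("fbc:", tree$op))
    for (a in tree$args) .sbmlWriteGpa(sub, a)
  }
}

.readNetworkSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("malformed SBML: no <model> in ", path)

  spn <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  mets <- .sbmlUnId(xml2::xml_attr(spn, "id"), "M_")

  parn <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(parn, "value")),
                     xml2::xml_attr(parn, "id"))

  # xml2 exposes namespaced attributes under their local name; fall back to
  # the prefixed form for writers that keep the prefix
  att <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    ifelse(is.na(v), xml2::xml_attr(node, paste0("fbc:", name)), v)
  }

  gpn <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glab <- setNames(att(gpn, "label"), att(gpn, "id"))

  objref <- xml2::xml_find_first(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(objref, "xml_missing"))
    stop("configuration error: SBML model has no active objective in ", path)
  objId <- .sbmlUnId(att(objref, "reaction"), "R_")

  rxn <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rxn)
  rxns <- .sbmlUnId(xml2::xml_attr(rxn, "id"), "R_")
  lb <- ub <- numeric(n); gpr <- character(n)
  atp <- character(0)
  trip <- list()
  for (k in seq_len(n)) {
    rk <- rxn[[k]]
    lb[k] <- parval[[att(rk, "lowerFluxBound")]]
    ub[k] <- parval[[att(rk, "upperFluxBound")]]
    if (identical(xml2::xml_attr(rk, "sboTerm"), "SBO:0000628")) atp <- rxns[k]
    refs <- xml2::xml_find_all(rk, "./s:listOfReactants/s:speciesReference", ns)
    prods <- xml2::xml_find_all(rk, "./s:listOfProducts/s:speciesReference", ns)
    sid <- c(.sbmlUnId(xml2::xml_attr(refs, "species"), "M_"),
             .sbmlUnId(xml2::xml_attr(prods, "species"), "M_"))
    sto <- c(-as.numeric(xml2::xml_attr(refs, "stoichiometry")),
             as.numeric(xml2::xml_attr(prods, "stoichiometry")))
    if (length(sid)) {
      idx <- match(sid, mets)
      if (anyNA(idx))
        stop("reaction '", rxns[k], "' references undeclared species: ",
             paste(sid[is.na(idx)], collapse = ", "))
      trip[[k]] <- data.frame(i = idx, j = k, x = sto)
    }
    gpa <- xml2::xml_find_first(rk, "./fbc:geneProductAssociation/*", ns)
    gpr[k] <- if (inherits(gpa, "xml_missing")) ""
              else gprToString(.sbmlReadGpa(gpa, glab, att))
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(mets), n))
  newMetabolicNetwork(rxns = rxns, mets = mets, S = S, lb = lb, ub = ub,
                      gpr = gpr, objective = objId, atpDemand = atp,
                      id = xml2::xml_attr(mod, "id"))
}

.sbmlReadGpa <- function(node, glab, att) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- att(node, "geneProduct")
    lab <- glab[gid]
    return(if (!is.na(lab)) unname(lab) else .sbmlUnId(gid, "G_"))
  }
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, .sbmlReadGpa, glab = glab, att = att))
}
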