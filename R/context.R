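#' Discretize expression into ternary expressed/unknown/inactive calls
#'
#' Per sample, a two-component Gaussian mixture is fitted to
#' `log2(expression + 1)` of the genes with nonzero expression
#' (via [mclust::Mclust]). A gene is called expressed (+1) when its
#' posterior probability of belonging to the high component is at least
#' `p_hi`, inactive (-1) when at most `p_lo`, unknown (0) otherwise. Genes
#' with zero expression are called inactive directly. The fit is
#' deterministic (hierarchical-clustering initialisation), so duplicated
#' samples yield identical call columns.
#'
#' A degenerate sample (all values equal) cannot support a two-component
#' fit; its calls are all 0 with a warning.
#'
#' @param expression gene x sample matrix of non-negative values
#'   (FPKM/TPM-like), or a [SummarizedExperiment::SummarizedExperiment] whose
#'   first assay is such a matrix.
#' @param p_hi,p_lo posterior thresholds for +1 / -1 calls (defaults 0.9 and
#'   0.1).
#' @return integer matrix of calls in \{-1, 0, 1\}, same dimnames as the
#'   input.
#' @export
discretizeExpression <- function(expression, p_hi = 0.9, p_lo = 0.1) {
  if (is(expression, "SummarizedExperiment"))
    expression <- SummarizedExperiment::assay(expression, 1)
  x <- as.matrix(expression)
  if (any(x < 0)) stop("expression values must be non-negative")
  if (ncol(x) < 1) stop("need at least one sample")
  calls <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (s in seq_len(ncol(x))) {
    v <- x[, s]
    nz <- which(v > 0)
    if (length(unique(v)) == 1L) {
      warning("sample ", colnames(x)[s] %||% s,
              " is degenerate (all values equal); all calls set to unknown")
      next
    }
    calls[v == 0, s] <- -1L
    if (length(nz) < 4L) next  # too few points for a mixture; leave unknown
    lv <- log2(v[nz] + 1)
    if (length(unique(lv)) == 1L) next
    fit <- suppressWarnings(
      tryCatch(mclust::Mclust(lv, G = 2, modelNames = "V", verbose = FALSE),
               error = function(e) NULL))
    if (is.null(fit))
      fit <- suppressWarnings(
        tryCatch(mclust::Mclust(lv, G = 2, modelNames = "E", verbose = FALSE),
                 error = function(e) NULL))
    if (is.null(fit)) next
    hi <- which.max(fit$parameters$mean)
    post <- fit$z[, hi]
    cc <- integer(length(nz))
    cc[post >= p_hi] <- 1L
    cc[post <= p_lo] <- -1L
    calls[nz, s] <- cc
  }
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map gene calls to a reaction core assignment
#'
#' Reaction score = GPR evaluation over the calls with `AND -> min`,
#' `OR -> max`. Score +1 puts the reaction in the core set, -1 in the
#' inactive set; 0 or an empty GPR leaves it unknown. Genes without calls
#' count as unknown.
#'
#' @param network a [MetabolicNetwork-class].
#' @param calls integer call matrix from [discretizeExpression()] (or a named
#'   vector for a single sample).
#' @param sample column name or index when `calls` is a matrix.
#' @return list with character vectors `core`, `inactive`, `unknown`
#'   (disjoint, covering all reactions).
#' @export
mapCallsToReactions <- function(network, calls, sample = 1L) {
  v <- if (is.matrix(calls)) calls[, sample] else calls
  if (is.null(names(v))) stop("calls must be named by gene id")
  sc <- vapply(network@gprTrees, function(tr) {
    s <- scoreGpr(tr, v)
    if (is.na(s)) 0L else s
  }, integer(1))
  empty <- !nzchar(network@gpr)
  core <- network@rxns[sc == 1L & !empty]
  inactive <- network@rxns[sc == -1L & !empty]
  unknown <- setdiff(network@rxns, c(core, inactive))
  list(core = core, inactive = inactive, unknown = unknown)
}

# Split reversible reactions into irreversible forward/backward pairs.
# Returns the split matrices plus the mapping back to original reactions.
.splitReversible <- function(network) {
  S <- as.matrix(network@S)
  lb <- network@lb; ub <- network@ub
  n <- ncol(S)
  cols <- list(); colLb <- colUb <- numeric(0)
  orig <- integer(0); dirn <- integer(0)
  for (j in seq_len(n)) {
    cols[[length(cols) + 1L]] <- S[, j]
    colLb <- c(colLb, max(lb[j], 0)); colUb <- c(colUb, max(ub[j], 0))
    orig <- c(orig, j); dirn <- c(dirn, 1L)
    if (lb[j] < 0) {
      cols[[length(cols) + 1L]] <- -S[, j]
      colLb <- c(colLb, 0); colUb <- c(colUb, -lb[j])
      orig <- c(orig, j); dirn <- c(dirn, -1L)
    }
  }
  list(S = do.call(cbind, cols), lb = colLb, ub = colUb,
       orig = orig, dirn = dirn)
}

#' FASTCORE-family extraction of a compact flux-consistent subnetwork
#'
#' Given a flux-consistent network and a core set `C`, returns a compact
#' reaction set `A` with `A` containing `C` and the subnetwork induced by
#' `A` flux-consistent at `epsilon`. The two-LP scheme of the FASTCORE
#' family is used on the reversible-split network: LP7 maximises the number
#' of core reactions carrying at least `epsilon` flux, then an L1-penalty LP
#' minimises the total flux through non-core reactions, and the support of
#' that sparse mode is accepted. Reaction ordering is fixed
#' (lexicographic input order), so the result is deterministic.
#'
#' @param network a flux-consistent [MetabolicNetwork-class] (pre-filter
#'   with [findConsistentSubnetwork()]; close inactive reactions
#'   beforehand).
#' @param core character vector of core reaction ids (must be within the
#'   network and flux-consistent).
#' @param epsilon consistency flux threshold.
#' @param tol LP tolerance.
#' @return character vector of reaction ids `A` (superset of `core`),
#'   sorted in network order.
#' @export
fastcoreExtract <- function(network, core, epsilon = .EPS_CONSISTENCY,
                            tol = .TOL_FEAS) {
  stopifnot(epsilon > 0)
  core <- unique(core)
  bad <- setdiff(core, network@rxns)
  if (length(bad)) stop("core reactions not in network: ",
                        paste(bad, collapse = ", "))
  if (!length(core)) return(character(0))

  sp <- .splitReversible(network)
  coreIdx <- match(core, network@rxns)
  suppTol <- max(tol * 100, epsilon * 1e-4)

  A <- integer(0)                # original reaction indices accepted
  J <- coreIdx                   # core reactions still to cover
  guard <- 0L
  while (length(J)) {
    guard <- guard + 1L
    if (guard > length(coreIdx) + 5L)
      stop("extraction failed to converge; blocked core reactions: ",
           paste(network@rxns[J], collapse = ", "))
    Jcols <- lapply(J, function(j) which(sp$orig == j))
    r <- .lp7(sp$S, sp$lb, sp$ub, Jcols, epsilon, tol)
    K <- J[r$achieved >= epsilon * 0.99]
    if (!length(K))
      stop("core reaction(s) cannot carry flux at epsilon: ",
           paste(network@rxns[J], collapse = ", "))
    # direction carried in the LP7 mode, per covered core reaction
    kcols <- vapply(K, function(j) {
      cand <- which(sp$orig == j)
      cand[which.max(r$v[cand])]
    }, integer(1))
    lb2 <- sp$lb
    lb2[kcols] <- pmax(lb2[kcols], epsilon)
    pen <- which(!(sp$orig %in% c(A, coreIdx)))
    obj <- numeric(ncol(sp$S)); obj[pen] <- 1
    r2 <- solveLP(obj, sp$S, numeric(nrow(sp$S)), lb2, sp$ub,
                  maximize = FALSE, tol = tol)
    if (r2$status != "optimal")
      stop("sparse-mode LP failed with status ", r2$status)
    supp <- unique(sp$orig[r2$x > suppTol])
    A <- union(A, union(supp, K))
    J <- setdiff(J, A)
  }
  out <- network@rxns[sort(A)]
  # guarantee the contract: the induced subnetwork is consistent at epsilon.
  # Non-core reactions that cannot reach epsilon inside the subnetwork are
  # dropped; a blocked core reaction is an error.
  if (network@objective %in% out) {
    sub <- subsetNetwork(network, out)
    cons <- findConsistentSubnetwork(sub, epsilon = epsilon, tol = tol)
    blocked <- setdiff(core, cons)
    if (length(blocked))
      stop("extracted subnetwork leaves core reaction(s) blocked: ",
           paste(blocked, collapse = ", "))
    out <- out[out %in% cons]
  }
  out
}

#' Pool per-sample gene calls into one consensus call vector
#'
#' Alternative ("pooled") route to a consensus model: instead of pooling
#' per-sample reaction assignments, the ternary gene calls themselves are
#' pooled by majority (+1 when more samples call a gene expressed than
#' inactive, -1 in the opposite case, 0 on ties), and the pooled vector is
#' mapped to reactions once. Use
#' `buildConsensusModel(net, list(mapCallsToReactions(net, poolGeneCalls(calls, samples))))`
#' for the pooled mode; passing per-sample assignments gives the agreement
#' mode.
#'
#' @param calls integer call matrix from [discretizeExpression()].
#' @param samples column names/indices to pool (default: all).
#' @return named integer vector of pooled calls.
#' @export
poolGeneCalls <- function(calls, samples = colnames(calls)) {
  sub <- calls[, samples, drop = FALSE]
  score <- rowSums(sub == 1L) - rowSums(sub == -1L)
  setNames(as.integer(sign(score)), rownames(sub))
}

#' Build a consensus context-specific model for a sample group
#'
#' Pools per-sample core assignments of one subtype: a reaction enters the
#' consensus core when it is core in at least a fraction `q` of the samples
#' and the consensus inactive set when inactive in at least `q` (core wins
#' on overlap, possible only for `q <= 0.5`). Inactive reactions are closed,
#' the network is reduced to its flux-consistent part, and one FASTCORE
#' extraction is run on the consensus core. The biomass objective, the
#' ATP-demand reaction (when present) and the exchange reactions opened by
#' the medium are always force-included in the core so the growth objective
#' survives extraction.
#'
#' @param network the generic [MetabolicNetwork-class] (bounds already
#'   medium-constrained via [applyMedium()]).
#' @param assignments list of per-sample core assignments from
#'   [mapCallsToReactions()].
#' @param q consensus threshold in (0, 1], default 0.9.
#' @param epsilon consistency threshold for extraction.
#' @param id id for the resulting model.
#' @param tol LP tolerance.
#' @return a [MetabolicNetwork-class]: the consensus context-specific model.
#' @export
buildConsensusModel <- function(network, assignments, q = 0.9,
                                epsilon = .EPS_CONSISTENCY, id = "consensus",
                                tol = .TOL_FEAS) {
  if (!length(assignments)) stop("need at least one sample assignment")
  if (!(q > 0 && q <= 1)) stop("'q' must be in (0, 1]")
  ns <- length(assignments)
  coreFrac <- table(factor(unlist(lapply(assignments, `[[`, "core")),
                           levels = network@rxns)) / ns
  inacFrac <- table(factor(unlist(lapply(assignments, `[[`, "inactive")),
                           levels = network@rxns)) / ns
  consCore <- network@rxns[coreFrac >= q]
  consInac <- setdiff(network@rxns[inacFrac >= q], consCore)

  forced <- c(network@objective, network@atpDemand)
  ex <- exchangeReactions(network)
  openEx <- ex[network@lb[match(ex, network@rxns)] < 0 |
               network@ub[match(ex, network@rxns)] > 0]
  forced <- unique(c(forced, openEx))
  consInac <- setdiff(consInac, forced)

  if (!length(setdiff(consCore, ex)))
    stop("empty consensus core: no internal reaction is core in >= ",
         q, " of the samples")

  work <- network
  closeIdx <- match(consInac, work@rxns)
  work@lb[closeIdx] <- 0; work@ub[closeIdx] <- 0

  cons <- findConsistentSubnetwork(work, epsilon = epsilon, tol = tol)
  if (!(work@objective %in% cons))
    stop("biomass objective is blocked after closing consensus-inactive ",
         "reactions; check medium and discretization")
  work <- subsetNetwork(work, cons)

  coreUse <- intersect(unique(c(consCore, forced)), cons)
  dropped <- setdiff(consCore, cons)
  if (length(dropped))
    message("consensus core reactions blocked in the consistent subnetwork ",
            "and dropped: ", paste(dropped, collapse = ", "))

  A <- fastcoreExtract(work, coreUse, epsilon = epsilon, tol = tol)
  out <- subsetNetwork(work, union(A, forced[forced %in% reactions(work)]))
  out@id <- id
  validObject(out)
  out
}

#' Per-model QC summary
#'
#' Reaction/metabolite/gene counts and the optimal growth rate of a model,
#' mirroring the usual model-statistics table of context-specific GEM
#' studies.
#'
#' @param model a [MetabolicNetwork-class].
#' @param samples number of samples the model was built from (optional).
#' @return one-row data.frame: model, samples, reactions, metabolites,
#'   genes, growth.
#' @export
modelSummary <- function(model, samples = NA_integer_) {
  sol <- fba(model)
  data.frame(model = model@id, samples = samples,
             reactions = length(model@rxns),
             metabolites = length(model@mets),
             genes = length(genes(model)),
             growth = if (sol@status == "optimal") sol@objval else NA_real_,
             stringsAsFactors = FALSE)
}
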