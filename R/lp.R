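#' Solve a linear program
#'
#' Thin interface over the package's bounded-variable primal simplex engine:
#' maximize (or minimize) `obj' x` subject to `A x (=, <=, >=) rhs` and
#' `lb <= x <= ub`. Inequality rows are converted to equalities with slack
#' variables before handing the problem to the engine.
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (dense or sparse).
#' @param rhs right-hand side vector.
#' @param lb,ub variable bounds (recycled); one of the two may be infinite
#'   per variable.
#' @param sense character vector of row senses in `"="`, `"<="`, `">="`
#'   (recycled, default all `"="`).
#' @param maximize logical, default TRUE.
#' @param tol feasibility/optimality tolerance of the engine.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), `x` (solution over the original variables) and `objval`.
#' @export
solveLP <- function(obj, A, rhs, lb, ub, sense = "=", maximize = TRUE,
                    tol = .TOL_FEAS) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  sense <- rep_len(sense, m)
  nle <- sum(sense == "<="); nge <- sum(sense == ">=")
  if (nle + nge > 0) {
    Sl <- matrix(0, m, nle + nge)
    j <- 0L
    slb <- sub <- numeric(0)
    for (i in seq_len(m)) {
      if (sense[i] == "<=") {
        j <- j + 1L; Sl[i, j] <- 1; slb <- c(slb, 0); sub <- c(sub, Inf)
      } else if (sense[i] == ">=") {
        j <- j + 1L; Sl[i, j] <- -1; slb <- c(slb, 0); sub <- c(sub, Inf)
      }
    }
    A <- cbind(A, Sl)
    obj <- c(obj, numeric(nle + nge))
    lb <- c(lb, slb); ub <- c(ub, sub)
  }
  cc <- if (maximize) obj else -obj
  res <- .simplex_solve(A, rhs, cc, lb, ub, tol = tol)
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(n)]
    if (!maximize) res$objval <- -res$objval
  }
  res
}

#' Flux balance analysis
#'
#' Maximizes the flux of the objective reaction subject to steady state
#' (`S v = 0`) and the reaction bounds. Solver status is reported
#' faithfully: an infeasible constraint set yields status `"infeasible"`
#' with an undefined optimum, never a silent zero.
#'
#' @param network a [MetabolicNetwork-class].
#' @param objective reaction id to maximize (default: the network's biomass
#'   objective).
#' @param tol LP tolerance.
#' @return a [FluxSolution-class].
#' @examples
#' net <- exampleChainNetwork()
#' fba(net)
#' @export
fba <- function(network, objective = objectiveReaction(network),
                tol = .TOL_FEAS) {
  stopifnot(is(network, "MetabolicNetwork"))
  j <- match(objective, network@rxns)
  if (is.na(j)) stop("objective reaction '", objective, "' not in network")
  n <- length(network@rxns)
  obj <- numeric(n); obj[j] <- 1
  res <- solveLP(obj, network@S, numeric(length(network@mets)),
                 network@lb, network@ub, tol = tol)
  if (res$status != "optimal")
    return(new("FluxSolution", objval = NA_real_, fluxes = numeric(0),
               status = res$status))
  new("FluxSolution", objval = res$objval,
      fluxes = setNames(res$x, network@rxns), status = "optimal")
}

#' Flux variability analysis
#'
#' Constrains the objective to at least `fraction * z*` of its optimum and
#' minimizes and maximizes each listed reaction independently. At
#' `fraction = 1` the constraint is relaxed to `(1 - 1e-6) * z*` to avoid
#' numerical infeasibility at the exact optimum (standard practice).
#' Unbounded directions cannot occur when the network carries finite caps on
#' all reactions (Recon-style +/-1000); results are capped at the reaction's
#' own bounds.
#'
#' @param network a [MetabolicNetwork-class].
#' @param reactions reaction ids to analyse (default: all).
#' @param fraction optimality fraction `f` in (0, 1].
#' @param objective objective reaction id (default biomass).
#' @param tol LP tolerance.
#' @return data.frame with columns `reaction`, `min`, `max`, plus the
#'   `fraction` used and the reference optimum `z*` as attributes
#'   (`fraction`, `optimum`).
#' @export
fva <- function(network, reactions = NULL, fraction = 1.0,
                objective = objectiveReaction(network), tol = .TOL_FEAS) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be a single number in (0, 1]")
  if (is.null(reactions)) reactions <- network@rxns
  idx <- match(reactions, network@rxns)
  if (anyNA(idx))
    stop("unknown reaction(s): ", paste(reactions[is.na(idx)], collapse = ", "))

  sol <- fba(network, objective = objective, tol = tol)
  if (sol@status != "optimal")
    stop("FVA requires a solvable network (FBA status: ", sol@status, ")")
  zstar <- sol@objval
  relax <- if (fraction >= 1) (1 - 1e-6) else fraction
  jobj <- match(objective, network@rxns)

  n <- length(network@rxns); m <- length(network@mets)
  objRow <- numeric(n); objRow[jobj] <- 1
  A <- rbind(as.matrix(network@S), objRow)
  rhs <- c(numeric(m), relax * zstar)
  sense <- c(rep("=", m), ">=")

  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    rmin <- solveLP(obj, A, rhs, network@lb, network@ub, sense = sense,
                    maximize = FALSE, tol = tol)
    rmax <- solveLP(obj, A, rhs, network@lb, network@ub, sense = sense,
                    maximize = TRUE, tol = tol)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    lo[k] <- max(rmin$objval, network@lb[idx[k]])
    hi[k] <- min(rmax$objval, network@ub[idx[k]])
    if (lo[k] > hi[k]) { mid <- (lo[k] + hi[k]) / 2; lo[k] <- hi[k] <- mid }
  }
  out <- data.frame(reaction = reactions, min = lo, max = hi,
                    stringsAsFactors = FALSE)
  attr(out, "fraction") <- fraction
  attr(out, "optimum") <- zstar
  out
}

# LP7 of the FASTCORE family: find a flux distribution maximizing the number
# of reactions in J that carry at least epsilon flux (via auxiliary z in
# [0, eps], z_j <= v_j). `Jcols` is a list: each element gives the column
# indices whose SUM must reach epsilon (one index for an irreversible
# reaction, the forward/backward pair for a split reversible one).
.lp7 <- function(S, lb, ub, Jcols, eps, tol = .TOL_FEAS) {
  m <- nrow(S); n <- ncol(S); q <- length(Jcols)
  if (q == 0) return(list(v = numeric(n), achieved = numeric(0)))
  A <- matrix(0, m + q, n + q)
  A[seq_len(m), seq_len(n)] <- as.matrix(S)
  for (k in seq_len(q)) {
    A[m + k, n + k] <- 1                 # z_k
    A[m + k, Jcols[[k]]] <- -1           # minus sum of member fluxes
  }
  rhs <- c(numeric(m), numeric(q))
  sense <- c(rep("=", m), rep("<=", q))
  obj <- c(numeric(n), rep(1, q))
  res <- solveLP(obj, A, rhs, c(lb, numeric(q)), c(ub, rep(eps, q)),
                 sense = sense, tol = tol)
  if (res$status != "optimal") stop("LP7 failed with status ", res$status)
  v <- res$x[seq_len(n)]
  list(v = v,
       achieved = vapply(Jcols, function(cols) sum(v[cols]), numeric(1)))
}

#' Flux-consistent subnetwork (FastCC-style sweep)
#'
#' Returns exactly the reactions that can carry `|v| >= epsilon` in some
#' steady-state flux distribution. Uses block LP7 sweeps over untested
#' reactions with direction flipping for reversible ones (FastCC), so the
#' number of LPs is far below the two-per-reaction brute force.
#'
#' @param network a [MetabolicNetwork-class].
#' @param epsilon consistency flux threshold (> 0), default `1e-4`.
#' @param tol LP tolerance.
#' @return sorted character vector of flux-consistent reaction ids.
#' @export
findConsistentSubnetwork <- function(network, epsilon = .EPS_CONSISTENCY,
                                     tol = .TOL_FEAS) {
  stopifnot(epsilon > 0)
  S <- as.matrix(network@S)
  lb <- network@lb; ub <- network@ub
  n <- ncol(S)
  ids <- network@rxns
  supp <- function(v) which(abs(v) >= epsilon * 0.99)

  irrev <- which(lb >= 0)
  A <- integer(0)
  if (length(irrev)) {
    r <- .lp7(S, lb, ub, as.list(irrev), epsilon, tol)
    A <- union(A, supp(r$v))
  }
  J <- setdiff(seq_len(n), A)
  flipped <- FALSE; singleton <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1] else J
    r <- .lp7(S, lb, ub, as.list(Ji), epsilon, tol)
    A <- union(A, supp(r$v))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE; singleton <- FALSE
    } else {
      JiRev <- Ji[lb[Ji] < 0]
      if (flipped || !length(JiRev)) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji)   # inconsistent reaction
        } else singleton <- TRUE
      } else {
        tmp <- lb[JiRev]
        lb[JiRev] <- -ub[JiRev]
        ub[JiRev] <- -tmp
        S[, JiRev] <- -S[, JiRev]
        flipped <- TRUE
      }
    }
  }
  sort(ids[sort(A)])
}

#' Restrict a network to a reaction subset
#'
#' Keeps the listed reactions and the metabolites they touch. The objective
#' must be inside the subset; the ATP-demand annotation is kept when its
#' reaction survives.
#'
#' @param network a [MetabolicNetwork-class].
#' @param keep reaction ids to keep.
#' @return a new [MetabolicNetwork-class].
#' @export
subsetNetwork <- function(network, keep) {
  idx <- match(keep, network@rxns)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(keep[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  S <- network@S[, idx, drop = FALSE]
  mkeep <- which(Matrix::rowSums(S != 0) > 0)
  if (!(network@objective %in% network@rxns[idx]))
    stop("objective reaction not in the kept subset")
  atp <- intersect(network@atpDemand, network@rxns[idx])
  newMetabolicNetwork(
    rxns = network@rxns[idx], mets = network@mets[mkeep],
    S = S[mkeep, , drop = FALSE],
    lb = network@lb[idx], ub = network@ub[idx],
    gpr = network@gpr[idx], objective = network@objective,
    atpDemand = atp, id = network@id)
}
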