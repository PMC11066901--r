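# Shared fixtures and independent oracles for the test suite.
#
# The LP oracle goes through boot::simplex (tableau simplex over x >= 0,
# an entirely separate implementation from the package's bounded-variable
# engine). Networks are built in code; nothing is read from disk.

# -- network construction ----------------------------------------------------

# rxns: list of list(id, mets = named coefs, lb, ub, gpr)
mkNetwork <- function(rxns, objective, atpDemand = character(0),
                      id = "test") {
  ids <- vapply(rxns, `[[`, character(1), "id")
  mets <- unique(unlist(lapply(rxns, function(r) names(r$mets))))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (k in seq_along(rxns)) S[names(rxns[[k]]$mets), k] <- rxns[[k]]$mets
  newMetabolicNetwork(
    rxns = ids, mets = mets, S = S,
    lb = vapply(rxns, function(r) r$lb %||% 0, numeric(1)),
    ub = vapply(rxns, function(r) r$ub %||% 1000, numeric(1)),
    gpr = vapply(rxns, function(r) r$gpr %||% "", character(1)),
    objective = objective, atpDemand = atpDemand, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rxn <- function(id, mets, lb = 0, ub = 1000, gpr = "")
  list(id = id, mets = mets, lb = lb, ub = ub, gpr = gpr)

# source(ub 10) -> A -> (ub 5) -> B -> sink(ub 100)
chainNetwork <- function() {
  mkNetwork(list(
    rxn("r_src", c(A = 1), ub = 10),
    rxn("r_ab", c(A = -1, B = 1), ub = 5),
    rxn("r_sink", c(B = -1), ub = 100)
  ), objective = "r_sink", id = "chain")
}

# two parallel branches, each ub 5, feeding a biomass that drains B
parallelNetwork <- function(branch_ub = 5, gprs = c("", "")) {
  mkNetwork(list(
    rxn("r_src", c(A = 1), ub = 100),
    rxn("r_b1", c(A = -1, B = 1), ub = branch_ub, gpr = gprs[1]),
    rxn("r_b2", c(A = -1, B = 1), ub = branch_ub, gpr = gprs[2]),
    rxn("r_bio", c(B = -1), ub = 100)
  ), objective = "r_bio", id = "parallel")
}

# random flux network: a chain backbone (guaranteed feasible) plus random
# extra reactions and a couple of reversible ones
randomNetwork <- function(n_extra = 6, n_mets = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mets <- paste0("m", seq_len(n_mets))
  rxns <- list(
    rxn("ex_in", setNames(1, mets[1]), ub = round(runif(1, 2, 10), 1)),
    rxn("ex_out", setNames(-1, mets[n_mets]), ub = 1000)
  )
  for (i in seq_len(n_mets - 1))
    rxns[[length(rxns) + 1L]] <-
      rxn(paste0("chain", i), setNames(c(-1, 1), mets[i:(i + 1)]),
          ub = round(runif(1, 1, 20), 1))
  for (k in seq_len(n_extra)) {
    pick <- sample(n_mets, 2)
    rev <- runif(1) < 0.4
    rxns[[length(rxns) + 1L]] <-
      rxn(paste0("x", k), setNames(c(-1, 1), mets[pick]),
          lb = if (rev) -round(runif(1, 1, 10), 1) else 0,
          ub = round(runif(1, 1, 10), 1))
  }
  mkNetwork(rxns, objective = "ex_out", id = "random")
}

# -- boot::simplex oracle ----------------------------------------------------

# maximize/minimize obj'v s.t. A v (sense) rhs, lb <= v <= ub, via
# boot::simplex after shifting to x = v - lb >= 0. Finite bounds required.
bootLP <- function(obj, A, rhs, lb, ub, sense = "=", maximize = TRUE) {
  A <- as.matrix(A)
  sense <- rep_len(sense, nrow(A))
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))

  # presolve: boot's tableau code breaks down on the degenerate rows that
  # knockouts create, so fix zero-width variables, drop zero rows, and
  # eliminate equality rows with a single nonzero entry (forced variables)
  fixed <- which(ub - lb < 1e-12)
  if (!length(fixed)) {
    zero <- which(apply(abs(A) < 1e-12, 1, all) & sense == "=")
    if (length(zero)) {
      if (any(abs(rhs[zero]) > 1e-9))
        return(list(status = "infeasible", objval = NA_real_))
      keepR <- setdiff(seq_len(nrow(A)), zero)
      return(bootLP(obj, A[keepR, , drop = FALSE], rhs[keepR], lb, ub,
                    sense[keepR], maximize))
    }
    nzc <- rowSums(abs(A) > 1e-12)
    singl <- which(nzc == 1 & sense == "=")
    if (length(singl)) {
      i <- singl[1]
      j <- which(abs(A[i, ]) > 1e-12)
      v <- rhs[i] / A[i, j]
      if (v < lb[j] - 1e-9 || v > ub[j] + 1e-9)
        return(list(status = "infeasible", objval = NA_real_))
      lb2 <- lb; ub2 <- ub
      lb2[j] <- ub2[j] <- v
      return(bootLP(obj, A, rhs, lb2, ub2, sense, maximize))
    }
  }
  if (length(fixed)) {
    contrib <- as.numeric(A[, fixed, drop = FALSE] %*% lb[fixed])
    objFix <- sum(obj[fixed] * lb[fixed])
    keep <- setdiff(seq_len(ncol(A)), fixed)
    if (!length(keep)) {
      eqOk <- all(abs(contrib - rhs)[sense == "="] < 1e-9) &&
        all((contrib <= rhs + 1e-9)[sense == "<="]) &&
        all((contrib >= rhs - 1e-9)[sense == ">="])
      return(if (eqOk) list(status = "optimal", objval = objFix, x = lb)
             else list(status = "infeasible", objval = NA_real_))
    }
    sub <- bootLP(obj[keep], A[, keep, drop = FALSE], rhs - contrib,
                  lb[keep], ub[keep], sense, maximize)
    if (sub$status == "optimal") {
      x <- numeric(length(lb)); x[fixed] <- lb[fixed]; x[keep] <- sub$x
      return(list(status = "optimal", objval = sub$objval + objFix, x = x))
    }
    return(sub)
  }
  m <- nrow(A); n <- ncol(A)
  shift <- as.numeric(A %*% lb)
  b <- rhs - shift
  A1 <- diag(n); b1 <- ub - lb                      # x <= ub - lb
  A2 <- NULL; b2 <- numeric(0)
  A3 <- NULL; b3 <- numeric(0)
  addRow <- function(a, v, type) {
    if (type == "<=") { A1 <<- rbind(A1, a); b1 <<- c(b1, v) }
    else if (type == ">=") { A2 <<- rbind(A2, a); b2 <<- c(b2, v) }
    else { A3 <<- rbind(A3, a); b3 <<- c(b3, v) }
  }
  for (i in seq_len(m)) {
    a <- A[i, ]; v <- b[i]; ty <- sense[i]
    if (ty == "=" && v < 0) { a <- -a; v <- -v }
    if (ty == ">=" && v < 0) { a <- -a; v <- -v; ty <- "<=" }
    if (ty == "<=" && v < 0) { a <- -a; v <- -v; ty <- ">=" }
    addRow(a, v, ty)
  }
  nIter <- 100 * (n + nrow(A1) + length(b2) + length(b3))
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize, eps = 1e-10,
                  n.iter = nIter),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1)
    return(list(status = if (!is.null(res) && res$solved == -1)
                  "infeasible" else "failed", objval = NA_real_))
  list(status = "optimal", objval = unname(res$value) + sum(obj * lb),
       x = as.numeric(res$soln) + lb)
}

bootFBA <- function(net, objective = objectiveReaction(net)) {
  obj <- numeric(length(reactions(net)))
  obj[match(objective, reactions(net))] <- 1
  bootLP(obj, as.matrix(stoichiometry(net)),
         numeric(length(metabolites(net))),
         unname(lowerBounds(net)), unname(upperBounds(net)))
}

# FVA oracle: min/max of each reaction with objective >= frac * z*
bootFVA <- function(net, rxns = reactions(net), frac = 1) {
  S <- as.matrix(stoichiometry(net))
  m <- nrow(S); n <- ncol(S)
  lb <- unname(lowerBounds(net)); ub <- unname(upperBounds(net))
  jo <- match(objectiveReaction(net), reactions(net))
  z <- bootFBA(net)$objval
  row <- numeric(n); row[jo] <- 1
  A <- rbind(S, row)
  rhs <- c(numeric(m), frac * (1 - 1e-6) * z)
  sense <- c(rep("=", m), ">=")
  t(vapply(rxns, function(r) {
    obj <- numeric(n); obj[match(r, reactions(net))] <- 1
    c(min = bootLP(obj, A, rhs, lb, ub, sense, FALSE)$objval,
      max = bootLP(obj, A, rhs, lb, ub, sense, TRUE)$objval)
  }, c(min = 0, max = 0)))
}

# brute-force consistency oracle: reaction consistent iff max |v| >= eps
bootConsistent <- function(net, eps = 1e-4) {
  S <- as.matrix(stoichiometry(net))
  lb <- unname(lowerBounds(net)); ub <- unname(upperBounds(net))
  n <- ncol(S)
  keep <- vapply(seq_len(n), function(j) {
    obj <- numeric(n); obj[j] <- 1
    hi <- bootLP(obj, S, numeric(nrow(S)), lb, ub, maximize = TRUE)
    if (hi$status == "optimal" && hi$objval >= eps * 0.999) return(TRUE)
    lo <- bootLP(obj, S, numeric(nrow(S)), lb, ub, maximize = FALSE)
    lo$status == "optimal" && lo$objval <= -eps * 0.999
  }, logical(1))
  sort(reactions(net)[keep])
}
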