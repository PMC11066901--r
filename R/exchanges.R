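#' Profile exchange reactions by flux variability at optimal growth
#'
#' Runs FVA over the exchange reactions that are open in the medium or
#' present in the model, at optimality fraction `f` (default 1.0, presets
#' 0.9 / 0.95 available by argument), and classifies directionality from the
#' signs of the flux range. The maximal attainable range `R_max` of each
#' exchange is the FVA range of the same reaction with the objective
#' constraint removed, which makes the relative range medium-aware;
#' set `rmax = "bounds"` for the raw bound-span alternative.
#'
#' Directionality calls (uptake is negative flux): `uptake-only`
#' (max <= tol), `release-only` (min >= -tol), `reversible`, `blocked`
#' (min = max = 0 within tol).
#'
#' @param model a [MetabolicNetwork-class] that grows (z* > 0).
#' @param medium optional [MediumDefinition-class] applied before profiling.
#' @param fraction optimality fraction f in (0, 1].
#' @param rmax `"attainable"` (objective-free FVA range, default) or
#'   `"bounds"` (raw bound span).
#' @param tol numerical tolerance for directionality calls.
#' @return data.frame with one row per exchange reaction: `reaction`,
#'   `metabolite`, `min`, `max`, `rmax_min`, `rmax_max`, `r` (relative
#'   range in \[0, 1\]), `directionality`, `model`; attribute `fraction`.
#' @export
profileExchanges <- function(model, medium = NULL, fraction = 1.0,
                             rmax = c("attainable", "bounds"), tol = 1e-6) {
  rmax <- match.arg(rmax)
  if (!is.null(medium)) model <- applyMedium(model, medium)
  sol <- fba(model)
  if (sol@status != "optimal" || sol@objval <= tol)
    stop("model does not grow under the given medium (z* = ",
         if (sol@status == "optimal") signif(sol@objval, 3) else sol@status,
         "); check medium composition and model extraction")

  ex <- exchangeReactions(model)
  idx <- match(ex, model@rxns)
  open <- model@lb[idx] < 0 | model@ub[idx] > 0
  ex <- ex[open]; idx <- idx[open]
  if (!length(ex)) stop("no open exchange reactions to profile")

  met <- vapply(idx, function(j) model@mets[which(model@S[, j] != 0)],
                character(1))
  vr <- fva(model, reactions = ex, fraction = fraction)

  if (rmax == "attainable") {
    # objective-free range: same LPs without the optimality row
    free <- .fvaFree(model, ex)
    rlo <- free$min; rhi <- free$max
  } else {
    rlo <- model@lb[idx]; rhi <- model@ub[idx]
  }
  span <- rhi - rlo
  r <- ifelse(span <= tol, 0, pmin(1, (vr$max - vr$min) / span))
  dirn <- mapply(function(lo, hi) {
    if (abs(lo) <= tol && abs(hi) <= tol) "blocked"
    else if (hi <= tol) "uptake-only"
    else if (lo >= -tol) "release-only"
    else "reversible"
  }, vr$min, vr$max)

  out <- data.frame(reaction = ex, metabolite = met,
                    min = vr$min, max = vr$max,
                    rmax_min = rlo, rmax_max = rhi, r = r,
                    directionality = dirn, model = model@id,
                    stringsAsFactors = FALSE)
  attr(out, "fraction") <- fraction
  attr(out, "optimum") <- attr(vr, "optimum")
  out
}

# min/max flux of each listed reaction without any objective constraint
.fvaFree <- function(model, reactions, tol = .TOL_FEAS) {
  idx <- match(reactions, model@rxns)
  n <- length(model@rxns)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    rmin <- solveLP(obj, model@S, numeric(length(model@mets)),
                    model@lb, model@ub, maximize = FALSE, tol = tol)
    rmax <- solveLP(obj, model@S, numeric(length(model@mets)),
                    model@lb, model@ub, maximize = TRUE, tol = tol)
    lo[k] <- max(rmin$objval, model@lb[idx[k]])
    hi[k] <- min(rmax$objval, model@ub[idx[k]])
  }
  data.frame(reaction = reactions, min = lo, max = hi)
}

#' Flag narrow-bounded exchanges
#'
#' An exchange is narrow-bounded when its relative FVA range at optimal
#' growth is at most `ratio_cutoff` of its maximal attainable range
#' (inclusive cutoff; default 10%). Any perturbation of a narrow-bounded
#' exchange necessarily alters growth. A reaction whose maximal range is
#' zero is fully fixed and reported narrow, not a division error.
#'
#' @param profile data.frame from [profileExchanges()].
#' @param ratio_cutoff cutoff in (0, 1], default 0.10.
#' @return the input with a logical `narrow` column added.
#' @export
classifyNarrowBounded <- function(profile, ratio_cutoff = 0.10) {
  if (!(ratio_cutoff > 0 && ratio_cutoff <= 1))
    stop("'ratio_cutoff' must be in (0, 1]")
  profile$narrow <- profile$r <= ratio_cutoff
  profile
}

#' Compare exchange profiles across models
#'
#' Builds a long-format comparison across context-specific models profiled
#' under the same medium: which models flag each metabolite narrow, its
#' directionality per model, and the ordering of uptake magnitudes. A
#' metabolite absent from a model is recorded as `"absent"`, not as a zero
#' flux. A metabolite narrow in exactly one model is marked specific to it.
#'
#' @param profiles list of profiles from [classifyNarrowBounded()] (>= 2),
#'   one per model.
#' @return data.frame: `metabolite`, `model`, `min`, `max`, `narrow`,
#'   `directionality`, `uptake` (magnitude of maximal uptake),
#'   `uptake_rank` (1 = strongest uptake for that metabolite across models),
#'   `narrow_in` (comma-joined models where narrow), `specificity`
#'   (`"pan"`, `"none"`, a single model id, or a comma-joined subset).
#' @export
compareExchangeProfiles <- function(profiles) {
  if (length(profiles) < 2) stop("need >= 2 model profiles to compare")
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p$model[1], character(1))
  mets <- sort(unique(unlist(lapply(profiles, `[[`, "metabolite"))))
  models <- names(profiles)
  rows <- list()
  for (m in mets) {
    per <- lapply(profiles, function(p) p[p$metabolite == m, , drop = FALSE])
    narrowIn <- models[vapply(per, function(p) nrow(p) > 0 && isTRUE(p$narrow[1]),
                              logical(1))]
    spec <- if (length(narrowIn) == 0) "none"
            else if (setequal(narrowIn, models)) "pan"
            else paste(narrowIn, collapse = ",")
    upt <- vapply(per, function(p) if (nrow(p)) max(0, -p$min[1]) else NA_real_,
                  numeric(1))
    rk <- rank(-upt, ties.method = "min", na.last = "keep")
    for (i in seq_along(models)) {
      p <- per[[i]]
      absent <- nrow(p) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, model = models[i],
        min = if (absent) NA_real_ else p$min[1],
        max = if (absent) NA_real_ else p$max[1],
        narrow = if (absent) NA else p$narrow[1],
        directionality = if (absent) "absent" else p$directionality[1],
        uptake = upt[i], uptake_rank = unname(rk[i]),
        narrow_in = paste(narrowIn, collapse = ","),
        specificity = spec, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
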