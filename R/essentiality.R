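#' Single-gene deletion screen
#'
#' For each gene, every reaction whose GPR rule evaluates to false under the
#' deletion is closed (both bounds set to 0), growth is re-optimized, and
#' the growth ratio `grRatio = z*_ko / z*_wt` recorded. The model is
#' restored between genes and results are independent of gene order. Genes
#' appearing in no GPR have grRatio 1 by construction. Ratios are clipped to
#' \[0, 1\] (an infeasible knockout counts as 0; deletions can never
#' improve the optimum).
#'
#' @param model a growing [MetabolicNetwork-class].
#' @param medium optional [MediumDefinition-class] applied first.
#' @param genes optional subset of gene ids (default: all model genes).
#' @param lethal_tol growth ratio at or below which a knockout counts as
#'   lethal (100% growth reduction tier).
#' @return data.frame: `gene`, `z_wt`, `z_ko`, `grRatio`, `lethal`.
#' @export
singleGeneDeletion <- function(model, medium = NULL, genes = NULL,
                               lethal_tol = 1e-6) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  wt <- fba(model)
  if (wt@status != "optimal" || wt@objval <= .TOL_FEAS * 10)
    stop("wild-type model does not grow; growth ratios are undefined")
  zwt <- wt@objval

  allGenes <- genes(model)
  if (is.null(genes)) genes <- allGenes
  ruleGenes <- lapply(model@gprTrees, gprGenes)

  zko <- vapply(genes, function(g) {
    hit <- which(vapply(seq_along(model@gprTrees), function(k) {
      g %in% ruleGenes[[k]] && !.gprEval(model@gprTrees[[k]], g)
    }, logical(1)))
    if (!length(hit)) return(zwt)
    ko <- model
    ko@lb[hit] <- 0; ko@ub[hit] <- 0
    s <- fba(ko)
    if (s@status != "optimal") 0 else s@objval
  }, numeric(1))

  gr <- pmin(pmax(zko / zwt, 0), 1)
  data.frame(gene = genes, z_wt = zwt, z_ko = pmax(zko, 0), grRatio = gr,
             lethal = gr <= lethal_tol, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify essential genes from a deletion screen
#'
#' A gene is essential when its knockout reduces growth by at least
#' `cutoff` (inclusive): `grRatio <= 1 - cutoff`. The lethal sub-flag marks
#' complete growth shutdown.
#'
#' @param results data.frame from [singleGeneDeletion()].
#' @param cutoff minimum growth reduction in (0, 1], default 0.5.
#' @return the input with a logical `essential` column; essential gene ids
#'   in attribute `"essential"`.
#' @export
classifyEssential <- function(results, cutoff = 0.5) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("'cutoff' must be in (0, 1]")
  results$essential <- results$grRatio <= 1 - cutoff + .TOL_FEAS
  attr(results, "essential") <- results$gene[results$essential]
  results
}

#' Annotate essential genes against a reference list
#'
#' Flags which predicted essential genes are members of a reference list of
#' common essential genes (e.g. pan-cancer CRISPR screens), supplied as a
#' plain one-gene-per-line file or a character vector. Duplicated reference
#' ids are deduplicated.
#'
#' @param essential character vector of essential gene ids (or the
#'   data.frame from [classifyEssential()]).
#' @param reference character vector of reference gene ids, or a file path.
#' @return data.frame `gene`, `common_essential`; summary counts in
#'   attribute `"summary"`.
#' @export
annotateCommonEssentials <- function(essential, reference) {
  if (is.data.frame(essential)) {
    if (is.null(essential$essential))
      stop("run classifyEssential() first")
    essential <- essential$gene[essential$essential]
  }
  if (length(reference) == 1L && file.exists(reference))
    reference <- readLines(reference, warn = FALSE)
  reference <- unique(trimws(reference))
  reference <- reference[nzchar(reference)]
  if (!length(reference) && length(essential))
    warning("empty reference list; all genes flagged non-member")
  out <- data.frame(gene = essential,
                    common_essential = essential %in% reference,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(essential = length(essential),
                            common = sum(out$common_essential))
  out
}
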