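#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `AND`
#' (complex subunits, all required) and `OR` (isozymes, any sufficient),
#' case-insensitive, `&`/`|` accepted, with parentheses. The empty string
#' parses to the empty rule, which no gene deletion can switch off.
#'
#' Parsing happens once, at model load time; evaluation ([evaluateGpr()])
#' never raises parse errors.
#'
#' @param text rule text, e.g. `"(g1 and g2) or g3"`.
#' @return a parse tree: `NULL` (empty rule), a gene id (character leaf), or
#'   `list(op = "and"|"or", args = list(...))`.
#' @examples
#' tr <- parseGpr("(g1 and g2) or g3")
#' evaluateGpr(tr, deleted = "g1")            # TRUE, g3 branch survives
#' evaluateGpr(tr, deleted = c("g1", "g3"))   # FALSE
#' @export
parseGpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop("malformed GPR rule (unexpected '", st$toks[st$pos], "'): ", text)
  tree
}

.gprTokenize <- function(text) {
  text <- gsub("&&?", " and ", text)
  text <- gsub("\\|\\|?", " or ", text)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gprParseOr <- function(st) {
  args <- list(.gprParseAnd(st))
  while (!is.na(tk <- .gprPeek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gprParseAnd <- function(st) {
  args <- list(.gprParseAtom(st))
  while (!is.na(tk <- .gprPeek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gprParseAtom <- function(st) {
  tk <- .gprPeek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of expression")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gprParseOr(st)
    if (is.na(.gprPeek(st)) || .gprPeek(st) != ")")
      stop("malformed GPR rule: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("malformed GPR rule (unexpected '", tk, "')")
  st$pos <- st$pos + 1L
  tk
}

#' Evaluate a GPR rule under a gene deletion
#'
#' A leaf gene is active iff it is not deleted; `and` is conjunction, `or`
#' disjunction. The empty rule is always active (a reaction without GPR is
#' never disabled by gene deletions, following the COBRA-community
#' convention).
#'
#' @param rule a parse tree from [parseGpr()] (or rule text, parsed on the
#'   fly).
#' @param deleted character vector of deleted gene ids.
#' @return logical: is the reaction still active?
#' @export
evaluateGpr <- function(rule, deleted = character(0)) {
  if (is.character(rule) && length(rule) == 1L && !is.list(rule) &&
      grepl("[[:space:]()]|&|\\|", rule))
    rule <- parseGpr(rule)
  .gprEval(rule, deleted)
}

.gprEval <- function(tree, deleted) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% deleted))
  vals <- vapply(tree$args, .gprEval, logical(1), deleted = deleted)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Score a GPR rule over ternary expression calls
#'
#' Maps gene-level calls (-1 inactive, 0 unknown, +1 expressed) to a
#' reaction-level score with `AND -> min` and `OR -> max`. Genes without a
#' call count as unknown (0). The empty rule scores NA (reaction state is
#' not decidable from expression).
#'
#' @param tree GPR parse tree.
#' @param calls named integer vector of calls in \{-1, 0, 1\}.
#' @return integer score in \{-1, 0, 1\}, or NA for the empty rule.
#' @export
scoreGpr <- function(tree, calls) {
  if (is.null(tree)) return(NA_integer_)
  .gprScore(tree, calls)
}

.gprScore <- function(tree, calls) {
  if (is.character(tree)) {
    v <- calls[tree]
    return(if (is.na(v)) 0L else as.integer(v))
  }
  vals <- vapply(tree$args, .gprScore, integer(1), calls = calls)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Genes referenced by a GPR parse tree
#' @param tree GPR parse tree.
#' @return character vector of gene ids (possibly empty).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes)))
}

#' Render a GPR parse tree back to text
#'
#' Inverse of [parseGpr()] up to whitespace and redundant parentheses:
#' `parseGpr(gprToString(tree))` reproduces `tree`.
#'
#' @param tree GPR parse tree.
#' @return rule text ("" for the empty rule).
#' @export
gprToString <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gprToString(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
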