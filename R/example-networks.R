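#' Small example network: a capped linear chain
#'
#' `source (ub 10) -> A -> (ub 5) -> B -> sink (ub 100)` with the sink as
#' objective; the optimum is the bottleneck capacity 5. Used in examples and
#' documentation.
#'
#' @return a [MetabolicNetwork-class] with 3 reactions and 2 metabolites.
#' @examples
#' net <- exampleChainNetwork()
#' fba(net)@objval   # 5, the bottleneck
#' @export
exampleChainNetwork <- function() {
  S <- matrix(c(1, 0, -1, 1, 0, -1), nrow = 2,
              dimnames = list(c("A", "B"), c("r_src", "r_ab", "r_sink")))
  newMetabolicNetwork(rxns = colnames(S), mets = rownames(S), S = S,
                      lb = c(0, 0, 0), ub = c(10, 5, 100),
                      objective = "r_sink", id = "chain")
}
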