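#' Simulate a random ultrametric phylogeny
#'
#' Generates a rooted ultrametric tree by coalescent-style pairwise joining
#' with exponential waiting times and rescales its depth to 1, so that the
#' phylogenetic covariance matrix derived from it ([phyloCovariance()]) has
#' unit diagonal. Tip labels are `sp01`, `sp02`, ....
#'
#' @param nSpecies number of tips (>= 2).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return an [ape::phylo] object, ultrametric with depth 1.
#' @examples
#' tr <- simulatePhylogeny(8, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # 1
#' @export
simulatePhylogeny <- function(nSpecies, seed = NULL) {
  nSpecies <- checkCount(nSpecies, "nSpecies", min = 2L)
  tr <- withSeed(seed, ape::rcoal(nSpecies,
                                  tip.label = sprintf("sp%02d", seq_len(nSpecies))))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}
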