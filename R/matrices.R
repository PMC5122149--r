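#' Random trees and distance matrices for validation
#'
#' Generators used to validate the tree-inference engine: a random unrooted
#' tree with branch lengths drawn uniformly from `br_range`; its additive
#' (path-length) distance matrix; and a mildly non-additive matrix obtained
#' by perturbing every distance with independent multiplicative noise
#' `1 + U(-amplitude, +amplitude)` (symmetrised), which emulates the
#' sampling error of distances estimated from finite alignments.
#'
#' @param n_taxa Number of leaves.
#' @param seed Integer seed.
#' @param br_range Branch-length range (substitutions/site).
#' @return `random_additive_tree()` an `ape::phylo`;
#'   `tree_distance_matrix()` and `perturb_distances()` labelled symmetric
#'   matrices.
#' @export
random_additive_tree <- function(n_taxa, seed, br_range = c(0.05, 1)) {
  assert_that(n_taxa >= 4, "n_taxa must be >= 4",
              class = "chsevol_invalid_argument")
  local_seed(seed, {
    ape::rtree(n_taxa, rooted = FALSE,
               br = function(n) runif(n, br_range[1], br_range[2]),
               tip.label = sprintf("t%02d", seq_len(n_taxa)))
  })
}

#' @rdname random_additive_tree
#' @param tree An `ape::phylo` with branch lengths.
#' @export
tree_distance_matrix <- function(tree) {
  dm <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(dm))
  dm[labs, labs]
}

#' @rdname random_additive_tree
#' @param dm Labelled symmetric distance matrix.
#' @param amplitude Multiplicative noise amplitude.
#' @export
perturb_distances <- function(dm, seed, amplitude = 0.05) {
  local_seed(seed, {
    n <- nrow(dm)
    noise <- matrix(runif(n * n, -amplitude, amplitude), n)
    noise <- (noise + t(noise)) / 2
    out <- dm * (1 + noise)
    diag(out) <- 0
    out
  })
}
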