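#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with two reproducibility-minded
#' conventions:
#'
#' * Ties in the Q criterion (within 1e-12) are broken by merging the pair
#'   whose subtree representative labels (the lexicographically smallest
#'   leaf label in each subtree) sort first, so the topology never depends
#'   on matrix row order.
#' * Negative intermediate branch lengths are clamped to zero and the
#'   deficit is moved to the sister branch, preserving the path length
#'   through the new node.
#'
#' @param dm Labelled symmetric distance matrix (>= 3 labels, zero
#'   diagonal).
#' @return An unrooted `ape::phylo` (stored with the conventional basal
#'   trifurcation).
#' @examples
#' dm <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'              dimnames = list(letters[1:3], letters[1:3]))
#' nj_tree(dm)
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm, tol = 1e-9)
  n <- nrow(dm)
  assert_that(n >= 3, "need at least 3 labels",
              class = "chsevol_invalid_argument")
  labels <- rownames(dm)
  sub <- labels            # newick fragments of active nodes
  rep_lab <- labels        # lexicographic representative per active node
  D <- dm
  while (length(sub) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on representative labels
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- D[i, j]; bi <- 0 }
    if (bj < 0) { bi <- D[i, j]; bj <- 0 }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- newd[-c(i, j)]
    merged <- paste0("(", sub[i], ":", format(bi, digits = 12), ",",
                     sub[j], ":", format(bj, digits = 12), ")")
    newrep <- min(rep_lab[i], rep_lab[j])
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    sub <- c(sub[-c(i, j)], merged)
    rep_lab <- c(rep_lab[-c(i, j)], newrep)
  }
  # resolve the final three nodes with the three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- paste0("(", sub[1], ":", format(b[1], digits = 12), ",",
                sub[2], ":", format(b[2], digits = 12), ",",
                sub[3], ":", format(b[3], digits = 12), ");")
  ape::read.tree(text = nwk)
}
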