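#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree
#' per replicate and scores every internal edge of the reference topology by
#' the percentage of valid replicate trees containing the same bipartition.
#' Replicates in which a pairwise distance is undefined (no shared columns,
#' or saturation under the Poisson correction) are discarded and counted,
#' not imputed; supports are percentages of the valid replicates.
#'
#' @param aln Alignment character matrix (>= 3 rows).
#' @param n_reps Number of bootstrap replicates (>= 1); 100 is the
#'   conventional choice.
#' @param correction Distance correction, see [pairwise_distance()].
#' @param seed Integer seed; supports are reproducible for a fixed seed.
#' @return Object of class `chs_boot_tree`: list with `tree` (the reference
#'   NJ `phylo`, internal node labels = rounded supports), `supports`
#'   (tibble: `bipartition`, `support`), `n_reps`, `n_valid`,
#'   `n_discarded`, `correction`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, correction = "poisson",
                              seed = 1) {
  validate_alignment(aln, min_rows = 3)
  assert_that(n_reps >= 1, "n_reps must be >= 1",
              class = "chsevol_invalid_argument")
  ref_tree <- nj_tree(pairwise_distance(aln, correction))
  ref_parts <- bipartitions(ref_tree)
  counts <- setNames(rep(0L, length(ref_parts)), ref_parts)
  n_valid <- 0L
  local_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_tree <- tryCatch(
        nj_tree(pairwise_distance(aln[, idx, drop = FALSE], correction)),
        chsevol_undefined_distance = function(e) NULL)
      if (is.null(rep_tree)) next
      n_valid <- n_valid + 1L
      hit <- ref_parts %in% bipartitions(rep_tree)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- if (n_valid > 0) 100 * as.numeric(counts) / n_valid
             else rep(NA_real_, length(ref_parts))
  tree <- annotate_supports(ref_tree, setNames(support, ref_parts))
  structure(list(tree = tree,
                 supports = tibble(bipartition = gsub("\r", ",", ref_parts),
                                   support = support),
                 n_reps = n_reps, n_valid = n_valid,
                 n_discarded = n_reps - n_valid,
                 correction = correction),
            class = "chs_boot_tree")
}

# write per-edge supports onto the internal node labels of `tree`
annotate_supports <- function(tree, support_by_part) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ref <- sort(tree$tip.label)[1]
  tips_below <- tips_under_nodes(tree)
  labs <- character(nnode)
  for (v in (ntip + 1L):(ntip + nnode)) {
    side <- tips_below[[v]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "\r")
    s <- support_by_part[key]
    labs[v - ntip] <- if (is.na(s)) "" else as.character(round(s))
  }
  tree$node.label <- labs
  tree
}

#' @export
print.chs_boot_tree <- function(x, ...) {
  cat("NJ tree (", x$correction, " distances), ", length(x$tree$tip.label),
      " leaves, ", x$n_valid, "/", x$n_reps, " valid bootstrap replicates\n",
      sep = "")
  if (nrow(x$supports)) {
    cat("  internal edge supports: ",
        paste(round(sort(x$supports$support, decreasing = TRUE)),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.chs_boot_tree <- function(x, ...) x$supports

#' @export
glance.chs_boot_tree <- function(x, ...) {
  tibble(n_leaves = length(x$tree$tip.label),
         n_edges_scored = nrow(x$supports),
         median_support = median(x$supports$support),
         n_reps = x$n_reps, n_valid = x$n_valid,
         n_discarded = x$n_discarded, correction = x$correction)
}
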