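# Tree utilities: bipartitions, Robinson-Foulds distance, outgroup rooting,
# long-branch flagging. Trees are ape::phylo; internal node labels (when
# present) carry bootstrap supports as integer strings in [0, 100].

# Non-trivial bipartitions of a tree as canonical strings: for every
# internal edge, the side NOT containing the reference leaf (the
# lexicographically first tip label), sorted and collapsed.
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  ref <- sort(tree$tip.label)[1]
  tips_below <- tips_under_nodes(tree)
  nodes <- setdiff(unique(tree$edge[, 1]), ntip + 1L) # internal, non-root
  parts <- vapply(nodes, function(v) {
    side <- tips_below[[v]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  unique(parts[!is.na(parts)])
}

# list: node id -> tip labels under that node
tips_under_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  nmax <- max(tree$edge)
  out <- vector("list", nmax)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  edges <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    out[[a]] <- c(out[[a]], out[[b]])
  }
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (the symmetric difference). Both trees must have the same leaf
#' label set; rootedness is ignored (bipartitions are unrooted objects).
#'
#' @param t1,t2 `ape::phylo` trees on the same leaves.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  assert_that(setequal(t1$tip.label, t2$tip.label) &&
                length(t1$tip.label) == length(t2$tip.label),
              "trees must share the same leaf label set",
              class = "chsevol_invalid_argument")
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Root a tree with a designated outgroup
#'
#' Checks that the outgroup labels form one side of a bipartition of the
#' unrooted tree (i.e. are monophyletic when viewed from the ingroup) and
#' roots the tree on the edge separating outgroup from ingroup, placing the
#' root at that edge's midpoint. Internal node labels (bootstrap supports)
#' follow their edges through the rerooting.
#'
#' @param tree `ape::phylo`.
#' @param outgroup_labels Character vector of outgroup tips.
#' @return A rooted `ape::phylo`.
#' @export
root_by_outgroup <- function(tree, outgroup_labels) {
  assert_that(all(outgroup_labels %in% tree$tip.label),
              paste0("outgroup labels not in tree: ",
                     paste(setdiff(outgroup_labels, tree$tip.label),
                           collapse = ", ")),
              class = "chsevol_invalid_argument")
  ntip <- length(tree$tip.label)
  og <- sort(unique(outgroup_labels))
  assert_that(length(og) < ntip, "outgroup cannot contain every leaf",
              class = "chsevol_invalid_argument")
  complement <- sort(setdiff(tree$tip.label, og))
  # the outgroup edge exists iff one bipartition side equals the outgroup;
  # in the stored (arbitrary) rooting that side may appear as either the
  # outgroup or its complement
  anchor <- og
  if (length(og) > 1) {
    tips_below <- tips_under_nodes(ape::unroot(tree))
    sides <- lapply(tips_below, sort)
    if (!any(vapply(sides, identical, logical(1), y = og))) {
      if (any(vapply(sides, identical, logical(1), y = complement))) {
        anchor <- complement # same edge, seen from the stored root's side
      } else {
        mrca_tips <- tips_under_nodes(tree)[[ape::getMRCA(tree, og)]]
        abort(paste0("outgroup is not monophyletic; intruding leaves: ",
                     paste(setdiff(mrca_tips, og), collapse = ", ")),
              class = c("chsevol_nonmonophyletic_outgroup", "chsevol_error"))
      }
    }
  }
  rooted <- ape::root(tree, outgroup = anchor, resolve.root = TRUE,
                      edgelabel = TRUE)
  # midpoint of the outgroup/ingroup edge
  root <- length(rooted$tip.label) + 1L
  kid_edges <- which(rooted$edge[, 1] == root)
  if (length(kid_edges) == 2) {
    tot <- sum(rooted$edge.length[kid_edges])
    rooted$edge.length[kid_edges] <- tot / 2
  }
  rooted
}

#' Flag suspiciously long terminal branches
#'
#' Leaves whose terminal branch exceeds `k` times the median terminal branch
#' length. Fast-evolving sequences flagged this way are the usual long-branch
#' attraction suspects and are typically excluded before classification.
#'
#' @param tree `ape::phylo` with >= 4 leaves.
#' @param k Multiplier on the median terminal branch length.
#' @return Character vector of flagged leaf labels (possibly empty).
#' @export
flag_long_branches <- function(tree, k = 4) {
  assert_that(length(tree$tip.label) >= 4, "need >= 4 leaves",
              class = "chsevol_invalid_argument")
  assert_that(k > 0, "k must be > 0", class = "chsevol_invalid_argument")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  len <- tree$edge.length[term]
  tips <- tree$tip.label[tree$edge[term, 2]]
  tips[len > k * median(len)]
}

# Support value of an internal node from its label ("" or NA -> NA).
node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip || is.null(tree$node.label)) return(NA_real_)
  lab <- tree$node.label[node - ntip]
  if (is.na(lab) || lab == "") return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

# Support of the edge subtending `node`. In a rooted binary tree the two
# root-child edges carry the same bipartition, so when the node's own label
# is empty its root-sibling's label (if any) applies.
clade_support <- function(tree, node) {
  s <- node_support(tree, node)
  if (!is.na(s)) return(s)
  root <- length(tree$tip.label) + 1L
  if (node == root) return(NA_real_)
  parent <- tree$edge[match(node, tree$edge[, 2]), 1]
  if (is.na(parent) || parent != root) return(s)
  sibs <- setdiff(tree$edge[tree$edge[, 1] == root, 2], node)
  if (length(sibs) != 1) return(s)
  node_support(tree, sibs)
}
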