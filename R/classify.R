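#' Test a label set for monophyly
#'
#' A set of leaves is monophyletic when the smallest clade containing all of
#' them contains no other leaf. The returned support is the bootstrap value
#' attached to that clade's subtending edge (`NA` at the root or when the
#' tree carries no supports).
#'
#' @param tree Rooted `ape::phylo`, optionally with supports as internal
#'   node labels.
#' @param labels Character vector of leaf labels.
#' @return List with `monophyletic` (logical) and `support` (numeric or
#'   `NA`).
#' @export
is_monophyletic <- function(tree, labels) {
  labels <- unique(labels)
  assert_that(all(labels %in% tree$tip.label),
              paste0("unknown labels: ",
                     paste(setdiff(labels, tree$tip.label), collapse = ", ")),
              class = "chsevol_invalid_argument")
  if (length(labels) == 1) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  mrca <- ape::getMRCA(tree, labels)
  clade <- tips_under_nodes(tree)[[mrca]]
  if (!setequal(clade, labels)) {
    return(list(monophyletic = FALSE, support = NA_real_))
  }
  list(monophyletic = TRUE, support = clade_support(tree, mrca))
}

#' Define sequence classes from two concordant trees
#'
#' A class is a proposed set of sequences that forms a well-supported
#' monophyletic group in the trees obtained under two independent inference
#' settings — here, NJ under two distance corrections. A proposal is
#' accepted only when it is monophyletic with support at or above
#' `support_min` in *both* trees; rejections record which tree and which
#' criterion failed.
#'
#' @param tree1,tree2 Rooted `ape::phylo` trees on the same leaves, with
#'   bootstrap supports as internal node labels.
#' @param proposed Named list: class name -> character vector of members.
#' @param support_min Minimum support (default 60, the conventional
#'   bootstrap threshold for "well-supported").
#' @return A tibble of class `chs_class_definitions`: `class`, `n_members`,
#'   `monophyletic1`, `support1`, `monophyletic2`, `support2`, `accepted`,
#'   `reason`, `members` (list-column).
#' @export
define_classes <- function(tree1, tree2, proposed, support_min = 60) {
  assert_that(setequal(tree1$tip.label, tree2$tip.label),
              "trees must share the same leaf set",
              class = "chsevol_invalid_argument")
  assert_that(is.list(proposed) && !is.null(names(proposed)) &&
                all(lengths(proposed) >= 1),
              "proposed must be a named list of non-empty member vectors",
              class = "chsevol_invalid_argument")
  rows <- imap(proposed, function(members, cls) {
    m1 <- is_monophyletic(tree1, members)
    m2 <- is_monophyletic(tree2, members)
    reason <- NA_character_
    ok <- TRUE
    for (k in 1:2) {
      m <- list(m1, m2)[[k]]
      if (!m$monophyletic) {
        reason <- paste0("not monophyletic (tree", k, ")"); ok <- FALSE; break
      }
      if (is.na(m$support) || m$support < support_min) {
        reason <- paste0("support ", if (is.na(m$support)) "unavailable"
                         else round(m$support), " < ", support_min,
                         " (tree", k, ")")
        ok <- FALSE; break
      }
    }
    tibble(class = cls, n_members = length(members),
           monophyletic1 = m1$monophyletic, support1 = m1$support,
           monophyletic2 = m2$monophyletic, support2 = m2$support,
           accepted = ok, reason = reason, members = list(members))
  })
  out <- bind_rows(rows)
  class(out) <- c("chs_class_definitions", class(out))
  out
}

#' Assign a query sequence to a defined class
#'
#' Strictly phylogenetic assignment: the query joins class `C` if and only
#' if the smallest clade containing the query and at least one reference
#' leaf has all of its reference leaves in `C` and that clade's support is
#' at or above `support_min`. Anything else — mixed reference neighbours,
#' reference leaves belonging to no class, insufficient support — yields
#' `"unclassified"`.
#'
#' @param tree Rooted `ape::phylo` containing the query leaf, with supports
#'   as internal node labels.
#' @param classes A `chs_class_definitions` tibble (accepted rows are used)
#'   or a named list class -> members.
#' @param query_label The query leaf label.
#' @param support_min Minimum support for the assignment clade.
#' @return A one-row tibble: `query`, `class`, `support`, `reason`.
#' @export
assign_query <- function(tree, classes, query_label, support_min = 60) {
  assert_that(query_label %in% tree$tip.label,
              paste0("query '", query_label, "' not in tree"),
              class = "chsevol_invalid_argument")
  membership <- class_membership(classes)
  ntip <- length(tree$tip.label)
  parent <- rep(NA_integer_, max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tips_below <- tips_under_nodes(tree)
  v <- parent[match(query_label, tree$tip.label)]
  refs <- character(0)
  while (!is.na(v)) {
    refs <- setdiff(tips_below[[v]], query_label)
    if (length(refs) >= 1) break
    v <- parent[v]
  }
  unclassified <- function(reason) {
    tibble(query = query_label, class = "unclassified",
           support = NA_real_, reason = reason)
  }
  if (is.na(v) || length(refs) == 0) {
    return(unclassified("no reference neighbours"))
  }
  cls <- unname(membership[refs])
  if (any(is.na(cls))) return(unclassified("neighbours outside any class"))
  if (length(unique(cls)) > 1) {
    return(unclassified("mixed reference neighbours"))
  }
  s <- clade_support(tree, v)
  if (is.na(s) || s < support_min) {
    return(unclassified(paste0("insufficient support (",
                               if (is.na(s)) "none" else round(s), ")")))
  }
  tibble(query = query_label, class = unique(cls), support = s,
         reason = "smallest supported clade is single-class")
}

class_membership <- function(classes) {
  if (inherits(classes, "chs_class_definitions") || is.data.frame(classes)) {
    classes <- classes[classes$accepted %||% TRUE, , drop = FALSE]
    members <- setNames(classes$members, classes$class)
  } else {
    members <- classes
  }
  assert_that(is.list(members) && !is.null(names(members)),
              "classes must be class definitions or a named list")
  setNames(rep(names(members), lengths(members)),
           unlist(members, use.names = FALSE))
}

#' Write class definitions as TSV (class, seq_id)
#' @param classes `chs_class_definitions` or named list.
#' @param path Output path.
#' @export
write_class_definitions <- function(classes, path) {
  membership <- class_membership(classes)
  write_tsv_plain(tibble(class = unname(membership),
                         seq_id = names(membership)), path)
}
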