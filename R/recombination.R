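#' Locate a chimera breakpoint from a duplicated motif
#'
#' Chimeric (recCHS-like) sequences carry two copies of the `QXXXY` motif —
#' one inherited with each parental fragment. When the ungapped sequence of
#' an aligned row has two or more motif copies, the breakpoint is placed at
#' the alignment column mapping to the midpoint between the first and
#' second match starts; with fewer than two copies there is no breakpoint.
#'
#' @param aligned_row Gapped amino-acid string (one alignment row).
#' @param motif A [motif_definition()] or pattern string (default
#'   `"QXXXY"`).
#' @return The 1-based alignment column of the breakpoint, or `NULL`.
#' @export
locate_breakpoint <- function(aligned_row,
                              motif = motif_definition("QXXXY", "QXXXY")) {
  rc <- chars(aligned_row)
  ungapped <- paste(rc[rc != GAP_CHAR], collapse = "")
  hits <- detect_motif_duplication(ungapped, motif)
  if (length(hits) < 2) return(NULL)
  mid_ungapped <- (hits[1] + hits[2]) %/% 2
  # map ungapped position -> alignment column
  which(cumsum(rc != GAP_CHAR) == mid_ungapped)[1]
}

#' Split an alignment into N- and C-terminal fragments
#'
#' @param aln Alignment character matrix.
#' @param column Number of columns in the N-terminal fragment
#'   (`0 < column < width`); the C-terminal fragment gets the rest.
#' @return List with `aln_n` and `aln_c`; concatenating them column-wise
#'   reproduces the input.
#' @export
split_alignment <- function(aln, column) {
  validate_alignment(aln)
  w <- ncol(aln)
  assert_that(column > 0 && column < w,
              paste0("split column must be strictly inside (0, ", w, ")"),
              class = "chsevol_invalid_argument")
  list(aln_n = aln[, seq_len(column), drop = FALSE],
       aln_c = aln[, (column + 1):w, drop = FALSE])
}

#' Diagnose a chimeric sequence by split-tree placement
#'
#' Splits the alignment at the breakpoint, infers an NJ tree with bootstrap
#' supports independently for the N- and C-terminal fragments, and finds
#' the query's nearest reference group in each (smallest supported clade
#' around the query, as in [assign_query()]). The verdict is chimeric when
#' the two fragments place the query confidently in *different* reference
#' groups — the discordant N-/C-terminal phylogenetic signal expected after
#' a fusion of two glycosyltransferase ancestries. Every positive verdict
#' carries the caveat that a transient acceleration of evolutionary rate
#' can blur phylogenetic signal in a similar way.
#'
#' @param aln Alignment character matrix containing the query and the
#'   reference sequences.
#' @param query_id Row id of the query.
#' @param reference_groups Named character vector reference id -> group
#'   (at least two groups).
#' @param breakpoint N-fragment width in columns (e.g. from
#'   [locate_breakpoint()]).
#' @param support_min Minimum support for each fragment placement.
#' @param n_reps Bootstrap replicates per fragment.
#' @param correction Distance correction.
#' @param min_fragment_columns Refuse fragments narrower than this.
#' @param seed Integer seed.
#' @return A one-row tibble of class `chs_chimera_report`: `seq_id`,
#'   `breakpoint`, `n_group`, `c_group`, `n_support`, `c_support`,
#'   `chimeric`, `note`. Fragment trees are attached as attribute `trees`.
#' @export
detect_chimera <- function(aln, query_id, reference_groups, breakpoint,
                           support_min = 60, n_reps = 100,
                           correction = "poisson",
                           min_fragment_columns = 50, seed = 1) {
  validate_alignment(aln, min_rows = 4)
  assert_that(query_id %in% rownames(aln), "query not in alignment",
              class = "chsevol_invalid_argument")
  refs <- names(reference_groups)
  assert_that(all(refs %in% rownames(aln)),
              "reference ids missing from alignment",
              class = "chsevol_invalid_argument")
  assert_that(length(unique(reference_groups)) >= 2,
              "need at least two reference groups",
              class = "chsevol_invalid_argument")
  frags <- split_alignment(aln, breakpoint)
  widths <- vapply(frags, ncol, integer(1))
  if (any(widths < min_fragment_columns)) {
    abort(paste0("fragment too short for placement: widths ",
                 paste(widths, collapse = "/"), " columns, minimum ",
                 min_fragment_columns),
          class = c("chsevol_fragment_too_short", "chsevol_error"))
  }
  place <- function(frag, which_seed) {
    sub <- frag[c(refs, query_id), , drop = FALSE]
    boot <- bootstrap_support(sub, n_reps = n_reps, correction = correction,
                              seed = which_seed)
    tree <- root_between_groups(boot$tree, reference_groups, query_id)
    a <- assign_query(tree, split(refs, unname(reference_groups)),
                      query_id, support_min = support_min)
    list(assign = a, tree = tree)
  }
  pn <- place(frags$aln_n, derive_seed(seed, 1))
  pc <- place(frags$aln_c, derive_seed(seed, 2))
  gn <- pn$assign$class; gc_ <- pc$assign$class
  chimeric <- gn != "unclassified" && gc_ != "unclassified" && gn != gc_
  note <- if (chimeric) {
    paste("discordant N-/C-terminal placements; a transient elevated",
          "evolutionary rate could mimic this pattern")
  } else if (gn == "unclassified" || gc_ == "unclassified") {
    paste0("insufficient placement (N: ", pn$assign$reason,
           "; C: ", pc$assign$reason, ")")
  } else {
    "concordant placements"
  }
  out <- tibble(seq_id = query_id, breakpoint = breakpoint,
                n_group = gn, c_group = gc_,
                n_support = pn$assign$support, c_support = pc$assign$support,
                chimeric = chimeric, note = note)
  class(out) <- c("chs_chimera_report", class(out))
  attr(out, "trees") <- list(n = pn$tree, c = pc$tree)
  out
}

# Root a tree on the edge that best separates the reference groups
# (ignoring the query), at that edge's midpoint. With cleanly diverged
# reference groups this is exact; otherwise the minimum-conflict edge wins.
root_between_groups <- function(tree, reference_groups, query_id = NULL) {
  groups <- sort(unique(unname(reference_groups)))
  g1 <- names(reference_groups)[reference_groups == groups[1]]
  tips_below <- tips_under_nodes(tree)
  labels <- setdiff(tree$tip.label, query_id)
  best <- NULL; best_cost <- Inf
  for (v in seq_len(max(tree$edge))) {
    if (v == length(tree$tip.label) + 1L) next
    side <- intersect(tips_below[[v]], labels)
    other <- setdiff(labels, side)
    cost <- min(length(setdiff(side, g1)) + length(intersect(other, g1)),
                length(intersect(side, g1)) + length(setdiff(other, g1)))
    if (cost < best_cost) { best_cost <- cost; best <- v }
  }
  og <- tips_below[[best]]
  if (length(og) == length(tree$tip.label)) return(tree)
  rooted <- tryCatch(root_by_outgroup(tree, og),
                     chsevol_error = function(e) tree)
  rooted
}
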