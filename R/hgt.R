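#' Sliding-window G+C profile of a nucleotide sequence
#'
#' Overlapping windows (default 1000 bp at a step of 30 bp, the conventional
#' setting for genomic-context composition scans). Only full windows are
#' scored, at starts `0, step, 2*step, ...` while `start + window <= length`,
#' so the number of windows obeys `floor((L - window)/step) + 1`. G+C is
#' counted case-insensitively; ambiguous bases (anything outside ACGT) are
#' excluded from both numerator and denominator.
#'
#' @param seq Nucleotide string.
#' @param window Window length in bp.
#' @param step Step between window starts in bp.
#' @return Tibble of class `chs_gc_profile` with columns `start` (0-based)
#'   and `gc`; zero rows if the sequence is shorter than the window.
#'   Attributes `window` and `step` record the parameters.
#' @examples
#' gc_windows(strrep("GCAT", 600), window = 1000, step = 30)
#' @export
gc_windows <- function(seq, window = 1000, step = 30) {
  assert_that(window >= 1 && step >= 1, "window and step must be >= 1",
              class = "chsevol_invalid_argument")
  b <- toupper(chars(seq))
  L <- length(b)
  empty <- tibble(start = integer(), gc = double())
  prof <- if (L < window) empty else {
    is_gc <- cumsum(c(0, b %in% c("G", "C")))
    is_acgt <- cumsum(c(0, b %in% c("A", "C", "G", "T")))
    starts0 <- seq(0L, L - window, by = step)
    gc_n <- is_gc[starts0 + window + 1] - is_gc[starts0 + 1]
    tot <- is_acgt[starts0 + window + 1] - is_acgt[starts0 + 1]
    tibble(start = starts0, gc = ifelse(tot > 0, gc_n / tot, NA_real_))
  }
  structure(prof, window = window, step = step,
            class = c("chs_gc_profile", class(prof)))
}

#' G+C content of a sequence (ambiguous bases excluded)
#' @param seq Nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  b <- toupper(chars(seq))
  sum(b %in% c("G", "C")) / sum(b %in% c("A", "C", "G", "T"))
}

#' Composition anomaly of a region against its genomic background
#'
#' Compares the overall G+C of a region (e.g. a candidate transferred gene)
#' with the distribution of background window values:
#' `z = (gc(region) - mean(background)) / sd(background)`, flagged when
#' `|z| >= z_min`. A recently transferred gene retains its donor's
#' composition and stands out from the surrounding genomic context. With a
#' degenerate (zero-variance) background the rule falls back to an absolute
#' difference of at least `abs_fallback`, and `z` is reported as a signed
#' infinity.
#'
#' @param region Nucleotide string.
#' @param background_profile A [gc_windows()] profile of the surrounding
#'   genomic context (non-empty).
#' @param z_min Z-score threshold.
#' @param abs_fallback Absolute G+C difference used when the background has
#'   zero variance.
#' @return List with `z`, `flag`, `region_gc`, `background_mean`.
#' @export
gc_anomaly <- function(region, background_profile, z_min = 2,
                       abs_fallback = 0.05) {
  assert_that(nrow(background_profile) >= 1,
              "background profile is empty",
              class = "chsevol_invalid_argument")
  bg <- background_profile$gc[!is.na(background_profile$gc)]
  assert_that(length(bg) >= 1, "background profile has no scored windows",
              class = "chsevol_invalid_argument")
  rgc <- gc_content(region)
  mu <- mean(bg)
  sdev <- if (length(bg) > 1) sd(bg) else 0
  if (sdev > 0) {
    z <- (rgc - mu) / sdev
    flag <- abs(z) >= z_min
  } else {
    z <- sign(rgc - mu) * Inf
    if (rgc == mu) z <- 0
    flag <- abs(rgc - mu) >= abs_fallback
  }
  list(z = z, flag = flag, region_gc = rgc, background_mean = mu)
}

#' Find leaves phylogenetically incongruent with their taxon group
#'
#' A leaf is called incongruent when the smallest well-supported clade
#' containing it and at least `min_context` other leaves has *all* of those
#' other leaves in a single taxon group different from the leaf's own —
#' e.g. a bacterial sequence nested inside an otherwise fungal clade, the
#' classic gene-tree signature of a horizontal transfer towards bacteria.
#' Clades below `support_min` are skipped while walking towards the root.
#'
#' @param gene_tree `ape::phylo` with bootstrap supports as internal node
#'   labels.
#' @param taxon_groups Named character vector mapping leaf labels — or the
#'   taxon part of `taxon|gene` labels — to group names. Every leaf must
#'   resolve.
#' @param support_min Minimum clade support.
#' @param min_context Minimum number of other leaves in the deciding clade.
#' @return Tibble: `leaf`, `leaf_group`, `clade_group`, `support` (zero
#'   rows when the tree is congruent).
#' @export
detect_incongruent_leaves <- function(gene_tree, taxon_groups,
                                      support_min = 60, min_context = 2) {
  grp <- resolve_groups(gene_tree$tip.label, taxon_groups)
  ntip <- length(gene_tree$tip.label)
  parent <- rep(NA_integer_, max(gene_tree$edge))
  parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  tips_below <- tips_under_nodes(gene_tree)
  root <- ntip + 1L
  out <- list()
  for (i in seq_len(ntip)) {
    leaf <- gene_tree$tip.label[i]
    v <- parent[i]
    while (!is.na(v)) {
      if (v == root) break # the root carries no support; stop
      s <- clade_support(gene_tree, v)
      others <- setdiff(tips_below[[v]], leaf)
      if (!is.na(s) && s >= support_min && length(others) >= min_context) {
        og <- unique(grp[others])
        if (length(og) == 1 && og != grp[leaf]) {
          out[[length(out) + 1L]] <- tibble(
            leaf = leaf, leaf_group = unname(grp[leaf]),
            clade_group = og, support = s)
        }
        break # smallest supported contextful clade decides
      }
      v <- parent[v]
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(leaf = character(), leaf_group = character(),
           clade_group = character(), support = double())
}

resolve_groups <- function(labels, taxon_groups) {
  g <- taxon_groups[labels]
  miss <- is.na(g)
  g[miss] <- taxon_groups[leaf_taxon(labels[miss])]
  assert_that(!any(is.na(g)),
              paste0("unmapped leaves: ",
                     paste(labels[is.na(g)], collapse = ", ")),
              class = "chsevol_invalid_argument")
  setNames(unname(g), labels)
}

#' Jaccard similarity of two gene neighbourhoods
#'
#' Similarity of the flanking gene-family label sets of two focal genes
#' (strand-insensitive by default; with `strand_aware = TRUE` a family only
#' matches with equal orientation). Two empty neighbourhoods score 0.
#'
#' @param n_a,n_b Character vectors of neighbour family labels, optionally
#'   with strand suffixes when tibbles from [read_neighborhood()] rows are
#'   supplied as `family_label` / `strand` columns.
#' @param strand_aware Compare family labels together with strand signs.
#' @return Jaccard index in \[0, 1\].
#' @export
neighborhood_similarity <- function(n_a, n_b, strand_aware = FALSE) {
  a <- neighbor_set(n_a, strand_aware)
  b <- neighbor_set(n_b, strand_aware)
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

neighbor_set <- function(x, strand_aware) {
  if (is.data.frame(x)) {
    fams <- x$family_label
    if (strand_aware) fams <- paste0(fams, x$strand)
    return(unique(fams))
  }
  unique(as.character(x))
}

#' Detect co-transferred gene neighbourhoods across taxon groups
#'
#' Builds a graph over the genomes carrying focal genes, connecting two
#' genomes when they belong to *different* taxon groups and some pair of
#' their focal-gene neighbourhoods reaches `jaccard_min` similarity.
#' Conserved gene order around a focal gene in distantly related genomes is
#' the synteny line of evidence that the neighbourhood was transferred and
#' maintained as a unit (a classic operon-like signature). Connected
#' components with at least two genomes are reported together with the
#' family labels shared across their linking edges, and with the focal
#' genes whose neighbourhoods support the component.
#'
#' @param neighborhoods Tibble with columns `genome`, `gene_id`,
#'   `position_index`, `family_label`, `strand` (one row per neighbour).
#' @param taxon_groups Named character vector genome -> group.
#' @param focal_gene_ids Genes to consider (default: all in the table).
#' @param jaccard_min Similarity threshold for an edge.
#' @param strand_aware Passed to [neighborhood_similarity()].
#' @return Tibble: `component`, `genomes` (list), `groups` (list),
#'   `shared_families` (list), `gene_ids` (list); zero rows when no
#'   cross-group conservation exists.
#' @export
detect_cotransfer <- function(neighborhoods, taxon_groups,
                              focal_gene_ids = NULL, jaccard_min = 0.3,
                              strand_aware = FALSE) {
  nb <- as_tibble(neighborhoods)
  if (!is.null(focal_gene_ids)) nb <- filter(nb, .data$gene_id %in% focal_gene_ids)
  if (nrow(nb) == 0) return(empty_cotransfer())
  sets <- nb |>
    group_by(.data$genome, .data$gene_id) |>
    summarise(fams = list(neighbor_set(pick(everything()), strand_aware)),
              .groups = "drop")
  grp <- taxon_groups[sets$genome]
  assert_that(!any(is.na(grp)),
              paste0("genomes without a taxon group: ",
                     paste(unique(sets$genome[is.na(grp)]), collapse = ", ")),
              class = "chsevol_invalid_argument")
  n <- nrow(sets)
  edges <- list(); shared <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sets$genome[i] == sets$genome[j]) next
      if (grp[i] == grp[j]) next
      a <- sets$fams[[i]]; b <- sets$fams[[j]]
      u <- union(a, b)
      if (length(u) == 0) next
      jac <- length(intersect(a, b)) / length(u)
      if (jac >= jaccard_min) {
        edges[[length(edges) + 1L]] <- c(i, j)
        shared[[length(shared) + 1L]] <- intersect(a, b)
      }
    }
  }
  if (!length(edges)) return(empty_cotransfer())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  rows <- lapply(seq_along(keep), function(k) {
    members <- which(comp$membership == keep[k])
    in_comp <- vapply(edges, function(e) all(e %in% members), logical(1))
    tibble(component = k,
           genomes = list(sort(unique(sets$genome[members]))),
           groups = list(sort(unique(unname(grp[members])))),
           shared_families = list(sort(unique(unlist(shared[in_comp])))),
           gene_ids = list(sort(sets$gene_id[members])))
  })
  bind_rows(rows)
}

empty_cotransfer <- function() {
  tibble(component = integer(), genomes = list(), groups = list(),
         shared_families = list(), gene_ids = list())
}

#' Combine the three lines of horizontal-transfer evidence
#'
#' One row per candidate gene with logical columns `incongruent` (gene-tree
#' placement conflicts with the taxon group), `gc_flag` (composition
#' anomaly) and `synteny` (member of a cross-group conserved
#' neighbourhood). The verdict is `"strong"` with two or more lines of
#' evidence, `"weak"` with exactly one, `"none"` otherwise — mirroring the
#' way transfer claims are argued from independent signals rather than any
#' single test.
#'
#' @param evidence Tibble with `seq_id` and the three logical columns
#'   (missing columns are treated as all-`FALSE`); extra score columns are
#'   carried through.
#' @return Tibble of class `chs_hgt_calls` with added `n_evidence` and
#'   `verdict` columns.
#' @export
combine_evidence <- function(evidence) {
  ev <- as_tibble(evidence)
  assert_that("seq_id" %in% names(ev), "evidence needs a seq_id column",
              class = "chsevol_invalid_argument")
  for (col in c("incongruent", "gc_flag", "synteny")) {
    if (!col %in% names(ev)) ev[[col]] <- FALSE
    ev[[col]] <- ev[[col]] %in% TRUE # NA -> FALSE
  }
  ev <- ev |>
    mutate(n_evidence = .data$incongruent + .data$gc_flag + .data$synteny,
           verdict = case_when(n_evidence >= 2 ~ "strong",
                               n_evidence == 1 ~ "weak",
                               TRUE ~ "none"))
  class(ev) <- c("chs_hgt_calls", class(ev))
  ev
}

#' @export
glance.chs_hgt_calls <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_strong = sum(x$verdict == "strong"),
         n_weak = sum(x$verdict == "weak"),
         n_incongruent = sum(x$incongruent),
         n_gc_flagged = sum(x$gc_flag),
         n_synteny = sum(x$synteny))
}
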