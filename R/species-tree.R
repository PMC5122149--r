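#' Sample a random ultrametric species tree
#'
#' Generates a rooted, binary, ultrametric species tree by sequential random
#' coalescence: `n_taxa - 1` node heights are drawn, sorted, rescaled so the
#' root sits exactly at `depth`, and lineages are merged uniformly at random
#' at successive heights. Branch lengths are in expected substitutions per
#' site, so every root-to-leaf path has length `depth`.
#'
#' When `groups` is supplied (a named integer vector, e.g.
#' `c(fungi = 6, bacteria = 6)`), each group becomes a basal clade: group
#' subtrees of height `depth * (1 - stem_fraction)` are joined by stems at the
#' root, which mimics deeply diverged taxon groups (say, eukaryotes versus
#' bacteria) and gives horizontal-transfer simulations a clean cross-group
#' signal.
#'
#' @param n_taxa Number of leaves (>= 3). Ignored when `groups` is given.
#' @param depth Root-to-leaf path length (> 0).
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @param groups Optional named integer vector of group sizes.
#' @param stem_fraction Fraction of `depth` taken by the stems joining group
#'   subtrees to the root (only used with `groups`).
#' @return An object of class `chs_species_tree`: a list with `tree`
#'   (`ape::phylo`, rooted, ultrametric) and `groups` (tibble with columns
#'   `taxon`, `group`).
#' @examples
#' st <- sample_species_tree(6, depth = 1, seed = 1)
#' st2 <- sample_species_tree(seed = 2, groups = c(fungi = 4, bacteria = 4))
#' @export
sample_species_tree <- function(n_taxa = NULL, depth = 1, seed,
                                groups = NULL, stem_fraction = 0.5) {
  assert_that(depth > 0, "depth must be > 0")
  if (is.null(groups)) {
    assert_that(!is.null(n_taxa) && n_taxa >= 3,
                "n_taxa must be >= 3", class = "chsevol_invalid_argument")
    labels <- sprintf("t%02d", seq_len(n_taxa))
    nwk <- local_seed(seed, random_coalescent_newick(labels, depth))
    grp <- tibble(taxon = labels, group = "all")
  } else {
    assert_that(!is.null(names(groups)) && all(groups >= 1),
                "groups must be a named vector of positive sizes",
                class = "chsevol_invalid_argument")
    assert_that(sum(groups) >= 3, "need at least 3 taxa in total",
                class = "chsevol_invalid_argument")
    assert_that(stem_fraction > 0 && stem_fraction < 1,
                "stem_fraction must be in (0, 1)")
    sub_height <- depth * (1 - stem_fraction)
    nwk <- local_seed(seed, {
      subs <- character(0)
      labs <- list()
      for (g in names(groups)) {
        labels <- sprintf("%s%02d", substr(g, 1, 3), seq_len(groups[[g]]))
        labs[[g]] <- labels
        subs <- c(subs, if (groups[[g]] == 1) {
          paste0(labels, ":", format(depth, digits = 12))
        } else {
          paste0(strip_semicolon(random_coalescent_newick(labels, sub_height)),
                 ":", format(depth - sub_height, digits = 12))
        })
      }
      # join group stems pectinately at the root (all joins at height depth)
      if (length(subs) == 1) {
        paste0(subs, ";")
      } else {
        out <- paste0("(", subs[1], ",", subs[2], ")")
        for (i in seq_along(subs)[-(1:2)]) {
          out <- paste0("(", out, ":0,", subs[i], ")")
        }
        paste0(out, ";")
      }
    })
    grp <- tibble(
      taxon = unlist(lapply(names(groups), function(g)
        sprintf("%s%02d", substr(g, 1, 3), seq_len(groups[[g]])))),
      group = rep(names(groups), groups))
  }
  tree <- ape::read.tree(text = nwk)
  structure(list(tree = tree, groups = grp), class = "chs_species_tree")
}

strip_semicolon <- function(x) sub(";$", "", x)

# Random ultrametric newick over `labels` with root height `height`.
# Caller is responsible for seeding.
random_coalescent_newick <- function(labels, height) {
  n <- length(labels)
  if (n == 1) return(paste0(labels, ";"))
  hs <- c(if (n > 2) sort(runif(n - 2, 0, height)), height)
  sub <- labels
  top <- rep(0, n) # height of each active subtree's root
  for (h in hs) {
    pick <- sample.int(length(sub), 2)
    i <- min(pick); j <- max(pick)
    merged <- paste0("(", sub[i], ":", format(h - top[i], digits = 12), ",",
                     sub[j], ":", format(h - top[j], digits = 12), ")")
    sub <- c(sub[-c(i, j)], merged)
    top <- c(top[-c(i, j)], h)
  }
  paste0(sub, ";")
}

#' @export
print.chs_species_tree <- function(x, ...) {
  cat("Species tree with", length(x$tree$tip.label), "taxa in",
      length(unique(x$groups$group)), "group(s)\n")
  print(x$tree)
  invisible(x)
}

#' Event rates for gene-family evolution
#'
#' Container for the per-lineage rates of the birth-death-transfer process
#' used by [evolve_family()]. Rates are events per lineage per unit branch
#' length; `recombination_probability` is a per-family probability used by
#' the higher-level fixture generators.
#'
#' @param duplication,loss,hgt Non-negative rates.
#' @param recombination_probability Probability in \[0, 1\].
#' @return A list of class `chs_event_rates`.
#' @export
event_rates <- function(duplication = 0, loss = 0, hgt = 0,
                        recombination_probability = 0) {
  assert_that(all(c(duplication, loss, hgt) >= 0),
              "rates must be >= 0", class = "chsevol_invalid_argument")
  assert_that(recombination_probability >= 0 && recombination_probability <= 1,
              "recombination_probability must be in [0, 1]",
              class = "chsevol_invalid_argument")
  structure(list(duplication = duplication, loss = loss, hgt = hgt,
                 recombination_probability = recombination_probability),
            class = "chs_event_rates")
}
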