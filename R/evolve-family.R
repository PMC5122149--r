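#' Evolve a gene family along a species tree
#'
#' Simulates a birth-death-transfer process top-down along the branches of an
#' ultrametric species tree. A single gene enters the root; along every
#' branch each gene lineage experiences duplications (the lineage splits in
#' place), losses (the lineage dies) and horizontal transfers (a copy jumps
#' to another branch alive at the transfer time, while the donor lineage
#' continues — additive acquisition, as observed for bacterial recipients)
#' as a Poisson process with the given per-unit-length rates. At speciation
#' nodes every surviving lineage follows both descendant branches.
#'
#' Gene lineages keep their identifier through speciations; duplications and
#' transfers mint new identifiers. Extant genes are the lineages that reach a
#' leaf, labelled `taxon|geneid`. The returned gene tree has branch lengths
#' in the species tree's units, and the event log records every event with
#' the species branch (named by its child node: a tip label, or `nK` for
#' internal node K), the event time measured from the root, the parent
#' lineage and the lineage created (if any).
#'
#' `planted_hgt` forces transfers at chosen places in addition to (or instead
#' of) rate-sampled ones: a tibble with columns `time`, `donor_taxon`,
#' `recipient_taxon`. Each planted transfer is taken from the ancestral
#' lineage of `donor_taxon` alive at `time` into the ancestral branch of
#' `recipient_taxon` at that time, and is logged like any other event, so
#' ground truth stays consistent with the gene tree.
#'
#' @param species_tree A [sample_species_tree()] result or an ultrametric
#'   rooted `ape::phylo`.
#' @param rates An [event_rates()] object.
#' @param seed Integer seed.
#' @param planted_hgt Optional tibble of forced transfers (see Details).
#' @return A list of class `chs_gene_family` with elements `gene_tree`
#'   (`ape::phylo`, or `NULL` if fewer than 2 genes survive), `leaves`
#'   (character vector of extant gene labels), `log` (tibble: `kind`,
#'   `donor`, `recipient`, `time`, `gene_id`, `child_id`, ordered by time)
#'   and `species_tree`.
#' @examples
#' st <- sample_species_tree(6, depth = 1, seed = 1)
#' fam <- evolve_family(st, event_rates(duplication = 0.5, loss = 0.1), seed = 2)
#' @export
evolve_family <- function(species_tree, rates, seed, planted_hgt = NULL) {
  st <- as_species_tree(species_tree)
  phy <- st$tree
  assert_that(inherits(rates, "chs_event_rates"),
              "rates must come from event_rates()",
              class = "chsevol_invalid_argument")

  ntip <- length(phy$tip.label)
  nt <- ape::node.depth.edgelength(phy) # time of each node, root = 0
  root <- ntip + 1L
  kids <- children_list(phy)
  parent <- rep(NA_integer_, max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  node_name <- function(v) if (v <= ntip) phy$tip.label[v] else paste0("n", v)
  # resolve a taxon's ancestral branch alive at time t
  branch_at <- function(taxon, t) {
    v <- match(taxon, phy$tip.label)
    assert_that(!is.na(v), paste0("unknown taxon ", taxon),
                class = "chsevol_invalid_argument")
    while (!is.na(parent[v]) && nt[parent[v]] >= t) v <- parent[v]
    v
  }

  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$counter <- 0L
  if (!is.null(planted_hgt)) {
    planted_hgt <- as_tibble(planted_hgt)
    assert_that(all(c("time", "donor_taxon", "recipient_taxon") %in%
                      names(planted_hgt)),
                "planted_hgt needs columns time, donor_taxon, recipient_taxon",
                class = "chsevol_invalid_argument")
    env$planted <- planted_hgt |>
      mutate(donor_node = map_int(seq_len(nrow(planted_hgt)), function(i)
        branch_at(planted_hgt$donor_taxon[i], planted_hgt$time[i])),
        consumed = FALSE)
  } else {
    env$planted <- NULL
  }

  new_gene <- function() {
    env$counter <- env$counter + 1L
    paste0("g", env$counter)
  }
  log_event <- function(kind, donor, recipient, time, gene_id, child_id) {
    env$log[[length(env$log) + 1L]] <-
      list(kind = kind, donor = donor, recipient = recipient,
           time = time, gene_id = gene_id, child_id = child_id)
  }
  alive_branches <- function(t, exclude) {
    v <- seq_len(max(phy$edge))[-root]
    v <- v[nt[parent[v]] < t & t < nt[v]]
    setdiff(v, exclude)
  }

  total_rate <- rates$duplication + rates$loss + rates$hgt

  # simulate lineage `gid` on the branch into node v, from time t0;
  # returns a nested node list or NULL if the lineage leaves no descendants
  sim_edge <- function(gid, v, t0) {
    t_end <- nt[v]
    # next planted transfer on this branch?
    tp <- Inf; pi <- NA_integer_
    if (!is.null(env$planted)) {
      cand <- which(!env$planted$consumed & env$planted$donor_node == v &
                      env$planted$time > t0 & env$planted$time <= t_end)
      if (length(cand)) {
        pi <- cand[which.min(env$planted$time[cand])]
        tp <- env$planted$time[pi]
      }
    }
    te <- if (total_rate > 0) t0 + rexp(1, total_rate) else Inf
    if (te >= t_end && tp >= t_end) {
      if (v <= ntip) {
        return(list(leaf = paste0(phy$tip.label[v], "|", gid), time = t_end))
      }
      subs <- compact2(sim_edge(gid, kids[[v]][1], t_end),
                       sim_edge(gid, kids[[v]][2], t_end))
      return(join_node(subs, t_end))
    }
    if (tp < te) {
      env$planted$consumed[pi] <- TRUE
      r <- branch_at(env$planted$recipient_taxon[pi], tp)
      child <- new_gene()
      log_event("hgt", node_name(v), node_name(r), tp, gid, child)
      subs <- compact2(sim_edge(gid, v, tp), sim_edge(child, r, tp))
      return(join_node(subs, tp))
    }
    kind <- sample(c("duplication", "loss", "hgt"), 1,
                   prob = c(rates$duplication, rates$loss, rates$hgt))
    if (kind == "loss") {
      log_event("loss", node_name(v), NA_character_, te, gid, NA_character_)
      return(NULL)
    }
    if (kind == "duplication") {
      child <- new_gene()
      log_event("duplication", node_name(v), NA_character_, te, gid, child)
      subs <- compact2(sim_edge(gid, v, te), sim_edge(child, v, te))
      return(join_node(subs, te))
    }
    # hgt
    rec <- alive_branches(te, exclude = v)
    if (!length(rec)) { # nowhere to go: continue unchanged
      return(sim_edge(gid, v, te))
    }
    r <- rec[sample.int(length(rec), 1)]
    child <- new_gene()
    log_event("hgt", node_name(v), node_name(r), te, gid, child)
    subs <- compact2(sim_edge(gid, v, te), sim_edge(child, r, te))
    join_node(subs, te)
  }

  res <- local_seed(seed, {
    g1 <- new_gene()
    subs <- compact2(sim_edge(g1, kids[[root]][1], 0),
                     sim_edge(g1, kids[[root]][2], 0))
    join_node(subs, 0)
  })

  log <- if (length(env$log)) {
    bind_rows(lapply(env$log, as_tibble)) |> arrange(.data$time)
  } else {
    tibble(kind = character(), donor = character(), recipient = character(),
           time = double(), gene_id = character(), child_id = character())
  }

  leaves <- collect_leaves(res)
  gene_tree <- NULL
  if (length(leaves) >= 2) {
    gene_tree <- ape::read.tree(text = paste0(to_newick(res, 0), ";"))
  }
  structure(list(gene_tree = gene_tree, leaves = leaves, log = log,
                 species_tree = st),
            class = "chs_gene_family")
}

as_species_tree <- function(x) {
  if (inherits(x, "chs_species_tree")) return(x)
  if (inherits(x, "phylo")) {
    return(structure(list(tree = x,
                          groups = tibble(taxon = x$tip.label, group = "all")),
                     class = "chs_species_tree"))
  }
  abort("species_tree must be a chs_species_tree or phylo",
        class = c("chsevol_invalid_argument", "chsevol_error"))
}

children_list <- function(phy) {
  kids <- vector("list", max(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  }
  kids
}

compact2 <- function(a, b) Filter(Negate(is.null), list(a, b))

# Combine surviving child subtrees at an event/speciation time:
# 0 survivors -> NULL, 1 -> pass through (branch lengths merge naturally
# because lengths are recomputed from absolute times), 2 -> internal node.
join_node <- function(subs, time) {
  if (length(subs) == 0) return(NULL)
  if (length(subs) == 1) return(subs[[1]])
  list(time = time, children = subs)
}

collect_leaves <- function(node) {
  if (is.null(node)) return(character(0))
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, collect_leaves))
}

to_newick <- function(node, parent_time) {
  if (!is.null(node$leaf)) {
    return(paste0(node$leaf, ":", format(node$time - parent_time, digits = 12)))
  }
  inner <- paste(vapply(node$children, to_newick, character(1),
                        parent_time = node$time), collapse = ",")
  paste0("(", inner, "):", format(node$time - parent_time, digits = 12))
}

#' @export
print.chs_gene_family <- function(x, ...) {
  cat("Gene family:", length(x$leaves), "extant genes;",
      nrow(x$log), "events (",
      paste(names(table(x$log$kind)), table(x$log$kind), collapse = ", "),
      ")\n")
  invisible(x)
}
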