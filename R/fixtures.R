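#' Configuration for the standard simulated CHS family
#'
#' Defaults define the package's standard study conditions: 12 species in
#' two deeply diverged groups (six "fungi", six "bacteria"), tree depth 1.0
#' expected substitutions per site with the group split halfway, a
#' duplication-loss process sized to yield a few tens of genes, three
#' planted recent horizontal transfers from fungi into bacterial branches
#' (amelioration 0, i.e. the transferred coding sequences keep the donor
#' G+C), per-group G+C targets of 0.42 (fungi) and 0.58 (bacteria), a
#' conserved three-gene neighbourhood co-transferred with each focal gene,
#' and a distant outgroup sequence for rooting.
#'
#' @param groups Named vector of group sizes.
#' @param depth Species-tree depth (substitutions/site).
#' @param stem_fraction Fraction of depth below the group split.
#' @param duplication_rate,loss_rate,hgt_rate Per-lineage event rates for
#'   [evolve_family()] (`hgt_rate` is the *random* transfer rate; planted
#'   transfers are controlled by `n_hgt`).
#' @param n_hgt Number of planted transfers.
#' @param hgt_donor_group,hgt_recipient_group Groups for planted transfers.
#' @param hgt_time_range Transfer times (fraction of depth from the root).
#' @param amelioration Compositional amelioration of transferred genes
#'   (0 = fully donor-like, recent transfer).
#' @param gc_by_group Named G+C targets per group (an `out` entry covers
#'   the outgroup).
#' @param root_protein Root protein (must carry the planted motifs).
#' @param subst_rate,indel_rate Sequence-evolution rates.
#' @param outgroup,outgroup_depth Add a distant outgroup leaf for rooting,
#'   attached at the gene-tree root at this extra distance.
#' @param n_decay Number of genes whose catalytic motifs are degraded
#'   (dubious-candidate controls).
#' @param neighborhood_size Neighbour families recorded per focal gene.
#' @param pool_size Distinct background families per group.
#' @param context_length Length of the simulated host genomic context per
#'   gene (bp).
#' @param min_genes Minimum extant family size; smaller simulations are
#'   retried with a derived seed.
#' @return A list of class `chs_fixture_config`.
#' @export
fixture_config <- function(groups = c(fungi = 6, bacteria = 6),
                           depth = 1, stem_fraction = 0.5,
                           duplication_rate = 0.8, loss_rate = 0.1,
                           hgt_rate = 0, n_hgt = 3,
                           hgt_donor_group = "fungi",
                           hgt_recipient_group = "bacteria",
                           hgt_time_range = c(0.55, 0.9),
                           amelioration = 0,
                           gc_by_group = c(fungi = 0.42, bacteria = 0.58,
                                           out = 0.5),
                           root_protein = chs_root_protein(),
                           subst_rate = 1, indel_rate = 0.01,
                           outgroup = TRUE, outgroup_depth = 1.5,
                           n_decay = 0,
                           neighborhood_size = 6, pool_size = 20,
                           context_length = 6000,
                           min_genes = 8) {
  structure(as.list(environment()), class = "chs_fixture_config")
}

#' Simulate a complete CHS gene family with ground truth
#'
#' Runs the full generative model behind the package's validation: species
#' tree, duplication-loss(-transfer) gene-family evolution with planted
#' horizontal transfers, sequence evolution with immutable planted motifs,
#' codon back-translation with per-group G+C (transferred genes keep the
#' donor composition, moderated by `amelioration`), host genomic contexts,
#' and gene neighbourhoods with a conserved trio co-transferred between the
#' donor-side and recipient genomes of each transfer.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed; the whole simulation is reproducible.
#' @return A list of class `chs_simulation`: `species_tree`, `gene_tree`
#'   (including the outgroup leaf when configured), `genes` (tibble:
#'   `gene_id`, `taxon`, `group`, `protein`, `cds`, `is_hgt`, `hgt_event`,
#'   `motif_decayed`), `alignment`, `log`, `neighborhoods`, `contexts`
#'   (named character), `taxon_groups`, `config`, `seed`.
#' @export
simulate_chs_family <- function(config = fixture_config(), seed) {
  cfg <- config
  assert_that(inherits(cfg, "chs_fixture_config"),
              "config must come from fixture_config()")
  # retry with derived seeds until the family is large enough (deterministic)
  for (attempt in 0:24) {
    s <- derive_seed(seed, attempt * 101)
    st <- sample_species_tree(depth = cfg$depth, seed = derive_seed(s, 1),
                              groups = cfg$groups,
                              stem_fraction = cfg$stem_fraction)
    planted <- plan_hgt_events(cfg, st, derive_seed(s, 2))
    fam <- evolve_family(st, event_rates(cfg$duplication_rate, cfg$loss_rate,
                                         cfg$hgt_rate),
                         seed = derive_seed(s, 3), planted_hgt = planted)
    origins <- hgt_leaf_origins(fam)
    hgt_children <- fam$log$child_id[fam$log$kind == "hgt"]
    planted_ok <- length(hgt_children) >= cfg$n_hgt &&
      all(hgt_children %in% origins)
    if (cfg$n_hgt == 0) planted_ok <- TRUE
    if (!is.null(fam$gene_tree) &&
        length(fam$leaves) >= cfg$min_genes && planted_ok) break
  }
  assert_that(!is.null(fam$gene_tree) && length(fam$leaves) >= cfg$min_genes,
              "simulation failed to produce a sufficiently large family")

  gene_tree <- fam$gene_tree
  taxon_groups <- setNames(st$groups$group, st$groups$taxon)
  if (isTRUE(cfg$outgroup)) {
    nwk <- strip_semicolon(ape::write.tree(gene_tree))
    gene_tree <- ape::read.tree(text = paste0(
      "(", nwk, ":0,out|og1:", format(cfg$outgroup_depth, digits = 12), ");"))
    taxon_groups <- c(taxon_groups, out = "out")
  }

  seqs <- evolve_sequences(gene_tree, cfg$root_protein,
                           subst_rate = cfg$subst_rate,
                           indel_rate = cfg$indel_rate,
                           seed = derive_seed(s, 4),
                           taxon_groups = taxon_groups,
                           gc_by_group = cfg$gc_by_group)
  genes <- seqs$genes |>
    mutate(group = unname(taxon_groups[.data$taxon]))

  # ground-truth transfer annotation: a gene is transferred if its lineage
  # id descends (through later duplications) from an hgt child lineage
  hgt_children <- fam$log$child_id[fam$log$kind == "hgt"]
  parent_of <- setNames(fam$log$gene_id[!is.na(fam$log$child_id)],
                        fam$log$child_id[!is.na(fam$log$child_id)])
  hgt_of <- function(gid) {
    while (!is.na(gid)) {
      if (gid %in% hgt_children) return(gid)
      gid <- if (gid %in% names(parent_of)) parent_of[[gid]] else NA_character_
    }
    NA_character_
  }
  genes <- genes |>
    mutate(hgt_origin = map_chr(leaf_gene(.data$gene_id), hgt_of),
           is_hgt = !is.na(.data$hgt_origin),
           hgt_event = match(.data$hgt_origin,
                             fam$log$child_id[fam$log$kind == "hgt"])) |>
    select(-"hgt_origin")

  # transferred genes keep the donor composition (tempered by amelioration)
  donor_gc <- cfg$gc_by_group[[cfg$hgt_donor_group]]
  for (i in which(genes$is_hgt)) {
    host_gc <- cfg$gc_by_group[[genes$group[i]]]
    genes$cds[i] <- apply_composition_shift(
      list(cds = genes$cds[i]), donor_gc = donor_gc,
      amelioration = cfg$amelioration, host_gc = host_gc,
      seed = derive_seed(s, 50 + i))$cds
  }

  # dubious-candidate controls
  genes$motif_decayed <- FALSE
  if (cfg$n_decay > 0) {
    eligible <- which(genes$taxon != "out")
    pick <- local_seed(derive_seed(s, 5),
                       sample(eligible, min(cfg$n_decay, length(eligible))))
    genes$protein[pick] <- vapply(genes$protein[pick], decay_motifs,
                                  character(1), USE.NAMES = FALSE)
    genes$motif_decayed[pick] <- TRUE
  }

  nb <- simulate_neighborhoods(genes, fam, st, cfg, derive_seed(s, 6))

  contexts <- setNames(vapply(seq_len(nrow(genes)), function(i) {
    if (is.na(genes$cds[i])) return(NA_character_)
    simulate_genome_context(cfg$context_length,
                            cfg$gc_by_group[[genes$group[i]]],
                            derive_seed(s, 100 + i))
  }, character(1)), genes$gene_id)
  contexts <- contexts[!is.na(contexts)]

  structure(list(species_tree = st, gene_tree = gene_tree, genes = genes,
                 alignment = seqs$alignment, log = fam$log,
                 neighborhoods = nb, contexts = contexts,
                 taxon_groups = taxon_groups, config = cfg, seed = seed),
            class = "chs_simulation")
}

# choose donor/recipient taxa and times for the planted transfers
plan_hgt_events <- function(cfg, st, seed) {
  if (cfg$n_hgt == 0) return(NULL)
  donors <- st$groups$taxon[st$groups$group == cfg$hgt_donor_group]
  recips <- st$groups$taxon[st$groups$group == cfg$hgt_recipient_group]
  assert_that(length(donors) >= 1 && length(recips) >= 1,
              "donor/recipient groups missing from the species tree")
  # distinct donors and recipients when group sizes allow: transfers then
  # involve different lineages and leave independent incongruence signals
  local_seed(seed, tibble(
    time = runif(cfg$n_hgt, cfg$hgt_time_range[1] * cfg$depth,
                 cfg$hgt_time_range[2] * cfg$depth),
    donor_taxon = sample(rep_len(sample(donors), cfg$n_hgt)),
    recipient_taxon = sample(rep_len(sample(recips), cfg$n_hgt))))
}

# For every extant leaf, the hgt child-lineage it descends from (NA if
# vertically inherited); used both for ground truth and retry checks.
hgt_leaf_origins <- function(fam) {
  hgt_children <- fam$log$child_id[fam$log$kind == "hgt"]
  if (!length(fam$leaves)) return(character(0))
  parent_of <- setNames(fam$log$gene_id[!is.na(fam$log$child_id)],
                        fam$log$child_id[!is.na(fam$log$child_id)])
  vapply(leaf_gene(fam$leaves), function(gid) {
    while (!is.na(gid)) {
      if (gid %in% hgt_children) return(gid)
      gid <- if (gid %in% names(parent_of)) parent_of[[gid]] else NA_character_
    }
    NA_character_
  }, character(1))
}

# Background neighbourhoods from group-specific family pools, plus a
# conserved per-event trio shared between each transfer's recipient genome
# and an extant genome descending from the donor branch.
simulate_neighborhoods <- function(genes, fam, st, cfg, seed) {
  local_seed(seed, {
    pools <- lapply(unique(genes$group), function(g)
      sprintf("%s_fam%02d", substr(g, 1, 3), seq_len(cfg$pool_size)))
    names(pools) <- unique(genes$group)
    rows <- list()
    nb_of <- list()
    for (i in seq_len(nrow(genes))) {
      if (genes$taxon[i] == "out") next
      fams <- sample(pools[[genes$group[i]]], cfg$neighborhood_size)
      nb_of[[genes$gene_id[i]]] <- fams
    }
    # conserved trio per transfer event
    hgt_rows <- fam$log[fam$log$kind == "hgt", , drop = FALSE]
    phy <- st$tree
    used_partners <- character(0)
    for (k in seq_len(nrow(hgt_rows))) {
      trio <- sprintf(c("DUF1800.e%d", "DUF1501.e%d", "SE.e%d"), k)
      recip_leaves <- genes$gene_id[!is.na(genes$hgt_event) &
                                      genes$hgt_event == k]
      if (!length(recip_leaves)) next
      for (gid in recip_leaves) {
        host <- sample(pools[[genes$group[genes$gene_id == gid][1]]],
                       cfg$neighborhood_size - 3)
        nb_of[[gid]] <- c(trio, host)
      }
      # extant partner genome on the donor side (one per event)
      donor_lab <- hgt_rows$donor[k]
      donor_node <- if (grepl("^n[0-9]+$", donor_lab)) {
        as.integer(sub("^n", "", donor_lab))
      } else match(donor_lab, phy$tip.label)
      donor_taxa <- tips_under_nodes(phy)[[donor_node]]
      partner_genes <- setdiff(
        genes$gene_id[genes$taxon %in% donor_taxa & !genes$is_hgt],
        used_partners)
      if (length(partner_genes)) {
        pg <- sample1(partner_genes)
        used_partners <- c(used_partners, pg)
        nb_of[[pg]] <- c(trio, nb_of[[pg]][-(1:3)])
      }
    }
    for (gid in names(nb_of)) {
      fams <- nb_of[[gid]]
      rows[[gid]] <- tibble(
        genome = genes$taxon[genes$gene_id == gid][1],
        gene_id = gid,
        position_index = seq_along(fams) - 1L,
        family_label = fams,
        strand = ifelse(grepl("^(DUF|SE)", fams), "+",
                        sample(c("+", "-"), length(fams), replace = TRUE)))
    }
    bind_rows(rows)
  })
}

#' @export
print.chs_simulation <- function(x, ...) {
  cat("Simulated CHS family:", nrow(x$genes), "genes in",
      length(unique(x$genes$taxon)), "taxa;",
      sum(x$genes$is_hgt), "transferred,",
      sum(x$genes$motif_decayed), "motif-decayed\n")
  invisible(x)
}

#' Write a simulation to disk as a plain-text fixture
#'
#' Emits the complete fixture: unaligned protein and coding-sequence FASTA,
#' the true alignment, species and gene trees (newick), the event log, the
#' neighbourhood table, the taxon map and the host genomic contexts. All
#' output is byte-identical across runs with the same config and seed.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `files` (named paths) and `simulation`.
#' @export
emit_fixture <- function(config = fixture_config(), seed, out_dir) {
  sim <- simulate_chs_family(config, seed)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    assert_that(dir.exists(out_dir), paste0("cannot create ", out_dir),
                class = "chsevol_io_error")
  }
  p <- function(f) file.path(out_dir, f)
  files <- c(proteins = p("proteins.fasta"), cds = p("cds.fasta"),
             alignment = p("true_alignment.fasta"),
             species_tree = p("species_tree.nwk"),
             gene_tree = p("gene_tree.nwk"),
             events = p("events.tsv"),
             neighborhoods = p("neighborhoods.tsv"),
             taxon_map = p("taxon_map.tsv"),
             contexts = p("contexts.fasta"))
  write_fasta(setNames(sim$genes$protein, sim$genes$gene_id),
              files[["proteins"]])
  with_cds <- !is.na(sim$genes$cds)
  write_fasta(setNames(sim$genes$cds[with_cds],
                       sim$genes$gene_id[with_cds]), files[["cds"]])
  write_alignment(sim$alignment, files[["alignment"]])
  write_newick(sim$species_tree$tree, files[["species_tree"]])
  write_newick(sim$gene_tree, files[["gene_tree"]])
  write_tsv_plain(sim$log, files[["events"]])
  write_tsv_plain(sim$neighborhoods, files[["neighborhoods"]])
  write_tsv_plain(tibble(seq_id = sim$genes$gene_id,
                         taxon = sim$genes$taxon,
                         group = sim$genes$group), files[["taxon_map"]])
  write_fasta(sim$contexts, files[["contexts"]])
  invisible(list(files = files, simulation = sim))
}

#' Simulate planted sequence classes for classification tests
#'
#' Builds a gene tree of `n_classes` deeply diverged monophyletic classes
#' (each an independent random ultrametric subtree over `n_taxa` taxa, of
#' height `within_depth`, joined by long stems so between-class divergence
#' is at least `between_depth`), evolves sequences along it, and returns
#' the alignment with the ground-truth class membership.
#'
#' @param n_taxa Taxa per class.
#' @param n_classes Number of classes (>= 2).
#' @param within_depth Class subtree height (substitutions/site).
#' @param between_depth Minimum leaf-to-leaf path between classes.
#' @param subst_rate Substitution rate multiplier.
#' @param root_protein Root protein.
#' @param seed Integer seed.
#' @return List: `gene_tree`, `alignment`, `genes`, `classes` (named list
#'   class -> member labels).
#' @export
simulate_class_family <- function(n_taxa = 12, n_classes = 3,
                                  within_depth = 0.05, between_depth = 0.4,
                                  subst_rate = 1,
                                  root_protein = chs_root_protein(),
                                  seed) {
  assert_that(n_classes >= 2, "need >= 2 classes",
              class = "chsevol_invalid_argument")
  stem <- between_depth / 2
  class_names <- LETTERS[seq_len(n_classes)]
  nwk <- local_seed(derive_seed(seed, 1), {
    subs <- vapply(seq_len(n_classes), function(k) {
      labels <- sprintf("t%02d|%s", seq_len(n_taxa), class_names[k])
      paste0(strip_semicolon(random_coalescent_newick(labels, within_depth)),
             ":", format(stem, digits = 12))
    }, character(1))
    out <- paste0("(", subs[1], ",", subs[2], ")")
    for (k in seq_len(n_classes)[-(1:2)]) {
      out <- paste0("(", out, ":0,", subs[k], ")")
    }
    paste0(out, ";")
  })
  gene_tree <- ape::read.tree(text = nwk)
  seqs <- evolve_sequences(gene_tree, root_protein, subst_rate = subst_rate,
                           indel_rate = 0, seed = derive_seed(seed, 2))
  classes <- lapply(setNames(class_names, class_names), function(cl)
    gene_tree$tip.label[endsWith(gene_tree$tip.label, paste0("|", cl))])
  list(gene_tree = gene_tree, alignment = seqs$alignment,
       genes = seqs$genes, classes = classes)
}

#' Simulate chimeric queries with reference families
#'
#' Evolves two deeply diverged families (`A`, CHS-like, and `B`, HAS-like),
#' then builds chimeric queries by fusing the N-terminal part of a `B`
#' member with the C-terminal part of an `A` member at the `QXXXY` motif
#' (via [make_recombinant()]), lightly mutating the fusion. The fusion
#' inserts a second motif copy, so references receive a matching gap block
#' in the combined alignment and homology is exact. Controls are `A`
#' members not used as references.
#'
#' @param n_refs Reference sequences per family.
#' @param n_controls Control (non-chimeric) queries.
#' @param n_chimeras Chimeric queries.
#' @param within_depth,between_depth Family divergence parameters.
#' @param extra_mutations Substitutions added to each chimera after fusion.
#' @param root_protein Root protein.
#' @param seed Integer seed.
#' @return List: `alignment` (references + all queries),
#'   `reference_groups` (named vector id -> `"A"`/`"B"`), `queries`
#'   (tibble: `seq_id`, `is_chimera`), `breakpoint_motif`.
#' @export
simulate_chimera_set <- function(n_refs = 8, n_controls = 10,
                                 n_chimeras = 10, within_depth = 0.05,
                                 between_depth = 0.8, extra_mutations = 3,
                                 root_protein = chs_root_protein(), seed) {
  fam <- simulate_class_family(n_taxa = n_refs + n_controls, n_classes = 2,
                               within_depth = within_depth,
                               between_depth = between_depth,
                               root_protein = root_protein,
                               seed = derive_seed(seed, 1))
  a_leaves <- fam$classes$A
  b_leaves <- fam$classes$B
  refs_a <- a_leaves[seq_len(n_refs)]
  refs_b <- b_leaves[seq_len(n_refs)]
  controls <- setdiff(a_leaves, refs_a)[seq_len(n_controls)]
  aln <- fam$alignment # indel-free: alignment positions == sequence positions
  L <- ncol(aln)
  motif <- motif_definition("QXXXY", "QXXXY")
  q5 <- detect_motif_duplication(root_protein, motif)[1]
  n_end <- q5 + 4L
  # The duplicated-motif diagnostic presupposes that QXXXY is rare: the
  # planted copy is the only one in a non-recombinant sequence. Random
  # drift occasionally creates spurious matches (sometimes inherited by a
  # whole class); the generator removes them so the fixture carries the
  # motif uniqueness the breakpoint rule relies on.
  aln <- local_seed(derive_seed(seed, 9), {
    for (r in seq_len(nrow(aln))) {
      repeat {
        hits <- motif_starts(paste(aln[r, ], collapse = ""),
                             motif_regex(motif))
        hits <- setdiff(hits, q5)
        if (!length(hits)) break
        aln[r, hits] <- sample(setdiff(AA_ALPHABET, "Q"), length(hits),
                               replace = TRUE)
      }
    }
    aln
  })
  # references and controls get a gap block where chimeras carry the
  # second motif copy
  pad <- function(row) c(row[1:n_end], rep(GAP_CHAR, 5), row[(n_end + 1):L])
  rows <- t(apply(aln, 1, pad))
  rownames(rows) <- rownames(aln)
  # N-terminal parents must carry the planted motif as their first QXXXY
  # copy, so the duplicated-motif diagnostic locates the true junction
  clean_b <- refs_b[vapply(refs_b, function(id) {
    pre <- motif_starts(paste(aln[id, ], collapse = ""), motif_regex(motif))
    all(pre >= q5)
  }, logical(1))]
  if (!length(clean_b)) clean_b <- refs_b
  chim_rows <- local_seed(derive_seed(seed, 2), {
    lapply(seq_len(n_chimeras), function(i) {
      src_b <- sample1(clean_b) # N-terminal ancestry: HAS-like
      src_a <- sample1(refs_a)  # C-terminal ancestry: CHS-like
      # fusion at the planted motif: N-part through the motif copy of the
      # B parent, C-part from the motif copy of the A parent (both copies
      # retained, as in make_recombinant)
      cc <- c(aln[src_b, 1:n_end], aln[src_a, q5:L])
      protected <- q5:(q5 + 9) # both motif copies
      idx <- sample(setdiff(seq_along(cc), protected), extra_mutations)
      for (p_ in idx) cc[p_] <- sample1(setdiff(AA_ALPHABET, cc[p_]))
      cc
    })
  })
  chim_ids <- sprintf("chimera%02d", seq_len(n_chimeras))
  chim_mat <- do.call(rbind, chim_rows)
  rownames(chim_mat) <- chim_ids
  full <- rbind(rows, chim_mat)
  list(alignment = full,
       reference_groups = setNames(rep(c("A", "B"), each = n_refs),
                                   c(refs_a, refs_b)),
       queries = tibble(seq_id = c(chim_ids, controls),
                        is_chimera = rep(c(TRUE, FALSE),
                                         c(n_chimeras, n_controls))),
       breakpoint_motif = motif)
}
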