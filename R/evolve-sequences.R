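#' Evolve protein sequences along a gene tree
#'
#' Evolves the root protein down a gene tree under a uniform-rate Poisson
#' replacement process: each site accumulates `Poisson(subst_rate * branch)`
#' replacement events, each replacing the residue with one of the 19 other
#' amino acids uniformly at random. No rate matrix and no across-site rate
#' heterogeneity are used, which keeps the expected p-distance between two
#' leaves at total path length `d` in closed form:
#' `p = (19/20) * (1 - exp(-(20/19) * subst_rate * d))`.
#'
#' The root protein must carry the planted CHS motif set — three catalytic
#' aspartates (D), one `QXXRW` and one `QXXXY` — and those anchor positions
#' are immutable (no substitution, no deletion, no insertion inside a motif
#' span) unless `motif_decay = TRUE`, so descendant proteins are guaranteed
#' to pass the catalytic-motif filter. Indels are single-column insertions
#' and deletions; true homology columns are tracked throughout, so the true
#' alignment is returned alongside the leaf sequences.
#'
#' Coding sequences are generated by codon back-translation under the
#' standard genetic code, with the synonymous-codon choice calibrated so the
#' expected G+C content matches a per-taxon-group target (see
#' [back_translate()]).
#'
#' @param gene_tree `ape::phylo` with branch lengths; leaf labels either
#'   plain taxon names or `taxon|geneid`.
#' @param root_protein Amino-acid string containing the planted motifs.
#' @param subst_rate Substitutions per site per unit branch length.
#' @param indel_rate Indel events per site per unit branch length.
#' @param seed Integer seed.
#' @param taxon_groups Named character vector taxon -> group (used to pick
#'   the G+C target); unknown taxa fall back to the first `gc_by_group` entry.
#' @param gc_by_group Named numeric vector group -> target G+C in \[0, 1\];
#'   `NULL` disables coding-sequence generation.
#' @param motif_decay If `TRUE`, motif anchors are mutable like any other
#'   site (used to generate "dubious" negative controls).
#' @return A list with `genes` (tibble: `gene_id`, `taxon`, `protein`,
#'   `cds`) and `alignment` (true-alignment character matrix, gap `"-"`).
#' @examples
#' st <- sample_species_tree(4, depth = 0.3, seed = 1)
#' prot <- chs_root_protein(seed = 5)
#' out <- evolve_sequences(st$tree, prot, subst_rate = 1, indel_rate = 0,
#'                         seed = 2)
#' @export
evolve_sequences <- function(gene_tree, root_protein, subst_rate = 1,
                             indel_rate = 0, seed, taxon_groups = NULL,
                             gc_by_group = NULL, motif_decay = FALSE) {
  assert_that(inherits(gene_tree, "phylo"), "gene_tree must be a phylo")
  anchors <- planted_motif_anchors(root_protein)
  assert_that(!is.null(anchors),
              "root_protein must contain the planted motifs (D, D, D, QXXRW, QXXXY)",
              class = "chsevol_invalid_argument")

  root_chars <- chars(root_protein)
  n0 <- length(root_chars)
  # keys: real-valued column identities; span: motif-span id per key (NA none)
  span <- rep(NA_integer_, n0)
  if (!motif_decay) {
    for (i in seq_along(anchors$spans)) span[anchors$spans[[i]]] <- i
  }
  root_state <- list(keys = as.numeric(seq_len(n0)), aa = root_chars,
                     span = span)

  phy <- stats::reorder(gene_tree, "cladewise")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L

  leaf_states <- local_seed(seed, {
    states <- vector("list", max(phy$edge))
    states[[root]] <- root_state
    out <- vector("list", ntip)
    for (i in seq_len(nrow(phy$edge))) {
      a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
      st <- mutate_state(states[[a]], phy$edge.length[i], subst_rate,
                         indel_rate)
      if (b <= ntip) out[[b]] <- st else states[[b]] <- st
    }
    out
  })
  names(leaf_states) <- phy$tip.label

  all_keys <- sort(unique(unlist(lapply(leaf_states, `[[`, "keys"))))
  aln <- matrix(GAP_CHAR, nrow = ntip, ncol = length(all_keys),
                dimnames = list(phy$tip.label, NULL))
  for (nm in phy$tip.label) {
    st <- leaf_states[[nm]]
    aln[nm, match(st$keys, all_keys)] <- st$aa
  }

  genes <- tibble(
    gene_id = phy$tip.label,
    taxon = leaf_taxon(phy$tip.label),
    protein = unname(vapply(leaf_states, function(s)
      paste(s$aa, collapse = ""), character(1)))
  )
  if (!is.null(gc_by_group)) {
    grp <- if (is.null(taxon_groups)) rep(names(gc_by_group)[1], nrow(genes))
           else unname(taxon_groups[genes$taxon])
    grp[is.na(grp)] <- names(gc_by_group)[1]
    genes$cds <- vapply(seq_len(nrow(genes)), function(i)
      back_translate(genes$protein[i], gc_target = gc_by_group[[grp[i]]],
                     seed = derive_seed(seed, i)), character(1))
  } else {
    genes$cds <- NA_character_
  }
  list(genes = genes, alignment = aln)
}

# One branch of sequence evolution on a (keys, aa, span) state.
# Caller is responsible for seeding.
mutate_state <- function(state, len, subst_rate, indel_rate) {
  keys <- state$keys; aa <- state$aa; span <- state$span
  n <- length(keys)
  mutable <- is.na(span)
  # substitutions: per-site Poisson, sequential jumps to a random other aa
  k <- rpois(n, subst_rate * len)
  k[!mutable] <- 0L
  for (i in which(k > 0)) {
    cur <- aa[i]
    for (j in seq_len(k[i])) cur <- sample(setdiff(AA_ALPHABET, cur), 1)
    aa[i] <- cur
  }
  # indels: single-column events
  n_ev <- rpois(1, indel_rate * len * n)
  for (e in seq_len(n_ev)) {
    n <- length(keys)
    if (runif(1) < 0.5 && any(is.na(span))) { # deletion
      i <- sample1(which(is.na(span)))
      keys <- keys[-i]; aa <- aa[-i]; span <- span[-i]
    } else { # insertion at a slot not strictly inside a motif span
      inside <- if (n > 1) {
        !is.na(span[-n]) & !is.na(span[-1]) & span[-n] == span[-1]
      } else logical(0)
      # slot s = insert before existing position s; s = n+1 appends
      slots <- c(TRUE, !inside, TRUE)
      slot <- sample1(which(slots))
      newkey <- if (slot == 1) keys[1] - 1
                else if (slot == n + 1) keys[n] + 1
                else runif(1, keys[slot - 1], keys[slot])
      keys <- append(keys, newkey, after = slot - 1)
      aa <- append(aa, sample(AA_ALPHABET, 1), after = slot - 1)
      span <- append(span, NA_integer_, after = slot - 1)
    }
  }
  list(keys = keys, aa = aa, span = span)
}

# Locate the planted motifs in a root protein; NULL if incomplete.
# Spans are 1-based index vectors of protected positions.
planted_motif_anchors <- function(protein) {
  rep_cat <- find_catalytic_motifs(protein)
  if (!rep_cat$complete) return(NULL)
  q5 <- detect_motif_duplication(protein, motif_definition("QXXXY", "QXXXY"))
  if (length(q5) < 1) return(NULL)
  d <- rep_cat$assignment[1:3]
  qrw <- rep_cat$assignment[4]
  list(spans = list(d[1], d[2], d[3], qrw:(qrw + 4), q5[1]:(q5[1] + 4)))
}

#' Default CHS-like root protein for simulations
#'
#' Builds a deterministic random protein of the given length with the
#' canonical planted motif layout: catalytic aspartates at positions 30, 60
#' and 90, the `QXXRW` motif at 120 and a single `QXXXY` at 160 (1-based).
#' Residues elsewhere are drawn uniformly from the 20 amino acids; accidental
#' extra `QXXRW`/`QXXXY` matches are resolved by resampling, so the planted
#' copies are the only ones.
#'
#' @param length Protein length (>= 170).
#' @param seed Integer seed.
#' @return An amino-acid string.
#' @export
chs_root_protein <- function(length = 260, seed = 101) {
  assert_that(length >= 170, "length must be >= 170")
  local_seed(seed, {
    aa <- sample(AA_ALPHABET, length, replace = TRUE)
    aa[c(30, 60, 90)] <- "D"
    aa[120:124] <- c("Q", "T", "L", "R", "W")
    aa[160:164] <- c("Q", "V", "L", "N", "Y")
    prot <- paste(aa, collapse = "")
    # resample any accidental extra motif matches
    repeat {
      qrw <- motif_starts(prot, "Q..RW")
      q5 <- motif_starts(prot, "Q...Y")
      extra <- c(setdiff(qrw, 120), setdiff(q5, 160))
      if (!length(extra)) break
      for (p in extra) {
        aa[p] <- sample(setdiff(AA_ALPHABET, c("Q", aa[p])), 1)
      }
      prot <- paste(aa, collapse = "")
    }
    prot
  })
}

# All (possibly overlapping) 1-based match starts of a regex.
motif_starts <- function(x, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Degrade the catalytic motifs of a protein
#'
#' Produces a "dubious" variant of a simulated CHS protein by destroying
#' every `QXXRW` occurrence (the tryptophan is replaced by leucine), so the
#' catalytic-motif filter no longer finds a complete motif set. Used to
#' generate negative controls for the candidate screen.
#'
#' @param protein Amino-acid string.
#' @return The decayed protein string.
#' @export
decay_motifs <- function(protein) {
  aa <- chars(protein)
  repeat {
    hits <- motif_starts(paste(aa, collapse = ""), "Q..RW")
    if (!length(hits)) break
    aa[hits + 4L] <- "L"
  }
  paste(aa, collapse = "")
}

#' Back-translate a protein with a target G+C content
#'
#' Chooses synonymous codons under the standard genetic code so that the
#' expected G+C fraction of the coding sequence equals `gc_target`. Each
#' codon is sampled with weight `theta^g * (1 - theta)^(3 - g)` (where `g`
#' is the codon's G+C count) and `theta` is solved by bisection; targets
#' outside the achievable range for the given protein composition are
#' clamped to the nearest achievable value.
#'
#' @param protein Amino-acid string.
#' @param gc_target Desired G+C fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, gc_target, seed) {
  aa <- chars(protein)
  tab <- codon_table()
  assert_that(all(aa %in% names(tab)),
              "protein contains letters outside the 20-residue alphabet",
              class = "chsevol_invalid_argument")
  theta <- solve_theta(aa, gc_target, tab)
  local_seed(seed, {
    codons <- vapply(aa, function(a) {
      cs <- tab[[a]]
      w <- theta^cs$gc * (1 - theta)^(3 - cs$gc)
      cs$codon[sample.int(length(cs$codon), 1, prob = w)]
    }, character(1))
    paste(codons, collapse = "")
  })
}

# codon -> aa table from the standard genetic code, grouped by amino acid
codon_table <- function() {
  if (!is.null(chsevol_cache$codon_table)) return(chsevol_cache$codon_table)
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  tab <- lapply(split(names(gc), unname(gc)), function(cs) {
    list(codon = cs,
         gc = vapply(strsplit(cs, ""), function(b) sum(b %in% c("G", "C")),
                     numeric(1)))
  })
  chsevol_cache$codon_table <- tab
  tab
}
chsevol_cache <- new.env(parent = emptyenv())

expected_gc <- function(aa_counts, theta, tab) {
  num <- 0
  for (a in names(aa_counts)) {
    cs <- tab[[a]]
    w <- theta^cs$gc * (1 - theta)^(3 - cs$gc)
    num <- num + aa_counts[[a]] * sum(w * cs$gc) / sum(w)
  }
  num / (3 * sum(unlist(aa_counts)))
}

solve_theta <- function(aa, gc_target, tab) {
  counts <- as.list(table(aa))
  lo <- 1e-9; hi <- 1 - 1e-9
  g_lo <- expected_gc(counts, lo, tab)
  g_hi <- expected_gc(counts, hi, tab)
  if (gc_target <= g_lo) return(lo)
  if (gc_target >= g_hi) return(hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_gc(counts, mid, tab) < gc_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Shift the G+C composition of a coding sequence
#'
#' Models the compositional signature of a horizontal transfer: synonymous
#' codon positions are resampled so the expected coding-sequence G+C becomes
#' the amelioration mixture
#' `donor_gc * (1 - amelioration) + host_gc * amelioration`.
#' The encoded protein is untouched (the edit is strictly synonymous). A
#' freshly transferred gene (`amelioration = 0`) keeps the donor's
#' composition; an anciently transferred one (`amelioration` near 1) has
#' drifted to the host's.
#'
#' @param gene A one-row tibble (or list) with at least `protein` and `cds`.
#' @param donor_gc,host_gc G+C fractions in \[0, 1\].
#' @param amelioration Mixing fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return The gene with its `cds` replaced (same type as the input).
#' @export
apply_composition_shift <- function(gene, donor_gc, amelioration, host_gc,
                                    seed) {
  cds <- if (is.data.frame(gene)) gene$cds[[1]] else gene$cds
  assert_that(is_string(cds) && !is.na(cds) && nchar(cds) > 0,
              "gene has no cds", class = "chsevol_invalid_argument")
  assert_that(amelioration >= 0 && amelioration <= 1,
              "amelioration must be in [0, 1]",
              class = "chsevol_invalid_argument")
  target <- donor_gc * (1 - amelioration) + host_gc * amelioration
  protein <- translate_cds(cds)
  new_cds <- back_translate(protein, target, seed)
  if (is.data.frame(gene)) gene$cds[[1]] <- new_cds else gene$cds <- new_cds
  gene
}

#' Translate a coding sequence (standard genetic code)
#' @param cds Nucleotide string, length divisible by 3, no stop codons.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Fuse two proteins into a chimera at a shared motif
#'
#' Builds a recombinant (recCHS-like) protein: the N-terminal part of
#' `gene_n` up to and including its first occurrence of the breakpoint
#' motif, followed by the C-terminal part of `gene_c` from its first motif
#' occurrence onwards. Both motif copies are retained, so the fusion carries
#' a tandem motif duplication — the diagnostic signature the chimera scanner
#' looks for. Coding sequences, when both inputs have one, are fused at the
#' corresponding codons.
#'
#' @param gene_n,gene_c One-row tibbles (or lists) with `protein` and
#'   optionally `cds`.
#' @param breakpoint_motif A [motif_definition()] (default `QXXXY`).
#' @return A one-row tibble: `gene_id`, `taxon`, `protein`, `cds`,
#'   `is_recombinant = TRUE`.
#' @export
make_recombinant <- function(gene_n, gene_c,
                             breakpoint_motif = motif_definition("QXXXY", "QXXXY")) {
  gn <- as_gene_row(gene_n); gc_ <- as_gene_row(gene_c)
  pat <- motif_regex(breakpoint_motif)
  hn <- motif_starts(gn$protein, pat)
  hc <- motif_starts(gc_$protein, pat)
  assert_that(length(hn) >= 1 && length(hc) >= 1,
              paste0("breakpoint motif ", breakpoint_motif$pattern,
                     " absent from an input protein"),
              class = "chsevol_invalid_argument")
  w <- nchar(breakpoint_motif$pattern)
  n_end <- hn[1] + w - 1L         # keep gene_n through its motif copy
  c_start <- hc[1]                # keep gene_c from its motif copy onward
  protein <- paste0(substr(gn$protein, 1, n_end),
                    substr(gc_$protein, c_start, nchar(gc_$protein)))
  cds <- NA_character_
  if (is_string(gn$cds) && !is.na(gn$cds) &&
      is_string(gc_$cds) && !is.na(gc_$cds)) {
    cds <- paste0(substr(gn$cds, 1, 3 * n_end),
                  substr(gc_$cds, 3 * (c_start - 1) + 1, nchar(gc_$cds)))
  }
  tibble(gene_id = paste0(gn$gene_id %||% "recN", "x", gc_$gene_id %||% "recC"),
         taxon = gn$taxon %||% NA_character_,
         protein = protein, cds = cds, is_recombinant = TRUE)
}

as_gene_row <- function(g) {
  if (is.data.frame(g)) {
    assert_that(nrow(g) == 1, "expected a single gene (one-row tibble)")
    as.list(g)
  } else if (is.list(g)) g
  else if (is_string(g)) list(protein = g, cds = NA_character_)
  else abort("gene must be a one-row tibble, list, or protein string",
             class = c("chsevol_invalid_argument", "chsevol_error"))
}

#' Simulate a genomic background sequence
#'
#' Random nucleotide sequence with independent positions at a given G+C
#' fraction; used as the host genomic context around simulated genes for
#' composition-anomaly analysis.
#'
#' @param length Sequence length.
#' @param gc Target G+C fraction.
#' @param seed Integer seed.
#' @return A nucleotide string.
#' @export
simulate_genome_context <- function(length, gc, seed) {
  local_seed(seed, {
    paste(sample(c("G", "C", "A", "T"), length, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
          collapse = "")
  })
}
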