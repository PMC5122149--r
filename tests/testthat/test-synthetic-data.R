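# Gene-family evolution simulator: species trees, the
# duplication/loss/transfer process, sequence evolution, composition
# shifts, recombinants and fixture emission.

test_that("sampled species trees are binary, ultrametric and seeded", {
  st <- sample_species_tree(3, depth = 1.0, seed = 7)
  expect_equal(length(st$tree$tip.label), 3)
  expect_equal(st$tree$Nnode, 2) # rooted binary: n - 1 internal nodes

  n1 <- ape::write.tree(sample_species_tree(8, depth = 0.5, seed = 1)$tree)
  n2 <- ape::write.tree(sample_species_tree(8, depth = 0.5, seed = 1)$tree)
  expect_identical(n1, n2)
  n3 <- ape::write.tree(sample_species_tree(8, depth = 0.5, seed = 2)$tree)
  expect_false(identical(n1, n3))

  st16 <- sample_species_tree(16, depth = 1.0, seed = 42)
  depths <- ape::node.depth.edgelength(st16$tree)[1:16] # independent traversal
  expect_true(all(abs(depths - 1.0) < 1e-9))
  expect_true(all(st16$tree$edge.length >= 0))

  expect_error(sample_species_tree(2, depth = 1, seed = 1),
               class = "chsevol_invalid_argument")
})

test_that("grouped species trees have group-monophyletic basal clades", {
  st <- sample_species_tree(seed = 3, groups = c(fungi = 5, bacteria = 4))
  expect_setequal(unique(st$groups$group), c("fungi", "bacteria"))
  fungi <- st$groups$taxon[st$groups$group == "fungi"]
  expect_true(is_monophyletic(st$tree, fungi)$monophyletic)
  expect_true(all(abs(ape::node.depth.edgelength(st$tree)[1:9] - 1) < 1e-9))
})

test_that("the null process reproduces the species tree exactly", {
  st <- sample_species_tree(7, depth = 1, seed = 11)
  fam <- evolve_family(st, event_rates(), seed = 5)
  expect_equal(nrow(fam$log), 0)
  expect_equal(length(fam$leaves), 7) # one gene per taxon
  expect_equal(rf_distance(strip_gene_suffix(fam$gene_tree), st$tree), 0)
})

test_that("the event log replays to the gene tree's leaf set", {
  st <- sample_species_tree(8, depth = 1, seed = 2)
  cases <- list(
    list(rates = event_rates(duplication = 0.6), seed = 1),
    list(rates = event_rates(duplication = 0.5, loss = 0.3), seed = 2),
    list(rates = event_rates(duplication = 0.4, loss = 0.2, hgt = 0.3),
         seed = 3),
    list(rates = event_rates(hgt = 0.5), seed = 4))
  for (case in cases) {
    fam <- evolve_family(st, case$rates, seed = case$seed)
    replayed <- replay_event_log(st$tree, fam$log)
    expect_setequal(fam$leaves, replayed)
    if (!is.null(fam$gene_tree)) {
      expect_setequal(fam$gene_tree$tip.label, fam$leaves)
    }
  }
})

test_that("transfer events have distinct donor and recipient branches", {
  st <- sample_species_tree(8, depth = 1, seed = 2)
  fam <- evolve_family(st, event_rates(hgt = 0.8), seed = 9)
  hgt <- fam$log[fam$log$kind == "hgt", ]
  expect_gt(nrow(hgt), 0)
  expect_true(all(hgt$donor != hgt$recipient))
})

test_that("planted transfers are logged and leave extant descendants", {
  st <- sample_species_tree(seed = 4, groups = c(fungi = 4, bacteria = 4))
  planted <- tibble::tibble(time = c(0.6, 0.75),
                            donor_taxon = c("fun01", "fun03"),
                            recipient_taxon = c("bac02", "bac04"))
  fam <- evolve_family(st, event_rates(), seed = 6, planted_hgt = planted)
  hgt <- fam$log[fam$log$kind == "hgt", ]
  expect_equal(nrow(hgt), 2)
  expect_setequal(replay_event_log(st$tree, fam$log), fam$leaves)
})

test_that("sequence evolution respects rates, anchors and homology", {
  prot <- chs_root_protein(seed = 5)
  st <- sample_species_tree(4, depth = 0.3, seed = 1)

  out0 <- evolve_sequences(st$tree, prot, subst_rate = 0, indel_rate = 0,
                           seed = 2)
  expect_true(all(out0$genes$protein == prot))

  out1 <- evolve_sequences(st$tree, prot, subst_rate = 1, indel_rate = 0,
                           seed = 3)
  expect_false(any(out1$alignment == "-")) # indel-free => gapless
  expect_true(all(vapply(out1$genes$protein, function(p)
    find_catalytic_motifs(p)$complete, logical(1)))) # anchors immutable

  out2 <- evolve_sequences(st$tree, prot, subst_rate = 1, indel_rate = 0.05,
                           seed = 4)
  expect_true(any(out2$alignment == "-"))
  ung <- gsub("-", "", aln_to_strings(out2$alignment), fixed = TRUE)
  expect_identical(unname(ung[out2$genes$gene_id]),
                   out2$genes$protein) # alignment rows match sequences

  expect_error(evolve_sequences(st$tree, strrep("A", 200), seed = 1),
               class = "chsevol_invalid_argument")
})

test_that("observed p-distance matches the closed-form expectation", {
  # two leaves separated by total path 0.5 under unit rate
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  n <- 2000
  prot <- chs_root_protein(length = n, seed = 3)
  out <- evolve_sequences(tr, prot, subst_rate = 1, indel_rate = 0, seed = 8)
  p_obs <- mean(split_chars(out$genes$protein[1]) !=
                  split_chars(out$genes$protein[2]))
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.5))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("composition shifts hit the amelioration mixture synonymously", {
  prot1000 <- chs_root_protein(length = 1000, seed = 21)
  g <- list(cds = back_translate(prot1000, 0.5, seed = 1))

  # full amelioration: host composition, protein untouched
  g_host <- apply_composition_shift(g, donor_gc = 0.30, amelioration = 1,
                                    host_gc = 0.60, seed = 2)
  expect_lt(abs(gc_content(g_host$cds) - 0.60), 0.03)
  expect_identical(translate_cds(g_host$cds), prot1000)

  # no amelioration: donor composition (cds length 3000)
  g_donor <- apply_composition_shift(g, donor_gc = 0.30, amelioration = 0,
                                     host_gc = 0.60, seed = 3)
  expect_lt(abs(gc_content(g_donor$cds) - 0.30), 0.03)
  expect_identical(translate_cds(g_donor$cds), prot1000)

  expect_error(apply_composition_shift(list(cds = NA_character_), 0.3, 0,
                                       0.6, seed = 1),
               class = "chsevol_invalid_argument")
})

test_that("composition converges to the mixture target on long sequences", {
  prot10k <- chs_root_protein(length = 10000, seed = 31) # 30,000 nt cds
  g <- list(cds = back_translate(prot10k, 0.5, seed = 1))
  target <- 0.36 * (1 - 0.5) + 0.60 * 0.5 # donor 0.36, host 0.60, amel 0.5
  shifted <- apply_composition_shift(g, donor_gc = 0.36, amelioration = 0.5,
                                     host_gc = 0.60, seed = 2)
  expect_lt(abs(gc_content(shifted$cds) - target), 0.01)
})

test_that("recombinants fuse at the motif and duplicate it", {
  r <- make_recombinant(list(protein = "AAQWWWYAA"),
                        list(protein = "CCQRRRYCC"))
  expect_identical(r$protein, "AAQWWWYQRRRYCC")
  expect_length(detect_motif_duplication(r$protein, "QXXXY"), 2)
  expect_true(r$is_recombinant)

  same <- make_recombinant(list(protein = "AAQWWWYAA"),
                           list(protein = "AAQWWWYAA"))
  expect_identical(same$protein, "AAQWWWYQWWWYAA") # tandem duplication

  # fixture pair from the simulator: the scanner is the oracle
  st <- sample_species_tree(4, depth = 0.2, seed = 2)
  out <- evolve_sequences(st$tree, chs_root_protein(seed = 5),
                          subst_rate = 1, indel_rate = 0, seed = 6)
  fused <- make_recombinant(out$genes[1, ], out$genes[2, ])
  expect_gte(length(detect_motif_duplication(fused$protein,
                                             motif_definition("QXXXY", "QXXXY"))), 2)

  expect_error(make_recombinant(list(protein = "AAAA"),
                                list(protein = "CCQRRRYCC")),
               class = "chsevol_invalid_argument")
})

test_that("emitted fixtures are byte-identical and internally consistent", {
  cfg <- fixture_config(groups = c(fungi = 4, bacteria = 4), n_hgt = 2,
                        duplication_rate = 0.5, min_genes = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- emit_fixture(cfg, seed = 11, out_dir = d1)
  f2 <- emit_fixture(cfg, seed = 11, out_dir = d2)
  for (k in names(f1$files)) {
    expect_identical(unname(tools::md5sum(f1$files[[k]])),
                     unname(tools::md5sum(f2$files[[k]])),
                     info = k)
  }

  log <- read_event_log(f1$files[["events"]])
  expect_equal(sum(log$kind == "hgt"), 2)

  prot <- read_fasta(f1$files[["proteins"]])
  tmap <- read_taxon_map(f1$files[["taxon_map"]])
  expect_setequal(names(prot), tmap$seq_id) # every id exactly once
  expect_equal(anyDuplicated(tmap$seq_id), 0)
})
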