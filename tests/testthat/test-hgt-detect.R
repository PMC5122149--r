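# G+C windows, composition anomaly, incongruence, synteny and the
# combined transfer verdict.

test_that("gc_windows obeys the count law and matches a naive counter", {
  prof <- gc_windows(strrep("G", 2000), window = 1000, step = 30)
  expect_equal(nrow(prof), floor((2000 - 1000) / 30) + 1) # 34 windows
  expect_true(all(prof$gc == 1))
  expect_equal(prof$start, seq(0, by = 30, length.out = 34))

  prof_at <- gc_windows(strrep("AT", 1000), window = 1000, step = 30)
  expect_true(all(prof_at$gc == 0))

  mixed <- simulate_genome_context(3000, gc = 0.47, seed = 5)
  prof_m <- gc_windows(mixed, window = 500, step = 37)
  oracle <- oracle_gc_windows(mixed, 500, 37)
  expect_equal(prof_m$start, oracle$start)
  expect_equal(prof_m$gc, oracle$gc)

  # ambiguous bases drop out of numerator and denominator
  ambig <- paste0(strrep("G", 60), strrep("N", 20), strrep("A", 60))
  pa <- gc_windows(ambig, window = 140, step = 10)
  expect_equal(pa$gc, 60 / 120)

  expect_equal(nrow(gc_windows("ACGT", window = 10, step = 3)), 0)
  expect_error(gc_windows("ACGT", window = 0),
               class = "chsevol_invalid_argument")
})

test_that("the window count law holds over random parameters", {
  withr::with_seed(21, {
    for (i in 1:30) {
      L <- sample(50:3000, 1)
      window <- sample(10:L, 1)
      step <- sample(1:200, 1)
      prof <- gc_windows(simulate_genome_context(L, 0.5, seed = i),
                         window = window, step = step)
      expect_equal(nrow(prof), floor((L - window) / step) + 1)
    }
  })
})

test_that("composition anomalies are judged by z-score with a fallback", {
  bg <- gc_windows(simulate_genome_context(8000, 0.5, seed = 1))
  same <- gc_anomaly(simulate_genome_context(900, 0.5, seed = 2), bg)
  expect_false(same$flag)
  expect_lt(abs(same$z), 2)

  low <- gc_anomaly(simulate_genome_context(900, 0.30, seed = 3), bg)
  expect_true(low$flag)
  expect_lt(low$z, -2)

  # degenerate background: absolute-difference fallback
  uni <- gc_windows(strrep("GCGC", 1000))
  fb <- gc_anomaly(strrep("GCGCGCGCAT", 100), uni) # region gc 0.8, bg 1.0
  expect_true(fb$flag)
  expect_identical(fb$z, -Inf)
  fb2 <- gc_anomaly(strrep("GC", 500), uni)
  expect_false(fb2$flag)

  expect_error(gc_anomaly("ACGT", gc_windows("ACG", window = 10)),
               class = "chsevol_invalid_argument")
})

test_that("transferred genes stand out from their host context", {
  sim <- simulate_chs_family(fixture_config(), seed = 8)
  hgt_genes <- sim$genes$gene_id[sim$genes$is_hgt]
  expect_gte(length(hgt_genes), 3)
  for (gid in hgt_genes) {
    prof <- gc_windows(sim$contexts[[gid]])
    an <- gc_anomaly(sim$genes$cds[sim$genes$gene_id == gid], prof)
    expect_true(an$flag)
  }
})

test_that("neighborhood similarity is the Jaccard of family sets", {
  expect_equal(neighborhood_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(neighborhood_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(neighborhood_similarity(c("DUF1800", "DUF1501", "SE"),
                                       c("DUF1800", "DUF1501", "porin")),
               0.5)
  expect_equal(neighborhood_similarity(character(0), character(0)), 0)
})

test_that("cross-group conserved neighbourhoods form components", {
  nb <- tibble::tibble(
    genome = rep(c("dickeya", "brenneria", "fusarium"), each = 3),
    gene_id = rep(c("chs1", "chs2", "chs3"), each = 3),
    position_index = rep(0:2, 3),
    family_label = c("DUF1800", "DUF1501", "SE",
                     "DUF1800", "DUF1501", "SE",
                     "x1", "x2", "x3"),
    strand = "+")
  groups <- c(dickeya = "entero", brenneria = "pecto", fusarium = "fungi")
  comps <- detect_cotransfer(nb, groups, jaccard_min = 0.5)
  expect_equal(nrow(comps), 1)
  expect_setequal(comps$genomes[[1]], c("brenneria", "dickeya"))
  expect_setequal(comps$shared_families[[1]], c("DUF1800", "DUF1501", "SE"))

  # same group everywhere: the cross-group requirement blocks all edges
  same_group <- setNames(rep("entero", 3), names(groups))
  expect_equal(nrow(detect_cotransfer(nb, same_group, jaccard_min = 0.5)), 0)
})

test_that("simulated co-transferred neighbourhoods are recovered exactly", {
  sim <- simulate_chs_family(fixture_config(), seed = 15)
  comps <- detect_cotransfer(sim$neighborhoods, sim$taxon_groups,
                             jaccard_min = 0.3)
  hgt_genes <- sim$genes$gene_id[sim$genes$is_hgt]
  recovered <- unique(unlist(comps$gene_ids))
  expect_true(all(hgt_genes %in% recovered))
  # every component member either received or donated the neighbourhood
  trio_genes <- unique(sim$neighborhoods$gene_id[
    grepl("^(DUF|SE)", sim$neighborhoods$family_label)])
  expect_true(all(recovered %in% trio_genes))
})

test_that("incongruent leaves are found by smallest supported clade", {
  tr <- ape::read.tree(text = paste0(
    "(((f1:1,f2:1)100:1,(hgt_b:1,f3:1)100:1)100:1,",
    "((b1:1,b2:1)100:1,b3:2)100:1)r;"))
  groups <- c(f1 = "fungi", f2 = "fungi", f3 = "fungi", hgt_b = "bacteria",
              b1 = "bacteria", b2 = "bacteria", b3 = "bacteria")
  calls <- detect_incongruent_leaves(tr, groups, support_min = 60)
  expect_equal(calls$leaf, "hgt_b")
  expect_equal(calls$clade_group, "fungi")
  expect_gte(calls$support, 60)

  congruent <- ape::read.tree(text = paste0(
    "(((f1:1,f2:1)100:1,f3:2)100:1,((b1:1,b2:1)100:1,b3:2)100:1)r;"))
  expect_equal(nrow(detect_incongruent_leaves(congruent, groups)), 0)

  expect_error(detect_incongruent_leaves(tr, groups[-1]),
               class = "chsevol_invalid_argument")
})

test_that("evidence combination follows the two-line rule", {
  ev <- tibble::tibble(
    seq_id = c("g1", "g2", "g3", "g4"),
    incongruent = c(TRUE, FALSE, TRUE, FALSE),
    gc_flag = c(TRUE, FALSE, FALSE, FALSE),
    synteny = c(FALSE, TRUE, TRUE, FALSE))
  calls <- combine_evidence(ev)
  expect_equal(calls$verdict, c("strong", "weak", "strong", "none"))
  # a verdict of strong always rests on >= 2 evidence lines
  expect_true(all(calls$n_evidence[calls$verdict == "strong"] >= 2))
  # missing evidence columns count as absent
  partial <- combine_evidence(tibble::tibble(seq_id = "g", gc_flag = TRUE))
  expect_equal(partial$verdict, "weak")
})

test_that("raising thresholds never increases the number of calls", {
  sim <- simulate_chs_family(fixture_config(), seed = 23)
  trimmed <- trim_alignment(sim$alignment)
  bt <- bootstrap_support(trimmed, n_reps = 60, seed = 2)
  tr <- ape::drop.tip(root_by_outgroup(bt$tree, "out|og1"), "out|og1")
  n_prev <- Inf
  for (smin in c(50, 70, 90)) {
    n <- nrow(detect_incongruent_leaves(tr, sim$taxon_groups,
                                        support_min = smin))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (jmin in c(0.2, 0.4, 0.8)) {
    comps <- detect_cotransfer(sim$neighborhoods, sim$taxon_groups,
                               jaccard_min = jmin)
    n <- length(unique(unlist(comps$gene_ids)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
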