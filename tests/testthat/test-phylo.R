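# Distances, neighbor joining, Robinson-Foulds, rooting, bootstrap.

test_that("pairwise distances count mismatches over shared columns", {
  aln <- aln_from_strings(c(
    a = "AAAAAAAAAA",
    b = "AAAAACCCCC", # 5 of 10 differ
    c = "AAAAAAAAAA"))
  dp <- pairwise_distance(aln, "p")
  expect_equal(dp["a", "c"], 0)
  expect_equal(dp["a", "b"], 0.5)
  dpois <- pairwise_distance(aln, "poisson")
  expect_equal(dpois["a", "b"], -log(0.5))

  gappy <- aln_from_strings(c(a = "AA--", b = "--CC", c = "AACC"))
  expect_error(pairwise_distance(gappy, "p"),
               class = "chsevol_undefined_distance")
  sat <- aln_from_strings(c(a = "AAAA", b = "CCCC", c = "AACC"))
  expect_error(pairwise_distance(sat, "poisson"),
               class = "chsevol_undefined_distance")
  expect_equal(pairwise_distance(sat, "p")["a", "b"], 1)
})

test_that("three-taxon NJ solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, dimnames = list(c("a", "b", "c"),
                                              c("a", "b", "c")))
  tr <- nj_tree(dm)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["a", "b"], 3)
  expect_equal(d["a", "c"], 4)
  expect_equal(d["b", "c"], 5)
  # terminal branches: (3+4-5)/2 = 1, etc.
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ recovers additive trees exactly (with ape::nj concurring)", {
  for (i in 1:30) {
    n <- 4 + (i %% 9)
    tr <- random_additive_tree(n, seed = 1000 + i)
    dm <- tree_distance_matrix(tr)
    nj <- nj_tree(dm)
    expect_equal(rf_distance(nj, tr), 0)
    expect_equal(max(abs(tree_distance_matrix(nj) - dm)), 0,
                 tolerance = 1e-9)
    expect_equal(rf_distance(nj, ape::nj(dm)), 0) # independent NJ agrees
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               class = "chsevol_invalid_argument")
})

test_that("NJ is deterministic under label permutations and ties", {
  tr <- random_additive_tree(7, seed = 77)
  dm <- tree_distance_matrix(tr)
  perm <- rev(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(rf_distance(t1, t2), 0)
  # fully tied matrix (star): still deterministic, no error
  star <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(star) <- 0
  expect_identical(ape::write.tree(nj_tree(star)),
                   ape::write.tree(nj_tree(star)))
})

test_that("rf_distance equals brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               class = "chsevol_invalid_argument")
  for (i in 1:20) {
    a <- random_additive_tree(8, seed = 300 + i)
    b <- random_additive_tree(8, seed = 600 + i)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a),
                                              ape::unroot(b))))
  }
})

test_that("rf_distance behaves as a metric on same-leaf trees", {
  trees <- lapply(1:6, function(i) random_additive_tree(7, seed = 40 + i))
  for (i in 1:5) {
    a <- trees[[i]]; b <- trees[[i + 1]]; c_ <- trees[[(i %% 6) + 1]]
    expect_equal(rf_distance(a, a), 0)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_lte(rf_distance(a, c_), rf_distance(a, b) + rf_distance(b, c_))
  }
})

test_that("outgroup rooting splits outgroup from ingroup at the midpoint", {
  tr <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  rooted <- root_by_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(rooted))
  expect_true(is_monophyletic(rooted, c("A", "B"))$monophyletic)
  root_edges <- rooted$edge.length[rooted$edge[, 1] ==
                                     length(rooted$tip.label) + 1]
  expect_equal(root_edges[1], root_edges[2])

  expect_error(root_by_outgroup(tr, c("A", "C")),
               class = "chsevol_nonmonophyletic_outgroup")
  expect_error(root_by_outgroup(tr, c("A", "E")),
               class = "chsevol_invalid_argument")
})

test_that("rooting a simulated gene tree recovers the planted root split", {
  sim <- simulate_chs_family(fixture_config(n_hgt = 0, indel_rate = 0),
                             seed = 3)
  dm <- pairwise_distance(sim$alignment, "poisson")
  tr <- nj_tree(dm)
  rooted <- root_by_outgroup(tr, "out|og1")
  ingroup <- setdiff(rooted$tip.label, "out|og1")
  expect_true(is_monophyletic(rooted, ingroup)$monophyletic)
  # the ingroup root bipartition matches the simulated gene-tree root
  sim_tree <- ape::drop.tip(sim$gene_tree, "out|og1")
  kids <- sim_tree$edge[sim_tree$edge[, 1] ==
                          length(sim_tree$tip.label) + 1, 2]
  clade <- chsevol:::tips_under_nodes(sim_tree)[[kids[1]]]
  expect_true(is_monophyletic(rooted, clade)$monophyletic)
})

test_that("long terminal branches are flagged against the median", {
  star <- nj_tree(tree_distance_matrix(
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")))
  expect_length(flag_long_branches(star, k = 4), 0)

  tr <- ape::read.tree(text = "((A:1,B:10):1,(C:1,D:1):1);")
  expect_identical(flag_long_branches(tr, k = 4), "B")

  expect_error(flag_long_branches(ape::read.tree(text = "(A:1,B:1);")),
               class = "chsevol_invalid_argument")
})

test_that("bootstrap supports are percentages of valid replicates", {
  cf <- simulate_class_family(n_taxa = 4, n_classes = 2, seed = 6)
  b1 <- bootstrap_support(cf$alignment, n_reps = 1, seed = 3)
  expect_true(all(b1$supports$support %in% c(0, 100)))

  b2 <- bootstrap_support(cf$alignment, n_reps = 30, seed = 4)
  b3 <- bootstrap_support(cf$alignment, n_reps = 30, seed = 4)
  expect_identical(b2$supports, b3$supports) # seeded determinism
  expect_true(all(b2$supports$support >= 0 & b2$supports$support <= 100))
  expect_equal(b2$n_valid + b2$n_discarded, b2$n_reps)

  # deep split, low within-class rate: saturated support for the full
  # class bipartitions themselves
  class_a <- sort(grep("\\|A$", rownames(cf$alignment), value = TRUE))
  class_b <- sort(grep("\\|B$", rownames(cf$alignment), value = TRUE))
  sides <- strsplit(b2$supports$bipartition, ",")
  is_class_split <- vapply(sides, function(x)
    setequal(x, class_a) || setequal(x, class_b), logical(1))
  expect_true(any(is_class_split))
  expect_true(all(b2$supports$support[is_class_split] == 100))
})

test_that("bootstrap supports stabilize across seeds at 200 replicates", {
  # balanced tree with uniform internal edges: every split is resolvable,
  # so supports should be reproducible run to run
  tr <- ape::compute.brlen(ape::stree(8, "balanced",
                                      tip.label = sprintf("t%02d", 1:8)),
                           0.06)
  out <- evolve_sequences(tr, chs_root_protein(length = 1000, seed = 2),
                          subst_rate = 1, indel_rate = 0, seed = 3)
  ba <- bootstrap_support(out$alignment, n_reps = 200, seed = 1)
  bb <- bootstrap_support(out$alignment, n_reps = 200, seed = 2)
  merged <- merge(ba$supports, bb$supports, by = "bipartition")
  expect_equal(nrow(merged), 5) # 8-leaf unrooted: 5 internal edges
  expect_true(all(abs(merged$support.x - merged$support.y) < 5))
})
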