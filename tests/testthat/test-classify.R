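# Monophyly testing, two-tree class definition and query assignment.

test_that("monophyly matches the smallest-spanning-clade definition", {
  tr <- ape::read.tree(text = "((A1:1,A2:1)90:1,(B1:1,B2:1)80:1)r;")
  m <- is_monophyletic(tr, c("A1", "A2"))
  expect_true(m$monophyletic)
  expect_equal(m$support, 90)
  m2 <- is_monophyletic(tr, c("A1", "B1"))
  expect_false(m2$monophyletic)
  expect_true(is.na(m2$support))
  expect_error(is_monophyletic(tr, c("A1", "Z9")),
               class = "chsevol_invalid_argument")

  # exhaustive check against a clade-enumeration oracle on random trees
  for (i in 1:15) {
    tr10 <- random_additive_tree(10, seed = 500 + i)
    tr10 <- root_by_outgroup(tr10, tr10$tip.label[1])
    clades <- lapply(ape::prop.part(tr10), function(idx)
      tr10$tip.label[idx]) # independent clade list
    withr::with_seed(i, {
      labels <- sample(tr10$tip.label, sample(2:5, 1))
    })
    oracle <- any(vapply(clades, function(cl) setequal(cl, labels),
                         logical(1)))
    expect_identical(is_monophyletic(tr10, labels)$monophyletic, oracle)
  }
})

test_that("classes require supported monophyly in both trees", {
  cf <- simulate_class_family(n_taxa = 6, n_classes = 3, seed = 11)
  b1 <- bootstrap_support(cf$alignment, n_reps = 60, correction = "p",
                          seed = 1)
  b2 <- bootstrap_support(cf$alignment, n_reps = 60, correction = "poisson",
                          seed = 2)
  r1 <- root_by_outgroup(b1$tree, cf$classes$C)
  r2 <- root_by_outgroup(b2$tree, cf$classes$C)

  defs <- define_classes(r1, r2, cf$classes, support_min = 60)
  expect_true(all(defs$accepted))
  expect_true(all(defs$support1 >= 60 & defs$support2 >= 60))

  mixed <- list(AB = c(cf$classes$A, cf$classes$B[1]))
  bad <- define_classes(r1, r2, mixed, support_min = 60)
  expect_false(bad$accepted)
  expect_match(bad$reason, "not monophyletic \\(tree1\\)")

  none <- define_classes(r1, r2, cf$classes, support_min = 101)
  expect_false(any(none$accepted))

  expect_error(define_classes(r1, ape::drop.tip(r2, cf$classes$A[1]),
                              cf$classes),
               class = "chsevol_invalid_argument")
})

test_that("define_classes with identical trees reduces to one criterion", {
  cf <- simulate_class_family(n_taxa = 5, n_classes = 2, seed = 13)
  b <- bootstrap_support(cf$alignment, n_reps = 60, seed = 1)
  r <- root_by_outgroup(b$tree, cf$classes$B)
  both <- define_classes(r, r, cf$classes["A"], support_min = 60)
  single <- is_monophyletic(r, cf$classes$A)
  expect_equal(both$accepted,
               single$monophyletic && single$support >= 60)
  expect_equal(both$support1, both$support2)
})

test_that("queries are assigned by their smallest supported clade", {
  cf <- simulate_class_family(n_taxa = 7, n_classes = 3, seed = 17)
  query <- cf$classes$A[1]
  classes <- lapply(cf$classes, setdiff, y = query)
  b <- bootstrap_support(cf$alignment, n_reps = 80, seed = 3)
  r <- root_by_outgroup(b$tree, classes$C)
  a <- assign_query(r, classes, query, support_min = 60)
  expect_equal(a$class, "A")
  expect_gte(a$support, 60)

  # a query attached on the path between the two class clades sees mixed
  # reference neighbours
  tr <- ape::read.tree(text = paste0(
    "((q:1,((A1:1,A2:1)100:1,(B1:1,B2:1)100:1)100:1)100:1,o:3)r;"))
  a2 <- assign_query(tr, list(A = c("A1", "A2"), B = c("B1", "B2")), "q")
  expect_equal(a2$class, "unclassified")
  expect_match(a2$reason, "mixed")

  # only the query and an outgroup: nothing to assign to
  tr2 <- ape::read.tree(text = "(q:1,(o1:1,o2:1)50:1)r;")
  a3 <- assign_query(tr2, list(A = c("x1", "x2")), "q")
  expect_equal(a3$class, "unclassified")

  expect_error(assign_query(tr, list(A = "A1"), "nope"),
               class = "chsevol_invalid_argument")
})

test_that("assignment is invariant under class-preserving relabeling", {
  cf <- simulate_class_family(n_taxa = 6, n_classes = 2, seed = 19)
  query <- cf$classes$A[2]
  classes <- lapply(cf$classes, setdiff, y = query)
  b <- bootstrap_support(cf$alignment, n_reps = 60, seed = 4)
  r <- root_by_outgroup(b$tree, classes$B)
  a1 <- assign_query(r, classes, query)

  # permute labels within classes (a bijective relabeling)
  perm <- setNames(r$tip.label, r$tip.label)
  swap <- classes$A[1:2]
  perm[swap] <- rev(swap)
  r2 <- r
  r2$tip.label <- unname(perm[r$tip.label])
  classes2 <- lapply(classes, function(m) unname(perm[m]))
  a2 <- assign_query(r2, classes2, query)
  expect_equal(a1$class, a2$class)
})
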