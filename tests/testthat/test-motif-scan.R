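# Catalytic-motif scanner, PSSM screen and hydropathy predictor.

test_that("catalytic motif completeness follows the ordered D,D,D,QXXRW rule", {
  rep1 <- find_catalytic_motifs("MDAADLLDAAQAARWM", min_gap = 1)
  expect_true(rep1$complete)
  expect_equal(rep1$d_positions, c(2, 5, 8)) # 1-based
  expect_equal(rep1$qxxrw_starts, 11)

  rep2 <- find_catalytic_motifs("MAAAQAARW") # no aspartate
  expect_false(rep2$complete)
  expect_true(rep2$dubious)

  rep3 <- find_catalytic_motifs("QRRRW")
  expect_equal(rep3$qxxrw_starts, 1)
  expect_false(rep3$complete)

  # QXXRW before the third aspartate does not qualify
  expect_false(find_catalytic_motifs("DQAARWDAD", min_gap = 1)$complete)

  # default separation requires spread-out aspartates
  expect_false(find_catalytic_motifs("MDAADLLDAAQAARWM")$complete)
  expect_true(find_catalytic_motifs(chs_root_protein(seed = 2))$complete)
})

test_that("candidate filtering partitions by motif completeness", {
  st <- sample_species_tree(5, depth = 0.3, seed = 1)
  out <- evolve_sequences(st$tree, chs_root_protein(seed = 5),
                          subst_rate = 1, indel_rate = 0, seed = 2)
  genes <- dplyr::bind_rows(out$genes, out$genes |>
                              dplyr::mutate(gene_id = paste0(gene_id, "b")))
  decayed_idx <- c(2, 5, 9)
  genes$protein[decayed_idx] <- vapply(genes$protein[decayed_idx],
                                       decay_motifs, character(1))
  parts <- filter_candidates(genes)
  expect_setequal(parts$dubious$gene_id, genes$gene_id[decayed_idx])
  expect_equal(nrow(parts$kept) + nrow(parts$dubious), nrow(genes))
  expect_identical(parts$kept$gene_id,
                   genes$gene_id[-decayed_idx]) # order preserved

  all_ok <- filter_candidates(out$genes)
  expect_equal(nrow(all_ok$dubious), 0)

  empty <- filter_candidates(out$genes[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$dubious), 0)
})

test_that("motif duplication uses leftmost non-overlapping matching", {
  q5 <- motif_definition("QXXXY", "QXXXY")
  expect_equal(detect_motif_duplication("QAAAYQAAAY", q5), c(1, 6))
  expect_equal(detect_motif_duplication("QAAAY", q5), 1)
  expect_equal(detect_motif_duplication("AAAA", q5), integer(0))
  # overlapping candidates counted once, leftmost greedy
  expect_equal(detect_motif_duplication("QQAAYAY", q5), 1)
})

test_that("motif scans agree with a position-by-position oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      prot <- paste(sample(c("A", "D", "Q", "R", "W", "Y"), 60,
                           replace = TRUE), collapse = "")
      rep_ <- find_catalytic_motifs(prot, min_gap = 3)
      expect_identical(rep_$d_positions, oracle_pattern_starts(prot, "D"))
      expect_identical(rep_$qxxrw_starts,
                       oracle_pattern_starts(prot, "QXXRW"))
      # completeness oracle: exhaustive search over ordered assignments
      ds <- rep_$d_positions; qs <- rep_$qxxrw_starts
      feasible <- FALSE
      for (q in qs) {
        d3 <- ds[ds < q]
        if (length(d3) >= 3 &&
            any(vapply(d3, function(a)
              any(vapply(d3[d3 >= a + 3], function(b)
                any(d3 >= b + 3), logical(1))), logical(1)))) {
          feasible <- TRUE
        }
      }
      expect_identical(rep_$complete, feasible)
    }
  })
})

test_that("appending residues never removes an existing motif hit", {
  withr::with_seed(7, {
    for (i in 1:50) {
      prot <- paste(sample(c("A", "Q", "R", "W", "Y"), 40, replace = TRUE),
                    collapse = "")
      before <- oracle_pattern_starts(prot, "QXXRW")
      after <- oracle_pattern_starts(paste0(prot, "QAARW"), "QXXRW")
      expect_true(all(before %in% after))
    }
  })
})

test_that("PSSM scores match the log-odds formula", {
  p <- build_pssm(c(a = "A", b = "A"), pseudocount = 1)
  expect_equal(unname(p$scores["A", 1]), log2((2 + 0.05) / 3 / 0.05))
  expect_equal(p$width, 1)

  # an all-gap (>= 50% gaps) column is dropped
  p2 <- build_pssm(c(a = "A-", b = "A-"), pseudocount = 1)
  expect_equal(p2$width, 1)

  # a uniform column scores ~0 for every residue
  aln20 <- setNames(chsevol:::AA_ALPHABET, paste0("s", 1:20))
  p3 <- build_pssm(aln20, pseudocount = 1)
  expect_true(all(abs(p3$scores[, 1]) < 0.1))
})

test_that("PSSM scanning is position-faithful and finds the planted motif", {
  st <- sample_species_tree(6, depth = 0.2, seed = 3)
  out <- evolve_sequences(st$tree, chs_root_protein(seed = 5),
                          subst_rate = 1, indel_rate = 0, seed = 4)
  seed_aln <- out$alignment[, 100:139]
  pssm <- build_pssm(seed_aln)
  consensus <- paste(apply(seed_aln, 2, function(col)
    names(sort(table(col), decreasing = TRUE))[1]), collapse = "")
  target <- paste0(strrep("P", 50), consensus, strrep("P", 50))
  hits <- pssm_scan(pssm, target, threshold = -Inf)
  expect_equal(hits$start[1], 51) # top hit at the planted offset
  # every reported score equals the naive per-window sum
  for (k in sample(nrow(hits), 10)) {
    expect_equal(hits$score[k],
                 oracle_window_score(pssm, target, hits$start[k]))
  }
  # poly-P protein scores below 0 everywhere against a non-P profile
  polyp <- pssm_scan(pssm, strrep("P", 60), threshold = 0)
  expect_equal(nrow(polyp), 0)
  # too-short protein: empty result, not an error
  expect_equal(nrow(pssm_scan(pssm, "AA")), 0)
})

test_that("threshold calibration keeps shuffled sequences below ~1%", {
  st <- sample_species_tree(6, depth = 0.2, seed = 3)
  out <- evolve_sequences(st$tree, chs_root_protein(seed = 5),
                          subst_rate = 1, indel_rate = 0, seed = 4)
  pssm <- build_pssm(out$alignment[, 100:139])
  pssm <- calibrate_pssm_threshold(pssm, out$genes$protein,
                                   n_shuffles = 300, fpr = 0.01, seed = 9)
  hits_above <- withr::with_seed(10, {
    vapply(1:300, function(i) {
      shuf <- paste(sample(split_chars(out$genes$protein[1])), collapse = "")
      nrow(pssm_scan(pssm, shuf)) > 0
    }, logical(1))
  })
  expect_lt(mean(hits_above), 0.03)
  # the true sequences themselves still score above threshold
  expect_true(all(vapply(out$genes$protein, function(p)
    nrow(pssm_scan(pssm, p)) > 0, logical(1))))
})

test_that("hydropathy segments match brute-force threshold runs", {
  segs <- predict_tm_segments(strrep("I", 30), window = 19, cutoff = 1.6)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end), c(1, 30))

  expect_equal(nrow(predict_tm_segments(strrep("R", 30), window = 19,
                                        cutoff = 1.6)), 0)

  expect_error(predict_tm_segments(strrep("I", 30), window = 10),
               class = "chsevol_invalid_argument")

  # amphipathic toy: oracle = naive centred means + run extraction
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  withr::with_seed(3, {
    for (i in 1:20) {
      prot <- paste(sample(names(kd), 80, replace = TRUE), collapse = "")
      w <- 7; cut <- 0.9537 # off the 0.1/7 grid: no borderline windows
      aa <- split_chars(prot)
      centers <- 4:(80 - 3)
      means <- vapply(centers, function(c_)
        mean(kd[aa[(c_ - 3):(c_ + 3)]]), numeric(1))
      ok <- means >= cut
      spans <- list()
      j <- 1
      while (j <= length(ok)) {
        if (ok[j]) {
          k <- j
          while (k < length(ok) && ok[k + 1]) k <- k + 1
          spans[[length(spans) + 1]] <- c(centers[j] - 3, centers[k] + 3)
          j <- k + 1
        } else j <- j + 1
      }
      # merge overlapping oracle spans
      merged <- list()
      for (sp in spans) {
        last <- if (length(merged)) merged[[length(merged)]] else NULL
        if (!is.null(last) && sp[1] <= last[2] + 1) {
          merged[[length(merged)]] <- c(last[1], max(last[2], sp[2]))
        } else merged[[length(merged) + 1]] <- sp
      }
      segs <- predict_tm_segments(prot, window = w, cutoff = cut)
      expect_equal(nrow(segs), length(merged))
      if (length(merged)) {
        expect_equal(segs$start, vapply(merged, `[`, numeric(1), 1))
        expect_equal(segs$end, vapply(merged, `[`, numeric(1), 2))
      }
    }
  })
})
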