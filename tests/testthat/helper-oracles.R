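# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: naive loops, closed forms, and third-party
# implementations (ape / phangorn) only.

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Naive sliding-window G+C, one explicit loop per window.
oracle_gc_windows <- function(seq, window, step) {
  b <- toupper(split_chars(seq))
  L <- length(b)
  if (L < window) return(data.frame(start = integer(), gc = double()))
  starts <- seq(0, L - window, by = step)
  gc <- vapply(starts, function(s) {
    win <- b[(s + 1):(s + window)]
    sum(win %in% c("G", "C")) / sum(win %in% c("A", "C", "G", "T"))
  }, numeric(1))
  data.frame(start = starts, gc = gc)
}

# Naive column entropy score.
oracle_entropy_score <- function(col) {
  col <- col[col != "-"]
  if (length(col) == 0) return(0)
  p <- table(col) / length(col)
  1 - (-sum(p * log2(p))) / log2(20)
}

# Naive exact-pattern scan (X wildcard), overlapping matches, 1-based.
oracle_pattern_starts <- function(protein, pattern) {
  pc <- split_chars(pattern)
  sc <- split_chars(protein)
  w <- length(pc)
  if (length(sc) < w) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(length(sc) - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (pc[j] != "X" && pc[j] != sc[s + j - 1]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Naive PSSM window score.
oracle_window_score <- function(pssm, protein, start) {
  aa <- split_chars(protein)
  total <- 0
  for (j in seq_len(pssm$width)) {
    a <- aa[start + j - 1]
    if (a %in% rownames(pssm$scores)) total <- total + pssm$scores[a, j]
  }
  unname(total)
}

# Replay an event log with a deterministic interpreter: lineages descend
# through speciations, logged events (in time order) apply to the copy of
# the named lineage on the named branch. Returns the extant leaf labels.
replay_event_log <- function(species_phylo, log) {
  phy <- species_phylo
  ntip <- length(phy$tip.label)
  nt <- ape::node.depth.edgelength(phy)
  kids <- lapply(seq_len(max(phy$edge)), function(v)
    phy$edge[phy$edge[, 1] == v, 2])
  node_of <- function(lab) {
    if (grepl("^n[0-9]+$", lab)) as.integer(sub("^n", "", lab))
    else match(lab, phy$tip.label)
  }
  log <- log[order(log$time), , drop = FALSE]
  consumed <- rep(FALSE, nrow(log))
  leaves <- character(0)

  descend <- function(gid, v, t0) {
    repeat {
      idx <- which(!consumed & log$gene_id == gid &
                     vapply(log$donor, node_of, 1L) == v &
                     log$time > t0 & log$time <= nt[v])
      if (length(idx)) {
        i <- idx[which.min(log$time[idx])]
        consumed[i] <<- TRUE
        if (log$kind[i] == "loss") return(invisible())
        if (log$kind[i] == "duplication") {
          descend(log$child_id[i], v, log$time[i])
          t0 <- log$time[i]
          next
        }
        if (log$kind[i] == "hgt") {
          descend(log$child_id[i], node_of(log$recipient[i]), log$time[i])
          t0 <- log$time[i]
          next
        }
      }
      break
    }
    if (v <= ntip) {
      leaves <<- c(leaves, paste0(phy$tip.label[v], "|", gid))
    } else {
      for (c_ in kids[[v]]) descend(gid, c_, nt[v])
    }
  }
  root <- ntip + 1L
  for (c_ in kids[[root]]) descend("g1", c_, 0)
  leaves
}

# Brute-force minimum-OLS topology over all unrooted 6-taxon trees.
make_ols_oracle <- function(labs) {
  all6 <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  prep <- lapply(all6, function(tr) {
    X <- phangorn::designTree(tr)
    list(tree = tr, P = solve(crossprod(X), t(X)), X = X)
  })
  function(dm) {
    dvec <- dm[lower.tri(dm)]
    sse <- vapply(prep, function(pr) {
      beta <- pr$P %*% dvec
      sum((pr$X %*% beta - dvec)^2)
    }, numeric(1))
    prep[[which.min(sse)]]$tree
  }
}

strip_gene_suffix <- function(tree, suffix = "\\|g1$") {
  tree$tip.label <- sub(suffix, "", tree$tip.label)
  tree
}
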