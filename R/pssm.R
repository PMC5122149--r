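#' Build a position-specific scoring matrix from a seed alignment
#'
#' Profile-based candidate screening: columns with at least 50% gaps are
#' dropped, and each remaining column gets per-residue log-odds scores
#' `log2((count + pseudocount * bg) / (n + pseudocount) / bg)`, where `n` is
#' the number of non-gap residues in the column and the background is
#' uniform (1/20) by default.
#'
#' @param seed_alignment Alignment character matrix (or named character
#'   vector of gapped strings) with at least two sequences.
#' @param pseudocount Positive pseudocount mass.
#' @param background Named numeric vector of background frequencies over the
#'   20 amino acids; default uniform.
#' @param threshold Score threshold stored with the matrix (use
#'   [calibrate_pssm_threshold()] to set it empirically).
#' @return An object of class `chs_pssm`: `scores` (20 x width matrix),
#'   `width`, `background`, `pseudocount`, `threshold`.
#' @export
build_pssm <- function(seed_alignment, pseudocount = 1, background = NULL,
                       threshold = 0) {
  if (is.character(seed_alignment) && !is.matrix(seed_alignment)) {
    seed_alignment <- aln_from_strings(seed_alignment)
  }
  validate_alignment(seed_alignment, min_rows = 2)
  assert_that(pseudocount > 0, "pseudocount must be > 0",
              class = "chsevol_invalid_argument")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  keep <- column_gap_fraction(seed_alignment) < 0.5
  assert_that(any(keep), "no column with <50% gaps",
              class = "chsevol_invalid_argument")
  aln <- seed_alignment[, keep, drop = FALSE]
  scores <- vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    col <- col[col != GAP_CHAR]
    n <- length(col)
    counts <- table(factor(col, levels = AA_ALPHABET))
    log2((as.numeric(counts) + pseudocount * background[AA_ALPHABET]) /
           (n + pseudocount) / background[AA_ALPHABET])
  }, numeric(20))
  scores <- matrix(scores, nrow = 20, dimnames = list(AA_ALPHABET, NULL))
  structure(list(scores = scores, width = ncol(scores),
                 background = background, pseudocount = pseudocount,
                 threshold = threshold),
            class = "chs_pssm")
}

#' @export
print.chs_pssm <- function(x, ...) {
  cat("PSSM: width", x$width, "| threshold", format(x$threshold, digits = 4),
      "\n")
  invisible(x)
}

#' Scan a protein with a PSSM
#'
#' Scores every window of the protein as the sum of per-column log-odds
#' scores and returns the windows scoring at or above the threshold, sorted
#' by score (descending). Residues outside the 20-letter alphabet contribute
#' a score of 0. A protein shorter than the matrix yields no hits.
#'
#' @param pssm A [build_pssm()] object.
#' @param protein Amino-acid string.
#' @param threshold Score cutoff; defaults to the matrix's stored threshold.
#' @return Tibble with columns `start` (1-based) and `score`.
#' @export
pssm_scan <- function(pssm, protein, threshold = NULL) {
  assert_that(inherits(pssm, "chs_pssm"), "pssm must be a chs_pssm")
  threshold <- threshold %||% pssm$threshold
  aa <- chars(protein)
  n <- length(aa); w <- pssm$width
  if (n < w) return(tibble(start = integer(), score = double()))
  row_idx <- match(aa, AA_ALPHABET) # NA for non-standard letters
  starts <- seq_len(n - w + 1)
  scores <- vapply(starts, function(s) {
    ri <- row_idx[s:(s + w - 1)]
    ok <- !is.na(ri)
    sum(pssm$scores[cbind(ri[ok], which(ok))])
  }, numeric(1))
  hits <- tibble(start = starts, score = scores) |>
    filter(.data$score >= threshold) |>
    arrange(desc(.data$score), .data$start)
  hits
}

#' Calibrate a PSSM score threshold on shuffled sequences
#'
#' The profile screen is meant to be permissive — it should detect every
#' true family member while rejecting unrelated sequences. The threshold is
#' set empirically as the `1 - fpr` quantile of maximal window scores over
#' length-matched shuffles of the seed sequences, so that fewer than
#' `fpr` of random same-composition sequences score above it.
#'
#' @param pssm A [build_pssm()] object.
#' @param sequences Character vector of (ungapped) reference sequences whose
#'   shuffles define the null distribution.
#' @param n_shuffles Number of shuffles.
#' @param fpr Target false-positive rate among shuffles.
#' @param seed Integer seed.
#' @return The `chs_pssm` with its `threshold` replaced.
#' @export
calibrate_pssm_threshold <- function(pssm, sequences, n_shuffles = 1000,
                                     fpr = 0.01, seed = 1) {
  assert_that(length(sequences) >= 1, "need at least one sequence")
  null_max <- local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- sample1(sequences)
      shuf <- paste(sample(chars(s)), collapse = "")
      h <- pssm_scan(pssm, shuf, threshold = -Inf)
      if (nrow(h)) max(h$score) else -Inf
    }, numeric(1))
  })
  pssm$threshold <- unname(quantile(null_max, 1 - fpr, type = 1))
  pssm
}

#' Read or write a PSSM as plain text
#'
#' The serialisation is a tab-separated matrix (rows = the 20 amino acids)
#' preceded by header lines `#width`, `#pseudocount`, `#threshold`.
#'
#' @param pssm A `chs_pssm`.
#' @param path File path.
#' @return `write_pssm()` returns the path invisibly; `read_pssm()` the
#'   `chs_pssm`.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("#width\t", pssm$width),
               paste0("#pseudocount\t", format(pssm$pseudocount, digits = 12)),
               paste0("#threshold\t", format(pssm$threshold, digits = 12))),
             con, sep = "\n")
  for (a in AA_ALPHABET) {
    writeLines(paste(c(a, format(pssm$scores[a, ], digits = 12)),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:3], "\t")
  vals <- lapply(strsplit(lines[-(1:3)], "\t"), function(x) {
    setNames(list(as.numeric(x[-1])), x[1])
  })
  scores <- do.call(rbind, lapply(vals, `[[`, 1))
  rownames(scores) <- vapply(vals, names, character(1))
  scores <- scores[AA_ALPHABET, , drop = FALSE]
  structure(list(scores = scores, width = as.integer(hdr[[1]][2]),
                 background = setNames(rep(1 / 20, 20), AA_ALPHABET),
                 pseudocount = as.numeric(hdr[[2]][2]),
                 threshold = as.numeric(hdr[[3]][2])),
            class = "chs_pssm")
}
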