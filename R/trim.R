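#' Score alignment columns for conservation
#'
#' Two scoring modes, both mapped to \[0, 1\] with gaps excluded:
#'
#' * `"entropy"`: `1 - H(column) / log2(20)`, where `H` is the Shannon
#'   entropy of the non-gap residue frequencies. A perfectly conserved
#'   column scores 1; a column with 20 equally frequent residues scores 0.
#' * `"similarity"`: the mean pairwise substitution-matrix score over all
#'   non-gap residue pairs, min-max normalised by the matrix's extreme
#'   entries (BLOSUM62 by default; any 20x20 matrix can be supplied, so the
#'   within-division versus cross-division matrix choice is a configuration
#'   switch).
#'
#' Columns with fewer than two non-gap residues are scored 0 in similarity
#' mode (no pair to assess) and by the entropy of whatever is present in
#' entropy mode (a single residue scores 1).
#'
#' @param aln Alignment character matrix, >= 2 rows.
#' @param method `"entropy"` or `"similarity"`.
#' @param matrix Optional substitution matrix (defaults to BLOSUM62).
#' @return Numeric vector of per-column scores in \[0, 1\].
#' @export
score_columns <- function(aln, method = c("entropy", "similarity"),
                          matrix = NULL) {
  validate_alignment(aln, min_rows = 2)
  method <- match.arg(method)
  if (method == "entropy") {
    return(vapply(seq_len(ncol(aln)), function(j) {
      col <- aln[, j]
      col <- col[col != GAP_CHAR]
      if (length(col) == 0) return(0)
      p <- as.numeric(table(col)) / length(col)
      h <- -sum(p * log2(p))
      1 - h / log2(20)
    }, numeric(1)))
  }
  m <- matrix %||% blosum62()
  rng <- range(m[AA_ALPHABET, AA_ALPHABET])
  vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    col <- col[col != GAP_CHAR & col %in% AA_ALPHABET]
    if (length(col) < 2) return(0)
    pairs <- utils::combn(length(col), 2)
    s <- mean(m[cbind(col[pairs[1, ]], col[pairs[2, ]])])
    (s - rng[1]) / (rng[2] - rng[1])
  }, numeric(1))
}

blosum62 <- function() {
  if (is.null(chsevol_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    chsevol_cache$blosum62 <- e$BLOSUM62
  }
  chsevol_cache$blosum62
}

#' Trim ambiguously aligned or highly variable alignment columns
#'
#' Removes columns whose smoothed conservation score (running mean over
#' `smoothing_window` columns) falls below `score_cutoff`, or whose gap
#' fraction exceeds `gap_cutoff` — the usual cleanup before phylogenetic
#' inference, which discards the hypervariable regions that destabilise CHS
#' trees. Filtering is iterated to a fixed point so the operation is
#' idempotent: trimming a trimmed alignment with the same parameters is a
#' no-op.
#'
#' @param aln Alignment character matrix.
#' @param score_cutoff Minimum smoothed score, in \[0, 1\].
#' @param gap_cutoff Maximum column gap fraction, in \[0, 1\].
#' @param smoothing_window Odd window for score smoothing.
#' @param method,matrix Passed to [score_columns()].
#' @return The trimmed alignment with attribute `kept_columns`: the original
#'   (input) indices of the surviving columns, in order.
#' @export
trim_alignment <- function(aln, score_cutoff = 0.5, gap_cutoff = 0.5,
                           smoothing_window = 3,
                           method = c("entropy", "similarity"),
                           matrix = NULL) {
  validate_alignment(aln, min_rows = 2)
  method <- match.arg(method)
  assert_that(score_cutoff >= 0 && score_cutoff <= 1 &&
                gap_cutoff >= 0 && gap_cutoff <= 1,
              "cutoffs must be in [0, 1]",
              class = "chsevol_invalid_argument")
  assert_that(smoothing_window %% 2 == 1 && smoothing_window >= 1,
              "smoothing_window must be odd and >= 1",
              class = "chsevol_invalid_argument")
  kept <- seq_len(ncol(aln))
  cur <- aln
  repeat {
    if (ncol(cur) == 0) break
    sc <- smooth_scores(score_columns(cur, method = method, matrix = matrix),
                        smoothing_window)
    keep <- sc >= score_cutoff & column_gap_fraction(cur) <= gap_cutoff
    if (all(keep)) break
    cur <- cur[, keep, drop = FALSE]
    kept <- kept[keep]
  }
  attr(cur, "kept_columns") <- kept
  cur
}

# centred running mean with shrinking windows at the edges
smooth_scores <- function(x, window) {
  if (window == 1 || length(x) <= 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Write the kept-column index map of a trimmed alignment
#'
#' Companion output of [trim_alignment()]: a TSV with 0-based output and
#' input column indices, so trimmed-tree coordinates can be traced back to
#' the original alignment.
#'
#' @param trimmed Result of [trim_alignment()].
#' @param path Output path.
#' @export
write_index_map <- function(trimmed, path) {
  kept <- attr(trimmed, "kept_columns")
  assert_that(!is.null(kept), "trimmed must come from trim_alignment()")
  write_tsv_plain(tibble(kept_column_output_index = seq_along(kept) - 1L,
                         input_column_index = kept - 1L), path)
}
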