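#' Define a protein motif
#'
#' A motif is a fixed-width pattern over the amino-acid alphabet where `X`
#' matches any residue, e.g. `"QXXRW"` (the catalytic motif shared by
#' processive GT2 glycosyltransferases) or `"QXXXY"` (whose duplication marks
#' recombined CHS).
#'
#' @param name Motif name.
#' @param pattern Pattern string over amino-acid letters plus `X`.
#' @param min_copies_expected Copies expected in a normal protein.
#' @return A list of class `chs_motif`.
#' @export
motif_definition <- function(name, pattern, min_copies_expected = 1) {
  assert_that(is_string(pattern) && nchar(pattern) >= 1,
              "pattern must be a non-empty string",
              class = "chsevol_invalid_argument")
  assert_that(all(chars(pattern) %in% c(AA_ALPHABET, "X")),
              "pattern may only use amino-acid letters and X",
              class = "chsevol_invalid_argument")
  structure(list(name = name, pattern = pattern,
                 min_copies_expected = min_copies_expected),
            class = "chs_motif")
}

motif_regex <- function(motif) {
  pat <- if (inherits(motif, "chs_motif")) motif$pattern else motif
  gsub("X", ".", pat, fixed = TRUE)
}

#' Check a protein for the catalytic CHS motifs
#'
#' Chitin synthase activity requires three conserved aspartates followed by
#' the `QXXRW` motif. This scanner records every aspartate position and every
#' `QXXRW` match (1-based starts) and reports the protein as `complete` when
#' an ordered assignment `D < D < D < QXXRW` exists with at least `min_gap`
#' residues between consecutive aspartates; otherwise the protein is
#' `dubious` and should be disqualified from classification.
#'
#' @param protein Amino-acid string.
#' @param min_gap Minimum separation (residues) between assigned aspartates.
#' @return A list of class `chs_motif_report`: `d_positions`,
#'   `qxxrw_starts`, `assignment` (the 4 chosen positions, or `NULL`),
#'   `complete`, `dubious`.
#' @examples
#' find_catalytic_motifs("MDAADLLDAAQAARWM", min_gap = 1)$complete
#' @export
find_catalytic_motifs <- function(protein, min_gap = 10) {
  assert_that(is_string(protein) && nchar(protein) > 0,
              "protein must be a non-empty string",
              class = "chsevol_invalid_argument")
  d <- motif_starts(protein, "D")
  q <- motif_starts(protein, "Q..RW")
  assignment <- NULL
  # greedy earliest assignment is optimal for an ordered chain constraint
  if (length(d) >= 3 && length(q) >= 1) {
    d1 <- d[1]
    d2 <- d[d >= d1 + min_gap][1]
    d3 <- if (!is.na(d2)) d[d >= d2 + min_gap][1] else NA
    qw <- if (!is.na(d3)) q[q > d3][1] else NA
    if (!is.na(qw)) assignment <- c(d1, d2, d3, qw)
  }
  structure(list(d_positions = d, qxxrw_starts = q, assignment = assignment,
                 complete = !is.null(assignment),
                 dubious = is.null(assignment)),
            class = "chs_motif_report")
}

#' @export
print.chs_motif_report <- function(x, ...) {
  cat("Catalytic motif report:",
      if (x$complete) "complete (D, D, D, QXXRW found in order)"
      else "dubious (motif set incomplete)", "\n")
  cat("  D positions:", paste(x$d_positions, collapse = " "), "\n")
  cat("  QXXRW starts:", paste(x$qxxrw_starts, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.chs_motif_report <- function(x, ...) {
  bind_rows(
    tibble(motif = "D", start = as.integer(x$d_positions)),
    tibble(motif = "QXXRW", start = as.integer(x$qxxrw_starts))
  )
}

#' Partition candidate genes by catalytic-motif completeness
#'
#' Applies [find_catalytic_motifs()] to every gene and splits the input into
#' the genes carrying the full catalytic motif set (`kept`) and the dubious
#' ones (`dubious`). Input order is preserved in both parts.
#'
#' @param genes Tibble with at least a `protein` column.
#' @param min_gap Passed to [find_catalytic_motifs()].
#' @return A list with tibbles `kept` and `dubious`; both carry a
#'   `motif_complete` column.
#' @export
filter_candidates <- function(genes, min_gap = 10) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    genes$motif_complete <- logical(0)
    return(list(kept = genes, dubious = genes))
  }
  genes$motif_complete <- vapply(
    genes$protein, function(p) find_catalytic_motifs(p, min_gap)$complete,
    logical(1), USE.NAMES = FALSE)
  list(kept = genes[genes$motif_complete, , drop = FALSE],
       dubious = genes[!genes$motif_complete, , drop = FALSE])
}

#' Find non-overlapping copies of a motif
#'
#' Leftmost-greedy, non-overlapping matching of a motif pattern; two or more
#' copies flag a motif duplication (the recCHS signature for `QXXXY`).
#'
#' @param protein Amino-acid string.
#' @param motif A [motif_definition()] or pattern string.
#' @return Integer vector of 1-based match starts.
#' @examples
#' detect_motif_duplication("QAAAYQAAAY", motif_definition("QXXXY", "QXXXY"))
#' @export
detect_motif_duplication <- function(protein, motif) {
  m <- gregexpr(motif_regex(motif), protein)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}
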