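#' Alignment containers
#'
#' chsevol stores a protein multiple sequence alignment as a plain character
#' matrix: one row per sequence (rownames are the sequence ids), one column
#' per alignment column, one residue or `"-"` per cell. These helpers convert
#' between that matrix form and named character vectors of gapped strings.
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @return `aln_from_strings()` returns the character matrix;
#'   `aln_to_strings()` the named character vector.
#' @examples
#' aln <- aln_from_strings(c(a = "MK-W", b = "MKAW"))
#' aln_to_strings(aln)
#' @export
aln_from_strings <- function(seqs) {
  assert_that(is.character(seqs) && length(seqs) >= 1 &&
                !is.null(names(seqs)), "seqs must be a named character vector")
  assert_that(length(unique(nchar(seqs))) == 1,
              "alignment rows must all have the same length")
  assert_that(!anyDuplicated(names(seqs)), "alignment ids must be unique")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' @rdname aln_from_strings
#' @param aln Alignment character matrix.
#' @export
aln_to_strings <- function(aln) {
  setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

validate_alignment <- function(aln, min_rows = 1) {
  assert_that(is.matrix(aln) && is.character(aln),
              "alignment must be a character matrix")
  assert_that(nrow(aln) >= min_rows,
              paste0("alignment needs at least ", min_rows, " rows"))
  assert_that(!is.null(rownames(aln)) && !anyDuplicated(rownames(aln)),
              "alignment rows must have unique ids")
  invisible(aln)
}

# Fraction of gap characters per column.
column_gap_fraction <- function(aln) colMeans(aln == GAP_CHAR)

# Remove gaps from one aligned row.
ungap <- function(row_chars) row_chars[row_chars != GAP_CHAR]
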