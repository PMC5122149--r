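#' Pairwise distances from a protein alignment
#'
#' For each sequence pair, only columns where both rows are non-gap count.
#' `p` is the mismatch fraction over those shared columns; `poisson` is the
#' Poisson-corrected distance `-ln(1 - p)`. A pair with no shared non-gap
#' column, or with `p >= 1` under the Poisson correction, is an undefined
#' distance and raises an error naming the pair (bootstrap replicates catch
#' this and are discarded).
#'
#' @param aln Alignment character matrix, >= 3 rows.
#' @param correction `"p"` or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment row ids.
#' @export
pairwise_distance <- function(aln, correction = c("p", "poisson")) {
  validate_alignment(aln, min_rows = 3)
  correction <- match.arg(correction)
  ids <- rownames(aln)
  n <- nrow(aln)
  gap <- aln == GAP_CHAR
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      if (ns == 0) {
        abort(paste0("undefined distance: sequences '", ids[i], "' and '",
                     ids[j], "' share no non-gap columns"),
              class = c("chsevol_undefined_distance", "chsevol_error"))
      }
      p <- sum(aln[i, shared] != aln[j, shared]) / ns
      if (correction == "poisson") {
        if (p >= 1) {
          abort(paste0("undefined distance: sequences '", ids[i], "' and '",
                       ids[j], "' differ at every shared column (p >= 1)"),
                class = c("chsevol_undefined_distance", "chsevol_error"))
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

validate_distance_matrix <- function(dm, tol = 1e-12) {
  assert_that(is.matrix(dm) && is.numeric(dm) && nrow(dm) == ncol(dm),
              "distance matrix must be square numeric",
              class = "chsevol_invalid_argument")
  assert_that(all(is.finite(dm)), "distance matrix entries must be finite",
              class = "chsevol_invalid_argument")
  assert_that(max(abs(dm - t(dm))) <= tol,
              "distance matrix must be symmetric",
              class = "chsevol_invalid_argument")
  assert_that(all(abs(diag(dm)) == 0), "diagonal must be exactly 0",
              class = "chsevol_invalid_argument")
  assert_that(!is.null(rownames(dm)) && !anyDuplicated(rownames(dm)),
              "distance matrix needs unique labels",
              class = "chsevol_invalid_argument")
  invisible(dm)
}

#' Write or read a distance matrix as square TSV
#' @param dm Labelled symmetric matrix.
#' @param path File path.
#' @export
write_distance_matrix <- function(dm, path) {
  tb <- as_tibble(as.data.frame(dm), rownames = "id")
  write_tsv_plain(tb, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"), progress = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb$id
  validate_distance_matrix(m, tol = 1e-9)
  m
}
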