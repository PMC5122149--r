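#' Read and write sequence, tree and table files
#'
#' Thin, validating wrappers around `Biostrings`, `ape` and `readr` for the
#' formats the pipeline exchanges. In-memory objects use R's 1-based,
#' inclusive coordinates; every file written by chsevol uses 0-based,
#' half-open coordinates (converted at the boundary).
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences;
#'   `read_alignment()` a character matrix (rows = sequences, one residue per
#'   cell); `read_newick()` an `ape::phylo`; the TSV readers return tibbles.
#' @name chs_io
NULL

#' @rdname chs_io
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  assert_that(!anyDuplicated(ids),
              paste0("duplicate sequence ids in ", path, ": ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              class = "chsevol_parse_error")
  setNames(as.character(set), ids)
}

#' @rdname chs_io
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width for FASTA output.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  assert_that(is.character(seqs) && !is.null(names(seqs)),
              "seqs must be a named character vector")
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' @rdname chs_io
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    abort(paste0("ragged alignment in ", path, ": sequence '", bad[1],
                 "' has length ", nchar(seqs[[bad[1]]]),
                 " but '", names(seqs)[1], "' has length ", lens[1]),
          class = c("chsevol_parse_error", "chsevol_error"))
  }
  aln_from_strings(seqs)
}

#' @rdname chs_io
#' @param aln Alignment character matrix.
#' @export
write_alignment <- function(aln, path, width = 70) {
  write_fasta(aln_to_strings(aln), path, width = width)
}

#' @rdname chs_io
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) abort(
                   paste0("cannot parse newick in ", path, ": ",
                          conditionMessage(e)),
                   class = c("chsevol_parse_error", "chsevol_error")))
  assert_that(!is.null(tr), paste0("cannot parse newick in ", path),
              class = "chsevol_parse_error")
  tr
}

#' @rdname chs_io
#' @param tree An `ape::phylo`, internal node labels (if any) carrying
#'   bootstrap supports in \[0, 100\].
#' @export
write_newick <- function(tree, path) {
  txt <- ape::write.tree(tree)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

#' @rdname chs_io
#' @export
read_taxon_map <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_that(all(c("seq_id", "taxon", "group") %in% names(tb)),
              "taxon map must have columns seq_id, taxon, group",
              class = "chsevol_parse_error")
  assert_that(!anyDuplicated(tb$seq_id), "duplicate seq_id in taxon map",
              class = "chsevol_parse_error")
  tb
}

#' @rdname chs_io
#' @export
read_neighborhood <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    genome = "c", gene_id = "c", position_index = "i",
    family_label = "c", strand = "c"), progress = FALSE)
  assert_that(all(tb$strand %in% c("+", "-")),
              "neighborhood strand must be '+' or '-'",
              class = "chsevol_parse_error")
  tb
}

#' @rdname chs_io
#' @export
read_event_log <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    kind = "c", donor = "c", recipient = "c", time = "d",
    gene_id = "c", child_id = "c"), progress = FALSE)
}

# Deterministic TSV writer (no timestamps, fixed number formatting).
write_tsv_plain <- function(tb, path) {
  tb <- as.data.frame(tb)
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(tb), collapse = "\t"), con, sep = "\n")
  if (nrow(tb)) {
    lines <- do.call(paste, c(lapply(tb, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
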