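# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic operations in chsevol take an explicit integer seed and
#' route it through this helper, so no function touches global RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @noRd
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Deterministically derive a stream of sub-seeds from one master seed.
# Kept below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 137 * as.numeric(i)) %% 2147483629L)
}

assert_that <- function(ok, msg, class = "chsevol_error") {
  if (!isTRUE(ok)) abort(msg, class = c(class, "chsevol_error"))
  invisible(TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

# Split simulated leaf labels "taxon|geneid" into their parts.
leaf_taxon <- function(labels) sub("\\|.*$", "", labels)
leaf_gene <- function(labels) sub("^[^|]*\\|", "", labels)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# sample() without the scalar-x surprise
sample1 <- function(x) x[sample.int(length(x), 1)]
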