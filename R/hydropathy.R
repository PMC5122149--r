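# Kyte-Doolittle hydropathy values (J Mol Biol 1982), standard constants.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Predict transmembrane-like segments by hydropathy
#'
#' Simple hydropathy-window transmembrane predictor: each position with a
#' full centred window gets the mean Kyte-Doolittle hydropathy of that
#' window; positions at or above the cutoff are extended to the windows they
#' represent, and overlapping spans are merged. Every CHS carries multiple
#' such membrane-spanning segments, so this serves as a coarse structural
#' annotation of candidates.
#'
#' @param protein Amino-acid string.
#' @param window Odd window length >= 5.
#' @param cutoff Mean-hydropathy cutoff (1.6 is the conventional value for
#'   membrane-spanning windows at window 19).
#' @return Tibble with 1-based inclusive `start`, `end` and
#'   `mean_hydropathy` (mean over the segment's qualifying windows); zero
#'   rows when nothing qualifies. Segments are non-overlapping and at least
#'   `window` residues long.
#' @examples
#' predict_tm_segments(strrep("I", 30), window = 19, cutoff = 1.6)
#' @export
predict_tm_segments <- function(protein, window = 19, cutoff = 1.6) {
  assert_that(window %% 2 == 1 && window >= 5,
              "window must be odd and >= 5",
              class = "chsevol_invalid_argument")
  aa <- chars(protein)
  n <- length(aa)
  half <- (window - 1) / 2
  empty <- tibble(start = integer(), end = integer(),
                  mean_hydropathy = double())
  if (n < window) return(empty)
  h <- unname(KYTE_DOOLITTLE[aa])
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  centers <- (half + 1):(n - half)
  means <- (cs[centers + half + 1] - cs[centers - half]) / window
  ok <- means >= cutoff
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1
  segs <- tibble(
    start = centers[starts_i[runs$values]] - half,
    end = centers[ends_i[runs$values]] + half,
    mean_hydropathy = vapply(which(runs$values), function(k)
      mean(means[starts_i[k]:ends_i[k]]), numeric(1)))
  # merge overlapping spans
  out <- segs[1, ]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$start[i] <= out$end[nrow(out)] + 1) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], segs$end[i])
      out$mean_hydropathy[nrow(out)] <-
        max(out$mean_hydropathy[nrow(out)], segs$mean_hydropathy[i])
    } else {
      out <- bind_rows(out, segs[i, ])
    }
  }
  out
}
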