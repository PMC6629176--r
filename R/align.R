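#' Global pairwise alignment (Needleman-Wunsch)
#'
#' End-to-end alignment with linear gap penalty and deterministic traceback
#' (diagonal preferred over a gap in `b`, preferred over a gap in `a` on
#' score ties). Default scoring is match +1, mismatch -1, gap -2.
#'
#' @param a,b Non-empty sequences (character scalars).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `score`, `aligned_a`, `aligned_b` (gap = `-`).
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  .nw_align_cpp(a, b, match, mismatch, gap)
}

#' Percent identity of two sequences under global alignment
#'
#' Identity = matching columns / alignment length x 100, computed on the
#' [nw_align()] alignment (match +1, mismatch -1, gap -2).
#'
#' @param a,b Non-empty sequences.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  aln <- nw_align(a, b)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Column map between two globally aligned sequences
#'
#' Maps every 0-based position of `a` to the 0-based position of `b` in the
#' same alignment column. When `b` has a gap in that column the position of
#' the last preceding `b` base is used (0 before any `b` base), so mapped
#' positions are monotone and usable for transferring site coordinates
#' between orthologous sequences.
#'
#' @param a,b Non-empty sequences.
#' @return Integer vector of length `nchar(a)`.
#' @export
alignment_column_map <- function(a, b) {
  aln <- nw_align(a, b)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  map <- integer(nchar(a))
  bi <- -1L
  ai <- 0L
  for (k in seq_along(ca)) {
    if (cb[k] != "-") bi <- bi + 1L
    if (ca[k] != "-") {
      ai <- ai + 1L
      map[ai] <- max(bi, 0L)
    }
  }
  map
}
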