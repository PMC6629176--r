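#' Scan a sequence with a position weight matrix
#'
#' Log2-odds scoring against a background distribution, both strands. A
#' pseudocount is mixed into the probability matrix before taking log-odds
#' so zero entries stay finite. Windows scoring at least `threshold_bits`
#' are reported with 0-based start positions on the forward strand, sorted
#' by position (forward strand first on ties).
#'
#' @param seq Sequence (ACGT; N scores as the background, i.e. 0 bits).
#' @param pwm 4 x width probability matrix, rows A/C/G/T, columns summing
#'   to 1 within 1e-6 (see [read_pwm()]).
#' @param threshold_bits Minimum reported score in bits.
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param pseudocount Probability pseudocount (default 0.01).
#' @param sequence_id Optional identifier copied into the output.
#' @return Data.frame with `sequence_id`, `position`, `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, threshold_bits,
                     background = rep(0.25, 4), pseudocount = 0.01,
                     sequence_id = NA_character_) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L) stop("malformed PWM: need a 4-row matrix")
  if (any(pwm < 0)) stop("malformed PWM: negative entry")
  if (any(abs(colSums(pwm) - 1) > 1e-6)) {
    stop("malformed PWM: columns must sum to 1")
  }
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  w <- ncol(pwm)
  p <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  lo <- log2(p / background)
  rownames(lo) <- c("A", "C", "G", "T")
  seq <- normalize_seq(seq)
  scan_strand <- function(s) {
    L <- nchar(s)
    if (L < w) return(data.frame(position = integer(), score = numeric()))
    cs <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- L - w + 1L
    score <- numeric(n)
    for (k in seq_len(w)) {
      base <- cs[seq_len(n) + k - 1L]
      col <- lo[, k][base]
      col[is.na(col)] <- 0  # N and other ambiguity codes score as background
      score <- score + col
    }
    data.frame(position = seq_len(n) - 1L, score = score)
  }
  fwd <- scan_strand(seq)
  fwd$strand <- "+"
  rc <- scan_strand(revcomp(seq))
  # a hit starting at p on the reverse complement occupies forward-strand
  # positions [L - p - w, L - p)
  rc$position <- nchar(seq) - rc$position - w
  rc$strand <- "-"
  hits <- rbind(fwd, rc)
  hits <- hits[hits$score >= threshold_bits, , drop = FALSE]
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  data.frame(sequence_id = rep(sequence_id, nrow(hits)),
             position = hits$position, strand = hits$strand,
             score = hits$score, stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus sequence of a PWM
#'
#' @param pwm 4 x width probability matrix (rows A/C/G/T).
#' @return Character scalar: the per-column argmax base.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm, 2L, which.max)], collapse = "")
}
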