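shannon_entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence (log base 2)
#'
#' `JSD2(p, q) = H((p+q)/2) - (H(p) + H(q))/2` with entropies in bits, so
#' the divergence lies in `[0, 1]`.
#'
#' @param p,q Probability vectors of equal length.
#' @return Divergence in bits.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  d <- shannon_entropy2(m) - (shannon_entropy2(p) + shannon_entropy2(q)) / 2
  min(max(d, 0), 1)
}

#' Tissue-specificity index of an expression profile
#'
#' The Cabili-style Jensen-Shannon specificity: the profile is normalized
#' to a probability vector `p` and scored as
#' `1 - sqrt(JSD2(p, e))`, where `e` is the one-hot profile at the argmax
#' tissue (first tissue in input order on ties). A perfectly tissue-specific
#' (one-hot) profile scores 1; flatter profiles score lower. The index is
#' invariant to profile scaling and permutation-equivariant in the tissues.
#'
#' @param profile Non-negative expression values (e.g. mean RPM per
#'   tissue), not all zero. Names, if present, are tissue labels.
#' @return List with `score` and `argmax_tissue` (label or index).
#' @export
specificity_index <- function(profile) {
  if (any(profile < 0)) stop("negative expression in profile")
  tot <- sum(profile)
  if (tot == 0) stop("all-zero expression profile")
  p <- profile / tot
  k <- which.max(p)
  e <- rep(0, length(p))
  e[k] <- 1
  score <- 1 - sqrt(js_divergence(p, e))
  argmax <- if (!is.null(names(profile))) names(profile)[k] else k
  list(score = score, argmax_tissue = argmax)
}

#' Binary tissue-specificity call
#'
#' @param score Specificity score in `[0, 1]`.
#' @param tau Threshold in `[0, 1]`; the comparison is closed
#'   (`score >= tau`). Default 0.8.
#' @return Logical.
#' @export
is_specific <- function(score, tau = 0.8) {
  stopifnot(tau >= 0, tau <= 1)
  score >= tau
}

#' Per-entity specificity scores from an expression matrix
#'
#' Columns are first averaged within tissue (across stages and replicates),
#' then each row profile is scored with [specificity_index()].
#'
#' @param expr A `secirc_expr` object.
#' @return Data.frame with `entity_id`, `score`, `argmax_tissue`.
#' @export
specificity_scores <- function(expr) {
  stopifnot(inherits(expr, "secirc_expr"))
  tissues <- unique(expr$samples$tissue)
  prof <- vapply(tissues, function(t) {
    rowMeans(expr$values[, expr$samples$tissue == t, drop = FALSE])
  }, numeric(nrow(expr$values)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1, dimnames = list(rownames(expr$values), tissues))
  res <- lapply(seq_len(nrow(prof)), function(i) specificity_index(prof[i, ]))
  data.frame(entity_id = rownames(expr$values),
             score = vapply(res, `[[`, numeric(1), "score"),
             argmax_tissue = vapply(res, function(r) as.character(r$argmax_tissue), character(1)),
             stringsAsFactors = FALSE)
}

#' Stage-specific versus shared super-enhancers
#'
#' For each super-enhancer of a stage, computes the fraction of its bases
#' covered by the union of the other stage's super-enhancers; the SE is
#' stage-specific iff that fraction is strictly below `max_other_cover`.
#'
#' @param se_by_stage Named list of exactly two interval data.frames
#'   (`chrom`, `start`, `end`, optional `id`), one per stage.
#' @param max_other_cover Coverage fraction above which an SE counts as
#'   shared; default 0.5.
#' @return Named list (per stage) of data.frames with the input intervals
#'   plus `other_cover` and logical `specific`.
#' @export
stage_specific_ses <- function(se_by_stage, max_other_cover = 0.5) {
  stopifnot(length(se_by_stage) == 2L, max_other_cover >= 0, max_other_cover <= 1)
  as_gr <- function(df) {
    if (nrow(df) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  }
  stages <- names(se_by_stage)
  if (is.null(stages)) stages <- paste0("stage", seq_along(se_by_stage))
  out <- list()
  for (i in 1:2) {
    df <- se_by_stage[[i]]
    other <- GenomicRanges::reduce(as_gr(se_by_stage[[3 - i]]))
    gr <- as_gr(df)
    if (length(gr) == 0L) {
      df$other_cover <- numeric(0)
      df$specific <- logical(0)
    } else {
      ov <- GenomicRanges::intersect(gr, other)
      covered <- numeric(length(gr))
      if (length(ov) > 0L) {
        hits <- GenomicRanges::findOverlaps(gr, ov)
        ints <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    ov[S4Vectors::subjectHits(hits)])
        w <- tapply(IRanges::width(ints), S4Vectors::queryHits(hits), sum)
        covered[as.integer(names(w))] <- as.numeric(w)
      }
      df$other_cover <- covered / (df$end - df$start)
      df$specific <- df$other_cover < max_other_cover
    }
    out[[stages[i]]] <- df
  }
  out
}

#' Fisher association between two binary labels
#'
#' Two-sided Fisher exact test on a 2x2 contingency table, e.g.
#' tissue-specific SE (yes/no) versus tissue-specific circRNA (yes/no).
#' The reported odds ratio is the sample cross-product `ad/bc` (`Inf` when
#' `bc = 0` and `ad > 0`; `NA` when both products are 0); the p-value sums
#' the exact hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed table.
#'
#' @param table 2x2 numeric matrix of counts `rbind(c(a, b), c(c, d))`.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_association <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  list(odds_ratio = or, p_value = min(p, 1))
}

# Two-sided Mann-Whitney/Wilcoxon rank-sum p-value: exact null when both
# groups have <= exact_max observations and there are no ties, normal
# approximation with continuity correction otherwise.
rank_sum_test <- function(x, y, exact_max = 10L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                     correct = TRUE)$p.value
}

#' Expression summary by enhancer class
#'
#' Median RPM per circRNA class (each circRNA summarized as its mean RPM
#' across all samples) and a two-sided rank-sum test comparing SE-circRNAs
#' with TE-circRNAs. The test is exact (full enumeration of the null) when
#' both classes have at most 10 members and no tied values, and uses the
#' normal approximation with continuity correction otherwise. With an empty
#' class the test is skipped with a warning.
#'
#' @param expr A `secirc_expr` object.
#' @param classes Data.frame from [classify_circs()].
#' @return List with `medians` (named numeric per class), `p_value`
#'   (NA when skipped) and `per_circ` (data.frame of circ-level means).
#' @export
class_expression_summary <- function(expr, classes) {
  stopifnot(inherits(expr, "secirc_expr"))
  mean_rpm <- rowMeans(expr$values)
  cls <- classes$label[match(rownames(expr$values), classes$circ_id)]
  per_circ <- data.frame(circ_id = rownames(expr$values), label = cls,
                         mean_rpm = mean_rpm, stringsAsFactors = FALSE,
                         row.names = NULL)
  labels <- c("SE-circRNA", "TE-circRNA", "other")
  medians <- vapply(labels, function(l) {
    v <- per_circ$mean_rpm[per_circ$label %in% l]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  se <- per_circ$mean_rpm[per_circ$label %in% "SE-circRNA"]
  te <- per_circ$mean_rpm[per_circ$label %in% "TE-circRNA"]
  if (length(se) == 0L || length(te) == 0L) {
    warning("empty SE-circRNA or TE-circRNA class; rank-sum test skipped")
    p <- NA_real_
  } else {
    p <- rank_sum_test(se, te)
  }
  list(medians = medians, p_value = p, per_circ = per_circ)
}
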