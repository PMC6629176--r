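#' Stitch enhancer peaks into candidate regions
#'
#' Peaks on the same chromosome whose gap is at most `stitch_window` are
#' merged transitively (ROSE convention). Optionally, peaks lying entirely
#' within `tss_exclusion` bp of a transcription start site are removed
#' before stitching, so promoter-proximal H3K27ac signal does not inflate
#' enhancer regions.
#'
#' @param peaks Data.frame of intervals as from [read_bed()] (`chrom`,
#'   `start`, `end`, `id`).
#' @param stitch_window Maximum gap (bp) bridged when merging; default
#'   12500.
#' @param tss_points Optional data.frame with `chrom` and `pos` giving TSS
#'   positions.
#' @param tss_exclusion Half-width (bp) of the TSS exclusion zone; 0
#'   disables the filter.
#' @return Data.frame of stitched regions sorted by (chrom, start):
#'   `chrom`, `start`, `end`, `region_id`, `n_peaks`, and a list column
#'   `members` of member peak ids.
#' @export
stitch_peaks <- function(peaks, stitch_window = 12500, tss_points = NULL,
                         tss_exclusion = 0) {
  stopifnot(stitch_window >= 0)
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) > 0 && (any(peaks$end <= peaks$start) || any(peaks$start < 0))) {
    stop("invalid peak interval: need 0 <= start < end")
  }
  if (!is.null(tss_points) && tss_exclusion > 0 && nrow(peaks) > 0) {
    drop <- rep(FALSE, nrow(peaks))
    for (k in seq_len(nrow(tss_points))) {
      zone_lo <- tss_points$pos[k] - tss_exclusion
      zone_hi <- tss_points$pos[k] + tss_exclusion
      drop <- drop | (peaks$chrom == tss_points$chrom[k] &
                        peaks$start >= zone_lo & peaks$end <= zone_hi)
    }
    peaks <- peaks[!drop, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_id = character(), n_peaks = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_window + 1,
                               with.revmap = TRUE)
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  red <- red[ord]
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.numeric(GenomicRanges::end(red)),
    stringsAsFactors = FALSE
  )
  out$region_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                           as.integer(out$end))
  out$n_peaks <- lengths(revmap)
  out$members <- lapply(revmap, function(ix) peaks$id[ix])
  out
}

#' Score and rank stitched regions
#'
#' The score of a region is the sum over member peaks of
#' `max(signal - control, 0)`: the background subtraction is floored at zero
#' per peak so that locally high control signal cannot produce negative
#' densities that dominate the region total. Without a control, the score is
#' the raw signal sum. Ranks are ascending by score (rank 1 = lowest), ties
#' broken by (chrom, start).
#'
#' @param regions Stitched regions from [stitch_peaks()].
#' @param signal_by_peak Named numeric vector of per-peak signal.
#' @param control_by_peak Optional named numeric vector of per-peak control
#'   signal.
#' @return `regions` with added `score` and `rank` columns.
#' @export
score_regions <- function(regions, signal_by_peak, control_by_peak = NULL) {
  if (nrow(regions) == 0L) {
    regions$score <- numeric(0)
    regions$rank <- integer(0)
    return(regions)
  }
  all_members <- unlist(regions$members, use.names = FALSE)
  missing <- setdiff(all_members, names(signal_by_peak))
  if (length(missing) > 0L) {
    stop("missing signal for peak(s): ", paste(utils::head(missing, 3), collapse = ", "))
  }
  net <- signal_by_peak
  if (!is.null(control_by_peak)) {
    ctrl <- control_by_peak[names(signal_by_peak)]
    ctrl[is.na(ctrl)] <- 0
    net <- pmax(signal_by_peak - ctrl, 0)
  }
  regions$score <- vapply(regions$members, function(ids) sum(net[ids]), numeric(1))
  ord <- order(regions$score, regions$chrom, regions$start)
  regions$rank <- integer(nrow(regions))
  regions$rank[ord] <- seq_len(nrow(regions))
  regions
}

#' Rank-curve tangent cutoff between typical and super-enhancers
#'
#' Scores are ranked ascending and both axes are min-max scaled to
#' `[0, 1]`; the cutoff is the (unscaled) score at the point maximizing
#' `x - y`, i.e. where a slope-1 line is tangent below the convex rank
#' curve (the ROSE geometric rule). Ties go to the largest `x` (highest
#' rank). When the curve does not rise above the diagonal by more than
#' 1e-12 — e.g. all scores equal — there is no super-enhancer regime and
#' `Inf` is returned as a "no super-enhancers" sentinel.
#'
#' @param scores Numeric vector of region scores (any order; ranked
#'   internally).
#' @return The cutoff score, or `Inf` when no cutoff exists.
#' @export
find_cutoff <- function(scores) {
  if (length(scores) == 0L) stop("find_cutoff: empty score vector")
  s <- sort(scores)
  n <- length(s)
  if (n == 1L || max(s) == min(s)) return(Inf)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  d <- x - y
  if (max(d) <= 1e-12) return(Inf)
  i <- max(which(d == max(d)))
  s[i]
}

#' Call super-enhancers from peaks and signal
#'
#' Composition of [stitch_peaks()], [score_regions()] and [find_cutoff()].
#' A region is a super-enhancer iff its score is strictly greater than the
#' cutoff (the cutoff point itself stays typical). With fewer than 3
#' stitched regions all regions are typical: a tangent on a 1-2 point curve
#' is meaningless.
#'
#' @param peaks Peak intervals (data.frame; a `signal` column is used when
#'   `signal_by_peak` is not given).
#' @param signal_by_peak Named numeric per-peak signal; defaults to the
#'   `signal` column of `peaks`.
#' @param control_by_peak Optional named numeric per-peak control.
#' @param stitch_window,tss_points,tss_exclusion Passed to [stitch_peaks()].
#' @param out_dir Optional directory; when given, writes
#'   `superenhancers.bed`, `typical_enhancers.bed`, `regions_ranked.tsv`
#'   and `rank_curve.tsv`.
#' @return Data.frame of scored regions with `is_super`; the cutoff score
#'   is in the `"cutoff_score"` attribute.
#' @export
call_superenhancers <- function(peaks, signal_by_peak = NULL,
                                control_by_peak = NULL,
                                stitch_window = 12500, tss_points = NULL,
                                tss_exclusion = 0, out_dir = NULL) {
  if (is.null(signal_by_peak)) {
    if (!"signal" %in% names(peaks)) {
      stop("no signal: provide signal_by_peak or a signal column in peaks")
    }
    signal_by_peak <- stats::setNames(peaks$signal, peaks$id)
  }
  regions <- stitch_peaks(peaks, stitch_window = stitch_window,
                          tss_points = tss_points, tss_exclusion = tss_exclusion)
  regions <- score_regions(regions, signal_by_peak, control_by_peak)
  cutoff <- if (nrow(regions) < 3L) Inf else find_cutoff(regions$score)
  regions$is_super <- regions$score > cutoff
  attr(regions, "cutoff_score") <- cutoff
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    bedify <- function(df) data.frame(chrom = df$chrom, start = df$start,
                                      end = df$end, id = df$region_id,
                                      strand = ".", signal = df$score,
                                      stringsAsFactors = FALSE)
    write_bed(bedify(regions[regions$is_super, , drop = FALSE]),
              file.path(out_dir, "superenhancers.bed"))
    write_bed(bedify(regions[!regions$is_super, , drop = FALSE]),
              file.path(out_dir, "typical_enhancers.bed"))
    tab <- regions[order(regions$rank), c("region_id", "chrom", "start",
                                          "end", "n_peaks", "score", "rank",
                                          "is_super")]
    tab$score <- format_num(tab$score)
    write.table(tab, file.path(out_dir, "regions_ranked.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    s <- sort(regions$score)
    curve <- data.frame(rank = seq_along(s), score = format_num(s))
    write.table(curve, file.path(out_dir, "rank_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  regions
}
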