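#' Promoter anchor point of a circRNA
#'
#' The host-gene TSS when known; otherwise the 5' end of the back-spliced
#' span (`start` on the + strand, `end` on the - strand). Strand must be
#' `+` or `-` for circRNAs.
#'
#' @param circs Data.frame with `start`, `end`, `strand` and optionally
#'   `host_tss` (NA when unknown).
#' @return Numeric vector of promoter positions, one per row.
#' @export
promoter_point <- function(circs) {
  if (any(!circs$strand %in% c("+", "-"))) {
    stop("circRNA strand must be '+' or '-'")
  }
  p <- ifelse(circs$strand == "+", circs$start, circs$end)
  if ("host_tss" %in% names(circs)) {
    p <- ifelse(is.na(circs$host_tss), p, circs$host_tss)
  }
  as.numeric(p)
}

#' Assign enhancers to the most proximal circRNA promoter
#'
#' Each enhancer is assigned to the circRNA whose promoter point minimizes
#' the distance to the enhancer region (0 when the point falls inside the
#' region, otherwise the bp gap to the nearest covered base), provided that
#' distance is at most `window`. Distance ties are broken by the
#' lexicographically smallest circRNA id; unassignable enhancers are
#' omitted. Assignment direction is enhancer -> promoter, so each enhancer
#' contributes to at most one circRNA.
#'
#' @param enhancers Data.frame with `chrom`, `start`, `end`, `region_id` (or
#'   `id`) and logical `is_super`.
#' @param circs Data.frame of circRNAs with `id`, `chrom`, `start`, `end`,
#'   `strand` and optional `host_tss`.
#' @param window Maximum assignment distance in bp (default 50000).
#' @return Data.frame with `enhancer_id`, `circ_id`, `distance`,
#'   `enhancer_class` (`"super"` or `"typical"`).
#' @export
assign_enhancers <- function(enhancers, circs, window = 50000) {
  eid <- if ("region_id" %in% names(enhancers)) enhancers$region_id else enhancers$id
  out <- list()
  if (nrow(enhancers) == 0L || nrow(circs) == 0L) {
    return(data.frame(enhancer_id = character(), circ_id = character(),
                      distance = numeric(), enhancer_class = character(),
                      stringsAsFactors = FALSE))
  }
  prom <- promoter_point(circs)
  circ_ord <- order(circs$id)
  for (i in seq_len(nrow(enhancers))) {
    same <- which(circs$chrom == enhancers$chrom[i])
    if (length(same) == 0L) next
    p <- prom[same]
    d <- pmax(enhancers$start[i] - p, p - (enhancers$end[i] - 1), 0)
    ok <- which(d <= window)
    if (length(ok) == 0L) next
    dmin <- min(d[ok])
    cand <- same[ok][d[ok] == dmin]
    pick <- cand[order(circs$id[cand])][1L]
    out[[length(out) + 1L]] <- data.frame(
      enhancer_id = eid[i],
      circ_id = circs$id[pick],
      distance = dmin,
      enhancer_class = if (isTRUE(enhancers$is_super[i])) "super" else "typical",
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(enhancer_id = character(), circ_id = character(),
                      distance = numeric(), enhancer_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify circRNAs by their assigned enhancer class
#'
#' A circRNA with at least one assigned super-enhancer is an SE-circRNA; one
#' with only typical enhancers is a TE-circRNA; one with no assignment is
#' "other". The labels partition the circRNA set.
#'
#' @param assignments Output of [assign_enhancers()].
#' @param circs circRNA data.frame with `id`.
#' @return Data.frame with `circ_id` and `label` in
#'   `c("SE-circRNA", "TE-circRNA", "other")`.
#' @export
classify_circs <- function(assignments, circs) {
  has_super <- unique(assignments$circ_id[assignments$enhancer_class == "super"])
  has_typical <- unique(assignments$circ_id[assignments$enhancer_class == "typical"])
  label <- ifelse(circs$id %in% has_super, "SE-circRNA",
                  ifelse(circs$id %in% has_typical, "TE-circRNA", "other"))
  data.frame(circ_id = circs$id, label = label, stringsAsFactors = FALSE)
}
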