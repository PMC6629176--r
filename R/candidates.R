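#' Fold-change filter between two developmental stages
#'
#' Per circRNA, the stage means are the averages over all samples of each
#' stage (tissues and replicates pooled). Fold change is computed with a
#' pseudocount, `FC = (mean2 + pc) / (mean1 + pc)`, so zero-expression rows
#' are defined; a circRNA is differentially expressed when `FC` is at least
#' `fc_threshold` or at most `1/fc_threshold` (the +/- fold-change interval,
#' both directions kept with sign in `log2fc`). The decision is on fold
#' change alone, matching a fold-change-interval presentation; no p-value
#' is applied.
#'
#' @param expr A `secirc_expr` object.
#' @param stage_pair Character vector of two stage labels
#'   `c(stage1, stage2)`; fold change is stage2 over stage1.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param pseudocount RPM pseudocount (default 0.1).
#' @return Data.frame with `circ_id`, `mean_rpm_stage1`, `mean_rpm_stage2`,
#'   `fold_change`, `log2fc`, `is_de`.
#' @export
fold_change_filter <- function(expr, stage_pair, fc_threshold = 1.5,
                               pseudocount = 0.1) {
  stopifnot(inherits(expr, "secirc_expr"), length(stage_pair) == 2L,
            fc_threshold >= 1, pseudocount >= 0)
  for (s in stage_pair) {
    if (!s %in% expr$samples$stage) stop("stage absent from matrix: ", s)
  }
  m1 <- rowMeans(expr$values[, expr$samples$stage == stage_pair[1], drop = FALSE])
  m2 <- rowMeans(expr$values[, expr$samples$stage == stage_pair[2], drop = FALSE])
  fc <- (m2 + pseudocount) / (m1 + pseudocount)
  data.frame(circ_id = rownames(expr$values),
             mean_rpm_stage1 = m1, mean_rpm_stage2 = m2,
             fold_change = fc, log2fc = log2(fc),
             is_de = fc >= fc_threshold | fc <= 1 / fc_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species conservation filter
#'
#' A circRNA passes when it appears in a complete row of the three-species
#' ortholog table (an ortholog identified in every species), mirroring a
#' filter for circRNAs conserved among humans, rats and mice. With
#' `require_all = FALSE` any row mentioning the circRNA suffices.
#'
#' @param circ_ids Character vector of circRNA ids (reference species).
#' @param orthologs Data.frame from [read_orthologs()]; first column is the
#'   reference species.
#' @param require_all Require an ortholog in all species (default TRUE).
#' @return Character vector: the conserved subset of `circ_ids`.
#' @export
conservation_filter <- function(circ_ids, orthologs, require_all = TRUE) {
  if (ncol(orthologs) < 3L) stop("malformed ortholog table: need 3 species columns")
  if (nrow(orthologs) == 0L) return(character(0))
  keep <- if (require_all) {
    stats::complete.cases(orthologs[, 1:3])
  } else {
    !is.na(orthologs[[1]])
  }
  intersect(circ_ids, orthologs[[1]][keep])
}

#' Select and rank candidate SE-circRNAs
#'
#' The candidate funnel: SE-circRNAs that are differentially expressed
#' between the two stages and conserved across all three species. Candidates
#' are ranked by `|log2fc|` descending, ties by specificity score
#' descending, then by circRNA id.
#'
#' @param classes Data.frame from [classify_circs()].
#' @param de_calls Data.frame from [fold_change_filter()].
#' @param conserved_set Character vector from [conservation_filter()].
#' @param specificity Optional data.frame from [specificity_scores()]
#'   (`entity_id`, `score`); missing scores are treated as 0.
#' @param orthologs Optional ortholog table; when given, the per-species
#'   ortholog ids are attached to the output.
#' @return Data.frame with `circ_id`, `log2fc`, `specificity`, `rank`
#'   (and ortholog id columns when supplied), ordered by rank.
#' @export
select_candidates <- function(classes, de_calls, conserved_set,
                              specificity = NULL, orthologs = NULL) {
  se_ids <- classes$circ_id[classes$label == "SE-circRNA"]
  de_ids <- de_calls$circ_id[de_calls$is_de]
  ids <- intersect(intersect(se_ids, de_ids), conserved_set)
  spec <- if (is.null(specificity)) {
    stats::setNames(numeric(0), character(0))
  } else {
    stats::setNames(specificity$score, specificity$entity_id)
  }
  out <- data.frame(
    circ_id = ids,
    log2fc = de_calls$log2fc[match(ids, de_calls$circ_id)],
    specificity = ifelse(is.na(spec[ids]), 0, spec[ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-abs(out$log2fc), -out$specificity, out$circ_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(orthologs) && nrow(out) > 0L) {
    ix <- match(out$circ_id, orthologs[[1]])
    for (j in 2:3) out[[names(orthologs)[j]]] <- orthologs[[j]][ix]
  }
  rownames(out) <- NULL
  out
}
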