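#' Build a validated pipeline run configuration
#'
#' Collects input paths and every stage parameter into one list, applying
#' the package defaults for anything not supplied. All referenced files
#' must exist at validation time.
#'
#' @param peaks,circs,expression,orthologs,circ_fasta,mirna_fasta Input
#'   file paths (`orthologs`, `circ_fasta`, `mirna_fasta` optional).
#' @param se_by_stage Optional named character vector/list of two BED paths
#'   (one per stage) with super-enhancer intervals for the stage-overlap
#'   analysis.
#' @param ortholog_fastas Optional named list of FASTA paths with ortholog
#'   circle sequences per non-reference species (used for conserved
#'   seed-site counting).
#' @param out_dir Output directory.
#' @param stitch_window,tss_exclusion Stitching parameters (bp).
#' @param tss Optional BED path of TSS positions for the exclusion filter.
#' @param assignment_window Enhancer-to-promoter window (bp).
#' @param tau Specificity threshold in `[0, 1]`.
#' @param max_other_cover Stage-overlap threshold in `[0, 1]`.
#' @param stage_pair Two stage labels; fold change is stage 2 over stage 1.
#' @param fc_threshold,pseudocount Fold-change filter parameters.
#' @param shift_tolerance Conserved-site positional tolerance (nt).
#' @return A `secirc_run_config` list.
#' @export
run_config <- function(peaks, circs, expression, orthologs = NULL,
                       circ_fasta = NULL, mirna_fasta = NULL,
                       se_by_stage = NULL, ortholog_fastas = NULL,
                       out_dir = tempfile("secirc_run_"),
                       stitch_window = 12500, tss = NULL, tss_exclusion = 0,
                       assignment_window = 50000, tau = 0.8,
                       max_other_cover = 0.5,
                       stage_pair = c("embryonic", "adult"),
                       fc_threshold = 1.5, pseudocount = 0.1,
                       shift_tolerance = 2L) {
  cfg <- list(peaks = peaks, circs = circs, expression = expression,
              orthologs = orthologs, circ_fasta = circ_fasta,
              mirna_fasta = mirna_fasta, se_by_stage = se_by_stage,
              ortholog_fastas = ortholog_fastas, out_dir = out_dir,
              stitch_window = stitch_window, tss = tss,
              tss_exclusion = tss_exclusion,
              assignment_window = assignment_window, tau = tau,
              max_other_cover = max_other_cover,
              stage_pair = stage_pair, fc_threshold = fc_threshold,
              pseudocount = pseudocount,
              shift_tolerance = as.integer(shift_tolerance))
  required <- c("peaks", "circs", "expression")
  for (f in required) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("missing input file for '", f, "': ", cfg[[f]])
    }
  }
  optional <- c("orthologs", "circ_fasta", "mirna_fasta", "tss")
  for (f in optional) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("missing input file for '", f, "': ", cfg[[f]])
    }
  }
  for (f in unlist(cfg$se_by_stage)) {
    if (!file.exists(f)) stop("missing stage SE file: ", f)
  }
  for (f in unlist(cfg$ortholog_fastas)) {
    if (!file.exists(f)) stop("missing ortholog FASTA: ", f)
  }
  stopifnot(cfg$stitch_window >= 0, cfg$assignment_window >= 0,
            cfg$tau >= 0, cfg$tau <= 1,
            cfg$max_other_cover >= 0, cfg$max_other_cover <= 1,
            cfg$fc_threshold >= 1, cfg$pseudocount >= 0,
            length(cfg$stage_pair) == 2L, cfg$shift_tolerance >= 0)
  class(cfg) <- "secirc_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `secirc_run_config` list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  for (f in c("peaks", "circs", "expression", "orthologs", "circ_fasta",
              "mirna_fasta", "tss")) {
    raw[[f]] <- resolve(raw[[f]])
  }
  if (!is.null(raw$se_by_stage)) raw$se_by_stage <- lapply(raw$se_by_stage, resolve)
  if (!is.null(raw$ortholog_fastas)) raw$ortholog_fastas <- lapply(raw$ortholog_fastas, resolve)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw)
}

stage_step <- function(report, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  report$timings_sec[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(report = report, value = res)
}

#' Run the full SE-circRNA discovery pipeline
#'
#' Executes super-enhancer calling, enhancer-to-circRNA assignment,
#' specificity analysis, the fold-change and conservation filters,
#' candidate selection, and (when sequences are provided) the seed-site
#' scan, writing all stage outputs and a machine-readable JSON report into
#' the configured output directory. Any stage failure aborts with the
#' stage name and cause. All outputs are deterministic given the
#' configuration: the only randomness in the package lives in
#' [generate_dataset()].
#'
#' @param config A `secirc_run_config` from [run_config()] or
#'   [read_run_config()].
#' @return Invisibly, the run report (also written as `report.json`): per
#'   stage entity counts (which are non-increasing along the candidate
#'   funnel), the SE cutoff score, expression summaries, the parameter
#'   echo, and wall-clock seconds per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "secirc_run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("secirc")),
    params = cfg[setdiff(names(cfg), c("out_dir"))],
    counts = list(), timings_sec = list()
  )

  # --- super-enhancer calling ----------------------------------------
  st <- stage_step(report, "se_calling", function() {
    peaks <- read_bed(cfg$peaks)
    if (!"signal" %in% names(peaks)) stop("peaks file lacks a signal column")
    tss_points <- NULL
    if (!is.null(cfg$tss)) {
      tss_bed <- read_bed(cfg$tss)
      tss_points <- data.frame(chrom = tss_bed$chrom, pos = tss_bed$start)
    }
    regions <- call_superenhancers(
      peaks, stitch_window = cfg$stitch_window, tss_points = tss_points,
      tss_exclusion = cfg$tss_exclusion, out_dir = cfg$out_dir)
    list(peaks = peaks, regions = regions)
  })
  report <- st$report
  peaks <- st$value$peaks
  regions <- st$value$regions
  report$counts$peaks <- nrow(peaks)
  report$counts$stitched_regions <- nrow(regions)
  report$counts$superenhancers <- sum(regions$is_super)
  report$cutoff_score <- attr(regions, "cutoff_score")

  # --- enhancer -> circRNA assignment --------------------------------
  st <- stage_step(report, "association", function() {
    circs <- read_bed(cfg$circs)
    assignments <- assign_enhancers(regions, circs,
                                    window = cfg$assignment_window)
    classes <- classify_circs(assignments, circs)
    write.table(classes, file.path(cfg$out_dir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(circs = circs, assignments = assignments, classes = classes)
  })
  report <- st$report
  classes <- st$value$classes
  report$counts$circRNAs <- nrow(classes)
  report$counts$se_circRNAs <- sum(classes$label == "SE-circRNA")
  report$counts$te_circRNAs <- sum(classes$label == "TE-circRNA")

  # --- expression: specificity + class summary -----------------------
  st <- stage_step(report, "specificity", function() {
    expr <- read_expression_matrix(cfg$expression)
    spec <- specificity_scores(expr)
    spec$specific <- is_specific(spec$score, cfg$tau)
    out <- spec
    out$score <- format_num(out$score)
    write.table(out, file.path(cfg$out_dir, "specificity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary <- class_expression_summary(expr, classes)
    is_se <- classes$label[match(spec$entity_id, classes$circ_id)] == "SE-circRNA"
    tab <- rbind(c(sum(is_se & spec$specific), sum(is_se & !spec$specific)),
                 c(sum(!is_se & spec$specific), sum(!is_se & !spec$specific)))
    fisher <- fisher_association(tab)
    stage_spec <- NULL
    if (!is.null(cfg$se_by_stage)) {
      beds <- lapply(cfg$se_by_stage, read_bed)
      stage_spec <- stage_specific_ses(beds, cfg$max_other_cover)
    }
    list(expr = expr, spec = spec, summary = summary, fisher = fisher,
         stage_spec = stage_spec)
  })
  report <- st$report
  expr <- st$value$expr
  spec <- st$value$spec
  report$class_median_rpm <- as.list(st$value$summary$medians)
  report$se_vs_te_rank_sum_p <- st$value$summary$p_value
  report$se_specificity_fisher <- st$value$fisher
  if (!is.null(st$value$stage_spec)) {
    report$stage_specific_ses <- lapply(st$value$stage_spec,
                                        function(df) sum(df$specific))
  }

  # --- fold change + conservation + candidates -----------------------
  st <- stage_step(report, "candidates", function() {
    de <- fold_change_filter(expr, cfg$stage_pair,
                             fc_threshold = cfg$fc_threshold,
                             pseudocount = cfg$pseudocount)
    out_de <- de
    for (col in c("mean_rpm_stage1", "mean_rpm_stage2", "fold_change", "log2fc")) {
      out_de[[col]] <- format_num(out_de[[col]])
    }
    write.table(out_de, file.path(cfg$out_dir, "de_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    orth <- NULL
    conserved <- de$circ_id  # no ortholog table: conservation not restrictive
    if (!is.null(cfg$orthologs)) {
      orth <- read_orthologs(cfg$orthologs)
      conserved <- conservation_filter(de$circ_id, orth)
    }
    cand <- select_candidates(classes, de, conserved, specificity = spec,
                              orthologs = orth)
    out_cand <- cand
    out_cand$log2fc <- format_num(out_cand$log2fc)
    out_cand$specificity <- format_num(out_cand$specificity)
    write.table(out_cand, file.path(cfg$out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(de = de, conserved = conserved, cand = cand)
  })
  report <- st$report
  cand <- st$value$cand
  report$counts$de_circRNAs <- sum(st$value$de$is_de)
  report$counts$conserved <- length(st$value$conserved)
  report$counts$candidates <- nrow(cand)

  # --- seed-site scan -------------------------------------------------
  if (!is.null(cfg$circ_fasta) && !is.null(cfg$mirna_fasta)) {
    st <- stage_step(report, "seed_scan", function() {
      circ_seqs <- read_fasta(cfg$circ_fasta)
      mirna_seqs <- read_fasta(cfg$mirna_fasta)
      sites <- scan_seed_sites(circ_seqs, mirna_seqs)
      write.table(sites, file.path(cfg$out_dir, "seed_sites.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      conserved_counts <- NULL
      if (!is.null(cfg$ortholog_fastas) && !is.null(cfg$orthologs) &&
          nrow(cand) > 0L) {
        orth <- read_orthologs(cfg$orthologs)
        oseqs <- lapply(cfg$ortholog_fastas, read_fasta)
        conserved_counts <- list()
        for (i in seq_len(nrow(cand))) {
          id <- cand$circ_id[i]
          row <- orth[match(id, orth[[1]]), ]
          if (anyNA(row)) next
          seqs <- c(circ_seqs[id],
                    stats::setNames(
                      vapply(seq_along(oseqs),
                             function(k) oseqs[[k]][[row[[k + 1L]]]],
                             character(1)),
                      unlist(row[-1L])))
          per_mirna <- vapply(names(mirna_seqs), function(mi) {
            sp_sites <- lapply(names(seqs), function(s) {
              find_seed_sites(seqs[[s]], mirna_seqs[[mi]],
                              circ_id = s, mirna_id = mi)
            })
            names(sp_sites) <- names(seqs)
            count_conserved_sites(sp_sites, seqs,
                                  shift_tolerance = cfg$shift_tolerance)
          }, integer(1))
          conserved_counts[[id]] <- as.list(per_mirna)
        }
      }
      list(n_sites = nrow(sites), conserved_counts = conserved_counts)
    })
    report <- st$report
    report$counts$seed_sites <- st$value$n_sites
    if (!is.null(st$value$conserved_counts)) {
      report$conserved_site_counts <- st$value$conserved_counts
    }
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
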