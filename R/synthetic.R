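# Fixed synthetic miRNAs. Seeds are chosen so that neither seed core is
# periodic and neither core is contained in the other's planted site
# string, which keeps planted sites scrubbable and unambiguous.
SYNTH_MIRNAS <- c(
  "synmiR-1" = "UACGAUCGAAGCUGCCAUGGAU",
  "synmiR-2" = "UGGCAUACCGUUAAGCCAUGAU"
)

# Genome layout constants: one entity (typical peak / planted SE cluster /
# lone circRNA / embryonic-only SE) per bin, content confined to a central
# zone so that cross-bin distances exceed both the stitching window and the
# enhancer-assignment window. This isolation is what makes the planted
# labels exact under noiseless placement.
SYNTH_BIN_WIDTH <- 140000
SYNTH_ZONE_OFFSET <- 40000
SYNTH_ZONE_WIDTH <- 60000

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the reference desk-scale dataset: 500 typical enhancer
#' peaks with LogNormal(0, 1) signal, 25 planted super-enhancer clusters
#' (3-5 peaks within one stitching window, signal scaled by the multiplier),
#' 120 circRNAs across 5 tissues and 2 developmental stages, planted
#' 2-fold stage changes, and 10 fully conserved SE + DE candidates, under
#' seed 42.
#'
#' @param n_chromosomes,chrom_length Genome shape (bp).
#' @param n_enhancer_peaks Number of typical enhancer peaks.
#' @param n_planted_SE_clusters Number of planted super-enhancer clusters.
#' @param SE_signal_multiplier Signal scale factor (> 1) for planted SE
#'   peaks.
#' @param n_circRNAs Total circRNAs.
#' @param n_tissues Number of tissues (first tissue is the focal one the
#'   planted SE-circRNAs are specific to).
#' @param stages Exactly two stage labels (fold change is stage 2 over
#'   stage 1).
#' @param n_replicates Replicates per tissue/stage.
#' @param planted_DE_fold Planted stage-mean fold change (>= 1).
#' @param rpm_noise_cv Coefficient of variation of multiplicative
#'   log-normal RPM noise; 0 gives the exact noiseless mode.
#' @param n_planted_candidates Number of planted SE+DE+conserved
#'   candidates.
#' @param circ_seq_length Length (nt) of each circular sequence.
#' @param substitution_rate Per-base substitution rate used to derive the
#'   pseudo-species ortholog sequences (default 0.02, which keeps identity
#'   at 95% or higher).
#' @param seed Integer RNG seed; sub-streams are derived by fixed offsets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_chromosomes = 2L,
                         chrom_length = 45e6,
                         n_enhancer_peaks = 500L,
                         n_planted_SE_clusters = 25L,
                         SE_signal_multiplier = 20,
                         n_circRNAs = 120L,
                         n_tissues = 5L,
                         stages = c("embryonic", "adult"),
                         n_replicates = 3L,
                         planted_DE_fold = 2,
                         rpm_noise_cv = 0.2,
                         n_planted_candidates = 10L,
                         circ_seq_length = 400L,
                         substitution_rate = 0.02,
                         seed = 42L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_enhancer_peaks = as.integer(n_enhancer_peaks),
              n_planted_SE_clusters = as.integer(n_planted_SE_clusters),
              SE_signal_multiplier = SE_signal_multiplier,
              n_circRNAs = as.integer(n_circRNAs),
              n_tissues = as.integer(n_tissues),
              stages = stages,
              n_replicates = as.integer(n_replicates),
              planted_DE_fold = planted_DE_fold,
              rpm_noise_cv = rpm_noise_cv,
              n_planted_candidates = as.integer(n_planted_candidates),
              circ_seq_length = as.integer(circ_seq_length),
              substitution_rate = substitution_rate,
              seed = as.integer(seed))
  counts <- c("n_chromosomes", "n_enhancer_peaks", "n_planted_SE_clusters",
              "n_circRNAs", "n_tissues", "n_replicates",
              "n_planted_candidates", "circ_seq_length")
  for (f in counts) if (cfg[[f]] < 0L) stop("negative count: ", f)
  if (cfg$SE_signal_multiplier <= 1) stop("SE_signal_multiplier must be > 1")
  if (cfg$planted_DE_fold < 1) stop("planted_DE_fold must be >= 1")
  if (length(cfg$stages) != 2L) stop("exactly two stage labels required")
  if (cfg$chrom_length <= 10 * 12500) {
    stop("chrom_length must exceed 10x the stitching window")
  }
  if (cfg$n_circRNAs == 0L && cfg$n_planted_candidates > 0L) {
    stop("degenerate config: planted candidates without circRNAs")
  }
  if (cfg$n_planted_candidates > min(cfg$n_planted_SE_clusters, cfg$n_circRNAs)) {
    stop("n_planted_candidates cannot exceed the planted SE-circRNA count")
  }
  if (cfg$rpm_noise_cv < 0) stop("rpm_noise_cv must be >= 0")
  if (cfg$substitution_rate < 0 || cfg$substitution_rate > 0.05) {
    stop("substitution_rate must be in [0, 0.05] to keep identity >= 95%")
  }
  if (cfg$circ_seq_length < 30L && cfg$n_circRNAs > 0L) {
    stop("circ_seq_length too short to plant seed sites")
  }
  class(cfg) <- "synth_config"
  cfg
}

synth_tissues <- function(n) {
  base <- c("heart", "brain", "lung", "liver", "colon")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("tissue", seq_len(n - length(base))))
}

# deterministic sub-stream seeding (documented fixed offsets)
synth_seed <- function(cfg, offset) {
  set.seed((cfg$seed %% 1000000L) * 1000L + offset)
}

mutate_base <- function(ch) {
  bases <- c("A", "C", "G", "T")
  bases[(match(ch, bases) %% 4L) + 1L]
}

# write a site string into the circle (char vector), modular positions
plant_site_chars <- function(cs, mirna, class, pos) {
  L <- length(cs)
  m <- normalize_seq(mirna)
  site7 <- revcomp(substr(m, 2L, 8L))
  core6 <- revcomp(substr(m, 2L, 7L))
  m8c <- chartr("ACGT", "TGCA", substr(m, 8L, 8L))
  put <- function(p, chars) {
    idx <- ((p + seq_along(chars) - 1L) %% L) + 1L
    cs[idx] <<- chars
  }
  sp <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  if (class == "8mer") {
    put(pos, sp(paste0(site7, "A")))
  } else if (class == "7mer-m8") {
    put(pos, sp(site7))
    nxt <- (pos + 7L) %% L
    if (cs[nxt + 1L] == "A") cs[nxt + 1L] <- "C"
  } else if (class == "7mer-A1") {
    put(pos, sp(paste0(core6, "A")))
    prv <- (pos - 1L) %% L
    if (cs[prv + 1L] == m8c) cs[prv + 1L] <- mutate_base(m8c)
  } else {
    stop("unsupported planted class: ", class)
  }
  cs
}

site_footprint <- function(pos, class, L) {
  ((pos + seq_len(SITE_LENGTHS[[class]]) - 1L) %% L)
}

# remove chance seed-core matches from a circle, leaving planted sites
# untouched; independent of the scanner (works on the doubled string)
scrub_cores <- function(cs, planted, mirnas) {
  L <- length(cs)
  protected <- unique(unlist(lapply(seq_len(nrow(planted)), function(i) {
    site_footprint(planted$position[i], planted$site_class[i], L)
  })))
  allowed_core_starts <- lapply(stats::setNames(names(mirnas), names(mirnas)), function(mi) {
    rows <- planted[planted$mirna_id == mi, , drop = FALSE]
    if (nrow(rows) == 0L) return(integer(0))
    ifelse(rows$site_class %in% c("8mer", "7mer-m8"),
           (rows$position + 1L) %% L, rows$position)
  })
  for (iter in 1:100) {
    dirty <- FALSE
    doubled <- paste(c(cs, cs[seq_len(min(5L, L))]), collapse = "")
    for (mi in names(mirnas)) {
      core <- revcomp(substr(normalize_seq(mirnas[[mi]]), 2L, 7L))
      hits <- gregexpr(core, doubled, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      starts <- (as.integer(hits) - 1L)
      starts <- unique(starts[starts < L] %% L)
      starts <- setdiff(starts, allowed_core_starts[[mi]])
      for (p in starts) {
        idx <- ((p + 0:5) %% L)
        free <- setdiff(idx, protected)
        if (length(free) == 0L) {
          stop("cannot scrub chance seed core overlapping planted sites")
        }
        tgt <- free[[min(3L, length(free))]]
        cs[tgt + 1L] <- mutate_base(cs[tgt + 1L])
        dirty <- TRUE
      }
    }
    if (!dirty) return(cs)
  }
  stop("seed-core scrubbing did not converge")
}

#' Generate a complete synthetic dataset with a planted-truth ledger
#'
#' Writes every input the SE-circRNA pipeline consumes — enhancer peaks
#' with signal (BED6+signal), circRNA spans (BED6), an RPM expression
#' matrix over tissues x stages x replicates, a three-pseudo-species
#' ortholog table, circle and miRNA FASTA files, per-stage super-enhancer
#' interval sets — plus a JSON truth ledger naming every planted entity.
#'
#' Planted structure: typical peak signal is LogNormal(0, 1); each planted
#' SE cluster has 3-5 peaks within one stitching window with signal
#' `SE_signal_multiplier * (1 + LogNormal(0, 1))` per peak, so every planted
#' cluster outscores every typical stitched region once the multiplier is
#' large. One circRNA promoter is placed within the assignment window of
#' each planted cluster (these are the planted SE-circRNAs, expressed
#' specifically in the first tissue); planted DE circRNAs have a
#' stage-mean RPM ratio equal to `planted_DE_fold` before noise; planted
#' candidates (SE and DE and conserved) carry three planted miRNA seed
#' sites, one spanning the back-splice junction. Chance seed-core matches
#' are scrubbed from background sequence so the ledger is the exact
#' scannable truth. Identical config and seed reproduce every file
#' byte-for-byte.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `ledger`
#'   (the planted truth) and `config`.
#' @export
generate_dataset <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".secirc_write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", out_dir)
  unlink(probe)

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  bins_per_chrom <- floor(cfg$chrom_length / SYNTH_BIN_WIDTH)
  n_bins <- cfg$n_chromosomes * bins_per_chrom

  n_se_circ <- min(cfg$n_planted_SE_clusters, cfg$n_circRNAs)
  n_te_circ <- min(25L, max(cfg$n_circRNAs - n_se_circ, 0L), cfg$n_enhancer_peaks)
  n_other_circ <- cfg$n_circRNAs - n_se_circ - n_te_circ
  shared_se <- floor(cfg$n_planted_SE_clusters * 0.4)
  n_emb_only <- cfg$n_planted_SE_clusters - shared_se
  n_needed <- cfg$n_enhancer_peaks + cfg$n_planted_SE_clusters +
    n_other_circ + n_emb_only
  if (n_needed > n_bins) {
    stop(sprintf("genome too small: %d layout bins needed, %d available; increase chrom_length or n_chromosomes",
                 n_needed, n_bins))
  }

  synth_seed(cfg, 1L)  # layout stream
  bin_order <- sample.int(n_bins, n_needed)
  bin_chrom <- chroms[(bin_order - 1L) %/% bins_per_chrom + 1L]
  bin_start <- ((bin_order - 1L) %% bins_per_chrom) * SYNTH_BIN_WIDTH
  zone <- function(k) bin_start[k] + SYNTH_ZONE_OFFSET
  take <- local({ used <- 0L; function(n) { ix <- used + seq_len(n); used <<- used + n; ix } })
  bins_typ <- take(cfg$n_enhancer_peaks)
  bins_se <- take(cfg$n_planted_SE_clusters)
  bins_other <- take(n_other_circ)
  bins_emb <- take(n_emb_only)

  # --- enhancer peaks -------------------------------------------------
  peaks <- list()
  if (cfg$n_enhancer_peaks > 0L) {
    w <- round(runif(cfg$n_enhancer_peaks, 800, 1200))
    off <- round(runif(cfg$n_enhancer_peaks, 0, 5000))
    peaks[["typ"]] <- data.frame(
      chrom = bin_chrom[bins_typ],
      start = zone(bins_typ) + off,
      end = zone(bins_typ) + off + w,
      id = sprintf("peak_%04d", seq_len(cfg$n_enhancer_peaks)),
      strand = ".",
      planted_se = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  se_regions <- NULL
  if (cfg$n_planted_SE_clusters > 0L) {
    cl <- list()
    for (s in seq_len(cfg$n_planted_SE_clusters)) {
      k <- sample(3:5, 1L)
      wid <- round(runif(k, 800, 1200))
      gap <- round(runif(k, 1500, 2500))  # gap[k] unused
      origin <- zone(bins_se[s]) + round(runif(1, 0, 2000))
      starts <- origin + cumsum(c(0, utils::head(wid + gap, -1L)))
      cl[[s]] <- data.frame(
        chrom = bin_chrom[bins_se[s]],
        start = starts, end = starts + wid,
        id = sprintf("sepeak_%02d_%d", s, seq_len(k)),
        strand = ".",
        planted_se = sprintf("plantedSE_%02d", s),
        stringsAsFactors = FALSE
      )
    }
    peaks[["se"]] <- do.call(rbind, cl)
    se_regions <- do.call(rbind, lapply(seq_along(cl), function(s) {
      data.frame(region_id = sprintf("plantedSE_%02d", s),
                 chrom = cl[[s]]$chrom[1L],
                 start = min(cl[[s]]$start), end = max(cl[[s]]$end),
                 stringsAsFactors = FALSE)
    }))
  }
  peaks <- if (length(peaks) > 0) do.call(rbind, peaks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), strand = character(),
               planted_se = character(), stringsAsFactors = FALSE)
  rownames(peaks) <- NULL

  synth_seed(cfg, 2L)  # signal stream
  is_se_peak <- !is.na(peaks$planted_se)
  signal <- numeric(nrow(peaks))
  signal[!is_se_peak] <- rlnorm(sum(!is_se_peak), 0, 1)
  signal[is_se_peak] <- cfg$SE_signal_multiplier * (1 + rlnorm(sum(is_se_peak), 0, 1))
  peaks$signal <- signal

  # --- circRNAs -------------------------------------------------------
  synth_seed(cfg, 3L)  # circ placement stream
  circ_ids <- sprintf("spA_circ_%07d", seq_len(cfg$n_circRNAs))
  se_circ_ids <- circ_ids[seq_len(n_se_circ)]
  te_circ_ids <- if (n_te_circ > 0L) circ_ids[n_se_circ + seq_len(n_te_circ)] else character(0)
  other_circ_ids <- if (n_other_circ > 0L) circ_ids[n_se_circ + n_te_circ + seq_len(n_other_circ)] else character(0)

  circs <- NULL
  if (cfg$n_circRNAs > 0L) {
    rows <- list()
    if (n_se_circ > 0L) {
      anchor_end <- vapply(seq_len(n_se_circ), function(s) se_regions$end[s], numeric(1))
      prom <- anchor_end + round(runif(n_se_circ, 5000, 20000))
      rows[["se"]] <- data.frame(
        chrom = se_regions$chrom[seq_len(n_se_circ)],
        start = prom, end = prom + round(runif(n_se_circ, 5000, 15000)),
        id = se_circ_ids, strand = "+", stringsAsFactors = FALSE)
    }
    if (n_te_circ > 0L) {
      # anchor TE-circRNAs to the lowest-signal typical peaks: those can
      # never drift above the rank-curve cutoff, so the planted TE labels
      # stay exact even when an extreme typical peak is called super
      typ <- peaks[!is_se_peak, ]
      host <- typ[order(typ$signal)[seq_len(n_te_circ)], ]
      prom <- host$end + round(runif(n_te_circ, 5000, 20000))
      rows[["te"]] <- data.frame(
        chrom = host$chrom, start = prom,
        end = prom + round(runif(n_te_circ, 5000, 15000)),
        id = te_circ_ids, strand = "+", stringsAsFactors = FALSE)
    }
    if (n_other_circ > 0L) {
      prom <- zone(bins_other) + round(runif(n_other_circ, 0, 5000))
      rows[["other"]] <- data.frame(
        chrom = bin_chrom[bins_other], start = prom,
        end = prom + round(runif(n_other_circ, 5000, 15000)),
        id = other_circ_ids, strand = "+", stringsAsFactors = FALSE)
    }
    circs <- do.call(rbind, rows)
    rownames(circs) <- NULL
  }

  # --- planted DE / candidate sets ------------------------------------
  n_cand <- min(cfg$n_planted_candidates, n_se_circ)
  candidate_ids <- se_circ_ids[seq_len(n_cand)]
  n_de_nonse <- min(n_cand, n_te_circ + n_other_circ)
  de_nonse_ids <- utils::head(c(other_circ_ids, te_circ_ids), n_de_nonse)
  de_ids <- c(candidate_ids, de_nonse_ids)
  de_dir <- rep(c(1, -1), length.out = length(de_ids))  # up/down alternation

  conserved_ids <- unique(c(
    candidate_ids,
    se_circ_ids[seq_len(min(n_se_circ, n_cand + 5L))][-seq_len(n_cand)],
    utils::head(setdiff(te_circ_ids, de_ids), 5L),
    utils::head(setdiff(other_circ_ids, de_ids), 10L)
  ))
  # conserved non-SE DE circRNAs exercise the funnel: DE + conserved but
  # not SE-associated, hence excluded from the candidates
  conserved_ids <- unique(c(conserved_ids, de_nonse_ids))
  incomplete_ids <- utils::head(setdiff(circ_ids, conserved_ids), 6L)

  # --- expression matrix ----------------------------------------------
  synth_seed(cfg, 4L)  # expression stream
  tissues <- synth_tissues(cfg$n_tissues)
  samples <- expand.grid(rep = seq_len(cfg$n_replicates), stage = cfg$stages,
                         tissue = tissues, stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "stage", "rep")]
  sample_ids <- sprintf("%s:%s:%d", samples$tissue, samples$stage, samples$rep)
  expr_paths <- NULL
  values <- NULL
  if (cfg$n_circRNAs > 0L && cfg$n_tissues > 0L) {
    base_scale <- rlnorm(cfg$n_circRNAs, 0, 0.25)
    mean_tissue <- matrix(2, nrow = cfg$n_circRNAs, ncol = cfg$n_tissues,
                          dimnames = list(circ_ids, tissues))
    mean_tissue[te_circ_ids, ] <- 6
    mean_tissue[se_circ_ids, ] <- 1
    mean_tissue[se_circ_ids, 1L] <- 50
    mean_tissue <- mean_tissue * base_scale
    fold_fac <- stats::setNames(rep(1, cfg$n_circRNAs), circ_ids)
    fold_fac[de_ids] <- ifelse(de_dir > 0, cfg$planted_DE_fold,
                               1 / cfg$planted_DE_fold)
    sigma <- if (cfg$rpm_noise_cv > 0) sqrt(log(1 + cfg$rpm_noise_cv^2)) else 0
    values <- matrix(0, nrow = cfg$n_circRNAs, ncol = length(sample_ids),
                     dimnames = list(circ_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      m <- mean_tissue[, samples$tissue[j]]
      if (samples$stage[j] == cfg$stages[2L]) m <- m * fold_fac
      noise <- if (sigma > 0) exp(rnorm(cfg$n_circRNAs, -sigma^2 / 2, sigma)) else 1
      values[, j] <- m * noise
    }
  }

  # --- sequences ------------------------------------------------------
  synth_seed(cfg, 5L)  # sequence stream
  L <- cfg$circ_seq_length
  planted_sites <- data.frame(circ_id = character(), mirna_id = character(),
                              position = integer(), site_class = character(),
                              spans_junction = logical(), stringsAsFactors = FALSE)
  circ_seqs <- character(0)
  if (cfg$n_circRNAs > 0L) {
    bases <- c("A", "C", "G", "T")
    seq_chars <- lapply(seq_len(cfg$n_circRNAs),
                        function(i) sample(bases, L, replace = TRUE))
    names(seq_chars) <- circ_ids
    plan <- list()
    for (id in candidate_ids) {
      plan[[length(plan) + 1L]] <- data.frame(
        circ_id = id, mirna_id = "synmiR-1",
        position = as.integer(c(L - 4L, round(L * 0.25), round(L * 0.62))),
        site_class = c("7mer-m8", "8mer", "7mer-m8"),
        stringsAsFactors = FALSE)
    }
    for (id in utils::head(other_circ_ids, 3L)) {
      plan[[length(plan) + 1L]] <- data.frame(
        circ_id = id, mirna_id = "synmiR-2",
        position = as.integer(round(L * 0.4)), site_class = "7mer-A1",
        stringsAsFactors = FALSE)
    }
    if (length(plan) > 0L) {
      planted_sites <- do.call(rbind, plan)
      planted_sites$spans_junction <-
        planted_sites$position + SITE_LENGTHS[planted_sites$site_class] > L
    }
    for (id in circ_ids) {
      rows <- planted_sites[planted_sites$circ_id == id, , drop = FALSE]
      cs <- seq_chars[[id]]
      for (i in seq_len(nrow(rows))) {
        cs <- plant_site_chars(cs, SYNTH_MIRNAS[[rows$mirna_id[i]]],
                               rows$site_class[i], rows$position[i])
      }
      cs <- scrub_cores(cs, rows, SYNTH_MIRNAS)
      seq_chars[[id]] <- cs
    }
    circ_seqs <- vapply(seq_chars, paste, character(1), collapse = "")
  }

  # --- pseudo-species orthologs ---------------------------------------
  synth_seed(cfg, 6L)  # ortholog stream
  orth_rows <- data.frame(spA_id = character(), spB_id = character(),
                          spC_id = character(), stringsAsFactors = FALSE)
  orth_seqs <- list(spB = character(0), spC = character(0))
  if (length(conserved_ids) > 0L || length(incomplete_ids) > 0L) {
    idx <- match(conserved_ids, circ_ids)
    orth_rows <- data.frame(
      spA_id = conserved_ids,
      spB_id = sprintf("spB_circ_%07d", idx),
      spC_id = sprintf("spC_circ_%07d", idx),
      stringsAsFactors = FALSE)
    if (length(incomplete_ids) > 0L) {
      iidx <- match(incomplete_ids, circ_ids)
      drop_b <- seq_along(incomplete_ids) %% 2L == 0L
      orth_rows <- rbind(orth_rows, data.frame(
        spA_id = incomplete_ids,
        spB_id = ifelse(drop_b, NA_character_, sprintf("spB_circ_%07d", iidx)),
        spC_id = ifelse(drop_b, sprintf("spC_circ_%07d", iidx), NA_character_),
        stringsAsFactors = FALSE))
    }
    mutate_seq <- function(id) {
      cs <- strsplit(circ_seqs[[id]], "", fixed = TRUE)[[1]]
      rows <- planted_sites[planted_sites$circ_id == id, , drop = FALSE]
      protected <- unique(unlist(lapply(seq_len(nrow(rows)), function(i) {
        site_footprint(rows$position[i], rows$site_class[i], length(cs))
      })))
      free <- setdiff(seq_along(cs) - 1L, protected)
      n_sub <- round(cfg$substitution_rate * length(free))
      if (n_sub > 0L) {
        tgt <- sample(free, n_sub)
        cs[tgt + 1L] <- vapply(cs[tgt + 1L], mutate_base, character(1))
      }
      cs <- scrub_cores(cs, rows, SYNTH_MIRNAS)
      paste(cs, collapse = "")
    }
    orth_seqs$spB <- stats::setNames(vapply(conserved_ids, mutate_seq, character(1)),
                                     orth_rows$spB_id[match(conserved_ids, orth_rows$spA_id)])
    orth_seqs$spC <- stats::setNames(vapply(conserved_ids, mutate_seq, character(1)),
                                     orth_rows$spC_id[match(conserved_ids, orth_rows$spA_id)])
  }

  # --- per-stage super-enhancer interval sets -------------------------
  stage_se <- list()
  adult_bed <- if (is.null(se_regions)) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), strand = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = se_regions$chrom, start = se_regions$start,
               end = se_regions$end, id = se_regions$region_id,
               strand = ".", stringsAsFactors = FALSE)
  }
  emb_bed <- adult_bed[seq_len(min(shared_se, nrow(adult_bed))), , drop = FALSE]
  if (n_emb_only > 0L) {
    emb_extra <- data.frame(
      chrom = bin_chrom[bins_emb],
      start = zone(bins_emb), end = zone(bins_emb) + 8000,
      id = sprintf("embSE_%02d", seq_len(n_emb_only)),
      strand = ".", stringsAsFactors = FALSE)
    emb_bed <- rbind(emb_bed, emb_extra)
  }
  stage_se[[cfg$stages[1L]]] <- emb_bed
  stage_se[[cfg$stages[2L]]] <- adult_bed

  # --- write files ----------------------------------------------------
  paths <- list(
    peaks = file.path(out_dir, "peaks.bed"),
    circs = file.path(out_dir, "circs.bed"),
    expression = file.path(out_dir, "expression.tsv"),
    orthologs = file.path(out_dir, "orthologs.tsv"),
    circ_fasta = file.path(out_dir, "circ_sequences.fa"),
    mirna_fasta = file.path(out_dir, "mirnas.fa"),
    orth_fasta_spB = file.path(out_dir, "orthologs_spB.synthetic.fa"),
    orth_fasta_spC = file.path(out_dir, "orthologs_spC.synthetic.fa"),
    se_stage1 = file.path(out_dir, sprintf("se_by_stage_%s.bed", cfg$stages[1L])),
    se_stage2 = file.path(out_dir, sprintf("se_by_stage_%s.bed", cfg$stages[2L])),
    ledger = file.path(out_dir, "truth_ledger.json")
  )
  write_bed(peaks[, c("chrom", "start", "end", "id", "strand", "signal")],
            paths$peaks)
  if (!is.null(circs)) write_bed(circs, paths$circs) else
    write_bed(data.frame(chrom = character(), start = numeric(),
                         end = numeric()), paths$circs)
  if (!is.null(values)) {
    write_expression_matrix(values, paths$expression)
  } else {
    writeLines(paste(c("circ_id", sample_ids), collapse = "\t"), paths$expression)
  }
  write_orthologs(orth_rows, paths$orthologs)
  write_fasta(circ_seqs, paths$circ_fasta)
  write_fasta(SYNTH_MIRNAS, paths$mirna_fasta)
  write_fasta(orth_seqs$spB, paths$orth_fasta_spB)
  write_fasta(orth_seqs$spC, paths$orth_fasta_spC)
  write_bed(stage_se[[cfg$stages[1L]]], paths$se_stage1)
  write_bed(stage_se[[cfg$stages[2L]]], paths$se_stage2)

  ledger <- list(
    planted_SE_region_ids = if (is.null(se_regions)) character(0) else se_regions$region_id,
    planted_SE_regions = se_regions,
    planted_SE_circ_ids = se_circ_ids,
    planted_TE_circ_ids = te_circ_ids,
    planted_DE_circ_ids = de_ids,
    planted_candidate_ids = candidate_ids,
    conserved_circ_ids = conserved_ids,
    planted_seed_sites = planted_sites,
    circle_length = L,
    seed = cfg$seed
  )
  jsonlite::write_json(ledger, paths$ledger, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(list(paths = paths, ledger = ledger, config = cfg))
}
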