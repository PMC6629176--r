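SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
SITE_LENGTHS <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

normalize_seq <- function(seq) chartr("U", "T", toupper(seq))

#' Extend a circular sequence for linear scanning
#'
#' Returns `seq` followed by its first `probe_len - 1` bases, so a linear
#' scan of the result with a probe of length `probe_len` finds every
#' circular occurrence — including sites spanning the back-splice junction —
#' exactly once, with positions reported modulo the circle length.
#'
#' @param seq Circle sequence.
#' @param probe_len Probe length, `1 <= probe_len <= nchar(seq)`.
#' @return Extended linear sequence.
#' @export
circularize <- function(seq, probe_len) {
  L <- nchar(seq)
  if (probe_len < 1 || probe_len > L) {
    stop("probe_len must be between 1 and the circle length")
  }
  paste0(seq, substr(seq, 1L, probe_len - 1L))
}

#' Scan a circular RNA for canonical miRNA seed sites
#'
#' TargetScan-style site classes on the circle (positions are 0-based on
#' the canonical rotation, modulo the circle length):
#' the core is a perfect match to the reverse complement of miRNA positions
#' 2-7; `7mer-m8` adds a match to miRNA position 8 on the 5' side of the
#' core (on the target); `7mer-A1` instead has an `A` opposite miRNA
#' position 1 on the 3' side; `8mer` has both; `6mer` neither. Each circle
#' position is reported once with its strongest class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer), and sites crossing the back-splice
#' junction are flagged. The reported position is the 5'-most target base
#' of the site.
#'
#' @param circ_seq Circle sequence (ACGT/U).
#' @param mirna_seq miRNA sequence, 5'->3', at least 8 nt.
#' @param circ_id,mirna_id Optional identifiers copied into the output.
#' @return Data.frame with `circ_id`, `mirna_id`, `position`, `site_class`,
#'   `spans_junction`, sorted by position.
#' @export
find_seed_sites <- function(circ_seq, mirna_seq, circ_id = NA_character_,
                            mirna_id = NA_character_) {
  circ <- normalize_seq(circ_seq)
  mir <- normalize_seq(mirna_seq)
  if (nchar(mir) < 8L) stop("miRNA sequence must be at least 8 nt")
  L <- nchar(circ)
  empty <- data.frame(circ_id = character(), mirna_id = character(),
                      position = integer(), site_class = character(),
                      spans_junction = logical(), stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  core <- revcomp(substr(mir, 2L, 7L))              # matches miRNA 2-7
  m8c <- chartr("ACGT", "TGCA", substr(mir, 8L, 8L)) # complement of position 8
  cs <- strsplit(circ, "", fixed = TRUE)[[1]]
  at <- function(i) cs[(i %% L) + 1L]               # 0-based circular index
  core_chars <- strsplit(core, "", fixed = TRUE)[[1]]
  hit <- rep(TRUE, L)
  for (k in 0:5) hit <- hit & (at(seq_len(L) - 1L + k) == core_chars[k + 1L])
  j <- which(hit) - 1L                              # 0-based core starts
  if (length(j) == 0L) return(empty)
  m8 <- at(j - 1L) == m8c
  a1 <- at(j + 6L) == "A"
  cls <- ifelse(m8 & a1, "8mer",
                ifelse(m8, "7mer-m8", ifelse(a1, "7mer-A1", "6mer")))
  pos <- ifelse(m8, (j - 1L) %% L, j)
  len <- SITE_LENGTHS[cls]
  out <- data.frame(circ_id = circ_id, mirna_id = mirna_id,
                    position = as.integer(pos), site_class = cls,
                    spans_junction = pos + len > L,
                    stringsAsFactors = FALSE)
  # one site per circle position: keep the strongest class
  out <- out[order(out$position, match(out$site_class, SITE_CLASSES)), , drop = FALSE]
  out <- out[!duplicated(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many circles against many miRNAs
#'
#' @param circ_seqs Named character vector of circle sequences.
#' @param mirna_seqs Named character vector of miRNA sequences.
#' @return Row-bound [find_seed_sites()] results.
#' @export
scan_seed_sites <- function(circ_seqs, mirna_seqs) {
  res <- list()
  for (ci in names(circ_seqs)) {
    for (mi in names(mirna_seqs)) {
      res[[paste(ci, mi)]] <- find_seed_sites(circ_seqs[[ci]], mirna_seqs[[mi]],
                                              circ_id = ci, mirna_id = mi)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count seed sites conserved across species
#'
#' A reference-species site of class 7mer or stronger is conserved when
#' every other species carries a site of class >= 7mer for the same miRNA
#' whose position — transferred through the pairwise global alignment
#' column map ([alignment_column_map()]) — lies within `shift_tolerance`
#' nucleotides of the reference site's aligned position.
#'
#' @param sites Named list of site data.frames (from [find_seed_sites()]),
#'   one per species; the first entry is the reference species.
#' @param seqs Named character vector of the species' circle sequences
#'   (same names as `sites`), used to compute the alignment maps.
#' @param shift_tolerance Allowed positional shift in nt (default 2).
#' @return Integer: number of conserved reference sites.
#' @export
count_conserved_sites <- function(sites, seqs, shift_tolerance = 2L) {
  stopifnot(length(sites) >= 2L, all(names(sites) %in% names(seqs)))
  strong <- c("8mer", "7mer-m8", "7mer-A1")
  sp <- names(sites)
  ref <- sites[[1L]]
  ref <- ref[ref$site_class %in% strong, , drop = FALSE]
  if (nrow(ref) == 0L) return(0L)
  n_cons <- 0L
  maps <- lapply(sp[-1L], function(s) alignment_column_map(seqs[[sp[1L]]], seqs[[s]]))
  names(maps) <- sp[-1L]
  for (i in seq_len(nrow(ref))) {
    ok <- TRUE
    for (s in sp[-1L]) {
      other <- sites[[s]]
      other <- other[other$site_class %in% strong &
                       other$mirna_id %in% ref$mirna_id[i], , drop = FALSE]
      mapped <- maps[[s]][ref$position[i] + 1L]
      if (nrow(other) == 0L ||
          !any(abs(other$position - mapped) <= shift_tolerance)) {
        ok <- FALSE
        break
      }
    }
    if (ok) n_cons <- n_cons + 1L
  }
  n_cons
}
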