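#' Read a BED file of genomic intervals
#'
#' Coordinates follow BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Columns beyond 6 are ignored except a numeric
#' seventh column, which is interpreted as a per-region signal density (as
#' written by [generate_dataset()] and consumed by [call_superenhancers()]).
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a BED3/BED6(+signal) file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `id`, `strand`
#'   and, when present in the file, `signal`. Row order follows the file.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("chrom", "start", "end", "id", "strand", "signal")
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), strand = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L], ": non-numeric coordinate")
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L],
         ": invalid interval (need 0 <= start < end)")
  }
  id <- ifelse(nf >= 4L,
               vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                      character(1)),
               paste0("region_", seq_along(fields)))
  strand <- ifelse(nf >= 6L,
                   vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".",
                          character(1)),
                   ".")
  badstr <- which(!strand %in% c("+", "-", "."))
  if (length(badstr) > 0L) {
    stop("BED parse error at line ", badstr[1L], ": strand must be +, - or .")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, id = id,
                    strand = strand, stringsAsFactors = FALSE)
  if (all(nf >= 7L)) {
    signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7L)))
    if (anyNA(signal)) {
      stop("BED parse error at line ", which(is.na(signal))[1L],
           ": non-numeric signal column")
    }
    if (any(signal < 0)) {
      stop("BED parse error at line ", which(signal < 0)[1L],
           ": negative signal")
    }
    out$signal <- signal
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: coordinates and strands round-trip exactly.
#' A `signal` column, when present, is written as column 7.
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `id`, `strand`, `signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  id <- if ("id" %in% names(intervals)) intervals$id else paste0("region_", seq_len(n))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  lines <- paste(intervals$chrom, format_coord(intervals$start),
                 format_coord(intervals$end), id, 0L, strand, sep = "\t")
  if ("signal" %in% names(intervals)) {
    lines <- paste(lines, format_num(intervals$signal), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) sprintf("%d", as.integer(round(x)))
format_num <- function(x) sprintf("%.6g", x)

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a circRNA expression matrix (RPM) from TSV
#'
#' The file has a header `circ_id<TAB>sample...` where each sample descriptor
#' has the syntax `tissue:stage:rep`. Values are reads per million mapped
#' reads (RPM) and must be non-negative; a missing or negative cell, a
#' duplicated circRNA id, or a ragged row is an error (RPM matrices are dense
#' by construction).
#'
#' @param path Path to the TSV file.
#' @return An object of class `secirc_expr`: a list with `values` (numeric
#'   matrix, rows = circRNA ids, columns = sample descriptors) and `samples`
#'   (data.frame with `sample`, `tissue`, `stage`, `rep`).
#' @export
read_expression_matrix <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("expression matrix has no header")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("expression matrix needs at least one sample column")
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample descriptor in header")
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stop("ragged row at line ", which(nf != length(header))[1L] + 1L)
  }
  circ_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(circ_ids)) {
    stop("duplicate circRNA id: ", circ_ids[duplicated(circ_ids)][1L])
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                   dimnames = list(circ_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) stop("non-numeric expression value at line ", i + 1L)
    values[i, ] <- v
  }
  if (any(values < 0)) stop("negative RPM value in expression matrix")
  expression_matrix(values)
}

#' Construct an expression-matrix object from a numeric matrix
#'
#' @param values Non-negative numeric matrix; rownames are circRNA ids and
#'   colnames are `tissue:stage:rep` sample descriptors.
#' @return A `secirc_expr` object (see [read_expression_matrix()]).
#' @export
expression_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("negative RPM value")
  parts <- strsplit(colnames(values), ":", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("sample descriptors must have the syntax tissue:stage:rep")
  }
  samples <- data.frame(
    sample = colnames(values),
    tissue = vapply(parts, `[[`, character(1), 1L),
    stage = vapply(parts, `[[`, character(1), 2L),
    rep = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, samples = samples), class = "secirc_expr")
}

#' @export
print.secirc_expr <- function(x, ...) {
  cat(sprintf("secirc expression matrix: %d circRNAs x %d samples (%d tissues, %d stages)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$tissue)), length(unique(x$samples$stage))))
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' @param expr A `secirc_expr` object or a named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  values <- if (inherits(expr, "secirc_expr")) expr$values else expr
  header <- paste(c("circ_id", colnames(values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i) {
    # 10 significant digits: enough that noiseless fold ratios survive the
    # round trip, while keeping files byte-stable across runs
    paste(c(rownames(values)[i], sprintf("%.10g", values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read DNA/RNA sequences from FASTA
#'
#' Sequences are uppercased and U is normalized to T, so downstream code
#' works in DNA space. Allowed alphabet is ACGTUN (case-insensitive).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (first whitespace-delimited
#'   token of each header is the id).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character in FASTA record: ", ids[bad][1L])
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a three-species ortholog table
#'
#' TSV with one column of circRNA ids per species (reference species first).
#' Empty cells and the literal `NA` denote a missing ortholog.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with one character column per species.
#' @export
read_orthologs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("ortholog table needs at least 3 species columns")
  tab[tab == ""] <- NA_character_
  tab
}

#' Write an ortholog table to TSV
#'
#' @param tab Data.frame as returned by [read_orthologs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthologs <- function(tab, path) {
  out <- tab
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-style position matrix
#'
#' Accepts the 4-row count format, with or without row labels
#' (`A [ 3 10 ... ]`) and with an optional `>name` header. Counts are
#' converted to per-column probabilities.
#'
#' @param path Path to the matrix file.
#' @return 4 x width numeric probability matrix with rows A, C, G, T; the
#'   motif name (if any) is kept in the `"name"` attribute.
#' @export
read_pwm <- function(path) {
  lines <- read_text_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NA_character_
  if (length(lines) > 0L && startsWith(lines[1L], ">")) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) != 4L) stop("malformed PWM: expected 4 matrix rows")
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(v)) stop("malformed PWM: non-numeric entry")
    v
  })
  if (length(unique(lengths(rows))) != 1L) stop("malformed PWM: ragged rows")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  colsum <- colSums(counts)
  if (any(colsum <= 0)) stop("malformed PWM: zero column")
  pwm <- sweep(counts, 2L, colsum, "/")
  attr(pwm, "name") <- name
  pwm
}
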