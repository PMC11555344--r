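# All coordinates inside the package are 0-based half-open (BED convention).
# 1-based inputs (Hi-C interaction positions, SNV tables, TSS positions,
# methylation probe positions) are converted on read.

VALID_STRANDS <- c("+", "-", ".")

#' Construct a validated interval table
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end` and
#' optionally `strand`, using 0-based half-open coordinates throughout.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must exceed `start`.
#' @param strand strand characters in `+`, `-`, `.` (default `.`).
#' @return data.frame with columns chrom, start, end, strand.
#' @export
intervals <- function(chrom, start, end, strand = ".") {
  strand <- rep_len(strand, length(chrom))
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% VALID_STRANDS)) stop("strand must be one of +, -, .")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Normalise chromosome-name dialects
#'
#' Maps bare names ("1", "MT") to the "chr"-prefixed dialect ("chr1", "chrM").
#'
#' @param x character vector of chromosome names.
#' @return character vector with "chr" prefix.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x[x == "MT"] <- "M"
  ifelse(startsWith(x, "chr"), x, paste0("chr", x))
}

#' Convert an interval table to a GRanges object
#'
#' @param x data.frame with chrom/start/end (0-based half-open) and optional
#'   strand column.
#' @return `GenomicRanges::GRanges` (1-based closed, as GRanges requires).
#' @keywords internal
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "."
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercased sequences, record order
#'   preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(set))
  # keep only the first word of each header, as aligners do
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a processed Hi-C interaction file
#'
#' Nine whitespace-separated columns: read name, strand1, chr1, position1,
#' fragment1, strand2, chr2, position2, fragment2. Positions are 1-based in
#' the file and converted to 0-based here. The fragment-label columns are
#' ignored; fragments are re-assigned downstream from the digestion map so
#' that network and digestion stages always agree.
#'
#' @param path interaction file path.
#' @param replicate_id replicate label attached to every record.
#' @param cell_line_id cell-line label attached to every record.
#' @return data.frame with columns read_name, strand1, chrom1, pos1, strand2,
#'   chrom2, pos2, replicate_id, cell_line_id; attribute `has_duplicates`
#'   is TRUE when a read name occurs more than once (deduplication happens in
#'   the network module).
#' @export
read_interaction_file <- function(path, replicate_id, cell_line_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop("interaction file '", path, "' line ", bad, ": expected 9 columns, got ",
         nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 4L]))
  pos2 <- suppressWarnings(as.numeric(m[, 8L]))
  if (anyNA(pos1) || anyNA(pos2)) {
    bad <- which(is.na(pos1) | is.na(pos2))[1L]
    stop("interaction file '", path, "' line ", bad, ": non-numeric position")
  }
  if (any(pos1 < 1) || any(pos2 < 1)) stop("interaction positions must be >= 1")
  out <- data.frame(
    read_name = m[, 1L],
    strand1 = m[, 2L], chrom1 = normalize_chrom(m[, 3L]), pos1 = pos1 - 1,
    strand2 = m[, 6L], chrom2 = normalize_chrom(m[, 7L]), pos2 = pos2 - 1,
    replicate_id = replicate_id, cell_line_id = cell_line_id,
    stringsAsFactors = FALSE
  )
  attr(out, "has_duplicates") <- anyDuplicated(out$read_name) > 0L
  out
}

#' Fraction of interval b covered by interval a
#'
#' Vectorised over rows. Returns 0 for disjoint intervals or different
#' chromosomes.
#'
#' @param a,b interval data.frames (recycled to common length).
#' @return numeric vector in \[0, 1\]: overlap length / length of `b`.
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  ov / (b$end[bi] - b$start[bi])
}

#' Write intervals as BED
#'
#' BED3 by default; a strand column other than all-"." promotes the output to
#' BED6, and `extra_columns` are appended after the core columns.
#'
#' @param x interval data.frame (0-based half-open).
#' @param path output path.
#' @param extra_columns optional data.frame of additional columns.
#' @export
write_bed <- function(x, path, extra_columns = NULL) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has_strand <- "strand" %in% names(x) && any(x$strand != ".")
  if (has_strand) {
    name <- if ("name" %in% names(x)) x$name else "."
    score <- if ("score" %in% names(x)) x$score else 0
    cols <- c(cols, list(name, score, x$strand))
  }
  if (!is.null(extra_columns)) cols <- c(cols, as.list(extra_columns))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path BED path.
#' @return interval data.frame; name/score columns kept when present.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  out <- intervals(normalize_chrom(x[[1L]]), x[[2L]], x[[3L]],
                   if (ncol(x) >= 6L) x[[6L]] else ".")
  if (ncol(x) >= 4L) out$name <- as.character(x[[4L]])
  if (ncol(x) >= 5L) out$score <- x[[5L]]
  out
}

#' Read a 10-column narrowPeak file
#' @param path narrowPeak path.
#' @return interval data.frame with name, score, strand, signal, p, q, summit.
#' @export
read_narrowpeak <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) != 10L) stop("narrowPeak requires 10 columns, got ", ncol(x))
  out <- intervals(normalize_chrom(x[[1L]]), x[[2L]], x[[3L]], x[[6L]])
  out$name <- x[[4L]]; out$score <- x[[5L]]
  out$signal <- x[[7L]]; out$p <- x[[8L]]; out$q <- x[[9L]]; out$summit <- x[[10L]]
  out
}

#' Read a per-sample somatic SNV table
#'
#' Tab-separated with header: sample, chrom, pos (1-based), ref, alt and an
#' optional cancer_type column. Indels are rejected; positions are converted
#' to 0-based.
#'
#' @param path SNV table path.
#' @return data.frame sample_id, chrom, pos (0-based), ref, alt, cancer_type.
#' @export
read_snv_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ct <- if ("cancer_type" %in% names(x)) x$cancer_type else NA_character_
  out <- data.frame(sample_id = as.character(x$sample),
                    chrom = normalize_chrom(x$chrom),
                    pos = as.numeric(x$pos) - 1,
                    ref = toupper(x$ref), alt = toupper(x$alt),
                    cancer_type = ct, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  if (!all(out$ref %in% bases & out$alt %in% bases))
    stop("SNV table contains non-SNV alleles (indels are not supported)")
  if (any(out$ref == out$alt)) stop("SNV with ref == alt")
  out
}

#' Write an SNV table (1-based positions on disk)
#' @param snvs data.frame as returned by [read_snv_table()].
#' @param path output path.
#' @export
write_snv_table <- function(snvs, path) {
  out <- data.frame(sample = snvs$sample_id, chrom = snvs$chrom,
                    pos = snvs$pos + 1, ref = snvs$ref, alt = snvs$alt,
                    cancer_type = snvs$cancer_type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated matrix (genes x samples) with a header row
#' @param path table path; first column holds row names.
#' @return numeric matrix.
#' @export
read_matrix_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                         check.names = FALSE)
  as.matrix(x)
}

#' Write a genes x samples matrix as a tab-separated table
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param rowname_header header for the row-name column.
#' @export
write_matrix_table <- function(m, path, rowname_header = "gene_id") {
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(m)), rowname_header), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
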