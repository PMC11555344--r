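# In-silico restriction digestion. HindIII cuts A/AGCTT: the cut is placed
# one base into the recognition site, forward strand only (the site is its
# own reverse complement, so a reverse-strand pass would duplicate cuts).

#' Digest a genome at restriction-enzyme recognition sites
#'
#' Every occurrence of `recognition_site` on the forward strand produces a
#' cut at `site_start + cut_offset`; fragments are the intervals between
#' consecutive cuts plus the chromosome ends, so each chromosome yields
#' (number of sites + 1) fragments that tile it exactly. Ambiguity bases (N)
#' never match the site.
#'
#' @param genome named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param recognition_site recognition sequence; default HindIII `AAGCTT`.
#' @param cut_offset cut position within the site, default 1 (A/AGCTT).
#' @return data.frame of fragments: chrom, start, end (0-based half-open),
#'   fragment_id (`chrom:start-end`).
#' @export
digest_genome <- function(genome, recognition_site = "AAGCTT", cut_offset = 1L) {
  if (cut_offset < 0L || cut_offset > nchar(recognition_site))
    stop("cut_offset must lie within the recognition site")
  res <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    seq <- genome[[i]]
    len <- nchar(seq)
    if (len == 0L) {
      warning("empty chromosome '", chrom, "' yields no fragments")
      res[[i]] <- NULL
      next
    }
    # fixed = TRUE: IUPAC ambiguity codes (incl. N) never match
    hits <- Biostrings::matchPattern(recognition_site,
                                     Biostrings::DNAString(seq), fixed = TRUE)
    cuts <- Biostrings::start(hits) - 1L + cut_offset  # 0-based cut coordinates
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0, sort(unique(cuts)), len)
    res[[i]] <- data.frame(chrom = chrom,
                           start = bounds[-length(bounds)],
                           end = bounds[-1L],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      fragment_id = character(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out$fragment_id <- fragment_id(out)
  out
}

#' Stable fragment identifier `chrom:start-end`
#' @param x interval data.frame.
#' @return character vector.
#' @export
fragment_id <- function(x) {
  paste0(x$chrom, ":", format(x$start, scientific = FALSE, trim = TRUE),
         "-", format(x$end, scientific = FALSE, trim = TRUE))
}

#' Summarise a fragment set
#'
#' @param fragments data.frame from [digest_genome()].
#' @return list with `count`, `median_length` (middle order statistic; mean of
#'   the two middles for even counts) and the numeric `lengths` vector.
#' @export
fragment_summary <- function(fragments) {
  if (is.null(fragments) || nrow(fragments) == 0L)
    stop("fragment_summary requires at least one fragment")
  lens <- fragments$end - fragments$start
  list(count = nrow(fragments),
       median_length = stats::median(lens),
       lengths = lens)
}
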