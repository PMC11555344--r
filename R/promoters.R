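# Strand-aware promoter definition: each TSS is extended 2000 bp upstream and
# 200 bp downstream relative to the gene's strand, per-gene intervals are
# merged, and every fragment overlapping a merged interval by >= 1 bp becomes
# a promoter fragment of that gene.

#' Map TSSs to protein-coding genes
#'
#' Drops TSSs on chrM/chrY, TSSs without a gene assignment, and TSSs assigned
#' to genes that are not protein-coding in the gene annotation.
#'
#' @param tss_table data.frame with columns chrom, pos (1-based TSS
#'   position) and gene_id (the annotation's gene assignment).
#' @param gene_annotation data.frame with columns gene_id, chrom, start, end,
#'   strand, gene_type.
#' @return data.frame gene_id, chrom, pos (0-based), strand; one row per
#'   retained TSS. Attribute `n_dropped` counts excluded TSSs.
#' @export
map_tss_to_genes <- function(tss_table, gene_annotation) {
  tss <- data.frame(chrom = normalize_chrom(tss_table$chrom),
                    pos = as.numeric(tss_table$pos) - 1,
                    gene_id = as.character(tss_table$gene_id),
                    stringsAsFactors = FALSE)
  n0 <- nrow(tss)
  tss <- tss[!(tss$chrom %in% c("chrM", "chrY")), , drop = FALSE]
  tss <- tss[!is.na(tss$gene_id) & nzchar(tss$gene_id), , drop = FALSE]
  coding <- gene_annotation[gene_annotation$gene_type == "protein_coding", ]
  idx <- match(tss$gene_id, coding$gene_id)
  tss <- tss[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom, pos = tss$pos,
                    strand = coding$strand[idx], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n0 - nrow(out)
  out
}

#' Define merged, strand-aware promoter regions
#'
#' A '+' strand TSS at 0-based position t yields \[t - up, t + down); a '-'
#' strand TSS yields \[t - down, t + up). Per-gene overlapping intervals are
#' merged, and intervals are clipped at chromosome bounds when lengths are
#' supplied.
#'
#' @param gene_tss data.frame from [map_tss_to_genes()].
#' @param up upstream extension in bp (default 2000).
#' @param down downstream extension in bp (default 200).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping.
#' @return data.frame gene_id, chrom, start, end, strand (merged intervals;
#'   a gene may span several rows).
#' @export
define_promoter_regions <- function(gene_tss, up = 2000L, down = 200L,
                                    chrom_lengths = NULL) {
  plus <- gene_tss$strand == "+"
  start <- ifelse(plus, gene_tss$pos - up, gene_tss$pos - down)
  end <- ifelse(plus, gene_tss$pos + down, gene_tss$pos + up)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[gene_tss$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  raw <- data.frame(gene_id = gene_tss$gene_id, chrom = gene_tss$chrom,
                    start = start, end = end, strand = gene_tss$strand,
                    stringsAsFactors = FALSE)
  raw <- raw[raw$end > raw$start, , drop = FALSE]
  merged <- lapply(split(raw, raw$gene_id), function(g) {
    gr <- GenomicRanges::reduce(as_granges(g))
    data.frame(gene_id = g$gene_id[1L],
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Assign promoter fragments to genes
#'
#' A fragment is a promoter fragment of a gene iff it overlaps at least 1 bp
#' of any of the gene's merged promoter intervals.
#'
#' @param promoter_regions data.frame from [define_promoter_regions()].
#' @param fragments fragment data.frame from [digest_genome()].
#' @return list with `per_gene` (data.frame gene_id, fragment_id) and
#'   `promoter_fragment_ids` (the global unique set).
#' @export
assign_promoter_fragments <- function(promoter_regions, fragments) {
  hit <- GenomicRanges::findOverlaps(as_granges(promoter_regions),
                                     as_granges(fragments), minoverlap = 1L,
                                     ignore.strand = TRUE)
  per_gene <- unique(data.frame(
    gene_id = promoter_regions$gene_id[S4Vectors::queryHits(hit)],
    fragment_id = fragments$fragment_id[S4Vectors::subjectHits(hit)],
    stringsAsFactors = FALSE))
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       promoter_fragment_ids = sort(unique(per_gene$fragment_id)))
}
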