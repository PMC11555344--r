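# Promoter-interaction network. A fragment-promoter interaction is valid when
# it has >= 2 deduplicated supporting read pairs coming from >= 2 distinct
# replicates (of >= 1 cell lines). Distal non-promoter fragments with >= 1
# valid edge are promoter-interacting fragments (PIFs).

#' Assign interaction read ends to digestion fragments
#'
#' Positions are matched against the digestion map (the fragment labels of the
#' interaction file are ignored). Records with both ends in the same fragment
#' (self-pairs) are discarded.
#'
#' @param records data.frame from [read_interaction_file()] (rows from several
#'   files may be concatenated).
#' @param fragments fragment data.frame from [digest_genome()].
#' @return data.frame frag_a, frag_b (unordered pair, lexicographically
#'   sorted), read_name, replicate_id, cell_line_id.
#' @export
assign_read_ends_to_fragments <- function(records, fragments) {
  frag_gr <- as_granges(fragments)
  locate <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    hit <- GenomicRanges::findOverlaps(gr, frag_gr, ignore.strand = TRUE,
                                       select = "first")
    if (anyNA(hit)) {
      bad <- which(is.na(hit))[1L]
      stop("read end at ", chrom[bad], ":", pos[bad] + 1,
           " falls outside the fragment map")
    }
    fragments$fragment_id[hit]
  }
  f1 <- locate(records$chrom1, records$pos1)
  f2 <- locate(records$chrom2, records$pos2)
  keep <- f1 != f2
  out <- data.frame(frag_a = pmin(f1[keep], f2[keep]),
                    frag_b = pmax(f1[keep], f2[keep]),
                    read_name = records$read_name[keep],
                    replicate_id = records$replicate_id[keep],
                    cell_line_id = records$cell_line_id[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count per-replicate support for each fragment pair
#'
#' Duplicate read names within a (cell line, replicate) count once.
#'
#' @param assigned data.frame from [assign_read_ends_to_fragments()].
#' @return data.frame frag_a, frag_b, cell_line_id, replicate_id, support.
#' @export
count_pair_support <- function(assigned) {
  dedup <- unique(assigned[, c("frag_a", "frag_b", "read_name",
                               "replicate_id", "cell_line_id")])
  key <- paste(dedup$frag_a, dedup$frag_b, dedup$cell_line_id,
               dedup$replicate_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(frag_a = vapply(parts, `[`, "", 1L),
                    frag_b = vapply(parts, `[`, "", 2L),
                    cell_line_id = vapply(parts, `[`, "", 3L),
                    replicate_id = vapply(parts, `[`, "", 4L),
                    support = as.integer(tab), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the promoter-interaction network
#'
#' An edge is kept iff exactly one side of the pair is a promoter fragment,
#' total deduplicated support is at least `min_support`, and support comes
#' from at least `min_replicates` distinct (cell line, replicate) combinations.
#' Promoter-promoter pairs are returned separately and excluded from the PIF
#' network.
#'
#' @param support_counts data.frame from [count_pair_support()].
#' @param promoter_assignment list from [assign_promoter_fragments()].
#' @param min_support minimum total supporting interactions (default 2).
#' @param min_replicates minimum distinct replicates (default 2).
#' @return list with `edges` (data.frame distal_fragment_id,
#'   promoter_fragment_id, gene_ids (comma-collapsed), support_count,
#'   n_replicates, replicate_set) and `promoter_promoter` (data.frame of
#'   excluded promoter-promoter pairs passing the same support rule).
#' @export
build_network <- function(support_counts, promoter_assignment,
                          min_support = 2L, min_replicates = 2L) {
  prom <- promoter_assignment$promoter_fragment_ids
  sc <- support_counts
  key <- paste(sc$frag_a, sc$frag_b, sep = "\r")
  tot <- tapply(sc$support, key, sum)
  reps <- tapply(paste(sc$cell_line_id, sc$replicate_id, sep = ":"), key,
                 function(x) sort(unique(x)))
  pairs <- strsplit(names(tot), "\r", fixed = TRUE)
  frag_a <- vapply(pairs, `[`, "", 1L)
  frag_b <- vapply(pairs, `[`, "", 2L)
  valid <- as.integer(tot) >= min_support & lengths(reps) >= min_replicates
  a_prom <- frag_a %in% prom
  b_prom <- frag_b %in% prom
  pif_edge <- valid & xor(a_prom, b_prom)
  pp_edge <- valid & a_prom & b_prom

  distal <- ifelse(a_prom, frag_b, frag_a)[pif_edge]
  promoter <- ifelse(a_prom, frag_a, frag_b)[pif_edge]
  gene_of <- split(promoter_assignment$per_gene$gene_id,
                   promoter_assignment$per_gene$fragment_id)
  genes <- vapply(promoter, function(f)
    paste(sort(unique(gene_of[[f]])), collapse = ","), "")
  edges <- data.frame(
    distal_fragment_id = distal,
    promoter_fragment_id = promoter,
    gene_ids = genes,
    support_count = as.integer(tot)[pif_edge],
    n_replicates = lengths(reps)[pif_edge],
    replicate_set = vapply(reps[pif_edge], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  pp <- data.frame(frag_a = frag_a[pp_edge], frag_b = frag_b[pp_edge],
                   support_count = as.integer(tot)[pp_edge],
                   n_replicates = lengths(reps)[pp_edge],
                   stringsAsFactors = FALSE)
  rownames(pp) <- NULL
  list(edges = edges, promoter_promoter = pp)
}

#' Classify all fragments into the five network classes
#'
#' Promoter class takes precedence. Among non-promoter fragments, a fragment
#' is a PIF iff it appears as the distal side of >= 1 valid edge; it is exonic
#' iff it overlaps >= 1 bp of any protein-coding exon, non-coding otherwise.
#'
#' @param fragments fragment data.frame.
#' @param promoter_fragment_ids global promoter-fragment set.
#' @param network list from [build_network()].
#' @param exons interval data.frame of protein-coding exons.
#' @return list with `table` (data.frame fragment_id, class) and `counts`
#'   (named vector over the five classes, summing to the fragment count).
#' @export
classify_fragments <- function(fragments, promoter_fragment_ids, network,
                               exons) {
  cls <- rep("nonpif_noncoding", nrow(fragments))
  exonic <- rep(FALSE, nrow(fragments))
  if (nrow(exons) > 0L) {
    hit <- GenomicRanges::findOverlaps(as_granges(fragments), as_granges(exons),
                                       minoverlap = 1L, ignore.strand = TRUE)
    exonic[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  is_pif <- fragments$fragment_id %in% network$edges$distal_fragment_id
  cls[is_pif & exonic] <- "pif_exonic"
  cls[is_pif & !exonic] <- "pif_noncoding"
  cls[!is_pif & exonic] <- "nonpif_exonic"
  cls[fragments$fragment_id %in% promoter_fragment_ids] <- "promoter"
  lv <- c("promoter", "pif_exonic", "pif_noncoding", "nonpif_exonic",
          "nonpif_noncoding")
  counts <- table(factor(cls, levels = lv))
  list(table = data.frame(fragment_id = fragments$fragment_id, class = cls,
                          stringsAsFactors = FALSE),
       counts = setNames(as.integer(counts), lv))
}

#' Distance class of each edge
#'
#' Different chromosomes give `trans_inter`; otherwise the midpoint-to-midpoint
#' distance classifies the edge as `cis` (<= `cis_max`) or `trans_intra`.
#'
#' @param edges edge data.frame from [build_network()].
#' @param fragments fragment data.frame.
#' @param cis_max cis distance threshold in bp (default 1e6).
#' @return character vector of classes, one per edge.
#' @export
distance_class <- function(edges, fragments, cis_max = 1e6) {
  idx_d <- match(edges$distal_fragment_id, fragments$fragment_id)
  idx_p <- match(edges$promoter_fragment_id, fragments$fragment_id)
  mid <- (fragments$start + fragments$end) / 2
  same <- fragments$chrom[idx_d] == fragments$chrom[idx_p]
  d <- abs(mid[idx_d] - mid[idx_p])
  ifelse(!same, "trans_inter", ifelse(d <= cis_max, "cis", "trans_intra"))
}

#' Degree summaries of the network
#'
#' Promoter degree is counted at gene level (distinct PIFs over the union of
#' the gene's promoter fragments); PIF degree counts distinct genes.
#'
#' @param network list from [build_network()].
#' @param promoter_assignment list from [assign_promoter_fragments()].
#' @return list with `promoter_degree` (named integer per gene, zero-degree
#'   genes included), `pif_degree` (named integer per PIF),
#'   `fraction_promoters_connected`, `median_interactions_per_promoter`.
#' @export
degree_summaries <- function(network, promoter_assignment) {
  genes <- sort(unique(promoter_assignment$per_gene$gene_id))
  edges <- network$edges
  prom_deg <- setNames(integer(length(genes)), genes)
  pif_deg <- integer(0)
  if (nrow(edges) > 0L) {
    per_edge_genes <- strsplit(edges$gene_ids, ",", fixed = TRUE)
    long <- data.frame(
      gene_id = unlist(per_edge_genes),
      distal = rep(edges$distal_fragment_id, lengths(per_edge_genes)),
      stringsAsFactors = FALSE)
    long <- unique(long)
    d1 <- table(long$gene_id)
    prom_deg[names(d1)] <- as.integer(d1)
    d2 <- table(long$distal)
    pif_deg <- setNames(as.integer(d2), names(d2))
  }
  list(promoter_degree = prom_deg,
       pif_degree = pif_deg,
       fraction_promoters_connected =
         if (length(prom_deg)) mean(prom_deg >= 1L) else 0,
       median_interactions_per_promoter =
         if (length(prom_deg)) stats::median(prom_deg) else 0)
}

#' Fraction of edges targeting a non-nearest promoter
#'
#' The nearest promoter of a PIF is the gene whose closest promoter-interval
#' boundary lies nearest the PIF midpoint on the same chromosome; ties break
#' toward the lexicographically smaller gene_id. Edges from PIFs on a
#' chromosome without promoters count as non-nearest.
#'
#' @param network list from [build_network()].
#' @param promoter_regions data.frame from [define_promoter_regions()].
#' @param fragments fragment data.frame.
#' @return list with `fraction_non_nearest` and the per-edge logical
#'   `non_nearest`.
#' @export
nearest_promoter_fraction <- function(network, promoter_regions, fragments) {
  edges <- network$edges
  if (nrow(edges) == 0L) stop("network has no edges")
  idx_d <- match(edges$distal_fragment_id, fragments$fragment_id)
  mid <- (fragments$start[idx_d] + fragments$end[idx_d]) / 2
  chrom <- fragments$chrom[idx_d]
  pr_by_chrom <- split(promoter_regions, promoter_regions$chrom)
  nearest_gene <- vapply(seq_len(nrow(edges)), function(i) {
    pr <- pr_by_chrom[[chrom[i]]]
    if (is.null(pr) || nrow(pr) == 0L) return(NA_character_)
    # distance from midpoint to closest interval boundary (0 if inside)
    d <- pmax(pr$start - mid[i], mid[i] - pr$end, 0)
    cand <- pr$gene_id[d == min(d)]
    sort(cand)[1L]
  }, "")
  edge_genes <- strsplit(edges$gene_ids, ",", fixed = TRUE)
  non_nearest <- vapply(seq_len(nrow(edges)), function(i) {
    if (is.na(nearest_gene[i])) return(TRUE)
    !(nearest_gene[i] %in% edge_genes[[i]])
  }, TRUE)
  list(fraction_non_nearest = mean(non_nearest), non_nearest = non_nearest)
}
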