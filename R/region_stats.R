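# Fragment-level sequence-constraint (depletion rank) comparisons,
# permutation-based peak enrichment with total-length-matched resampling,
# and the degree vs enrichment regression.

#' Median depletion-rank score per fragment
#'
#' A 500-bp scoring window contributes to a fragment iff more than half of the
#' window lies inside the fragment; the fragment's DR score is the median over
#' contributing windows. Fragments with no qualifying window get NA.
#'
#' @param fragments fragment data.frame.
#' @param dr_windows data.frame chrom, start, end, score (0-based half-open,
#'   typically 500-bp windows at 50-bp step).
#' @return named numeric vector (fragment_id -> median DR, NA when undefined).
#' @export
assign_dr <- function(fragments, dr_windows) {
  hit <- GenomicRanges::findOverlaps(as_granges(fragments),
                                     as_granges(dr_windows),
                                     ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  frac <- overlap_fraction(fragments[qi, , drop = FALSE],
                           dr_windows[si, , drop = FALSE])
  keep <- frac > 0.5
  med <- tapply(dr_windows$score[si][keep], qi[keep], stats::median)
  out <- setNames(rep(NA_real_, nrow(fragments)), fragments$fragment_id)
  out[as.integer(names(med))] <- as.numeric(med)
  out
}

#' Pairwise Wilcoxon rank-sum comparison of DR score groups
#'
#' @param groups named list of numeric vectors (NA dropped per group).
#' @param pairs optional 2-column matrix/data.frame of group-name pairs;
#'   default all pairs.
#' @return data.frame group1, group2, p, p_adj (Bonferroni over the requested
#'   comparisons).
#' @export
compare_dr <- function(groups, pairs = NULL) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- t(utils::combn(nm, 2L))
  }
  pairs <- as.matrix(pairs)
  p <- vapply(seq_len(nrow(pairs)), function(i)
    stats::wilcox.test(groups[[pairs[i, 1L]]], groups[[pairs[i, 2L]]],
                       exact = FALSE)$p.value, 0)
  data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L], p = p,
             p_adj = pmin(1, p * nrow(pairs)), stringsAsFactors = FALSE)
}

#' Distance from each fragment to the nearest exon
#'
#' 0 for overlapping fragments; Inf sentinel for fragments on chromosomes with
#' no exon.
#'
#' @param fragments fragment data.frame.
#' @param exons exon interval data.frame.
#' @param bins numeric vector of bin edges used for stratification labels
#'   (default c(0, 2000, 10000, 50000, Inf)).
#' @return data.frame fragment_id, distance, bin (factor).
#' @export
distance_to_exon <- function(fragments, exons,
                             bins = c(0, 2000, 10000, 50000, Inf)) {
  d <- rep(Inf, nrow(fragments))
  if (nrow(exons) > 0L) {
    hit <- GenomicRanges::distanceToNearest(as_granges(fragments),
                                            as_granges(exons),
                                            ignore.strand = TRUE)
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  edges <- unique(c(0, bins))
  lab <- cut(d, breaks = c(edges, Inf)[!duplicated(c(edges, Inf))],
             right = FALSE, include.lowest = TRUE)
  data.frame(fragment_id = fragments$fragment_id, distance = d, bin = lab,
             stringsAsFactors = FALSE)
}

# fraction of fragments overlapping >= 1 peak (or bp-coverage rate)
overlap_rate <- function(fragments, peaks, mode = c("fragment", "bp")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0L) return(0)
  hit <- GenomicRanges::findOverlaps(as_granges(fragments), as_granges(peaks),
                                     minoverlap = 1L, ignore.strand = TRUE)
  if (mode == "fragment") {
    length(unique(S4Vectors::queryHits(hit))) / nrow(fragments)
  } else {
    cov <- GenomicRanges::intersect(
      GenomicRanges::reduce(as_granges(fragments)),
      GenomicRanges::reduce(as_granges(peaks)), ignore.strand = TRUE)
    sum(GenomicRanges::width(cov)) / sum(fragments$end - fragments$start)
  }
}

#' Permutation test of peak enrichment in a fragment set
#'
#' The observed rate is the fraction of target fragments overlapping at least
#' one peak. Each permutation draws fragments from `pool` without replacement
#' until their cumulative length reaches the targets' total length, and the
#' empirical P is (1 + #\{resampled rate >= observed\}) / (n_perm + 1) so it is
#' never zero. The fold change divides the observed rate by the rate in
#' `reference` fragments (default: the pool), log2-transformed with a floor
#' `pseudo_rate` guarding zero denominators.
#'
#' @param target_fragments fragment data.frame (e.g. non-coding PIFs).
#' @param pool_fragments fragment data.frame to resample from (e.g. all
#'   non-coding fragments).
#' @param peaks interval data.frame of peaks.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param reference_fragments fragments defining the fold-change denominator
#'   (default `pool_fragments`, i.e. the non-PIF background).
#' @param mode "fragment" rate (default) or "bp" coverage rate.
#' @param pseudo_rate floor for rates inside the log2 ratio.
#' @return list: observed_rate, reference_rate, log2_fold_change,
#'   permutation_p, n_permutations, resampled_rates.
#' @export
permutation_enrichment <- function(target_fragments, pool_fragments, peaks,
                                   n_perm = 1000L, seed = 1L,
                                   reference_fragments = pool_fragments,
                                   mode = c("fragment", "bp"),
                                   pseudo_rate = 1e-4) {
  mode <- match.arg(mode)
  target_len <- sum(target_fragments$end - target_fragments$start)
  pool_len <- sum(pool_fragments$end - pool_fragments$start)
  if (pool_len < target_len)
    stop("pool total length is smaller than target total length")
  observed <- overlap_rate(target_fragments, peaks, mode)
  ref_rate <- overlap_rate(reference_fragments, peaks, mode)
  # precompute per-pool-fragment overlap flags once; a resample's rate is then
  # a mean over drawn flags (fragment mode) or length-weighted (bp mode)
  pool_hit <- rep(FALSE, nrow(pool_fragments))
  pool_covered <- rep(0, nrow(pool_fragments))
  if (nrow(peaks) > 0L) {
    red <- GenomicRanges::reduce(as_granges(peaks), ignore.strand = TRUE)
    h <- GenomicRanges::findOverlaps(as_granges(pool_fragments), red,
                                     minoverlap = 1L, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(h)
    pool_hit[unique(qi)] <- TRUE
    # peaks are reduced, so per-fragment covered bp adds up without double
    # counting; fragments in a restriction-digest pool are themselves disjoint
    ov <- pmin(pool_fragments$end[qi],
               GenomicRanges::end(red)[S4Vectors::subjectHits(h)]) -
      pmax(pool_fragments$start[qi],
           GenomicRanges::start(red)[S4Vectors::subjectHits(h)] - 1L)
    cv <- tapply(ov, qi, sum)
    pool_covered[as.integer(names(cv))] <- as.numeric(cv)
  }
  lens <- pool_fragments$end - pool_fragments$start
  set.seed(seed)
  resampled <- vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(nrow(pool_fragments))
    k <- which(cumsum(lens[ord]) >= target_len)[1L]
    sel <- ord[seq_len(k)]
    if (mode == "fragment") mean(pool_hit[sel]) else
      sum(pool_covered[sel]) / sum(lens[sel])
  }, 0)
  p <- (1 + sum(resampled >= observed)) / (n_perm + 1)
  lfc <- log2(max(observed, pseudo_rate) / max(ref_rate, pseudo_rate))
  list(observed_rate = observed, reference_rate = ref_rate,
       log2_fold_change = lfc, permutation_p = p, n_permutations = n_perm,
       resampled_rates = resampled)
}

#' Regression of peak enrichment on promoter-interaction degree
#'
#' PIF fragments are grouped by their promoter-interaction count; each group's
#' overlap rate is converted to a log2 fold change against the reference rate,
#' and the fold changes are regressed on degree.
#'
#' @param pif_fragments fragment data.frame of PIFs.
#' @param pif_degrees named integer vector (fragment_id -> promoter count).
#' @param peaks interval data.frame of peaks.
#' @param reference_fragments fragments defining the fold-change denominator.
#' @param pseudo_rate floor for rates inside the log2 ratio.
#' @return list: per_degree (data.frame degree, n, rate, log2_fold_change),
#'   pearson_r, slope, slope_p.
#' @export
degree_enrichment_correlation <- function(pif_fragments, pif_degrees, peaks,
                                          reference_fragments,
                                          pseudo_rate = 1e-4) {
  deg <- pif_degrees[pif_fragments$fragment_id]
  deg[is.na(deg)] <- 0L
  ref_rate <- overlap_rate(reference_fragments, peaks)
  groups <- split(seq_len(nrow(pif_fragments)), deg)
  per <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    r <- overlap_rate(pif_fragments[idx, , drop = FALSE], peaks)
    data.frame(degree = as.numeric(g), n = length(idx), rate = r,
               log2_fold_change = log2(max(r, pseudo_rate) /
                                         max(ref_rate, pseudo_rate)))
  }))
  per <- per[per$n > 0L, , drop = FALSE]
  if (length(unique(per$degree)) < 3L)
    stop("need >= 3 distinct degree values for the regression")
  fit <- stats::lm(log2_fold_change ~ degree, data = per)
  sm <- summary(fit)
  list(per_degree = per,
       pearson_r = stats::cor(per$degree, per$log2_fold_change),
       slope = unname(coef(fit)[2L]),
       slope_p = sm$coefficients["degree", "Pr(>|t|)"])
}
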