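# PWM motif-disruption scoring. Windows are scored by information-content
# weighted position probabilities, min-max normalised so the consensus word
# scores 1 and the anti-consensus 0; the match P value is the exact tail of
# the score distribution of a random background sequence, computed by
# dynamic-programming convolution over discretised score units.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param matrix 4 x L numeric matrix of per-position base probabilities;
#'   rownames A, C, G, T; each column sums to 1.
#' @param tf_name transcription-factor name.
#' @param motif_label motif label (default `tf_name`).
#' @param background nucleotide background frequencies (default uniform).
#' @return object of class `pif_pwm`.
#' @export
pwm <- function(matrix, tf_name, motif_label = tf_name,
                background = rep(0.25, 4)) {
  if (!all(rownames(matrix) == BASES)) stop("PWM rows must be A, C, G, T")
  if (ncol(matrix) < 4L) stop("PWM length must be >= 4")
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("each PWM position must sum to 1")
  names(background) <- BASES
  structure(list(tf_name = tf_name, motif_label = motif_label,
                 matrix = matrix, background = background),
            class = "pif_pwm")
}

#' Reverse complement of a PWM
#' @param p `pif_pwm` object.
#' @return `pif_pwm` scoring the opposite strand.
#' @export
reverse_complement_pwm <- function(p) {
  m <- p$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(p$matrix))),
                drop = FALSE]
  rownames(m) <- BASES
  pwm(m, p$tf_name, p$motif_label, p$background[c("T", "G", "C", "A")])
}

# per-position information content (bits, uniform reference)
pwm_ic <- function(p) {
  apply(p$matrix, 2L, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
}

# per-position, per-base contribution to the raw score
pwm_contributions <- function(p) {
  sweep(p$matrix, 2L, pwm_ic(p), "*")
}

#' Information-content score of a sequence window, normalised to \[0, 1\]
#'
#' The raw score sums IC-weighted base probabilities over positions; it is
#' min-max normalised between the anti-consensus (0) and consensus (1). A
#' zero-information PWM scores every sequence 0.5.
#'
#' @param seq_window character string of length equal to the motif (A/C/G/T).
#' @param p `pif_pwm` object.
#' @return score in \[0, 1\]; NA when the window contains a non-ACGT base.
#' @export
score_window <- function(seq_window, p) {
  L <- ncol(p$matrix)
  if (nchar(seq_window) != L) stop("window length must equal motif length")
  bases <- strsplit(toupper(seq_window), "")[[1L]]
  if (!all(bases %in% BASES)) return(NA_real_)
  contrib <- pwm_contributions(p)
  raw <- sum(contrib[cbind(match(bases, BASES), seq_len(L))])
  lo <- sum(apply(contrib, 2L, min))
  hi <- sum(apply(contrib, 2L, max))
  if (hi - lo < 1e-12) return(0.5)
  (raw - lo) / (hi - lo)
}

#' Exact score distribution of a PWM under its background
#'
#' Dynamic-programming convolution on discretised score units (bin width =
#' score range / 2^16). Used by [match_pvalue()].
#'
#' @param p `pif_pwm` object.
#' @param n_bins number of discretisation units across the score range.
#' @return list: mass (probability by unit-sum index), delta, lo, hi, L.
#' @keywords internal
pwm_score_distribution <- function(p, n_bins = 65536L) {
  contrib <- pwm_contributions(p)
  L <- ncol(contrib)
  lo_j <- apply(contrib, 2L, min)
  hi_j <- apply(contrib, 2L, max)
  rng <- sum(hi_j) - sum(lo_j)
  if (rng < 1e-12)
    return(list(mass = 1, delta = 1, lo = sum(lo_j), hi = sum(hi_j),
                L = L, degenerate = TRUE))
  delta <- rng / n_bins
  units <- round(sweep(contrib, 2L, lo_j, "-") / delta)  # 4 x L integers
  maxsum <- sum(apply(units, 2L, max))
  mass <- c(1, numeric(maxsum))  # index k+1 = P(unit sum == k)
  bg <- p$background
  for (j in seq_len(L)) {
    new <- numeric(maxsum + 1L)
    for (b in seq_len(4L)) {
      u <- units[b, j]
      pb <- bg[b]
      if (pb == 0) next
      if (u == 0L) new <- new + pb * mass
      else {
        idx <- seq_len(maxsum + 1L - u)
        new[idx + u] <- new[idx + u] + pb * mass[idx]
      }
    }
    mass <- new
  }
  list(mass = mass, delta = delta, lo = sum(lo_j), hi = sum(hi_j), L = L,
       degenerate = FALSE)
}

#' P value of a motif match score
#'
#' P(random background sequence scores >= `score`), on the normalised \[0, 1\]
#' scale, from the exact discretised distribution; monotone non-increasing in
#' `score`. Scores within half a discretisation unit per position of the
#' threshold are counted as matches (documented rounding guard).
#'
#' @param p `pif_pwm` object.
#' @param score normalised score in \[0, 1\].
#' @param dist optional precomputed [pwm_score_distribution()].
#' @return tail probability in \[0, 1\].
#' @export
match_pvalue <- function(p, score, dist = NULL) {
  if (score < 0 || score > 1) stop("score must be in [0, 1]")
  if (is.null(dist)) dist <- pwm_score_distribution(p)
  if (isTRUE(dist$degenerate)) return(1)
  rng_units <- (dist$hi - dist$lo) / dist$delta
  thr <- score * rng_units - dist$L / 2 - 0.5
  k0 <- max(0L, as.integer(ceiling(thr)))
  if (k0 + 1L > length(dist$mass)) return(0)
  sum(dist$mass[(k0 + 1L):length(dist$mass)])
}

#' Classify an allele difference
#' @param allele_diff signed ref - alt normalised score difference.
#' @return "neutral" (<0.4), "weak" (<0.7) or "strong" (>=0.7) by magnitude.
#' @export
classify_allele_diff <- function(allele_diff) {
  a <- abs(allele_diff)
  ifelse(a >= 0.7, "strong", ifelse(a >= 0.4, "weak", "neutral"))
}

#' Score the motif impact of SNVs
#'
#' Every placement of every PWM overlapping the SNV position is scored on both
#' strands for the reference and alternate alleles. Placements where either
#' allele reaches the match threshold (`match_pvalue` < `p_threshold`) are
#' kept; per (SNV, PWM) the placement with the best either-allele score is
#' reported. `allele_diff = ref_score - alt_score`: negative values indicate
#' motif creation by the alternate allele, positive values disruption.
#'
#' @param snvs SNV data.frame (0-based pos).
#' @param genome named character vector of chromosome sequences.
#' @param pwm_set list of `pif_pwm` objects.
#' @param p_threshold motif-match P threshold (default 1e-4).
#' @param keep effect classes to report (default "strong"; use
#'   c("neutral","weak","strong") for everything).
#' @return data.frame sample_id, chrom, pos, ref, alt, tf_name, motif_label,
#'   strand, offset, ref_score, alt_score, allele_diff, effect_class, match_p.
#' @export
snv_motif_effects <- function(snvs, genome, pwm_set, p_threshold = 1e-4,
                              keep = "strong") {
  out <- list()
  dists <- lapply(pwm_set, pwm_score_distribution)
  rc_set <- lapply(pwm_set, reverse_complement_pwm)
  rc_dists <- lapply(rc_set, pwm_score_distribution)
  for (i in seq_len(nrow(snvs))) {
    ch <- snvs$chrom[i]; pos <- snvs$pos[i]
    seq <- genome[[ch]]
    if (is.null(seq) || pos >= nchar(seq)) stop("SNV outside genome bounds")
    if (substr(seq, pos + 1L, pos + 1L) != snvs$ref[i])
      warning("SNV ref allele disagrees with genome at ", ch, ":", pos + 1)
    for (k in seq_along(pwm_set)) {
      L <- ncol(pwm_set[[k]]$matrix)
      best <- NULL
      for (strand in c("+", "-")) {
        pw <- if (strand == "+") pwm_set[[k]] else rc_set[[k]]
        dd <- if (strand == "+") dists[[k]] else rc_dists[[k]]
        for (o in (pos - L + 1L):pos) {
          if (o < 0L || o + L > nchar(seq)) next  # partial window: skip
          win <- substr(seq, o + 1L, o + L)
          rel <- pos - o + 1L
          ref_win <- win
          substr(ref_win, rel, rel) <- snvs$ref[i]
          alt_win <- win
          substr(alt_win, rel, rel) <- snvs$alt[i]
          rs <- score_window(ref_win, pw)
          as_ <- score_window(alt_win, pw)
          if (is.na(rs) || is.na(as_)) next  # N in window
          mp <- match_pvalue(pw, max(rs, as_), dd)
          if (mp >= p_threshold) next
          if (is.null(best) || max(rs, as_) > max(best$ref_score,
                                                  best$alt_score)) {
            best <- data.frame(
              sample_id = snvs$sample_id[i], chrom = ch, pos = pos,
              ref = snvs$ref[i], alt = snvs$alt[i],
              tf_name = pwm_set[[k]]$tf_name,
              motif_label = pwm_set[[k]]$motif_label,
              strand = strand, offset = o,
              ref_score = rs, alt_score = as_, allele_diff = rs - as_,
              effect_class = classify_allele_diff(rs - as_),
              match_p = mp, stringsAsFactors = FALSE)
          }
        }
      }
      if (!is.null(best) && best$effect_class %in% keep)
        out[[length(out) + 1L]] <- best
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = numeric(), ref = character(), alt = character(),
                      tf_name = character(), motif_label = character(),
                      strand = character(), offset = numeric(),
                      ref_score = numeric(), alt_score = numeric(),
                      allele_diff = numeric(), effect_class = character(),
                      match_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of intervals with open-chromatin peak sets
#'
#' @param intervals_df interval data.frame (e.g. somatic eQTL hotspots).
#' @param peak_sets named list of peak interval data.frames.
#' @return logical matrix, intervals x peak sets (>= 1 bp overlap).
#' @export
open_chromatin_overlap <- function(intervals_df, peak_sets) {
  out <- matrix(FALSE, nrow(intervals_df), length(peak_sets),
                dimnames = list(NULL, names(peak_sets)))
  gr <- as_granges(intervals_df)
  for (k in seq_along(peak_sets)) {
    if (nrow(peak_sets[[k]]) == 0L) next
    hit <- GenomicRanges::findOverlaps(gr, as_granges(peak_sets[[k]]),
                                       minoverlap = 1L, ignore.strand = TRUE)
    out[unique(S4Vectors::queryHits(hit)), k] <- TRUE
  }
  out
}

#' Write PWMs to a plain-text file
#'
#' Format: a header line `>tf_name<TAB>motif_label` followed by one line per
#' position with tab-separated A, C, G, T probabilities.
#'
#' @param pwm_set list of `pif_pwm` objects.
#' @param path output path.
#' @export
write_pwm_file <- function(pwm_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwm_set) {
    writeLines(paste0(">", p$tf_name, "\t", p$motif_label), con)
    for (j in seq_len(ncol(p$matrix)))
      writeLines(paste(format(p$matrix[, j], digits = 10), collapse = "\t"),
                 con)
  }
  invisible(path)
}

#' Read PWMs written by [write_pwm_file()]
#' @param path file path.
#' @return list of `pif_pwm` objects.
#' @export
read_pwm_file <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  ends <- c(heads[-1L] - 1L, length(lines))
  lapply(seq_along(heads), function(i) {
    hdr <- strsplit(sub("^>", "", lines[heads[i]]), "\t")[[1L]]
    rows <- lines[(heads[i] + 1L):ends[i]]
    m <- t(vapply(strsplit(rows, "\t"), as.numeric, numeric(4L)))
    m <- t(m)
    rownames(m) <- BASES
    pwm(m, hdr[1L], if (length(hdr) > 1L) hdr[2L] else hdr[1L])
  })
}
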