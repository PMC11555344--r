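# Recurrent somatic-mutation hotspot scan. A logistic background mutation
# model over user-supplied covariate tracks (features chosen by stability
# selection), with per-sample offsets calibrated to each sample's observed
# mutation load, supplies per-position per-sample mutation probabilities.
# 31-bp windows sliding at 1-bp step inside the target regions are scored by
# an exact Poisson-binomial tail on the number of mutated samples, BH-adjusted
# over all scanned windows.

#' Per-sample mutation rates by fragment class
#'
#' Rate = SNVs falling in the class's fragments / total class bp x 1e6, per
#' sample, with paired Wilcoxon signed-rank tests between PIF classes and
#' their matched non-PIF classes.
#'
#' @param snvs SNV data.frame (0-based pos).
#' @param class_table data.frame fragment_id, class from [classify_fragments()].
#' @param fragments fragment data.frame.
#' @return list: `rates` (samples x classes matrix, mutations/Mb), `medians`
#'   (per class), `tests` (data.frame of paired signed-rank comparisons).
#' @export
mutation_rate_by_class <- function(snvs, class_table, fragments) {
  samples <- sort(unique(snvs$sample_id))
  if (length(samples) < 2L) stop("need >= 2 samples")
  cls <- class_table$class[match(fragments$fragment_id,
                                 class_table$fragment_id)]
  lens <- fragments$end - fragments$start
  class_bp <- tapply(lens, cls, sum)
  # locate each SNV's fragment
  gr <- GenomicRanges::GRanges(snvs$chrom,
                               IRanges::IRanges(snvs$pos + 1L, snvs$pos + 1L))
  hit <- GenomicRanges::findOverlaps(gr, as_granges(fragments),
                                     select = "first", ignore.strand = TRUE)
  snv_cls <- cls[hit]
  lv <- names(class_bp)[!is.na(class_bp) & class_bp > 0]
  rates <- matrix(0, length(samples), length(lv),
                  dimnames = list(samples, lv))
  counts <- table(factor(snvs$sample_id, levels = samples),
                  factor(snv_cls, levels = lv))
  rates[, lv] <- as.matrix(counts) / rep(class_bp[lv], each = length(samples)) * 1e6
  pairs <- list(c("pif_exonic", "nonpif_exonic"),
                c("pif_noncoding", "nonpif_noncoding"))
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    if (!all(pr %in% lv)) return(NULL)
    d <- rates[, pr[1L]] - rates[, pr[2L]]
    p <- if (all(d == 0)) 1 else
      stats::wilcox.test(rates[, pr[1L]], rates[, pr[2L]], paired = TRUE,
                         exact = FALSE)$p.value
    data.frame(class_pif = pr[1L], class_nonpif = pr[2L],
               median_diff = stats::median(d), p = p,
               stringsAsFactors = FALSE)
  }))
  list(rates = rates, medians = apply(rates, 2L, stats::median), tests = tests)
}

# track value at positions: a track is an interval data.frame, optionally
# with a `score` column (value inside intervals, 0 outside; binary otherwise)
track_values <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(out)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  hit <- GenomicRanges::findOverlaps(gr, as_granges(t), select = "first",
                                     ignore.strand = TRUE)
  val <- if ("score" %in% names(t)) t$score else rep(1, nrow(t))
  out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  out
}

# feature matrix (positions x tracks) for given chrom/pos vectors
track_matrix <- function(tracks, chrom, pos) {
  cols <- lapply(names(tracks), function(nm) {
    v <- numeric(length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      v[sel] <- track_values(tracks[[nm]], ch, pos[sel])
    }
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks)
  m
}

# training set for the background model: mutated positions vs a uniform
# background subsample at bg_ratio : 1
background_training_set <- function(snvs, chrom_lengths, bg_ratio = 10L) {
  mut <- unique(snvs[, c("chrom", "pos")])
  n_bg <- bg_ratio * nrow(mut)
  probs <- chrom_lengths / sum(chrom_lengths)
  bg_chrom <- sample(names(chrom_lengths), n_bg, replace = TRUE, prob = probs)
  bg_pos <- floor(stats::runif(n_bg) * chrom_lengths[bg_chrom])
  data.frame(chrom = c(mut$chrom, bg_chrom), pos = c(mut$pos, bg_pos),
             y = rep(c(1L, 0L), c(nrow(mut), n_bg)), stringsAsFactors = FALSE)
}

#' Stability selection of background-model covariate tracks
#'
#' Repeated L1-penalised logistic fits (mutated vs background positions) on
#' random half-subsamples; a track is selected iff its coefficient is nonzero
#' in at least `freq_threshold` of the subsamples. Tracks named in
#' `nucleotide_features` (sequence-context features) must be selected in every
#' subsample (threshold 1).
#'
#' @param snvs SNV data.frame.
#' @param tracks named list of candidate covariate tracks.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_subsamples number of subsamples (default 50).
#' @param freq_threshold selection frequency cutoff (default 0.98).
#' @param nucleotide_features track names held to threshold 1.
#' @param bg_ratio background:mutated position ratio (default 10).
#' @param seed RNG seed.
#' @return character vector of selected track names; attribute `frequency`
#'   carries the per-track selection frequencies.
#' @export
stability_select_features <- function(snvs, tracks, chrom_lengths,
                                      n_subsamples = 50L,
                                      freq_threshold = 0.98,
                                      nucleotide_features = character(0),
                                      bg_ratio = 10L, seed = 1L) {
  if (length(tracks) < 1L) stop("need at least one candidate track")
  set.seed(seed)
  train <- background_training_set(snvs, chrom_lengths, bg_ratio)
  X <- track_matrix(tracks, train$chrom, train$pos)
  const <- apply(X, 2L, function(v) stats::var(v) == 0)
  if (any(const)) {
    message("dropping constant track(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0L) return(character(0))
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; duplicate and read the first coefficient
    X <- cbind(X, .dup = X[, 1L])
  }
  lam <- glmnet::cv.glmnet(X, train$y, family = "binomial", nfolds = 5L)
  lambda <- lam$lambda.1se
  n <- nrow(X)
  sel <- matrix(FALSE, n_subsamples, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, floor(n / 2))
    fit <- glmnet::glmnet(X[idx, , drop = FALSE], train$y[idx],
                          family = "binomial", lambda = lambda)
    sel[b, ] <- as.numeric(coef(fit))[-1L] != 0
  }
  freq <- colMeans(sel)
  freq <- freq[setdiff(names(freq), ".dup")]
  thr <- ifelse(names(freq) %in% nucleotide_features, 1, freq_threshold)
  out <- names(freq)[freq >= thr]
  attr(out, "frequency") <- freq
  out
}

#' Fit the covariate-aware background mutation model
#'
#' Logistic model P(mutation at position j in sample i) =
#' sigmoid(alpha_i + x_j . beta): beta is fit on mutated vs background
#' positions over the selected tracks, and the per-sample offsets alpha_i are
#' calibrated by root finding so each sample's expected genome-wide mutation
#' count matches its observed load.
#'
#' @param snvs SNV data.frame.
#' @param tracks named list of covariate tracks.
#' @param selected names of selected tracks (empty -> intercept-only model,
#'   i.e. a uniform background modulated only by per-sample load).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bg_ratio background:mutated ratio in the training set.
#' @param seed RNG seed for the background subsample.
#' @return object of class `pif_background` with elements `coefficients`,
#'   `selected_features`, `sample_offsets`, `eta` (per-chromosome position
#'   effect vectors) and `samples`.
#' @export
fit_background <- function(snvs, tracks, selected, chrom_lengths,
                           bg_ratio = 10L, seed = 1L) {
  set.seed(seed)
  samples <- sort(unique(snvs$sample_id))
  beta <- numeric(0)
  if (length(selected) > 0L) {
    train <- background_training_set(snvs, chrom_lengths, bg_ratio)
    X <- track_matrix(tracks[selected], train$chrom, train$pos)
    fit <- tryCatch(
      suppressWarnings(stats::glm(train$y ~ X, family = stats::binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && all(is.finite(coef(fit))) &&
      all(abs(coef(fit)[-1L]) < 20)
    if (ok) {
      beta <- coef(fit)[-1L]
    } else {
      warning("logistic fit unstable (separation?); using ridge fallback")
      rf <- glmnet::glmnet(cbind(X, 0), train$y, family = "binomial",
                           alpha = 0, lambda = 1e-2)
      beta <- as.numeric(coef(rf))[2L:(1L + ncol(X))]
    }
    names(beta) <- selected
  }
  # position effect over every genomic position, per chromosome
  eta <- lapply(names(chrom_lengths), function(ch) {
    pos <- seq_len(chrom_lengths[[ch]]) - 1L
    if (length(beta) == 0L) return(numeric(length(pos)))
    as.numeric(track_matrix(tracks[selected], rep(ch, length(pos)), pos) %*% beta)
  })
  names(eta) <- names(chrom_lengths)
  # calibrate alpha_i: sum_j sigmoid(alpha_i + eta_j) == observed count_i.
  # eta is piecewise constant, so work on its value histogram.
  all_eta <- unlist(eta, use.names = FALSE)
  tab <- table(round(all_eta, 8))
  vals <- as.numeric(names(tab)); cnts <- as.numeric(tab)
  loads <- table(factor(snvs$sample_id, levels = samples))
  alpha <- vapply(samples, function(s) {
    target <- as.numeric(loads[[s]])
    if (target == 0) return(-Inf)
    stats::uniroot(function(a) sum(cnts * stats::plogis(a + vals)) - target,
                   lower = -60, upper = 20, tol = 1e-10)$root
  }, 0)
  structure(list(coefficients = beta, selected_features = selected,
                 sample_offsets = alpha, eta = eta, samples = samples),
            class = "pif_background")
}

#' Per-position mutation probabilities under the background model
#' @param model `pif_background` object.
#' @param sample_id one sample.
#' @param chrom chromosome.
#' @param pos 0-based positions.
#' @return numeric vector of probabilities in (0, 1).
#' @export
background_prob <- function(model, sample_id, chrom, pos) {
  a <- model$sample_offsets[[sample_id]]
  stats::plogis(a + model$eta[[chrom]][pos + 1L])
}

#' Exact Poisson-binomial tail probability
#'
#' P(X >= k) where X is a sum of independent Bernoulli variables with
#' heterogeneous probabilities, by dynamic-programming convolution.
#'
#' @param probs per-trial success probabilities in \[0, 1\].
#' @param k observed count.
#' @return tail probability in \[0, 1\]; 0 when k > length(probs).
#' @export
poisson_binomial_tail <- function(probs, k) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  n <- length(probs)
  if (k <= 0L) return(1)
  if (k > n) return(0)
  dp <- c(1, numeric(n))  # dp[j+1] = P(X = j)
  for (p in probs) {
    dp <- c(dp[1L] * (1 - p), dp[-1L] * (1 - p) + dp[-(n + 1L)] * p)
  }
  min(1, max(0, sum(dp[(k + 1L):(n + 1L)])))
}

#' Scan regions for recurrent-mutation candidate windows
#'
#' Slides a `window`-bp window at 1-bp step inside each region (a region
#' shorter than the window contributes one window covering it). A window's
#' mutated-sample count is the number of samples with >= 1 SNV inside it;
#' windows reaching `min_count` are scored by [poisson_binomial_tail()] with
#' per-sample window probability 1 - prod(1 - p_ij) under the background
#' model. The attribute `n_windows_scanned` (total windows, scored or not)
#' feeds the BH correction in [merge_and_correct()].
#'
#' @param snvs SNV data.frame.
#' @param regions interval data.frame with fragment_id (one region class per
#'   run, e.g. promoter fragments or non-coding PIFs).
#' @param background `pif_background` model.
#' @param window window size in bp (default 31).
#' @param min_count minimum mutated samples (default 4).
#' @return data.frame chrom, start, end, region_id, count, sample_ids
#'   (comma-collapsed), p; attribute `n_windows_scanned`.
#' @export
scan_hotspots <- function(snvs, regions, background, window = 31L,
                          min_count = 4L) {
  samples <- background$samples
  events <- unique(snvs[, c("chrom", "pos", "sample_id")])
  n_windows <- 0
  out <- list()
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]
    r0 <- regions$start[r]; r1 <- regions$end[r]
    rlen <- r1 - r0
    if (rlen <= window) {
      starts_all <- r0
      wlen <- rlen
    } else {
      starts_all <- r0:(r1 - window)
      wlen <- window
    }
    n_windows <- n_windows + length(starts_all)
    ev <- events[events$chrom == ch & events$pos >= r0 & events$pos < r1, ,
                 drop = FALSE]
    if (nrow(ev) < min_count) next
    ev <- ev[order(ev$pos), , drop = FALSE]
    # only starts whose window can contain an event need counting
    cand_starts <- unique(unlist(lapply(ev$pos, function(p)
      max(r0, p - wlen + 1L):min(p, max(starts_all)))))
    cand_starts <- sort(cand_starts[cand_starts %in% starts_all |
                                      (rlen <= window & cand_starts == r0)])
    if (rlen <= window) cand_starts <- r0
    for (s in cand_starts) {
      in_win <- ev$pos >= s & ev$pos < s + wlen
      cnt <- length(unique(ev$sample_id[in_win]))
      if (cnt < min_count) next
      # per-sample probability of >= 1 mutation in the window
      pos <- s:(s + wlen - 1L)
      eta <- background$eta[[ch]][pos + 1L]
      pw <- vapply(samples, function(smp) {
        z <- background$sample_offsets[[smp]] + eta
        1 - exp(sum(-log1p(exp(z))))
      }, 0)
      p <- poisson_binomial_tail(pw, cnt)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + wlen,
        region_id = regions$fragment_id[r], count = cnt,
        sample_ids = paste(sort(unique(ev$sample_id[in_win])), collapse = ","),
        p = p, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               region_id = character(), count = integer(),
               sample_ids = character(), p = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_windows_scanned") <- n_windows
  res
}

# BH step-up with an explicit total test count m (unscored tests count as p=1)
bh_adjust_m <- function(p, m) {
  if (length(p) == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

#' Merge significant windows into hotspots and apply the FDR cutoff
#'
#' BH adjustment uses the total number of scanned windows (windows below the
#' count threshold enter as p = 1), so a single chance cluster cannot reach
#' significance merely by being the only scored window. Overlapping or
#' adjacent significant windows in the same region merge into maximal
#' intervals; the merged hotspot takes the minimum member p and q and the
#' union of mutated samples. Merged hotspots crossing a fragment boundary are
#' removed when `fragments` is supplied.
#'
#' @param candidates data.frame from [scan_hotspots()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @param n_tests total number of tests for BH; defaults to the
#'   `n_windows_scanned` attribute of `candidates`.
#' @param fragments optional fragment data.frame for boundary exclusion.
#' @return data.frame chrom, start, end, region_id, mutated_sample_count,
#'   sample_ids, p, q.
#' @export
merge_and_correct <- function(candidates, fdr_cut = 0.05, n_tests = NULL,
                              fragments = NULL) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_id = character(), mutated_sample_count = integer(),
                      sample_ids = character(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  if (is.null(n_tests)) n_tests <- attr(candidates, "n_windows_scanned")
  if (is.null(n_tests)) n_tests <- nrow(candidates)
  n_tests <- max(n_tests, nrow(candidates))
  q <- bh_adjust_m(candidates$p, n_tests)
  sig <- candidates[q <= fdr_cut, , drop = FALSE]
  sigq <- q[q <= fdr_cut]
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (rid in unique(sig$region_id)) {
    sel <- sig$region_id == rid
    s <- sig[sel, , drop = FALSE]; qs <- sigq[sel]
    o <- order(s$start)
    s <- s[o, , drop = FALSE]; qs <- qs[o]
    grp <- cumsum(c(1, s$start[-1L] > cummax(s$end[-nrow(s)])))
    for (g in unique(grp)) {
      m <- grp == g
      smp <- sort(unique(unlist(strsplit(s$sample_ids[m], ","))))
      out[[length(out) + 1L]] <- data.frame(
        chrom = s$chrom[1L], start = min(s$start[m]), end = max(s$end[m]),
        region_id = rid, mutated_sample_count = length(smp),
        sample_ids = paste(smp, collapse = ","),
        p = min(s$p[m]), q = min(qs[m]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(fragments) && nrow(res) > 0L) {
    crosses <- vapply(seq_len(nrow(res)), function(i) {
      fr <- fragments[fragments$chrom == res$chrom[i], , drop = FALSE]
      # an internal fragment boundary strictly inside the hotspot
      any(fr$start > res$start[i] & fr$start < res$end[i]) ||
        any(fr$end > res$start[i] & fr$end < res$end[i])
    }, TRUE)
    res <- res[!crosses, , drop = FALSE]
    rownames(res) <- NULL
  }
  res[order(res$p), , drop = FALSE]
}

#' Cancer-type specificity of hotspots
#'
#' @param hotspots data.frame from [merge_and_correct()].
#' @param snvs multi-cohort SNV data.frame with cancer_type.
#' @param cohort data.frame sample_id, cancer_type covering every patient
#'   (including unmutated ones).
#' @param focal_type the cancer type tested for exclusivity (default
#'   "melanoma").
#' @return list: `percent` (hotspot x cancer-type matrix of % mutated
#'   patients), `exclusive` (logical per hotspot: 0% in every non-focal type),
#'   `fraction_exclusive`.
#' @export
cancer_specificity <- function(hotspots, snvs, cohort,
                               focal_type = "melanoma") {
  types <- sort(unique(cohort$cancer_type))
  n_by_type <- table(factor(cohort$cancer_type, levels = types))
  types <- types[n_by_type > 0L]
  pct <- matrix(0, nrow(hotspots), length(types),
                dimnames = list(NULL, types))
  for (i in seq_len(nrow(hotspots))) {
    inside <- snvs$chrom == hotspots$chrom[i] &
      snvs$pos >= hotspots$start[i] & snvs$pos < hotspots$end[i]
    mut <- unique(snvs$sample_id[inside])
    ct <- cohort$cancer_type[match(mut, cohort$sample_id)]
    cnt <- table(factor(ct, levels = types))
    pct[i, ] <- 100 * as.numeric(cnt) / as.numeric(n_by_type[types])
  }
  other <- setdiff(types, focal_type)
  exclusive <- apply(pct[, other, drop = FALSE], 1L, function(v) all(v == 0))
  list(percent = pct, exclusive = exclusive,
       fraction_exclusive = mean(exclusive))
}

#' Correlation of per-patient mutated-hotspot count with mutation load
#'
#' @param hotspots data.frame from [merge_and_correct()].
#' @param snvs SNV data.frame.
#' @return list: r, p, per_patient (data.frame sample_id, n_hotspots, load).
#' @export
burden_correlation <- function(hotspots, snvs) {
  samples <- sort(unique(snvs$sample_id))
  if (length(samples) < 3L) stop("need >= 3 patients")
  load <- as.numeric(table(factor(snvs$sample_id, levels = samples)))
  nh <- vapply(samples, function(s) {
    sv <- snvs[snvs$sample_id == s, , drop = FALSE]
    sum(vapply(seq_len(nrow(hotspots)), function(i)
      any(sv$chrom == hotspots$chrom[i] & sv$pos >= hotspots$start[i] &
            sv$pos < hotspots$end[i]), TRUE))
  }, 0)
  if (stats::var(load) == 0) stop("constant mutation load: correlation undefined")
  ct <- stats::cor.test(nh, load)
  list(r = unname(ct$estimate), p = ct$p.value,
       per_patient = data.frame(sample_id = samples, n_hotspots = nh,
                                load = load, stringsAsFactors = FALSE))
}
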