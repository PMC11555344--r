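# Background mutation model, Poisson-binomial scan and hotspot calling.

test_that("poisson_binomial_tail handles edge cases and matches pbinom", {
  expect_equal(poisson_binomial_tail(c(0.2, 0.5), 0L), 1)
  expect_equal(poisson_binomial_tail(c(0.2, 0.5), 3L), 0)
  expect_error(poisson_binomial_tail(c(0.5, 1.2), 1L), "0, 1")
  # homogeneous probabilities collapse to the binomial tail
  for (p in c(0.01, 0.3, 0.9)) {
    for (k in c(1L, 3L, 7L)) {
      expect_equal(poisson_binomial_tail(rep(p, 10L), k),
                   pbinom(k - 1L, 10L, p, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("poisson_binomial_tail equals exhaustive enumeration (small n)", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:10, 1L)
    probs <- runif(n)
    k <- sample(0:(n + 1L), 1L)
    expect_equal(poisson_binomial_tail(probs, k), pb_tail_oracle(probs, k),
                 tolerance = 1e-10)
  }
})

test_that("per-sample offsets reproduce each sample's observed load", {
  co <- shared_cohort(1L)
  chrlen <- vapply(co$genome, nchar, 0L)
  bg <- fit_background(co$snvs, list(), character(0), chrlen)
  loads <- table(factor(co$snvs$sample_id, levels = bg$samples))
  for (s in sample(bg$samples, 10L)) {
    expected <- sum(vapply(names(chrlen), function(ch)
      sum(plogis(bg$sample_offsets[[s]] + bg$eta[[ch]])), 0))
    expect_equal(expected, as.numeric(loads[[s]]), tolerance = 1e-6)
  }
  p <- background_prob(bg, bg$samples[1L], "chr1", 0:99)
  expect_true(all(p > 0 & p < 1))
})

test_that("track covariates shift the fitted background in the right direction", {
  set.seed(21)
  g <- make_genome(seed = 21L)
  hot_track <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                          stringsAsFactors = FALSE)
  mut <- make_mutations(g$genome, NULL, n_samples = 60L,
                        covariate_tracks = list(list(track = hot_track,
                                                     multiplier = 6)),
                        seed = 21L)
  chrlen <- vapply(g$genome, nchar, 0L)
  bg <- fit_background(mut$snvs, list(open = hot_track), "open", chrlen,
                       seed = 21L)
  expect_gt(unname(bg$coefficients["open"]), 0)
  s <- bg$samples[1L]
  inside <- mean(background_prob(bg, s, "chr1", 0:999))
  outside <- mean(background_prob(bg, s, "chr2", 0:999))
  expect_gt(inside, outside)
})

test_that("stability selection keeps the informative track, drops noise", {
  set.seed(31)
  g <- make_genome(seed = 31L)
  hot_track <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                          stringsAsFactors = FALSE)
  noise_track <- data.frame(chrom = "chr2", start = 5e4, end = 6e4,
                            stringsAsFactors = FALSE)
  mut <- make_mutations(g$genome, NULL, n_samples = 60L,
                        covariate_tracks = list(list(track = hot_track,
                                                     multiplier = 8)),
                        seed = 31L)
  chrlen <- vapply(g$genome, nchar, 0L)
  sel <- stability_select_features(mut$snvs,
                                   list(open = hot_track,
                                        noise = noise_track),
                                   chrlen, n_subsamples = 30L, seed = 31L)
  expect_true("open" %in% sel)
  expect_false("noise" %in% sel)
  freq <- attr(sel, "frequency")
  expect_true(all(freq >= 0 & freq <= 1))
})

test_that("scan_hotspots counts every window and scores dense ones", {
  snvs <- data.frame(sample_id = paste0("S", 1:6), chrom = "chr1",
                     pos = c(50, 52, 55, 58, 300, 900),
                     ref = "A", alt = "C", cancer_type = "melanoma",
                     stringsAsFactors = FALSE)
  chrlen <- c(chr1 = 1000L)
  bg <- fit_background(snvs, list(), character(0), chrlen)
  regions <- data.frame(chrom = "chr1", start = 0, end = 1000,
                        fragment_id = "chr1:0-1000", stringsAsFactors = FALSE)
  cand <- scan_hotspots(snvs, regions, bg, window = 31L, min_count = 4L)
  # a 1000-bp region holds 1000 - 31 + 1 sliding 31-bp windows
  expect_equal(attr(cand, "n_windows_scanned"), 970L)
  expect_true(all(cand$count >= 4L))
  # the densest window holds the 4 clustered samples
  expect_true(any(cand$count == 4L &
                    cand$start <= 50 & cand$end > 58))
  # brute-force count check for each reported window
  for (i in seq_len(nrow(cand))) {
    inside <- snvs$pos >= cand$start[i] & snvs$pos < cand$end[i]
    expect_equal(cand$count[i], length(unique(snvs$sample_id[inside])))
  }
  expect_true(all(diff(order(cand$start)) > 0))
})

test_that("regions shorter than the window yield one covering window", {
  snvs <- data.frame(sample_id = paste0("S", 1:4), chrom = "chr1",
                     pos = c(2, 4, 6, 8), ref = "A", alt = "C",
                     cancer_type = "melanoma", stringsAsFactors = FALSE)
  bg <- fit_background(snvs, list(), character(0), c(chr1 = 1000L))
  regions <- data.frame(chrom = "chr1", start = 0, end = 20,
                        fragment_id = "chr1:0-20", stringsAsFactors = FALSE)
  cand <- scan_hotspots(snvs, regions, bg)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(0, 20))
})

test_that("BH uses the full scanned-window count and merges clusters", {
  cand <- data.frame(chrom = "chr1",
                     start = c(100, 101, 500), end = c(131, 132, 531),
                     region_id = "chr1:0-1000", count = c(5L, 5L, 4L),
                     sample_ids = c("S1,S2,S3,S4,S5", "S2,S3,S4,S5,S6",
                                    "S1,S2,S3,S7"),
                     p = c(1e-9, 2e-9, 0.04), stringsAsFactors = FALSE)
  attr(cand, "n_windows_scanned") <- 1000L
  hs <- merge_and_correct(cand, fdr_cut = 0.05)
  # q for the weak window is 0.04 * 1000 / 3 > 0.05 -> only the cluster stays
  expect_equal(nrow(hs), 1L)
  expect_equal(c(hs$start, hs$end), c(100, 132))
  expect_equal(hs$mutated_sample_count, 6L)
  expect_equal(hs$p, 1e-9)
  expect_equal(hs$q, bh_oracle(c(cand$p, rep(1, 997)))[1L])
})

test_that("merged hotspots crossing a fragment boundary are removed", {
  cand <- data.frame(chrom = "chr1", start = c(90, 100), end = c(121, 131),
                     region_id = "chr1:0-1000", count = 5L,
                     sample_ids = "S1,S2,S3,S4,S5",
                     p = 1e-10, stringsAsFactors = FALSE)
  attr(cand, "n_windows_scanned") <- 100L
  fr <- data.frame(chrom = "chr1", start = c(0, 110), end = c(110, 1000),
                   stringsAsFactors = FALSE)
  fr$fragment_id <- fragment_id(fr)
  expect_equal(nrow(merge_and_correct(cand, fragments = fr)), 0L)
  fr2 <- data.frame(chrom = "chr1", start = 0, end = 1000,
                    stringsAsFactors = FALSE)
  fr2$fragment_id <- fragment_id(fr2)
  expect_equal(nrow(merge_and_correct(cand, fragments = fr2)), 1L)
})

test_that("the cohort scan recovers every planted hotspot and nothing else", {
  co <- shared_cohort(1L)
  chrlen <- vapply(co$genome, nchar, 0L)
  bg <- fit_background(co$snvs, list(), character(0), chrlen)
  regions <- co$fragments[co$fragments$fragment_id %in%
    unique(co$truth$planted_hotspots$fragment_id), ]
  cand <- scan_hotspots(co$snvs, regions, bg)
  hs <- merge_and_correct(cand, fragments = co$fragments)
  ph <- co$truth$planted_hotspots
  for (i in seq_len(nrow(ph))) {
    covered <- any(hs$chrom == ph$chrom[i] & hs$start < ph$end[i] &
                     hs$end > ph$start[i])
    expect_true(covered)
  }
  # every call overlaps a planted window (no false positives in these regions)
  for (j in seq_len(nrow(hs))) {
    expect_true(any(ph$chrom == hs$chrom[j] & ph$start < hs$end[j] &
                      ph$end > hs$start[j]))
  }
  expect_true(all(hs$q <= 0.05))
})

test_that("mutation rates per class are normalised by class length", {
  fr <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 3000),
                   stringsAsFactors = FALSE)
  fr$fragment_id <- fragment_id(fr)
  cl <- data.frame(fragment_id = fr$fragment_id,
                   class = c("pif_noncoding", "nonpif_noncoding"),
                   stringsAsFactors = FALSE)
  snvs <- data.frame(sample_id = c("S1", "S1", "S2"), chrom = "chr1",
                     pos = c(10, 1500, 20), ref = "A", alt = "C",
                     cancer_type = "melanoma", stringsAsFactors = FALSE)
  out <- mutation_rate_by_class(snvs, cl, fr)
  expect_equal(out$rates["S1", "pif_noncoding"], 1 / 1000 * 1e6)
  expect_equal(out$rates["S1", "nonpif_noncoding"], 1 / 2000 * 1e6)
  expect_equal(out$rates["S2", "nonpif_noncoding"], 0)
  expect_equal(nrow(out$tests), 1L)
})

test_that("cancer specificity and burden correlation report cohort structure", {
  hs <- data.frame(chrom = "chr1", start = 100, end = 131,
                   region_id = "chr1:0-1000", mutated_sample_count = 2L,
                   sample_ids = "S1,S2", p = 1e-8, q = 1e-6,
                   stringsAsFactors = FALSE)
  snvs <- data.frame(sample_id = c("S1", "S2", "T1"),
                     chrom = "chr1", pos = c(105, 110, 500),
                     ref = "A", alt = "C",
                     cancer_type = c("melanoma", "melanoma", "lung"),
                     stringsAsFactors = FALSE)
  cohort <- data.frame(sample_id = c("S1", "S2", "S3", "T1", "T2"),
                       cancer_type = c("melanoma", "melanoma", "melanoma",
                                       "lung", "lung"),
                       stringsAsFactors = FALSE)
  cs <- cancer_specificity(hs, snvs, cohort)
  expect_equal(unname(cs$percent[1L, "melanoma"]), 100 * 2 / 3)
  expect_equal(unname(cs$percent[1L, "lung"]), 0)
  expect_true(cs$exclusive[1L])
  expect_equal(cs$fraction_exclusive, 1)

  set.seed(9)
  snvs2 <- data.frame(
    sample_id = rep(sprintf("S%02d", 1:20), times = c(rep(30, 10), rep(5, 10))),
    chrom = "chr1", pos = 0, ref = "A", alt = "C", cancer_type = "melanoma",
    stringsAsFactors = FALSE)
  snvs2$pos <- sample.int(10000L, nrow(snvs2), replace = TRUE)
  # two narrow hotspots: high-load patients hit them far more often
  hs2 <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(400, 5400),
                    region_id = c("x", "y"), mutated_sample_count = 5L,
                    sample_ids = "S01", p = 1e-8, q = 1e-6,
                    stringsAsFactors = FALSE)
  bc <- burden_correlation(hs2, snvs2)
  expect_true(is.finite(bc$r) && is.finite(bc$p))
  expect_equal(bc$per_patient$load,
               as.numeric(table(snvs2$sample_id)[bc$per_patient$sample_id]))
  snvs_const <- snvs2
  snvs_const$sample_id <- rep(sprintf("S%02d", 1:10), length.out = nrow(snvs2))
  # equal loads by construction -> correlation undefined
  counts <- table(snvs_const$sample_id)
  if (length(unique(counts)) == 1L)
    expect_error(burden_correlation(hs2, snvs_const), "constant")
})
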