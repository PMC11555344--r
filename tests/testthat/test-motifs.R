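# PWM construction, information-content scoring, match P values and
# SNV motif-impact calls.

make_informative_pwm <- function(consensus = "TGACGTCA", p_major = 0.97,
                                 name = "TFX") {
  L <- nchar(consensus)
  m <- matrix((1 - p_major) / 3, 4L, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  cb <- strsplit(consensus, "")[[1L]]
  for (j in seq_len(L)) m[cb[j], j] <- p_major
  pwm(m, name)
}

anti_consensus <- function(p) {
  paste(rownames(p$matrix)[apply(p$matrix, 2L, which.min)], collapse = "")
}

# a PWM whose information content concentrates on one position (offset 3,
# consensus 'C'), with the remaining positions mildly informative: a single
# SNV at the dominant position then flips most of the normalised score range,
# while a full-length match still clears the 1e-4 threshold
spiked_pwm <- function(name = "TFS") {
  consensus <- "TGACGTCA"
  L <- nchar(consensus)
  m <- matrix(0.2, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  cb <- strsplit(consensus, "")[[1L]]
  for (j in seq_len(L)) m[cb[j], j] <- 0.4
  m[, 4L] <- 0.01
  m["C", 4L] <- 0.97
  pwm(m, name)
}

test_that("pwm validates its matrix", {
  m <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_s3_class(pwm(m, "tf"), "pif_pwm")
  bad <- m; bad[1L, 1L] <- 0.5
  expect_error(pwm(bad, "tf"), "sum to 1")
  expect_error(pwm(m[, 1:3], "tf"), ">= 4")
  m2 <- m; rownames(m2) <- c("A", "C", "G", "U")
  expect_error(pwm(m2, "tf"), "A, C, G, T")
})

test_that("consensus scores 1, anti-consensus 0, degenerate 0.5", {
  p <- make_informative_pwm()
  expect_equal(score_window("TGACGTCA", p), 1)
  expect_equal(score_window(anti_consensus(p), p), 0)
  u <- pwm(matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL)),
           "flat")
  expect_equal(score_window("ACGTAC", u), 0.5)
  expect_equal(score_window("TTTTTT", u), 0.5)
  expect_true(is.na(score_window("TGACGTCN", p)))
  expect_error(score_window("TGA", p), "length")
})

test_that("scores are invariant under reverse complementation", {
  set.seed(14)
  for (i in 1:10) {
    L <- sample(4:9, 1L)
    m <- matrix(rexp(4 * L), 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- sweep(m, 2L, colSums(m), "/")
    p <- pwm(m, "tf")
    w <- random_dna(L)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1L]]),
                                       collapse = ""))
    expect_equal(score_window(w, p), score_window(rc, reverse_complement_pwm(p)),
                 tolerance = 1e-12)
  }
})

test_that("match_pvalue is a monotone tail with the right anchors", {
  p <- make_informative_pwm()
  expect_equal(match_pvalue(p, 0), 1)
  s <- seq(0, 1, by = 0.05)
  pv <- vapply(s, function(x) match_pvalue(p, x), 0)
  expect_true(all(diff(pv) <= 1e-12))
  expect_lt(match_pvalue(p, 1), 4^-6)
  expect_error(match_pvalue(p, 1.2), "0, 1")
  u <- pwm(matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL)),
           "flat")
  expect_equal(match_pvalue(u, 0.9), 1)  # zero-information: everything matches
})

test_that("match_pvalue equals exhaustive enumeration for short motifs", {
  set.seed(15)
  for (i in 1:6) {
    L <- sample(4:6, 1L)
    m <- matrix(rexp(4 * L) + 0.05, 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- sweep(m, 2L, colSums(m), "/")
    p <- pwm(m, "tf")
    enum <- enumerate_pwm_scores(p)
    d <- pifnet:::pwm_score_distribution(p)
    svals <- sort(unique(enum$score))
    mids <- (svals[-1L] + svals[-length(svals)]) / 2
    mids <- mids[diff(svals) > 1e-3]     # stay clear of the rounding guard
    for (s in c(0, mids)) {
      expect_equal(match_pvalue(p, s, dist = d),
                   sum(enum$prob[enum$score >= s]),
                   tolerance = 1e-6)
    }
  }
})

test_that("allele-difference classes use the 0.4/0.7 boundaries inclusively", {
  expect_equal(classify_allele_diff(c(0, 0.3999, 0.4, 0.5, 0.6999, 0.7, 1)),
               c("neutral", "neutral", "weak", "weak", "weak", "strong",
                 "strong"))
  # sign carries creation vs disruption; magnitude sets the class
  expect_equal(classify_allele_diff(c(-0.4, -0.75)), c("weak", "strong"))
})

test_that("snv_motif_effects flags a dominant-position SNV as strong", {
  p <- spiked_pwm()
  genome <- c(chr1 = paste0(strrep("C", 20), "TGACGTCA", strrep("C", 20)))
  snv <- data.frame(sample_id = "S1", chrom = "chr1", pos = 23L,
                    ref = "C", alt = "A", cancer_type = "melanoma",
                    stringsAsFactors = FALSE)
  # position 23 is the dominant consensus 'C' (motif offset 3, motif at 20)
  eff <- snv_motif_effects(snv, genome, list(p))
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$effect_class, "strong")
  expect_gt(eff$allele_diff, 0.7)     # disruption: ref is the better allele
  expect_equal(eff$offset, 20)
  expect_lt(eff$match_p, 1e-4)
})

test_that("motif creation is reported with a negative allele difference", {
  p <- spiked_pwm()
  # genome carries the broken motif; the alt allele restores the consensus
  genome <- c(chr1 = paste0(strrep("C", 20), "TGAAGTCA", strrep("C", 20)))
  snv <- data.frame(sample_id = "S1", chrom = "chr1", pos = 23L,
                    ref = "A", alt = "C", cancer_type = "melanoma",
                    stringsAsFactors = FALSE)
  eff <- snv_motif_effects(snv, genome, list(p))
  expect_equal(nrow(eff), 1L)
  expect_lt(eff$allele_diff, -0.7)
})

test_that("sub-strong effects are only reported when requested", {
  u <- pwm(matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL)),
           "flat")
  # evenly informative PWM: one SNV moves the score by ~1/8 of the range,
  # a matching placement exists, but the effect is below the 0.4 boundary
  p <- make_informative_pwm()
  genome <- c(chr1 = paste0(strrep("C", 20), "TGACGTCA", strrep("C", 20)))
  snv <- data.frame(sample_id = "S1", chrom = "chr1", pos = 23L,
                    ref = "C", alt = "A", cancer_type = "melanoma",
                    stringsAsFactors = FALSE)
  none <- snv_motif_effects(snv, genome, list(u))
  expect_equal(nrow(none), 0L)  # flat PWM never passes the match threshold
  none2 <- snv_motif_effects(snv, genome, list(p))
  expect_equal(nrow(none2), 0L)  # default keep = "strong" filters it out
  all_eff <- snv_motif_effects(snv, genome, list(p),
                               keep = c("neutral", "weak", "strong"))
  expect_equal(nrow(all_eff), 1L)
  expect_equal(all_eff$effect_class, "neutral")
  expect_equal(all_eff$allele_diff, 1 / 8, tolerance = 1e-6)
})

test_that("chromosome-edge placements are skipped, off-genome SNVs error", {
  p <- spiked_pwm()
  genome <- c(chr1 = "TGACGTCA")   # motif hugs the chromosome start
  snv <- data.frame(sample_id = "S1", chrom = "chr1", pos = 3L,
                    ref = "C", alt = "A", cancer_type = "melanoma",
                    stringsAsFactors = FALSE)
  eff <- snv_motif_effects(snv, genome, list(p))
  expect_equal(nrow(eff), 1L)      # only the complete placement survives
  expect_equal(eff$offset, 0)
  snv_bad <- snv; snv_bad$pos <- 99L
  expect_error(snv_motif_effects(snv_bad, genome, list(p)), "bounds")
  snv_mis <- snv; snv_mis$ref <- "G"
  expect_warning(snv_motif_effects(snv_mis, genome, list(p)), "disagrees")
})

test_that("the planted cohort motif is detected at the planted hotspot", {
  co <- shared_cohort(1L)
  mt <- co$truth$motif
  expect_false(is.null(mt))
  win <- substr(co$genome[[mt$chrom]], mt$start + 1L,
                mt$start + nchar(mt$consensus))
  expect_equal(win, mt$consensus)
  p1 <- co$tracks$pwms[[1L]]
  expect_equal(score_window(win, p1), 1)
  # an SNV in the planted consensus yields a disruptive match for the
  # informative PWM (its information content is spread over 8 positions, so
  # a single base change moves the score by ~1/8 of the range)
  mid <- mt$start + 3L
  ref <- substr(co$genome[[mt$chrom]], mid + 1L, mid + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  snv <- data.frame(sample_id = "S1", chrom = mt$chrom, pos = mid,
                    ref = ref, alt = alt, cancer_type = "melanoma",
                    stringsAsFactors = FALSE)
  eff <- snv_motif_effects(snv, co$genome, co$tracks$pwms,
                           keep = c("neutral", "weak", "strong"))
  hit <- eff[eff$tf_name == p1$tf_name, ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$allele_diff, 0)
  expect_lt(hit$match_p, 1e-4)
  expect_equal(hit$ref_score, 1)
})

test_that("open-chromatin overlap respects the half-open convention", {
  iv <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(50, 150, 250), stringsAsFactors = FALSE)
  peaks <- list(
    dnase = data.frame(chrom = "chr1", start = 25, end = 60,
                       stringsAsFactors = FALSE),
    faire = data.frame(chrom = "chr1", start = 150, end = 200,
                       stringsAsFactors = FALSE))
  ov <- open_chromatin_overlap(iv, peaks)
  expect_equal(unname(ov[, "dnase"]), c(TRUE, FALSE, FALSE))
  # [100,150) and [150,200) touch at 150 without sharing a base
  expect_equal(unname(ov[, "faire"]), c(FALSE, FALSE, FALSE))
})

test_that("PWM files round trip", {
  p1 <- make_informative_pwm(name = "TFA")
  p2 <- make_informative_pwm("GGAATG", 0.7, "TFB")
  path <- tempfile(fileext = ".pwm")
  write_pwm_file(list(p1, p2), path)
  back <- read_pwm_file(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1L]]$tf_name, "TFA")
  expect_equal(back[[2L]]$matrix, p2$matrix, tolerance = 1e-9)
})
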