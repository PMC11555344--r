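---
title: "pifnet: statistical methods for non-coding driver discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pifnet: statistical methods for non-coding driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifnet)
```

This vignette documents the models and numerical choices behind each analysis
stage, and the synthetic cohort used to validate them.

## Coordinates and identifiers

Every interval inside the package is 0-based half-open `[start, end)`.
1-based positions in on-disk formats (Hi-C interaction files, SNV tables,
TSS and probe positions) are converted at the I/O boundary. Fragments carry
canonical identifiers `chrom:start-end`.

## In-silico digestion

`digest_genome()` cuts at every exact occurrence of the HindIII recognition
site `AAGCTT` on the forward strand (the site is its own reverse complement,
so one strand suffices), with the cut placed after the first base
(`A / AGCTT`). Matching uses `Biostrings::matchPattern(fixed = TRUE)`, so an
`N` never matches. Fragments tile each chromosome completely: the first
fragment starts at 0, the last one ends at the chromosome length, and each
fragment starts where the previous one ends.

## Promoter definition

TSS positions are joined to the gene annotation; genes on chrM/chrY,
unassigned contigs and non-protein-coding biotypes are dropped. Each TSS gets
a strand-aware window of 2,000 bp upstream and 200 bp downstream
(`[t - 2000, t + 200)` on `+`, mirrored on `-`), clipped to chromosome
bounds; windows of the same gene are merged when they overlap. A fragment is
a promoter fragment of a gene when the merged window overlaps it by at least
1 bp (touching intervals do not overlap under half-open coordinates). One
fragment may serve several genes.

## Promoter-interaction network

Read pairs mapping both ends to the same fragment are discarded; pairs are
stored with the two fragment identifiers in lexicographic order. Within each
(cell line, replicate) library, duplicated read names count once. A
promoter–distal pair is a **valid edge** iff it has at least 2 deduplicated
supporting pairs arising from at least 2 distinct (cell line, replicate)
libraries — two replicates of one cell line qualify, as do single replicates
of two cell lines. Promoter–promoter contacts are reported separately and
excluded from the edge list.

Fragments are partitioned into five classes with promoter status taking
precedence: promoter, PIF-exonic, PIF-non-coding, non-PIF-exonic,
non-PIF-non-coding (exonic means ≥ 1 bp overlap with a protein-coding exon).
Edges are cis when the fragment midpoints lie on one chromosome at most 1 Mb
apart (the boundary is cis), trans-intrachromosomal beyond that, and
trans-interchromosomal across chromosomes. `nearest_promoter_fraction()`
reports how often a PIF skips its geometrically nearest promoter.

## Region statistics

`assign_dr()` gives each fragment the median depletion-rank score of all
500-bp scoring windows lying more than half inside it. Group comparisons use
Wilcoxon rank-sum tests with Bonferroni correction over the requested pairs.

`permutation_enrichment()` compares a target fragment set's peak-overlap rate
(per fragment, or per bp with `mode = "bp"`) to random fragment resamples
drawn from the pool by adding shuffled fragments until the target's total
length is matched — the same cumulative-length rule for every draw. The
permutation P-value is `(b + 1) / (n + 1)` where `b` counts resamples at
least as enriched, so it is never zero.

## Hotspot scan

The background is a per-position Bernoulli logistic model: sample $i$ mutates
position $j$ with probability $\sigma(\alpha_i + x_j^\top \beta)$, where
$x_j$ are positional covariate tracks (selected by stability selection over
lasso subsamples) and $\alpha_i$ is calibrated per sample by `uniroot` so
that the expected genome-wide count matches the sample's observed load; the
genome-wide sum is computed on a histogram of rounded linear predictors,
making calibration O(distinct values).

Windows of 31 bp at 1-bp steps are scored. The probability that sample $i$
mutates a window $W$ is $1 - \exp\left(\sum_{j \in W} -\log(1 +
e^{z_{ij}})\right)$ computed with `log1p(exp(z))` for stability. With $k$ the
number of samples actually mutated in $W$, the window P-value is the exact
Poisson-binomial tail $P(X \ge k)$ via the standard dynamic-programming
convolution (no normal or Poisson approximation). Only windows with at least
4 mutated samples are evaluated, but Benjamini–Hochberg correction uses $m =$
**all scanned windows**: sub-threshold windows enter as implicit $p = 1$,
which only affects the denominator. Adjacent or overlapping significant
windows merge into hotspots; merged hotspots that cross a restriction
fragment boundary are removed, so every hotspot is attributable to one
fragment.

## Somatic eQTL

Expression counts are upper-quartile normalised (sample counts scaled to
75th percentile × 1,000), genes with median normalised expression ≤ 1 are
dropped, then `log2(x + 1)` and per-gene z-scoring. Promoter methylation is
the mean beta over probes inside the gene's promoter region, with missing
samples imputed by the gene's cross-sample mean. Hidden expression factors
are the top principal components of the expression matrix after projecting
out known covariates (`qr.resid` + `svd`) — a residual-PCA stand-in for
factor-analysis approaches.

A hotspot is eQTL-eligible when ≥ 3 reference-cohort samples are mutated in
it. Hotspots link to genes through the promoter map (hotspot inside a
promoter fragment) and through network edges (hotspot inside a PIF links to
the genes of the connected promoter). Per gene, the design holds hotspot
indicators, CNA, promoter methylation, sex and hidden factors (the extended
mode adds one-hot ancestry and cancer type). `lasso_select()` runs
cross-validated lasso keeping covariates penalised equally; if no hotspot
survives, the penalty is relaxed along the path, and as a last resort the
hotspot with maximal absolute correlation is forced in (flagged). The
selected design is refit by OLS; the reported gene-level P is the F-test of
the fitted model against the same model with all hotspot columns removed.
Collinear covariate columns are dropped in QR order; a collinear *hotspot*
column is an error, not a silent drop. Gene-level P-values are BH-adjusted.

## Motif impact

A PWM column's information content is $IC_j = 2 + \sum_b p_{bj} \log_2
p_{bj}$. A window scores $\sum_j IC_j \, p_{b_j j}$, min–max normalised by the
per-column best and worst letters so the consensus scores exactly 1 and the
anti-consensus 0; windows containing `N` score `NA`; a zero-IC (degenerate)
PWM scores 0.5 everywhere. The match P-value is the probability under the
uniform base model that a random window scores at least the observed score,
computed from the exact discrete score distribution (convolution over
positions on a fixed-resolution integer grid; a half-unit guard keeps
rounding from moving scores across the threshold).

For each SNV, every window covering it on both strands (reverse-complemented
PWM for the minus strand) is scored with ref and alt alleles; the best
max-allele-scoring window with match P below `1e-4` is reported. The allele
difference (ref − alt) is classified neutral (< 0.4), weak (≥ 0.4) or strong
(≥ 0.7) in absolute value; positive differences are disruptions, negative
ones creations.

Note a structural property of min–max IC normalisation: with a length-$L$
PWM whose columns are equally informative, a single SNV can move the
normalised score by at most about $1/L$. Strong (≥ 0.7) single-SNV effects
therefore require PWMs whose information is concentrated in few positions.

## Synthetic cohorts

`simulate_cohort()` generates a genome with planted HindIII sites, a gene
annotation with decoy TSSs (chrM, non-coding biotypes), a Hi-C library with
planted valid edges, replicate structure, PCR duplicates and sub-threshold
noise pairs, somatic SNVs from the logistic background with per-sample load
variation and planted 31-bp hotspots (rate multiplier 100), expression with
planted eQTL effects ($\beta = \pm 1$ on the log2 scale) plus CNA,
methylation, sex and latent-factor structure, covariate tracks (peaks
enriched on planted PIFs, depletion-rank windows lowered on constrained
fragments) and a planted consensus motif instance inside the first hotspot.
All stage seeds derive deterministically from the cohort seed
(`stage_seed()`), and the ground truth is returned alongside the data.
Default sizes — 2 × 200 kb chromosomes, 30 genes, 100 samples, 40 edges,
4 hotspots — keep a full pipeline run under a minute.

```{r example, eval = FALSE}
co <- simulate_cohort(seed = 1)
frags <- digest_genome(co$genome)
net <- build_network(count_pair_support(
  assign_read_ends_to_fragments(co$hic$records, frags)),
  co$promoter_assignment)
bg <- fit_background(co$snvs, list(), character(0),
                     vapply(co$genome, nchar, 0L))
hs <- merge_and_correct(scan_hotspots(co$snvs, frags, bg), fragments = frags)
```
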