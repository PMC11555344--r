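# Synthetic cohort generator with planted ground truth: a toy genome with
# HindIII sites, genes/TSSs/exons, Hi-C interaction libraries with planted
# promoter edges, somatic SNVs with planted recurrence hotspots, expression
# with planted eQTL effects, and covariate/constraint/peak tracks. One global
# seed fans out to per-stage seeds through a fixed affine counter so stages
# can be regenerated in isolation.

#' Derive a per-stage seed from the global seed
#'
#' stage_seed = (seed * 1009 + stage * 97) mod (2^31 - 1), stages numbered
#' genome = 1, genes = 2, hic = 3, mutations = 4, expression = 5, tracks = 6.
#'
#' @param seed global integer seed.
#' @param stage stage counter.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 97) %% 2147483647)
}

#' Generate a random genome with planted restriction sites
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param length_per_chrom chromosome length in bp (default 2e5, >= 1000).
#' @param site_density target HindIII sites per bp (default 1/2000).
#' @param seed RNG seed.
#' @return list: `genome` (named character vector chr1..), `truth` with
#'   planted site positions (0-based) and the count of chance sites.
#' @export
make_genome <- function(n_chroms = 2L, length_per_chrom = 2e5,
                        site_density = 1 / 2000, seed = 1L) {
  if (length_per_chrom < 1000) stop("chromosome length must be >= 1000")
  set.seed(seed)
  site <- "AAGCTT"
  genome <- character(n_chroms)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  planted <- vector("list", n_chroms)
  names(planted) <- names(genome)
  for (i in seq_len(n_chroms)) {
    s <- sample(BASES, length_per_chrom, replace = TRUE)
    n_sites <- round(length_per_chrom * site_density)
    pos <- integer(0)
    if (n_sites > 0L) {
      pos <- sort(sample(seq(10L, length_per_chrom - 16L), n_sites))
      pos <- pos[c(TRUE, diff(pos) > 6L)]  # no overlapping plants
      for (p in pos) s[(p + 1L):(p + 6L)] <- strsplit(site, "")[[1L]]
    }
    if (length(pos) < 2L)
      warning("chromosome ", names(genome)[i], " has < 2 planted sites")
    genome[i] <- paste(s, collapse = "")
    planted[[i]] <- pos
  }
  n_chance <- sum(vapply(genome, function(g)
    length(Biostrings::matchPattern(site, Biostrings::DNAString(g))), 0L)) -
    length(unlist(planted))
  list(genome = genome,
       truth = list(planted_sites = planted, n_chance_sites = n_chance,
                    seed = seed))
}

#' Generate gene, exon and TSS annotation over a genome
#'
#' Genes are placed non-overlapping with random strand; each has 1-3 TSSs
#' near its strand-aware start and 2-4 exons. A couple of non-coding genes and
#' a TSS on chrM are included to exercise the protein-coding and chrM/chrY
#' filters.
#'
#' @param genome named character vector from [make_genome()].
#' @param n_genes number of genes (default 30).
#' @param seed RNG seed.
#' @return list: `genes` (gene_id, chrom, start, end, strand, gene_type),
#'   `exons` (gene_id + interval), `tss` (chrom, pos \[1-based\], gene_id),
#'   `truth` (excluded TSS count etc.).
#' @export
make_gene_annotation <- function(genome, n_genes = 30L, seed = 1L) {
  set.seed(seed)
  lens <- nchar(genome)
  slots_per_chrom <- pmax(1L, round(n_genes * lens / sum(lens)))
  while (sum(slots_per_chrom) < n_genes)
    slots_per_chrom[1L] <- slots_per_chrom[1L] + 1L
  while (sum(slots_per_chrom) > n_genes)
    slots_per_chrom[which.max(slots_per_chrom)] <-
      max(1L, slots_per_chrom[which.max(slots_per_chrom)] - 1L)
  genes <- list(); exons <- list(); tss <- list()
  gi <- 0L
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    n <- slots_per_chrom[ci]
    slot_len <- floor((lens[ci] - 6000) / n)
    if (slot_len < 4000)
      stop("chromosome too short for ", n, " genes")
    for (k in seq_len(n)) {
      gi <- gi + 1L
      slot0 <- 3000 + (k - 1L) * slot_len
      glen <- sample(3000:min(8000, slot_len - 500), 1L)
      gstart <- slot0 + sample.int(max(1L, slot_len - glen - 100L), 1L)
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("gene%02d", gi)
      gene_type <- if (gi %% 15L == 0L) "lncRNA" else "protein_coding"
      genes[[gi]] <- data.frame(gene_id = gene_id, chrom = ch,
                                start = gstart, end = gstart + glen,
                                strand = strand, gene_type = gene_type,
                                stringsAsFactors = FALSE)
      n_ex <- sample(2:4, 1L)
      ex_start <- sort(sample(seq(gstart, gstart + glen - 300, by = 50), n_ex))
      exons[[gi]] <- data.frame(gene_id = gene_id, chrom = ch,
                                start = ex_start,
                                end = ex_start + sample(100:300, n_ex,
                                                        replace = TRUE),
                                stringsAsFactors = FALSE)
      n_tss <- sample(1:3, 1L)
      anchor <- if (strand == "+") gstart else gstart + glen
      tpos <- unique(anchor + sample(0:400, n_tss) *
                       (if (strand == "+") 1L else -1L))
      tss[[gi]] <- data.frame(chrom = ch, pos = tpos + 1L, gene_id = gene_id,
                              stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  tss <- do.call(rbind, tss)
  # decoys: chrM TSS and a TSS on a non-coding gene
  tss <- rbind(tss, data.frame(chrom = "chrM", pos = 100L,
                               gene_id = genes$gene_id[1L],
                               stringsAsFactors = FALSE))
  list(genes = genes, exons = exons, tss = tss,
       truth = list(n_decoy_tss = 1L +
                      sum(tss$gene_id %in%
                            genes$gene_id[genes$gene_type != "protein_coding"]),
                    seed = seed))
}

#' Generate Hi-C interaction libraries with planted promoter edges
#'
#' Every planted edge receives 2-4 supporting read pairs spread over at least
#' two distinct replicates (so it passes the validity rule by construction);
#' each noise pair receives a single read in a single replicate (so it is
#' rejected). About 10% of planted reads are emitted twice under the same read
#' name to exercise deduplication.
#'
#' @param fragments fragment data.frame.
#' @param promoter_assignment list from [assign_promoter_fragments()].
#' @param planted_edges data.frame distal_fragment_id, promoter_fragment_id,
#'   gene_id.
#' @param n_replicates replicates per cell line (default 2; 2 cell lines).
#' @param noise_pairs number of single-support noise pairs (default 50).
#' @param seed RNG seed.
#' @return list: `records` (interaction record data.frame across all
#'   libraries), `truth` (planted pair keys).
#' @export
make_hic_library <- function(fragments, promoter_assignment, planted_edges,
                             n_replicates = 2L, noise_pairs = 50L, seed = 1L) {
  set.seed(seed)
  fr <- fragments
  idx_of <- setNames(seq_len(nrow(fr)), fr$fragment_id)
  rand_pos <- function(fid) {
    i <- idx_of[[fid]]
    floor(stats::runif(1L, fr$start[i], fr$end[i]))
  }
  reps <- expand.grid(cell_line_id = c("CL1", "CL2"),
                      replicate_id = paste0("rep", seq_len(n_replicates)),
                      stringsAsFactors = FALSE)
  rows <- list()
  rid <- 0L
  emit <- function(f1, f2, slot, name) {
    i1 <- idx_of[[f1]]; i2 <- idx_of[[f2]]
    data.frame(read_name = name,
               strand1 = sample(c("+", "-"), 1L), chrom1 = fr$chrom[i1],
               pos1 = rand_pos(f1),
               strand2 = sample(c("+", "-"), 1L), chrom2 = fr$chrom[i2],
               pos2 = rand_pos(f2),
               replicate_id = reps$replicate_id[slot],
               cell_line_id = reps$cell_line_id[slot],
               stringsAsFactors = FALSE)
  }
  for (e in seq_len(nrow(planted_edges))) {
    n_reads <- sample(2:4, 1L)
    slots <- c(sample(seq_len(nrow(reps)), 2L),
               sample(seq_len(nrow(reps)), max(0L, n_reads - 2L),
                      replace = TRUE))
    for (s in slots[seq_len(n_reads)]) {
      rid <- rid + 1L
      nm <- sprintf("read%06d", rid)
      rows[[length(rows) + 1L]] <- emit(planted_edges$distal_fragment_id[e],
                                        planted_edges$promoter_fragment_id[e],
                                        s, nm)
      if (stats::runif(1L) < 0.1)  # duplicate read name, same replicate
        rows[[length(rows) + 1L]] <- rows[[length(rows)]]
    }
  }
  planted_key <- paste(pmin(planted_edges$distal_fragment_id,
                            planted_edges$promoter_fragment_id),
                       pmax(planted_edges$distal_fragment_id,
                            planted_edges$promoter_fragment_id))
  if (noise_pairs > 0L) {
    tries <- 0L; added <- 0L
    used <- planted_key
    while (added < noise_pairs && tries < noise_pairs * 20L) {
      tries <- tries + 1L
      pair <- sample(fr$fragment_id, 2L)
      key <- paste(min(pair), max(pair))
      if (key %in% used) next  # keep every noise pair at single support
      used <- c(used, key)
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- emit(pair[1L], pair[2L],
                                        sample(seq_len(nrow(reps)), 1L),
                                        sprintf("read%06d", rid))
      added <- added + 1L
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "has_duplicates") <- anyDuplicated(records$read_name) > 0L
  list(records = records, truth = list(planted_pairs = sort(unique(planted_key)),
                                       seed = seed))
}

#' Write interaction records in the 9-column text format
#' @param records record data.frame (0-based positions; written 1-based).
#' @param path output path.
#' @export
write_interaction_file <- function(records, path) {
  lines <- paste(records$read_name, records$strand1, records$chrom1,
                 records$pos1 + 1, "frag_NA", records$strand2, records$chrom2,
                 records$pos2 + 1, "frag_NA", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Generate somatic SNVs with planted recurrence hotspots
#'
#' Exact per-position per-sample Bernoulli sampling (via thinning) with
#' probability base_rate x sample load factor x covariate-track multiplier x
#' hotspot multiplier.
#'
#' @param genome named character vector of sequences.
#' @param planted_hotspots data.frame chrom, start, end, multiplier (may have
#'   0 rows).
#' @param n_samples number of tumours (default 100).
#' @param base_rate per-bp per-sample mutation probability (default 3e-5,
#'   a melanoma-like load of ~30 mutations/Mb).
#' @param covariate_tracks named list of list(track = interval df,
#'   multiplier = numeric) elevating the rate inside the track.
#' @param load_sd log-sd of the per-sample load factor (default 0.3).
#' @param cancer_type cohort label (default "melanoma").
#' @param sample_prefix prefix for sample ids.
#' @param seed RNG seed.
#' @return list: `snvs` (SNV data.frame), `truth` (sample load factors,
#'   hotspot table).
#' @export
make_mutations <- function(genome, planted_hotspots = NULL, n_samples = 100L,
                           base_rate = 3e-5, covariate_tracks = NULL,
                           load_sd = 0.3, cancer_type = "melanoma",
                           sample_prefix = "S", seed = 1L) {
  set.seed(seed)
  lens <- nchar(genome)
  # per-position rate multiplier per chromosome
  mult <- lapply(names(genome), function(ch) {
    m <- rep(1, lens[[ch]])
    for (tr in covariate_tracks) {
      t <- tr$track[tr$track$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(t)))
        m[(t$start[r] + 1L):t$end[r]] <- m[(t$start[r] + 1L):t$end[r]] *
          tr$multiplier
    }
    if (!is.null(planted_hotspots)) {
      h <- planted_hotspots[planted_hotspots$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(h)))
        m[(h$start[r] + 1L):h$end[r]] <- m[(h$start[r] + 1L):h$end[r]] *
          h$multiplier[r]
    }
    m
  })
  names(mult) <- names(genome)
  sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
  load_factor <- exp(stats::rnorm(n_samples, 0, load_sd))
  rows <- list()
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in seq_len(n_samples)) {
    for (ch in names(genome)) {
      m <- mult[[ch]]
      pmax_i <- base_rate * load_factor[i] * max(m)
      if (pmax_i <= 0) next
      pmax_i <- min(pmax_i, 1)
      n_prop <- stats::rbinom(1L, lens[[ch]], pmax_i)
      if (n_prop == 0L) next
      pos <- sample.int(lens[[ch]], n_prop) - 1L  # 0-based, w/o replacement
      p <- base_rate * load_factor[i] * m[pos + 1L]
      keep <- stats::runif(n_prop) < p / pmax_i
      pos <- pos[keep]
      if (!length(pos)) next
      ref <- substring(genome[[ch]], pos + 1L, pos + 1L)
      ok <- ref %in% BASES
      pos <- pos[ok]; ref <- ref[ok]
      alt <- vapply(ref, function(b) sample(other[[b]], 1L), "")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[i], chrom = ch, pos = pos, ref = ref,
        alt = alt, cancer_type = cancer_type, stringsAsFactors = FALSE)
    }
  }
  snvs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = character(), pos = numeric(),
               ref = character(), alt = character(), cancer_type = character(),
               stringsAsFactors = FALSE)
  rownames(snvs) <- NULL
  snvs <- snvs[order(snvs$chrom, snvs$pos, snvs$sample_id), , drop = FALSE]
  list(snvs = snvs,
       truth = list(planted_hotspots = planted_hotspots,
                    load_factor = setNames(load_factor, sample_ids),
                    base_rate = base_rate, seed = seed))
}

#' Generate expression, CNA and methylation with planted eQTL effects
#'
#' Expression follows the eQTL regression model on the log2 scale: planted
#' hotspot effects, CNA, promoter methylation, sex and `k_latent` latent
#' factors plus Gaussian noise, then converted to RSEM-like raw counts with
#' per-sample depth factors so the 75th-percentile normalisation is
#' non-trivial.
#'
#' @param genes gene annotation data.frame.
#' @param hotspot_status samples x hotspots 0/1 matrix (column names must
#'   match `planted_eqtl$hotspot`).
#' @param planted_eqtl data.frame hotspot (column name), gene_id, beta.
#' @param covariates data.frame sample_id, sex (0/1).
#' @param promoter_regions data.frame from [define_promoter_regions()] (for
#'   probe placement).
#' @param k_latent number of latent factors (default 2).
#' @param noise_sd residual sd on the log2 scale (default 0.5).
#' @param seed RNG seed.
#' @return list: raw (genes x samples counts), cna, meth_beta (probes x
#'   samples), probe_positions, latent (samples x k), truth.
#' @export
make_expression <- function(genes, hotspot_status, planted_eqtl, covariates,
                            promoter_regions, k_latent = 2L, noise_sd = 0.5,
                            seed = 1L) {
  set.seed(seed)
  samples <- covariates$sample_id
  n <- length(samples)
  g_ids <- genes$gene_id
  G <- length(g_ids)
  cna <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), G * n, replace = TRUE,
                       prob = c(.03, .12, .7, .12, .03)), G, n,
                dimnames = list(g_ids, samples))
  latent <- matrix(stats::rnorm(n * k_latent), n, k_latent,
                   dimnames = list(samples,
                                   if (k_latent > 0L)
                                     paste0("lat", seq_len(k_latent))))
  lambda <- matrix(stats::rnorm(G * k_latent, 0, 0.6), G, k_latent)
  base_meth <- stats::runif(G, 0.1, 0.9)
  beta_cna <- 0.4; beta_m <- -1; beta_sex <- 0.3
  # gene-level methylation (before probe-level noise)
  meth_gene <- matrix(pmin(0.99, pmax(0.01,
    base_meth + stats::rnorm(G * n, 0, 0.05))), G, n,
    dimnames = list(g_ids, samples))
  z <- matrix(stats::rnorm(G * n, 0, noise_sd), G, n,
              dimnames = list(g_ids, samples))
  z <- z + beta_cna * cna + beta_m * meth_gene +
    matrix(rep(beta_sex * covariates$sex, each = G), G, n) +
    lambda %*% t(latent)
  for (r in seq_len(nrow(planted_eqtl))) {
    g <- planted_eqtl$gene_id[r]
    h <- hotspot_status[samples, planted_eqtl$hotspot[r]]
    z[g, ] <- z[g, ] + planted_eqtl$beta[r] * h
  }
  base_expr <- stats::runif(G, 4, 10)  # log2 baseline
  depth <- exp(stats::rnorm(n, 0, 0.25))
  raw <- round(sweep(2^(z + base_expr), 2L, depth, "*"))
  # promoter methylation probes: 2-3 per gene with a promoter region
  pr <- promoter_regions
  probe_rows <- list(); meth_rows <- list()
  pid <- 0L
  for (g in unique(pr$gene_id)) {
    p1 <- pr[pr$gene_id == g, , drop = FALSE][1L, ]
    n_probe <- sample(2:3, 1L)
    pos <- sort(sample(seq(p1$start, p1$end - 1L), n_probe))
    for (p in pos) {
      pid <- pid + 1L
      probe_id <- sprintf("probe%04d", pid)
      probe_rows[[pid]] <- data.frame(probe_id = probe_id, chrom = p1$chrom,
                                      pos = p, stringsAsFactors = FALSE)
      meth_rows[[pid]] <- pmin(0.99, pmax(0.01, meth_gene[g, ] +
                                            stats::rnorm(n, 0, 0.02)))
    }
  }
  probe_positions <- do.call(rbind, probe_rows)
  meth_beta <- do.call(rbind, meth_rows)
  rownames(meth_beta) <- probe_positions$probe_id
  colnames(meth_beta) <- samples
  list(raw = raw, cna = cna, meth_beta = meth_beta,
       probe_positions = probe_positions, latent = latent,
       truth = list(planted_eqtl = planted_eqtl, beta_cna = beta_cna,
                    beta_m = beta_m, beta_sex = beta_sex,
                    meth_gene = meth_gene, noise_sd = noise_sd, seed = seed))
}

#' Generate histone peaks, depletion-rank windows and PWMs
#'
#' Peaks land on planted-enriched fragments with probability `p_in` and on
#' other fragments with `p_out`; DR window scores are drawn lower (stronger
#' constraint) on planted-constrained fragments; the PWM set contains an
#' informative motif (pwm1), a moderately informative one and a
#' zero-information control.
#'
#' @param genome named character vector (for DR window tiling).
#' @param fragments fragment data.frame.
#' @param planted_enriched fragment ids carrying peaks at `p_in`.
#' @param planted_constrained fragment ids with lowered DR scores.
#' @param p_in,p_out per-fragment peak probabilities (defaults 0.8 / 0.1).
#' @param marks histone mark names (default H3K4me1, H3K27ac).
#' @param seed RNG seed.
#' @return list: peaks (named list of interval data.frames), dr_windows,
#'   pwms (list of `pif_pwm`), truth.
#' @export
make_tracks <- function(genome, fragments, planted_enriched = character(0),
                        planted_constrained = character(0),
                        p_in = 0.8, p_out = 0.1,
                        marks = c("H3K4me1", "H3K27ac"), seed = 1L) {
  set.seed(seed)
  peaks <- lapply(marks, function(mk) {
    pr <- ifelse(fragments$fragment_id %in% planted_enriched, p_in, p_out)
    sel <- which(stats::runif(nrow(fragments)) < pr)
    if (!length(sel))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    w <- pmin(500, fragments$end[sel] - fragments$start[sel])
    st <- fragments$start[sel] +
      floor(stats::runif(length(sel)) *
              (fragments$end[sel] - fragments$start[sel] - w + 1))
    data.frame(chrom = fragments$chrom[sel], start = st, end = st + w,
               stringsAsFactors = FALSE)
  })
  names(peaks) <- marks
  # 500-bp DR windows at 50-bp step; lower scores on constrained fragments
  dr <- do.call(rbind, lapply(names(genome), function(ch) {
    len <- nchar(genome[[ch]])
    st <- seq(0L, len - 500L, by = 50L)
    data.frame(chrom = ch, start = st, end = st + 500L,
               score = stats::runif(length(st), 0.2, 1),
               stringsAsFactors = FALSE)
  }))
  if (length(planted_constrained)) {
    cf <- fragments[fragments$fragment_id %in% planted_constrained, ,
                    drop = FALSE]
    hit <- GenomicRanges::findOverlaps(as_granges(dr), as_granges(cf),
                                       ignore.strand = TRUE)
    frac <- overlap_fraction(cf[S4Vectors::subjectHits(hit), , drop = FALSE],
                             dr[S4Vectors::queryHits(hit), , drop = FALSE])
    lower <- unique(S4Vectors::queryHits(hit)[frac > 0.5])
    dr$score[lower] <- stats::runif(length(lower), 0, 0.4)
  }
  # pwm1: highly informative 8-mer; pwm2: moderate; pwm3: zero information
  mk_pwm <- function(consensus, p_major, name) {
    L <- nchar(consensus)
    m <- matrix((1 - p_major) / 3, 4L, L, dimnames = list(BASES, NULL))
    cb <- strsplit(consensus, "")[[1L]]
    for (j in seq_len(L)) m[cb[j], j] <- p_major
    pwm(m, name)
  }
  pwms <- list(mk_pwm("TGACGTCA", 0.97, "TF1"),
               mk_pwm("GGAATG", 0.7, "TF2"),
               pwm(matrix(0.25, 4L, 6L, dimnames = list(BASES, NULL)), "TF3"))
  list(peaks = peaks, dr_windows = dr, pwms = pwms,
       truth = list(planted_enriched = planted_enriched,
                    planted_constrained = planted_constrained,
                    p_in = p_in, p_out = p_out, seed = seed))
}

#' Simulate a complete synthetic cohort with planted ground truth
#'
#' Orchestrates all generators: genome, digestion, genes/promoters, Hi-C with
#' planted edges, SNVs with planted hotspots, expression with planted eQTL
#' effects, and peak/DR/PWM tracks. The consensus of the informative PWM is
#' planted (before digestion bookkeeping is finalised) at the centre of the
#' first planted hotspot so motif-disruption scoring has a guaranteed target.
#'
#' @param seed global seed; per-stage seeds derive via [stage_seed()].
#' @param n_chroms,length_per_chrom,n_genes,n_samples,n_edges,n_hotspots,
#'   noise_pairs,base_rate,hotspot_multiplier,eqtl_beta,noise_sd scale and
#'   effect parameters (defaults are the package's study conditions).
#' @return list with every intermediate object plus `truth`.
#' @export
simulate_cohort <- function(seed = 1L, n_chroms = 2L, length_per_chrom = 2e5,
                            n_genes = 30L, n_samples = 100L, n_edges = 40L,
                            n_hotspots = 4L, noise_pairs = 50L,
                            base_rate = 3e-5, hotspot_multiplier = 100,
                            eqtl_beta = 1, noise_sd = 0.5) {
  gen <- make_genome(n_chroms, length_per_chrom, seed = stage_seed(seed, 1L))
  ann <- make_gene_annotation(gen$genome, n_genes, seed = stage_seed(seed, 2L))
  fragments <- digest_genome(gen$genome)
  gene_tss <- map_tss_to_genes(ann$tss, ann$genes)
  promoter_regions <- define_promoter_regions(
    gene_tss, chrom_lengths = nchar(gen$genome))
  pa <- assign_promoter_fragments(promoter_regions, fragments)

  set.seed(stage_seed(seed, 3L))
  nonprom <- fragments$fragment_id[!(fragments$fragment_id %in%
                                       pa$promoter_fragment_ids)]
  lens <- setNames(fragments$end - fragments$start, fragments$fragment_id)
  distal_pool <- nonprom[lens[nonprom] >= 200]
  distal <- sample(distal_pool, min(n_edges, length(distal_pool)))
  genes_with_prom <- unique(pa$per_gene$gene_id)
  target_gene <- sample(genes_with_prom, length(distal), replace = TRUE)
  prom_frag <- vapply(target_gene, function(g)
    pa$per_gene$fragment_id[pa$per_gene$gene_id == g][1L], "")
  planted_edges <- unique(data.frame(distal_fragment_id = distal,
                                     promoter_fragment_id = prom_frag,
                                     gene_id = target_gene,
                                     stringsAsFactors = FALSE))
  hic <- make_hic_library(fragments, pa, planted_edges,
                          noise_pairs = noise_pairs,
                          seed = stage_seed(seed, 3L))

  # planted hotspots: interior 31-bp windows, half in promoter fragments of
  # planted genes, half in planted distal (future non-coding PIF) fragments
  pick_window <- function(fid) {
    i <- match(fid, fragments$fragment_id)
    mid <- floor((fragments$start[i] + fragments$end[i]) / 2)
    data.frame(chrom = fragments$chrom[i], start = mid - 15L, end = mid + 16L,
               fragment_id = fid, stringsAsFactors = FALSE)
  }
  n_prom_hs <- ceiling(n_hotspots / 2)
  prom_candidates <- unique(prom_frag)[lens[unique(prom_frag)] >= 200]
  hs_frags <- c(sample(prom_candidates, min(n_prom_hs,
                                            length(prom_candidates))),
                sample(planted_edges$distal_fragment_id,
                       n_hotspots - min(n_prom_hs, length(prom_candidates))))
  planted_hotspots <- do.call(rbind, lapply(hs_frags, pick_window))
  planted_hotspots$multiplier <- hotspot_multiplier

  # plant the informative PWM consensus at the centre of the first hotspot
  # (the consensus contains no HindIII site, so the fragment map is unchanged)
  consensus <- "TGACGTCA"
  h1 <- planted_hotspots[1L, ]
  motif_truth <- NULL
  for (shift in c(0L, -8L, 8L)) {  # avoid the rare spot where planting would
    motif_start <- floor((h1$start + h1$end) / 2) - 4L + shift  # move a site
    g <- gen$genome[[h1$chrom]]
    substr(g, motif_start + 1L, motif_start + nchar(consensus)) <- consensus
    g2 <- gen$genome
    g2[[h1$chrom]] <- g
    if (identical(fragments$fragment_id, digest_genome(g2)$fragment_id)) {
      gen$genome <- g2
      motif_truth <- list(consensus = consensus, chrom = h1$chrom,
                          start = motif_start)
      break
    }
  }

  mut <- make_mutations(gen$genome, planted_hotspots, n_samples, base_rate,
                        seed = stage_seed(seed, 4L))
  covariates <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    sex = rep_len(c(0L, 1L), n_samples),
    ancestry = "European", cancer_type = "melanoma",
    stringsAsFactors = FALSE)

  hs_status <- hotspot_status_matrix(planted_hotspots, mut$snvs,
                                     covariates$sample_id)
  colnames(hs_status) <- paste0("ph", seq_len(nrow(planted_hotspots)))
  hs_gene <- vapply(planted_hotspots$fragment_id, function(f) {
    g1 <- pa$per_gene$gene_id[pa$per_gene$fragment_id == f]
    if (length(g1)) g1[1L] else
      planted_edges$gene_id[planted_edges$distal_fragment_id == f][1L]
  }, "")
  planted_eqtl <- data.frame(hotspot = colnames(hs_status), gene_id = hs_gene,
                             beta = eqtl_beta * c(1, -1)[1L +
                               (seq_len(nrow(planted_hotspots)) %% 2L)],
                             stringsAsFactors = FALSE)
  expr <- make_expression(ann$genes, hs_status, planted_eqtl, covariates,
                          promoter_regions, noise_sd = noise_sd,
                          seed = stage_seed(seed, 5L))
  tracks <- make_tracks(gen$genome, fragments,
                        planted_enriched = planted_edges$distal_fragment_id,
                        planted_constrained = planted_edges$distal_fragment_id,
                        seed = stage_seed(seed, 6L))
  list(genome = gen$genome, fragments = fragments, genes = ann$genes,
       exons = ann$exons, tss = ann$tss, gene_tss = gene_tss,
       promoter_regions = promoter_regions, promoter_assignment = pa,
       hic = hic, snvs = mut$snvs, covariates = covariates,
       expression = expr, tracks = tracks,
       truth = list(seed = seed, genome = gen$truth, annotation = ann$truth,
                    planted_edges = planted_edges,
                    planted_pairs = hic$truth$planted_pairs,
                    planted_hotspots = planted_hotspots,
                    planted_eqtl = planted_eqtl,
                    motif = motif_truth,
                    mutations = mut$truth, expression = expr$truth,
                    tracks = tracks$truth))
}

#' Write a simulated cohort to a directory tree
#'
#' Emits the real-data file layout: genome FASTA, fragment BED, TSS/gene/exon
#' tables, per-replicate Hi-C interaction files, SNV table, expression /
#' CNA / methylation matrices, covariates, narrowPeak-like peak BEDs, DR
#' window table, PWM file and `truth.json`.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(cohort$genome, file.path(dir, "genome.fa"))
  write_bed(cohort$fragments, file.path(dir, "fragments.bed"),
            extra_columns = data.frame(name = cohort$fragments$fragment_id))
  utils::write.table(cohort$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$exons, file.path(dir, "exons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hic_dir <- file.path(dir, "hic")
  dir.create(hic_dir, showWarnings = FALSE)
  rec <- cohort$hic$records
  for (cl in unique(rec$cell_line_id)) for (rp in unique(rec$replicate_id)) {
    sub <- rec[rec$cell_line_id == cl & rec$replicate_id == rp, , drop = FALSE]
    if (nrow(sub))
      write_interaction_file(sub, file.path(hic_dir,
                                            paste0(cl, "_", rp, ".txt")))
  }
  write_snv_table(cohort$snvs, file.path(dir, "snvs.tsv"))
  write_matrix_table(cohort$expression$raw, file.path(dir, "expression.tsv"))
  write_matrix_table(cohort$expression$cna, file.path(dir, "cna.tsv"))
  write_matrix_table(cohort$expression$meth_beta,
                     file.path(dir, "methylation.tsv"),
                     rowname_header = "probe_id")
  utils::write.table(cohort$expression$probe_positions,
                     file.path(dir, "probes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  for (mk in names(cohort$tracks$peaks))
    write_bed(cohort$tracks$peaks[[mk]],
              file.path(peak_dir, paste0(mk, ".bed")))
  utils::write.table(cohort$tracks$dr_windows, file.path(dir, "dr_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pwm_file(cohort$tracks$pwms, file.path(dir, "pwms.txt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
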