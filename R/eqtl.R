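# Somatic eQTL analysis: expression normalisation, promoter methylation
# aggregation, residual-PCA hidden factors, per-gene design assembly over
# network-linked hotspots, Lasso feature selection with lambda relaxation,
# and OLS with hotspot-level t tests plus a gene-level F test against the
# hotspot-free reduced model.

#' Normalise an RSEM-like expression matrix
#'
#' Per-sample 75th-percentile scaling x1000, gene filter (normalised median
#' above 1 across samples), log2(x + 1), then per-gene z-score.
#'
#' @param raw genes x samples matrix of non-negative counts.
#' @return list: `matrix` (retained genes x samples, z-scored), `stages`
#'   (applied transforms), `dropped_low` (genes failing the median filter),
#'   `dropped_constant` (genes with zero variance after log).
#' @export
normalize_expression <- function(raw) {
  if (any(raw < 0)) stop("expression counts must be >= 0")
  q75 <- apply(raw, 2L, stats::quantile, probs = 0.75)
  if (any(q75 <= 0)) stop("sample with non-positive 75th percentile (all-zero?)")
  norm <- sweep(raw, 2L, q75, "/") * 1000
  med <- apply(norm, 1L, stats::median)
  keep <- med > 1
  dropped_low <- rownames(raw)[!keep]
  lg <- log2(norm[keep, , drop = FALSE] + 1)
  sds <- apply(lg, 1L, stats::sd)
  dropped_const <- rownames(lg)[sds == 0]
  lg <- lg[sds > 0, , drop = FALSE]
  z <- t(scale(t(lg)))
  list(matrix = z,
       stages = c("quantile75_x1000", "median_gt1_filter", "log2_plus1",
                  "zscore"),
       dropped_low = dropped_low, dropped_constant = dropped_const)
}

#' Mean promoter methylation per gene and sample
#'
#' Averages beta values of probes located inside the gene's promoter
#' intervals; missing per-sample values are imputed with the gene's
#' cross-sample mean. Genes without any promoter probe are absent from the
#' output (and must be excluded from eQTL fitting).
#'
#' @param beta probes x samples matrix of beta values (may contain NA).
#' @param probe_positions data.frame probe_id, chrom, pos (0-based).
#' @param promoter_regions data.frame from [define_promoter_regions()].
#' @return genes x samples matrix of mean promoter beta values.
#' @export
promoter_methylation <- function(beta, probe_positions, promoter_regions) {
  pr_gr <- as_granges(promoter_regions)
  probe_gr <- GenomicRanges::GRanges(
    probe_positions$chrom,
    IRanges::IRanges(probe_positions$pos + 1L, probe_positions$pos + 1L))
  hit <- GenomicRanges::findOverlaps(probe_gr, pr_gr, ignore.strand = TRUE)
  if (length(hit) == 0L)
    return(matrix(0, 0L, ncol(beta), dimnames = list(NULL, colnames(beta))))
  map <- data.frame(
    probe = probe_positions$probe_id[S4Vectors::queryHits(hit)],
    gene = promoter_regions$gene_id[S4Vectors::subjectHits(hit)],
    stringsAsFactors = FALSE)
  map <- unique(map)
  genes <- sort(unique(map$gene))
  out <- matrix(NA_real_, length(genes), ncol(beta),
                dimnames = list(genes, colnames(beta)))
  for (g in genes) {
    probes <- map$probe[map$gene == g]
    sub <- beta[probes, , drop = FALSE]
    out[g, ] <- colMeans(sub, na.rm = TRUE)
  }
  # impute samples with no observed probe value to the gene mean
  for (i in seq_len(nrow(out))) {
    miss <- is.na(out[i, ])
    if (any(miss)) out[i, miss] <- mean(out[i, !miss])
  }
  out
}

#' Residual-PCA hidden expression factors
#'
#' Regresses known covariates out of each gene's expression and takes the
#' first `k` right singular vectors of the residual matrix as sample-level
#' latent factors (orthonormal columns).
#'
#' @param expr genes x samples matrix (normalised).
#' @param known_covariates samples x p numeric matrix (or NULL for
#'   intercept-only residuals).
#' @param k number of factors; 0 returns a 0-column matrix.
#' @return samples x k matrix of factors.
#' @export
estimate_hidden_factors <- function(expr, known_covariates = NULL, k) {
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0L)
    return(matrix(0, n, 0L, dimnames = list(colnames(expr), NULL)))
  X <- cbind(intercept = rep(1, n))
  if (!is.null(known_covariates) && NCOL(known_covariates) > 0L)
    X <- cbind(X, as.matrix(known_covariates))
  qrX <- qr(X)
  # residual of each gene row against the covariate space
  res <- t(qr.resid(qrX, t(expr)))
  sv <- svd(res, nu = 0L, nv = k)
  f <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(f) <- list(colnames(expr), paste0("f", seq_len(k)))
  f
}

#' Hotspots eligible for eQTL testing
#'
#' @param hotspots data.frame from [merge_and_correct()].
#' @param snvs SNV data.frame.
#' @param reference_samples sample ids of the reference cohort.
#' @param min_mutated minimum mutated reference samples (default 3).
#' @return subset of `hotspots`.
#' @export
eligible_hotspots <- function(hotspots, snvs, reference_samples,
                              min_mutated = 3L) {
  ref <- snvs[snvs$sample_id %in% reference_samples, , drop = FALSE]
  keep <- vapply(seq_len(nrow(hotspots)), function(i) {
    inside <- ref$chrom == hotspots$chrom[i] & ref$pos >= hotspots$start[i] &
      ref$pos < hotspots$end[i]
    length(unique(ref$sample_id[inside])) >= min_mutated
  }, TRUE)
  hotspots[keep, , drop = FALSE]
}

#' Link hotspots to genes through the promoter-interaction network
#'
#' A hotspot in a promoter fragment links to that fragment's genes; a hotspot
#' in a PIF links to the genes of every edge anchored at that fragment.
#'
#' @param hotspots data.frame with region_id (the host fragment).
#' @param network list from [build_network()].
#' @param promoter_assignment list from [assign_promoter_fragments()].
#' @return data.frame hotspot_idx, gene_id.
#' @export
link_hotspots_to_genes <- function(hotspots, network, promoter_assignment) {
  pg <- promoter_assignment$per_gene
  out <- list()
  for (i in seq_len(nrow(hotspots))) {
    rid <- hotspots$region_id[i]
    genes <- pg$gene_id[pg$fragment_id == rid]
    e <- network$edges[network$edges$distal_fragment_id == rid, , drop = FALSE]
    if (nrow(e) > 0L)
      genes <- c(genes, unlist(strsplit(e$gene_ids, ",", fixed = TRUE)))
    genes <- sort(unique(genes))
    if (length(genes))
      out[[length(out) + 1L]] <- data.frame(hotspot_idx = i, gene_id = genes,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(hotspot_idx = integer(), gene_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-sample hotspot mutation status
#' @param hotspots data.frame of hotspots.
#' @param snvs SNV data.frame.
#' @param samples sample ids defining the column order.
#' @return samples x hotspots 0/1 matrix (columns `h1`, `h2`, ...).
#' @export
hotspot_status_matrix <- function(hotspots, snvs, samples) {
  m <- matrix(0L, length(samples), nrow(hotspots),
              dimnames = list(samples, paste0("h", seq_len(nrow(hotspots)))))
  for (i in seq_len(nrow(hotspots))) {
    inside <- snvs$chrom == hotspots$chrom[i] & snvs$pos >= hotspots$start[i] &
      snvs$pos < hotspots$end[i]
    mut <- intersect(unique(snvs$sample_id[inside]), samples)
    m[mut, i] <- 1L
  }
  m
}

# one-hot encode a factor dropping the first (reference) level
one_hot_drop_first <- function(x, prefix) {
  f <- factor(x)
  lv <- levels(f)
  if (length(lv) < 2L) return(NULL)
  m <- vapply(lv[-1L], function(l) as.numeric(f == l), numeric(length(x)))
  colnames(m) <- paste0(prefix, lv[-1L])
  m
}

#' Assemble the eQTL design matrix for one gene
#'
#' Columns: hotspot status h1..hn, CNA, m (promoter methylation), sex, and in
#' extended mode one-hot ancestry and cancer-type blocks (first level
#' dropped), plus hidden factors.
#'
#' @param hotspot_status samples x hotspots 0/1 matrix for this gene's linked
#'   hotspots.
#' @param cna per-sample CNA values for this gene (-2..2).
#' @param meth per-sample mean promoter beta for this gene.
#' @param covariates data.frame with sample_id, sex (0/1) and, for extended
#'   mode, ancestry and cancer_type.
#' @param hidden_factors samples x k matrix.
#' @param mode "melanoma_only" (omits ancestry/cancer type) or "extended".
#' @return list: `X` (samples x p numeric matrix), `hotspot_cols` (column
#'   names of the hotspot block).
#' @export
assemble_design <- function(hotspot_status, cna, meth, covariates,
                            hidden_factors, mode = c("melanoma_only",
                                                     "extended")) {
  mode <- match.arg(mode)
  if (ncol(hotspot_status) == 0L) stop("gene has no eligible linked hotspot")
  X <- cbind(hotspot_status, CNA = as.numeric(cna), m = as.numeric(meth),
             sex = as.numeric(covariates$sex))
  if (mode == "extended") {
    anc <- one_hot_drop_first(covariates$ancestry, "anc_")
    ct <- one_hot_drop_first(covariates$cancer_type, "CT_")
    if (!is.null(anc)) X <- cbind(X, anc)
    if (!is.null(ct)) X <- cbind(X, ct)
  }
  if (!is.null(hidden_factors) && ncol(hidden_factors) > 0L)
    X <- cbind(X, hidden_factors)
  list(X = X, hotspot_cols = colnames(hotspot_status))
}

#' Lasso feature selection with hotspot-forcing lambda relaxation
#'
#' lambda is chosen by 10-fold cross-validated MSE over a 100-value log grid
#' spanning \[lambda_max, 1e-4 lambda_max\]. If every hotspot coefficient is
#' zero at the chosen lambda, lambda is stepped down the grid until at least
#' one hotspot enters (`relaxed = TRUE`); if no hotspot enters even at the
#' smallest lambda, the hotspot most correlated with y is forced in
#' (`forced = TRUE`).
#'
#' @param y response vector.
#' @param X design matrix from [assemble_design()].
#' @param hotspot_cols hotspot column names.
#' @param n_folds CV folds (default 10).
#' @param seed seed fixing the fold assignment.
#' @return list: selected (column names), lambda, relaxed, forced.
#' @export
lasso_select <- function(y, X, hotspot_cols, n_folds = 10L, seed = 1L) {
  n <- length(y)
  if (n < n_folds) stop("need at least n_folds samples")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  path <- glmnet::glmnet(X, y, alpha = 1, nlambda = 100,
                         lambda.min.ratio = 1e-4)
  grid <- path$lambda
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = grid, foldid = foldid)
  lambda <- cv$lambda.min
  coef_at <- function(l) {
    b <- as.numeric(coef(path, s = l, exact = FALSE))[-1L]
    names(b) <- colnames(X)
    b
  }
  b <- coef_at(lambda)
  relaxed <- FALSE; forced <- FALSE
  if (all(b[hotspot_cols] == 0)) {
    relaxed <- TRUE
    for (l in grid[grid < lambda]) {
      b <- coef_at(l)
      if (any(b[hotspot_cols] != 0)) { lambda <- l; break }
    }
  }
  selected <- names(b)[b != 0]
  if (!any(hotspot_cols %in% selected)) {
    forced <- TRUE
    cors <- abs(apply(X[, hotspot_cols, drop = FALSE], 2L, function(h)
      if (stats::sd(h) == 0) 0 else stats::cor(y, h)))
    selected <- c(selected, names(which.max(cors)))
  }
  list(selected = selected, lambda = lambda, relaxed = relaxed,
       forced = forced)
}

#' OLS fit with hotspot t tests and gene-level F test
#'
#' Fits y on the selected columns by ordinary least squares, reports the
#' two-sided t test per hotspot coefficient, and the F test of the full model
#' against the reduced model with the hotspot columns removed (non-hotspot
#' columns matched). Collinear columns are dropped in QR order.
#'
#' @param y response vector.
#' @param X_selected samples x p matrix of selected columns.
#' @param hotspot_cols names of the hotspot columns inside `X_selected`.
#' @return list: coefficients, hotspot_stats (data.frame term, beta, t, p),
#'   f_stat, f_p, dropped (collinear columns removed).
#' @export
fit_and_test <- function(y, X_selected, hotspot_cols) {
  hotspot_cols <- intersect(hotspot_cols, colnames(X_selected))
  if (length(hotspot_cols) == 0L)
    stop("no hotspot column in the selected design")
  df <- data.frame(y = y, X_selected, check.names = FALSE)
  full <- stats::lm(y ~ ., data = df)
  dropped <- names(coef(full))[is.na(coef(full))]
  if (length(dropped)) {
    keep <- setdiff(colnames(X_selected), dropped)
    df <- data.frame(y = y, X_selected[, keep, drop = FALSE],
                     check.names = FALSE)
    full <- stats::lm(y ~ ., data = df)
    hotspot_cols <- intersect(hotspot_cols, keep)
    if (length(hotspot_cols) == 0L)
      stop("all hotspot columns collinear with covariates")
  }
  other <- setdiff(names(df), c("y", hotspot_cols))
  red_df <- df[, c("y", other), drop = FALSE]
  reduced <- stats::lm(y ~ ., data = red_df)
  an <- stats::anova(reduced, full)
  sm <- summary(full)$coefficients
  # lm backtick-quotes non-syntactic names; match on cleaned rownames
  rn <- gsub("`", "", rownames(sm))
  hs <- do.call(rbind, lapply(hotspot_cols, function(h) {
    i <- match(h, rn)
    data.frame(term = h, beta = sm[i, 1L], t = sm[i, 3L], p = sm[i, 4L],
               stringsAsFactors = FALSE)
  }))
  rownames(hs) <- NULL
  list(coefficients = setNames(coef(full), gsub("`", "", names(coef(full)))),
       hotspot_stats = hs,
       f_stat = an$F[2L], f_p = an$`Pr(>F)`[2L], dropped = dropped)
}

#' Benjamini-Hochberg q values
#' @param p_values numeric vector of P values in \[0, 1\].
#' @return step-up adjusted q values.
#' @export
bh_fdr <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Run the somatic eQTL analysis over all linked genes
#'
#' For every gene with at least one eligible network-linked hotspot and
#' complete expression/CNA/methylation data: assemble the design, select
#' features by Lasso (hotspots forced in when necessary), fit OLS, and report
#' hotspot-level and gene-level statistics with independent BH corrections.
#'
#' @param expr normalised expression list from [normalize_expression()] or a
#'   genes x samples matrix.
#' @param hotspots eligible hotspot data.frame.
#' @param snvs SNV data.frame.
#' @param network list from [build_network()].
#' @param promoter_assignment list from [assign_promoter_fragments()].
#' @param cna genes x samples CNA matrix.
#' @param meth genes x samples promoter methylation matrix.
#' @param covariates data.frame sample_id, sex (+ ancestry, cancer_type for
#'   extended mode).
#' @param k_hidden number of residual-PCA hidden factors.
#' @param mode "melanoma_only" or "extended".
#' @param seed seed for CV fold assignment.
#' @param gene_annotation optional gene table (gene_id, chrom, start, end,
#'   strand) used to report the strand-adjusted hotspot-gene distance.
#' @return list: `results` (data.frame gene_id, hotspot columns, beta, t, p,
#'   q, gene_f, gene_p, gene_q, relaxed, forced, distance), `n_genes_tested`.
#' @export
run_somatic_eqtl <- function(expr, hotspots, snvs, network,
                             promoter_assignment, cna, meth, covariates,
                             k_hidden = 7L,
                             mode = c("melanoma_only", "extended"),
                             seed = 1L, gene_annotation = NULL) {
  mode <- match.arg(mode)
  emat <- if (is.list(expr) && !is.null(expr$matrix)) expr$matrix else expr
  samples <- colnames(emat)
  covariates <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  known <- cbind(sex = as.numeric(covariates$sex))
  if (mode == "extended") {
    anc <- one_hot_drop_first(covariates$ancestry, "anc_")
    ct <- one_hot_drop_first(covariates$cancer_type, "CT_")
    known <- cbind(known, anc, ct)
  }
  f <- estimate_hidden_factors(emat, known, k_hidden)
  status_all <- hotspot_status_matrix(hotspots, snvs, samples)
  links <- link_hotspots_to_genes(hotspots, network, promoter_assignment)
  genes <- intersect(intersect(unique(links$gene_id), rownames(emat)),
                     intersect(rownames(cna), rownames(meth)))
  rows <- list()
  gene_rows <- list()
  for (g in genes) {
    hidx <- sort(unique(links$hotspot_idx[links$gene_id == g]))
    hs <- status_all[, hidx, drop = FALSE]
    hname <- paste0("hs", hidx)
    colnames(hs) <- hname
    keep <- apply(hs, 2L, stats::var) > 0
    hs <- hs[, keep, drop = FALSE]
    if (ncol(hs) == 0L) next
    des <- assemble_design(hs, cna[g, samples], meth[g, samples], covariates,
                           f, mode)
    y <- emat[g, ]
    sel <- lasso_select(y, des$X, des$hotspot_cols, seed = seed)
    Xs <- des$X[, sel$selected, drop = FALSE]
    ft <- fit_and_test(y, Xs, intersect(des$hotspot_cols, sel$selected))
    hs_idx_kept <- as.integer(sub("^hs", "", ft$hotspot_stats$term))
    dist <- rep(NA_real_, nrow(ft$hotspot_stats))
    if (!is.null(gene_annotation)) {
      gi <- match(g, gene_annotation$gene_id)
      if (!is.na(gi)) {
        gstart <- if (gene_annotation$strand[gi] == "+")
          gene_annotation$start[gi] else gene_annotation$end[gi]
        sgn <- if (gene_annotation$strand[gi] == "+") 1 else -1
        dist <- sgn * (hotspots$start[hs_idx_kept] - gstart)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, hotspot_idx = hs_idx_kept,
      hotspot_chrom = hotspots$chrom[hs_idx_kept],
      hotspot_start = hotspots$start[hs_idx_kept],
      hotspot_end = hotspots$end[hs_idx_kept],
      beta = ft$hotspot_stats$beta, t = ft$hotspot_stats$t,
      p = ft$hotspot_stats$p, distance = dist,
      relaxed = sel$relaxed, forced = sel$forced, stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = g, f_stat = ft$f_stat, gene_p = ft$f_p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(results = NULL, gene_level = NULL, n_genes_tested = 0L))
  res <- do.call(rbind, rows)
  gl <- do.call(rbind, gene_rows)
  res$q <- bh_fdr(res$p)
  gl$gene_q <- bh_fdr(gl$gene_p)
  res$gene_p <- gl$gene_p[match(res$gene_id, gl$gene_id)]
  res$gene_q <- gl$gene_q[match(res$gene_id, gl$gene_id)]
  list(results = res, gene_level = gl, n_genes_tested = nrow(gl),
       hidden_factors = f)
}
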