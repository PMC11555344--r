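# Shared fixtures and independently written oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

# one full synthetic cohort per seed, generated once per test run
shared_cohort <- function(seed = 1L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cohort(seed = seed)
  .fixture_env[[key]]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# digestion oracle: plain regex scan for the literal site, cut at offset
brute_digest <- function(seq, site = "AAGCTT", offset = 1L) {
  hits <- gregexpr(site, seq, fixed = TRUE)[[1L]]
  starts <- if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
  cuts <- starts + offset
  cuts <- cuts[cuts > 0L & cuts < nchar(seq)]
  bounds <- c(0L, sort(unique(cuts)), nchar(seq))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q_sorted[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Poisson-binomial tail by exhaustive enumeration over all 2^n outcomes
pb_tail_oracle <- function(probs, k) {
  n <- length(probs)
  if (k <= 0L) return(1)
  if (k > n) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[seq_len(n)])
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1L, probs, 1 - probs))
  }
  total
}

# brute-force promoter-interaction network from raw interaction records:
# linear-search fragment lookup, read-name deduplication, the >= 2 support /
# >= 2 replicate rule, and the one-side-promoter requirement
brute_network_pairs <- function(records, fragments, promoter_ids,
                                min_support = 2L, min_replicates = 2L) {
  find_frag <- function(chrom, pos) {
    for (i in seq_len(nrow(fragments))) {
      if (fragments$chrom[i] == chrom && pos >= fragments$start[i] &&
          pos < fragments$end[i])
        return(fragments$fragment_id[i])
    }
    NA_character_
  }
  seen <- character(0)   # dedup key: pair + read name + cell + replicate
  support <- list()      # pair -> vector of "cell:replicate" labels
  for (r in seq_len(nrow(records))) {
    f1 <- find_frag(records$chrom1[r], records$pos1[r])
    f2 <- find_frag(records$chrom2[r], records$pos2[r])
    if (is.na(f1) || is.na(f2) || f1 == f2) next
    pair <- paste(min(f1, f2), max(f1, f2), sep = "|")
    dk <- paste(pair, records$read_name[r], records$cell_line_id[r],
                records$replicate_id[r])
    if (dk %in% seen) next
    seen <- c(seen, dk)
    support[[pair]] <- c(support[[pair]],
                         paste(records$cell_line_id[r],
                               records$replicate_id[r], sep = ":"))
  }
  keep <- character(0)
  for (pair in names(support)) {
    fr <- strsplit(pair, "|", fixed = TRUE)[[1L]]
    one_prom <- xor(fr[1L] %in% promoter_ids, fr[2L] %in% promoter_ids)
    if (length(support[[pair]]) >= min_support &&
        length(unique(support[[pair]])) >= min_replicates && one_prom)
      keep <- c(keep, pair)
  }
  sort(keep)
}

# all-words enumeration of the normalised PWM score distribution (L <= 6)
enumerate_pwm_scores <- function(p) {
  L <- ncol(p$matrix)
  words <- do.call(expand.grid,
                   c(rep(list(c("A", "C", "G", "T")), L),
                     stringsAsFactors = FALSE))
  scores <- apply(words, 1L, function(w)
    score_window(paste(w, collapse = ""), p))
  probs <- apply(words, 1L, function(w)
    prod(p$background[unlist(w)]))
  data.frame(score = scores, prob = probs)
}
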