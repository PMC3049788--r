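# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the implementation.

# naive scan-and-split digestion: check every window against the site
oracle_digest <- function(seq, site = "GATC") {
  L <- nchar(seq)
  k <- nchar(site)
  cuts <- integer()
  if (L >= k) {
    wins <- substring(seq, seq_len(L - k + 1L), k:L)
    cuts <- which(wins == site) - 1L
  }
  b <- sort(unique(c(0L, cuts, L)))
  data.frame(start = b[-length(b)], end = b[-1L])
}

# all-pairs nearest block by center distance, tie to smaller start
oracle_nearest <- function(query_row, blocks) {
  bl <- blocks[blocks$chrom == query_row$chrom, , drop = FALSE]
  if (!nrow(bl)) return(list(distance = NA_real_, start = NA_integer_))
  qc <- (query_row$start + query_row$end) %/% 2
  bc <- (bl$start + bl$end) %/% 2
  d <- abs(qc - bc)
  best <- which(d == min(d))
  best <- best[which.min(bl$start[best])]
  list(distance = d[best], start = bl$start[best])
}

# per-bp interval subtraction with score inheritance
oracle_subtract <- function(conserved, exons, L = 2200L) {
  out <- list()
  for (i in seq_len(nrow(conserved))) {
    covered <- rep(TRUE, L)
    covered[-seq(conserved$start[i] + 1L, conserved$end[i])] <- FALSE
    ex <- exons[exons$chrom == conserved$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      if (ex$end[j] > ex$start[j])
        covered[seq(ex$start[j] + 1L, ex$end[j])] <- FALSE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = conserved$chrom[i], start = starts[keep], end = ends[keep],
        score = conserved$score[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exact two-sided rank-sum p by enumeration of all rank assignments
# (tie-free data only)
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subs <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[subs], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# hypergeometric upper tail by literal enumeration of all n-subsets of a
# universe whose first K elements form the gene set
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# minimal gap between two 0-based half-open intervals (0 when overlapping)
oracle_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

# the worked micro-genome used throughout:
# "AAGATCTTGATCAA" digests into [0,2) [2,8) [8,14)
tiny_index <- function() {
  digest_genome(genome_index(sequences = c(c1 = "AAGATCTTGATCAA")))
}

# a small multi-chromosome synthetic study for integration-style tests
small_cfg <- function(seed = 101L, ...) {
  args <- list(seed = seed, n_chroms = 3L, chrom_length = 8e4,
               n_blocks_per_chrom = 5L, total_tags = 2e4,
               cis_decay_exponent = 1.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# library_counts from a bare table (chrom, start, end, count)
lib_from <- function(df, bait_id = "B") {
  library_counts(df, bait_id = bait_id)
}

# cir_set built directly from member coordinates (for set-arithmetic tests)
cir_from_members <- function(members, bait_obj, threshold = 50L) {
  structure(list(bait = bait_obj, threshold = threshold,
                 members = members, excluded_flanking = NULL),
            class = "cir_set")
}

fake_bait <- function(chrom = "c1", start = 0L, end = 2L, ordinal = 0L,
                      id = "B1") {
  bait(id, data.frame(chrom = chrom, start = start, end = end,
                      ordinal = ordinal, stringsAsFactors = FALSE))
}
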