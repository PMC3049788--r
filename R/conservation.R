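# Conservation-proximity analysis: non-exonic conservation blocks,
# center-to-center nearest distances, the sampled genomic null, and the
# two-sample Wilcoxon comparison with Q-Q summaries.

#' Build non-exonic conservation blocks
#'
#' Subtracts the union of exonic intervals from each conserved element;
#' the resulting pieces inherit the parent element's score, and pieces of
#' zero length disappear. Blocks are returned sorted by chromosome and
#' start.
#'
#' @param conserved data.frame of conserved elements (`chrom`, `start`,
#'   `end`, `score`), e.g. PhastCons most-conserved elements read with
#'   [read_bed()].
#' @param exons data.frame of exonic intervals (`chrom`, `start`, `end`).
#' @return data.frame of class `conservation_blocks` (`chrom`, `start`,
#'   `end`, `score`), with a `"provenance"` attribute.
#' @export
build_nonexonic_blocks <- function(conserved, exons) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(conserved)))
  if (nrow(conserved) == 0L || nrow(exons) == 0L) {
    out <- conserved[, c("chrom", "start", "end", "score")]
  } else {
    levs <- unique(c(conserved$chrom, exons$chrom))
    gb <- GenomicRanges::GRanges(
      factor(conserved$chrom, levels = levs),
      IRanges::IRanges(conserved$start + 1L, conserved$end))
    ge <- GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(exons$chrom, levels = levs),
      IRanges::IRanges(exons$start + 1L, exons$end)))
    pieces <- GenomicRanges::subtract(gb, ge, ignore.strand = TRUE)
    lens <- S4Vectors::elementNROWS(pieces)
    flat <- unlist(pieces, use.names = FALSE)
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(flat)),
      start = BiocGenerics::start(flat) - 1L,
      end = BiocGenerics::end(flat),
      score = rep(conserved$score, lens),
      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(n_conserved = nrow(conserved),
                                  n_exons = nrow(exons))
  class(out) <- c("conservation_blocks", "data.frame")
  out
}

#' Nearest conservation block, center to center
#'
#' For each query interval, finds the same-chromosome block whose center is
#' nearest to the query center (floor midpoints); ties are broken toward
#' the block with the smaller start. Queries on chromosomes without any
#' block get `NA` and are counted, not errored.
#'
#' @param query data.frame of intervals (`chrom`, `start`, `end`).
#' @param blocks Blocks from [build_nonexonic_blocks()] (any data.frame
#'   with `chrom`, `start`, `end` and optionally `score`).
#' @return data.frame with one row per query: `block` (row index into
#'   `blocks`, `NA` if none on the chromosome), `distance` (bp) and
#'   `score` (of the nearest block, if `blocks` carries scores).
#' @export
nearest_block <- function(query, blocks) {
  qc <- fragment_center(query)
  bc <- fragment_center(blocks)
  ord <- order(blocks$chrom, bc, blocks$start)
  res_block <- rep(NA_integer_, nrow(query))
  res_dist <- rep(NA_real_, nrow(query))
  for (ch in unique(query$chrom)) {
    bi <- ord[blocks$chrom[ord] == ch]
    qi <- which(query$chrom == ch)
    if (!length(bi)) next
    centers <- bc[bi]
    j <- findInterval(qc[qi], centers)
    left <- pmax(j, 1L)
    right <- pmin(j + 1L, length(bi))
    dl <- abs(qc[qi] - centers[left])
    dr <- abs(qc[qi] - centers[right])
    use_left <- dl <= dr            # tie -> left, i.e. smaller start
    pick <- ifelse(use_left, left, right)
    res_block[qi] <- bi[pick]
    res_dist[qi] <- pmin(dl, dr)
  }
  out <- data.frame(block = res_block, distance = res_dist)
  if (!is.null(blocks$score)) out$score <- blocks$score[res_block]
  out
}

#' Distance sample to nearest conservation blocks
#'
#' One center-to-center distance per member fragment (or per supplied
#' fragment). Fragments on chromosomes without blocks are excluded and the
#' exclusion is counted.
#'
#' @param x A `cir_set` (member fragments are used) or a data.frame of
#'   fragments.
#' @param blocks Blocks from [build_nonexonic_blocks()].
#' @param label Sample label, e.g. `"experiment"`, `"control"`,
#'   `"simulation"`, `"nonCNC"`.
#' @return Object of class `distance_sample`: `label`, `values` (bp),
#'   `scores` (nearest-block scores, if available), `source_bait_ids`,
#'   `n_excluded`.
#' @export
distance_sample <- function(x, blocks,
                            label = c("experiment", "control",
                                      "simulation", "nonCNC")) {
  label <- match.arg(label)
  if (inherits(x, "cir_set")) {
    frags <- x$members
    src <- x$bait$bait_id
  } else {
    frags <- x
    src <- attr(x, "bait_id") %||% NA_character_
  }
  nb <- nearest_block(frags, blocks)
  ok <- !is.na(nb$distance)
  structure(list(label = label,
                 values = nb$distance[ok],
                 scores = if (!is.null(nb$score)) nb$score[ok] else NULL,
                 source_bait_ids = src,
                 n_excluded = sum(!ok)),
            class = "distance_sample")
}

#' Pool distance samples
#'
#' Concatenates values (and scores) of samples sharing a label, recording
#' all contributing bait ids.
#'
#' @param ... `distance_sample` objects.
#' @return A pooled `distance_sample`.
#' @export
pool_distance_samples <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  scores <- lapply(xs, `[[`, "scores")
  structure(list(label = xs[[1]]$label,
                 values = unlist(lapply(xs, `[[`, "values"), use.names = FALSE),
                 scores = if (all(!vapply(scores, is.null, TRUE)))
                   unlist(scores, use.names = FALSE) else NULL,
                 source_bait_ids = unlist(lapply(xs, `[[`, "source_bait_ids")),
                 n_excluded = sum(vapply(xs, `[[`, 0L, "n_excluded"))),
            class = "distance_sample")
}

#' Null-sampling configuration
#'
#' @param n_samples Number of fragments to sample (default 10000).
#' @param seed RNG seed (required, for reproducibility).
#' @param replacement Sample with replacement (default without).
#' @return Object of class `null_config`.
#' @export
null_config <- function(n_samples = 10000L, seed, replacement = FALSE) {
  stopifnot(n_samples >= 1L)
  if (missing(seed)) stop("seed is required")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 replacement = isTRUE(replacement)),
            class = "null_config")
}

#' Sample restriction fragments genome-wide (simulation null)
#'
#' Uniform per-fragment sample over all fragments of the index;
#' deterministic given the seed in `cfg`.
#'
#' @param index A `fragment_index`.
#' @param cfg A [null_config()].
#' @return data.frame of sampled fragments (`chrom`, `start`, `end`,
#'   `ordinal`).
#' @export
sample_null_fragments <- function(index, cfg) {
  n <- nrow(index$fragments)
  if (!cfg$replacement && cfg$n_samples > n)
    stop(sprintf("cannot sample %d of %d fragments without replacement",
                 cfg$n_samples, n))
  idx <- with_seed(cfg$seed,
                   sample.int(n, cfg$n_samples, replace = cfg$replacement))
  out <- index$fragments[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_values <- function(x) {
  if (inherits(x, "distance_sample")) x$values else as.numeric(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of two samples.
#' The exact null distribution is used when `n1 + n2 <= 20` and there are
#' no ties; otherwise the normal approximation with mid-ranks, tie
#' correction and continuity correction. The method used is recorded.
#'
#' @param x,y `distance_sample`s or numeric vectors, both non-empty.
#' @return Object of class `rank_test_result`: `statistic` (Mann-Whitney U
#'   for `x`), `p_value`, `method`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  vx <- sample_values(x); vy <- sample_values(y)
  if (!length(vx) || !length(vy)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(vx, vy)) > 0L
  exact <- (length(vx) + length(vy) <= 20L) && !ties
  if (length(unique(c(vx, vy))) == 1L) {
    # degenerate: every observation tied; no evidence of a shift
    return(structure(list(statistic = length(vx) * length(vy) / 2,
                          p_value = 1, method = "normal-approximation",
                          n1 = length(vx), n2 = length(vy)),
                     class = "rank_test_result"))
  }
  ht <- stats::wilcox.test(vx, vy, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (exact) "exact" else "normal-approximation",
                 n1 = length(vx), n2 = length(vy)),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, n = (%d, %d), P = %.5g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Paired empirical quantiles (Q-Q points)
#'
#' Empirical quantiles of both samples at `n_quantiles` evenly spaced
#' probabilities in `[0, 1]`, type-7 interpolation. Identical samples fall
#' on the diagonal.
#'
#' @param x,y `distance_sample`s or numeric vectors.
#' @param n_quantiles Number of probability points (default 100).
#' @return data.frame with columns `prob`, `qx`, `qy`.
#' @export
qq_points <- function(x, y, n_quantiles = 100L) {
  vx <- sample_values(x); vy <- sample_values(y)
  if (!length(vx) || !length(vy)) stop("both samples must be non-empty")
  probs <- seq(0, 1, length.out = n_quantiles)
  data.frame(prob = probs,
             qx = stats::quantile(vx, probs, type = 7, names = FALSE),
             qy = stats::quantile(vy, probs, type = 7, names = FALSE))
}

#' Conservation scores of nearest blocks
#'
#' The score of each fragment's nearest (center-to-center) block, with an
#' optional Wilcoxon comparison against another sample's scores.
#'
#' @param frags data.frame of fragments (`chrom`, `start`, `end`).
#' @param blocks Blocks with a `score` column.
#' @param compare Optional numeric vector (or `distance_sample` carrying
#'   `scores`) to compare against.
#' @return List with `scores`, `n_excluded` and (when `compare` is given)
#'   `test`, a `rank_test_result`.
#' @export
nearest_block_scores <- function(frags, blocks, compare = NULL) {
  if (is.null(blocks$score)) stop("blocks must carry scores")
  nb <- nearest_block(frags, blocks)
  ok <- !is.na(nb$distance)
  out <- list(scores = nb$score[ok], n_excluded = sum(!ok))
  if (!is.null(compare)) {
    cmp <- if (inherits(compare, "distance_sample")) compare$scores
           else as.numeric(compare)
    out$test <- wilcoxon_rank_sum(out$scores, cmp)
  }
  out
}
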