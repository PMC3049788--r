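# Synthetic-data generator: genomes with planted restriction sites,
# conservation annotation, baits and 4C libraries with known ground truth,
# plus a Monte-Carlo recovery harness. Fully deterministic under a seed.

#' Synthetic study configuration
#'
#' Defaults model a scaled-down 4C study of a 4-cutter digestion: geometric
#' inter-site spacing with mean 256 bp (the expectation for a 4-base
#' recognition site), conservation-block scores in the 525-710 range of
#' PhastCons most-conserved elements, a 5 kb conservation-enrichment
#' window, and a 4-fold sampling enrichment of fragments near blocks in
#' cross-linked libraries.
#'
#' @param seed Master RNG seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bp (recycled to
#'   `n_chroms`; a full vector gives per-chromosome lengths).
#' @param site_spacing_mean Mean inter-site (GATC) spacing in bp.
#' @param n_blocks_per_chrom Conservation blocks per chromosome.
#' @param block_length_range Min/max block length in bp.
#' @param exonic_fraction Share of blocks also emitted as exons (these are
#'   removed by exon subtraction).
#' @param score_range Min/max conservation score.
#' @param n_baits Number of baits to define.
#' @param trans_fraction Probability a ligation partner lies on another
#'   chromosome.
#' @param cis_decay_exponent Power-law exponent of cis partner distance
#'   decay: weight proportional to `(1 + |center - bait_center|)^-exponent`.
#' @param conservation_enrichment Multiplicative sampling weight for
#'   fragments whose center is within `enrichment_window` of a non-exonic
#'   block center.
#' @param enrichment_window bp (default 5000).
#' @param total_tags Reads per library.
#' @param crosslinked `FALSE` gives the no-cross-link control: uniform
#'   genome-wide fragment sampling regardless of the other parameters.
#' @return Object of class `synthetic_config` (a list).
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 4L, chrom_length = 1.5e6,
                             site_spacing_mean = 256,
                             n_blocks_per_chrom = 40L,
                             block_length_range = c(500L, 1500L),
                             exonic_fraction = 0.2,
                             score_range = c(525, 710),
                             n_baits = 10L,
                             trans_fraction = 0.5,
                             cis_decay_exponent = 1.5,
                             conservation_enrichment = 4,
                             enrichment_window = 5000,
                             total_tags = 1.2e6,
                             crosslinked = TRUE) {
  stopifnot(trans_fraction >= 0, trans_fraction <= 1,
            exonic_fraction >= 0, exonic_fraction <= 1,
            conservation_enrichment >= 0,
            all(chrom_length > 0), site_spacing_mean > 4,
            total_tags >= 1)
  lens <- rep_len(as.numeric(chrom_length), n_chroms)
  if (!is.null(names(chrom_length)) && length(chrom_length) == n_chroms)
    names(lens) <- names(chrom_length)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = lens,
                 site_spacing_mean = site_spacing_mean,
                 n_blocks_per_chrom = as.integer(n_blocks_per_chrom),
                 block_length_range = as.integer(block_length_range),
                 exonic_fraction = exonic_fraction,
                 score_range = score_range,
                 n_baits = as.integer(n_baits),
                 trans_fraction = trans_fraction,
                 cis_decay_exponent = cis_decay_exponent,
                 conservation_enrichment = conservation_enrichment,
                 enrichment_window = enrichment_window,
                 total_tags = as.integer(total_tags),
                 crosslinked = isTRUE(crosslinked)),
            class = "synthetic_config")
}

#' Human-like chromosome lengths
#'
#' 24 chromosome lengths proportional to the human karyotype, scaled to a
#' requested total; used to reproduce the "random library spreads over
#' ~99% of the genome" control behaviour at tractable sizes.
#'
#' @param total_bp Total genome size to scale to.
#' @return Named numeric vector of lengths (chr1..chr22, chrX, chrY).
#' @export
human_like_chrom_lengths <- function(total_bp = 2e6) {
  mb <- c(chr1 = 247, chr2 = 243, chr3 = 199, chr4 = 191, chr5 = 181,
          chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 140, chr10 = 135,
          chr11 = 134, chr12 = 132, chr13 = 114, chr14 = 106, chr15 = 100,
          chr16 = 89, chr17 = 79, chr18 = 76, chr19 = 63, chr20 = 62,
          chr21 = 47, chr22 = 50, chrX = 155, chrY = 58)
  round(mb / sum(mb) * total_bp)
}

# background sequence free of the site, vectorised with a cleanup pass
random_background <- function(n, site = "GATC") {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  while (grepl(site, s, fixed = TRUE)) {
    # break each occurrence by replacing its last base
    repl <- paste0(substr(site, 1, nchar(site) - 1L), "A")
    s <- gsub(site, repl, s, fixed = TRUE)
  }
  s
}

#' Generate a synthetic genome
#'
#' Random sequences in which the restriction site occurs only at planted
#' positions with geometric inter-site spacing (mean
#' `cfg$site_spacing_mean`); the background is scrubbed so no accidental
#' site completes across it. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param site Recognition site (default `"GATC"`).
#' @return A `genome_index` with sequences (chromosomes named `chr1`,
#'   `chr2`, ... unless `cfg$chrom_length` is named).
#' @export
generate_genome <- function(cfg, site = "GATC") {
  lens <- cfg$chrom_length
  nm <- names(lens)
  if (is.null(nm)) nm <- paste0("chr", seq_along(lens))
  k <- nchar(site)
  gap_mean <- cfg$site_spacing_mean - k
  seqs <- with_seed(cfg$seed, {
    vapply(seq_along(lens), function(i) {
      L <- lens[i]
      if (L < cfg$site_spacing_mean)
        warning("chromosome shorter than mean site spacing; may be a single fragment")
      pieces <- list()
      total <- 0
      while (total < L) {
        gap <- stats::rgeom(1L, prob = 1 / (gap_mean + 1))
        pieces[[length(pieces) + 1L]] <- random_background(gap, site)
        pieces[[length(pieces) + 1L]] <- site
        total <- total + gap + k
      }
      substr(paste(unlist(pieces), collapse = ""), 1L, L)
    }, character(1))
  })
  names(seqs) <- nm
  genome_index(sequences = seqs)
}

#' Generate conservation annotation with ground truth
#'
#' Places `n_blocks_per_chrom` non-overlapping conserved blocks per
#' chromosome with integer scores uniform in `score_range`; a fraction
#' `exonic_fraction` of blocks is duplicated into the exon set (so that
#' exon subtraction removes them entirely). Deterministic given the seed.
#'
#' @param cfg A [synthetic_config()].
#' @param genome A `genome_index`.
#' @param seed Seed override (default derived from `cfg$seed`).
#' @return List of class `synthetic_annotation`: `conserved` and `exons`
#'   data.frames (BED-like, 0-based half-open) and `ground_truth`.
#' @export
generate_annotation <- function(cfg, genome, seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, 1L)
  res <- with_seed(seed, {
    rows <- list()
    for (ch in genome$chrom_names) {
      L <- genome$chrom_lengths[[ch]]
      placed <- data.frame(start = numeric(), end = numeric())
      tries <- 0L
      while (nrow(placed) < cfg$n_blocks_per_chrom) {
        tries <- tries + 1L
        if (tries > 1000L * cfg$n_blocks_per_chrom)
          stop("could not place non-overlapping blocks; reduce density")
        len <- sample(seq(cfg$block_length_range[1],
                          cfg$block_length_range[2]), 1L)
        st <- sample.int(max(L - len, 1L), 1L) - 1L
        if (nrow(placed) == 0L ||
            all(st + len <= placed$start | st >= placed$end))
          placed <- rbind(placed, data.frame(start = st, end = st + len))
      }
      placed <- placed[order(placed$start), , drop = FALSE]
      placed$chrom <- ch
      rows[[ch]] <- placed
    }
    conserved <- do.call(rbind, rows)[, c("chrom", "start", "end")]
    conserved$score <- round(stats::runif(nrow(conserved),
                                          cfg$score_range[1],
                                          cfg$score_range[2]))
    n_ex <- round(cfg$exonic_fraction * nrow(conserved))
    ex_idx <- if (n_ex > 0) sort(sample.int(nrow(conserved), n_ex))
              else integer()
    list(conserved = conserved,
         exons = conserved[ex_idx, c("chrom", "start", "end"), drop = FALSE])
  })
  rownames(res$conserved) <- rownames(res$exons) <- NULL
  structure(list(conserved = res$conserved, exons = res$exons,
                 ground_truth = list(cfg = cfg, seed = seed,
                                     exonic_rows = nrow(res$exons))),
            class = "synthetic_annotation")
}

#' Generate a synthetic 4C library
#'
#' Draws `cfg$total_tags` ligation partners for the bait. Each draw is
#' trans (a uniformly random fragment on another chromosome) with
#' probability `trans_fraction`, otherwise cis with probability
#' proportional to `(1 + |center - bait_center|)^-cis_decay_exponent`.
#' Within either branch the weight of a fragment whose center is within
#' `enrichment_window` of a non-exonic conservation block center is
#' multiplied by `conservation_enrichment`. With `crosslinked = FALSE`
#' (the no-cross-link control) sampling is uniform genome-wide regardless
#' of the other parameters. Deterministic given the seed.
#'
#' @param cfg A [synthetic_config()].
#' @param index `fragment_index` of the generated genome.
#' @param annotation A `synthetic_annotation` (or `NULL` for no
#'   conservation enrichment).
#' @param bait A [bait()] whose fragment belongs to `index`.
#' @param seed Seed override (default derived from `cfg$seed`).
#' @return A `library_counts`; total counts equal `cfg$total_tags`.
#' @export
generate_library <- function(cfg, index, annotation, bait, seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, 2L)
  f <- index$fragments
  centers <- fragment_center(f)
  near <- rep(FALSE, nrow(f))
  if (!is.null(annotation) && cfg$conservation_enrichment != 1) {
    blocks <- build_nonexonic_blocks(annotation$conserved, annotation$exons)
    if (nrow(blocks)) {
      nb <- nearest_block(f, blocks)
      near <- !is.na(nb$distance) & nb$distance <= cfg$enrichment_window
    }
  }
  enr <- ifelse(near, cfg$conservation_enrichment, 1)
  is_cis <- f$chrom == bait$fragment$chrom
  b_center <- fragment_center(bait$fragment)
  counts <- with_seed(seed, {
    if (!cfg$crosslinked) {
      w <- rep(1, nrow(f))
      as.integer(stats::rmultinom(1L, cfg$total_tags, w))
    } else {
      n_trans <- stats::rbinom(1L, cfg$total_tags, cfg$trans_fraction)
      n_cis <- cfg$total_tags - n_trans
      out <- integer(nrow(f))
      if (any(!is_cis) && n_trans > 0) {
        w_t <- enr[!is_cis]
        out[!is_cis] <- as.integer(stats::rmultinom(1L, n_trans, w_t))
      } else if (n_trans > 0) {
        # single-chromosome genome: trans draws fall back to cis
        n_cis <- n_cis + n_trans
      }
      if (any(is_cis) && n_cis > 0) {
        w_c <- (1 + abs(centers[is_cis] - b_center))^(-cfg$cis_decay_exponent) *
          enr[is_cis]
        out[is_cis] <- out[is_cis] +
          as.integer(stats::rmultinom(1L, n_cis, w_c))
      }
      out
    }
  })
  keep <- counts > 0L
  new_library_counts(
    data.frame(chrom = f$chrom[keep], start = f$start[keep],
               end = f$end[keep], ordinal = f$ordinal[keep],
               count = counts[keep], stringsAsFactors = FALSE),
    bait_id = bait$bait_id, crosslinked = cfg$crosslinked)
}

#' Pick synthetic baits
#'
#' Deterministically selects `cfg$n_baits` distinct fragments (away from
#' chromosome ends where possible) as baits.
#'
#' @param cfg A [synthetic_config()].
#' @param index A `fragment_index`.
#' @param seed Seed override.
#' @param kind Bait kind label.
#' @return List of [bait()]s named by bait id.
#' @export
generate_baits <- function(cfg, index, seed = NULL, kind = "CNC") {
  seed <- seed %||% derive_seed(cfg$seed, 3L)
  f <- index$fragments
  inner <- which(ave(f$ordinal, f$chrom, FUN = function(o)
    o > min(o) & o < max(o)) == 1)
  pool <- if (length(inner) >= cfg$n_baits) inner else seq_len(nrow(f))
  idx <- with_seed(seed, sample(pool, cfg$n_baits))
  baits <- lapply(seq_along(idx), function(i)
    bait(sprintf("%s%d", if (kind == "CNC") "CNC" else "nonCNC", i),
         f[idx[i], , drop = FALSE], kind = kind))
  stats::setNames(baits, vapply(baits, `[[`, "", "bait_id"))
}

#' Write a library as synthetic PSL alignments
#'
#' Expands per-fragment counts into one 21-column PSL record per tag
#' (alternating strands, `+` tags anchored at the fragment start, `-` tags
#' at the fragment end) so the tag-processing stage can be exercised end
#' to end. Optionally injects records that must be filtered out: matches
#' shorter than 29 nt, alignments with a 2 nt gap, and multi-mapping
#' reads.
#'
#' @param lib A `library_counts` (keep totals small; one line per tag).
#' @param index The `fragment_index`.
#' @param path Output path.
#' @param read_length Simulated read length.
#' @param n_short,n_gapped,n_multi Numbers of deliberately failing records
#'   to inject.
#' @return Invisibly, the expected number of accepted tags.
#' @export
write_synthetic_psl <- function(lib, index, path, read_length = 36L,
                                n_short = 0L, n_gapped = 0L, n_multi = 0L) {
  rec <- function(id, chrom, start, end, strand, matches = read_length,
                  q_start = 0L, gap = 0L) {
    bs <- if (gap > 0L) {
      half <- matches %/% 2L
      sprintf("%d,%d,", half, matches - half)
    } else sprintf("%d,", matches)
    qs <- if (gap > 0L) sprintf("0,%d,", matches %/% 2L)
          else sprintf("%d,", q_start)
    ts <- if (gap > 0L) sprintf("%d,%d,", start, start + matches %/% 2L + gap)
          else sprintf("%d,", start)
    paste(matches, 0L, 0L, 0L, 0L, 0L, if (gap > 0L) 1L else 0L, gap,
          strand, id, read_length, q_start, q_start + matches, chrom,
          index$genome$chrom_lengths[[chrom]], start, end,
          if (gap > 0L) 2L else 1L, bs, qs, ts, sep = "\t")
  }
  lines <- character()
  rid <- 0L
  for (i in seq_len(nrow(lib$counts))) {
    r <- lib$counts[i, ]
    for (k in seq_len(r$count)) {
      rid <- rid + 1L
      strand <- if (k %% 2L == 0L) "-" else "+"
      if (strand == "+")
        lines <- c(lines, rec(sprintf("tag%06d", rid), r$chrom, r$start,
                              min(r$start + read_length, r$end), "+"))
      else
        lines <- c(lines, rec(sprintf("tag%06d", rid), r$chrom,
                              max(r$end - read_length, r$start), r$end, "-"))
    }
  }
  ch1 <- lib$counts$chrom[1]
  st1 <- lib$counts$start[1]
  for (k in seq_len(n_short))
    lines <- c(lines, rec(sprintf("short%03d", k), ch1, st1, st1 + 20L, "+",
                          matches = 20L))
  for (k in seq_len(n_gapped))
    lines <- c(lines, rec(sprintf("gapped%03d", k), ch1, st1,
                          st1 + read_length + 2L, "+", gap = 2L))
  for (k in seq_len(n_multi)) {
    lines <- c(lines, rec(sprintf("multi%03d", k), ch1, st1,
                          st1 + read_length, "+"))
    lines <- c(lines, rec(sprintf("multi%03d", k), ch1, st1 + 100L,
                          st1 + 100L + read_length, "+"))
  }
  writeLines(lines, path)
  invisible(sum(lib$counts$count))
}

#' Monte-Carlo recovery experiment
#'
#' For each parameter point of `grid` (columns override fields of
#' `base_cfg`), runs `n_replicates` independent replicates. Each replicate
#' regenerates the conservation annotation, places one bait per chromosome,
#' generates one library per bait, and computes: the raw trans tag share of
#' the first library (estimator of `trans_fraction`), the Wilcoxon p-value
#' of the pooled member-fragment distances versus a fresh uniform
#' simulation null, and the reproducibility between two replicates of the
#' first library. Distances are pooled across baits -- the analysis design
#' for comparing against a genome-wide null, since pooling one bait per
#' chromosome balances the chromosome composition of the experiment sample
#' with that of the null (a single bait's library systematically excludes
#' its own chromosome, which the null contains). The genome is generated
#' once from `base_cfg`. Fully deterministic given `master_seed`.
#'
#' @param grid data.frame of parameter overrides (e.g. columns
#'   `conservation_enrichment`, `trans_fraction`, `total_tags`,
#'   `crosslinked`).
#' @param n_replicates Replicates per grid point.
#' @param master_seed Master seed.
#' @param base_cfg Base [synthetic_config()].
#' @param alpha Nominal test level for the rejection-rate summary.
#' @param null_size Simulation-null sample size per replicate.
#' @param threshold,n_flank Interaction-calling parameters.
#' @return data.frame with one row per grid point: `rejection_rate`,
#'   `mean_p`, `mean_n_members`, `trans_coverage_2sigma`,
#'   `mean_abs_trans_error`, `mean_reproducibility`, `n_tested`.
#' @export
run_recovery_experiment <- function(grid, n_replicates = 100L,
                                    master_seed = 1L,
                                    base_cfg = synthetic_config(),
                                    alpha = 0.05, null_size = 2000L,
                                    threshold = 50L, n_flank = 1L) {
  genome <- generate_genome(base_cfg)
  index <- digest_genome(genome)
  n_frags <- nrow(index$fragments)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- base_cfg
    for (col in names(grid)) cfg[[col]] <- grid[[col]][g]
    pvals <- rep(NA_real_, n_replicates)
    nmem <- rep(NA_real_, n_replicates)
    covered <- rep(NA, n_replicates)
    abs_err <- rep(NA_real_, n_replicates)
    repro <- rep(NA_real_, n_replicates)
    sigma <- sqrt(cfg$trans_fraction * (1 - cfg$trans_fraction) /
                    cfg$total_tags)
    for (r in seq_len(n_replicates)) {
      s0 <- derive_seed(master_seed, g * 100003L + r * 7L)
      ann <- generate_annotation(cfg, genome, seed = derive_seed(s0, 1L))
      blocks <- build_nonexonic_blocks(ann$conserved, ann$exons)
      # one bait per chromosome, drawn away from the chromosome ends
      f <- index$fragments
      bait_rows <- with_seed(derive_seed(s0, 2L), vapply(
        genome$chrom_names, function(ch) {
          rows <- index$rows[[ch]]
          inner <- rows[seq(2L, max(length(rows) - 1L, 2L))]
          inner[sample.int(length(inner), 1L)]
        }, 0L))
      baits <- lapply(seq_along(bait_rows), function(i)
        bait(sprintf("B%d", i), f[bait_rows[i], , drop = FALSE]))
      cir_list <- vector("list", length(baits))
      for (i in seq_along(baits)) {
        lib_i <- generate_library(cfg, index, ann, baits[[i]],
                                  seed = derive_seed(s0, 10L + i))
        cir_list[[i]] <- call_cirs(lib_i, baits[[i]], index,
                                   threshold = threshold, n_flank = n_flank)
        if (i == 1L) {
          # trans-fraction recovery from the raw counts of library 1
          est <- sum(lib_i$counts$count[
            lib_i$counts$chrom != baits[[i]]$fragment$chrom]) /
            lib_i$total_tags
          abs_err[r] <- abs(est - cfg$trans_fraction)
          covered[r] <- abs_err[r] <= 2 * sigma
          # reproducibility against a second replicate of library 1
          lib_dup <- generate_library(cfg, index, ann, baits[[i]],
                                      seed = derive_seed(s0, 5L))
          cir_dup <- call_cirs(lib_dup, baits[[i]], index,
                               threshold = threshold, n_flank = n_flank)
          if (nrow(cir_list[[i]]$members) > 0L)
            repro[r] <- replicate_reproducibility(cir_list[[i]], cir_dup)
        }
      }
      nonempty <- cir_list[vapply(cir_list, function(cs)
        nrow(cs$members) > 0L, TRUE)]
      nmem[r] <- sum(vapply(nonempty, function(cs) nrow(cs$members), 0L))
      if (length(nonempty) && nrow(blocks)) {
        ds <- do.call(pool_distance_samples,
                      lapply(nonempty, distance_sample, blocks = blocks,
                             label = "experiment"))
        nulls <- sample_null_fragments(
          index, null_config(min(null_size, n_frags),
                             seed = derive_seed(s0, 4L)))
        dn <- distance_sample(nulls, blocks, "simulation")
        if (length(ds$values) >= 2L)
          pvals[r] <- wilcoxon_rank_sum(ds, dn)$p_value
      }
    }
    out[[g]] <- data.frame(
      rejection_rate = mean(pvals < alpha, na.rm = TRUE),
      mean_p = mean(pvals, na.rm = TRUE),
      mean_n_members = mean(nmem, na.rm = TRUE),
      trans_coverage_2sigma = mean(covered, na.rm = TRUE),
      mean_abs_trans_error = mean(abs_err, na.rm = TRUE),
      mean_reproducibility = mean(repro, na.rm = TRUE),
      n_tested = sum(!is.na(pvals)))
  }
  cbind(grid, do.call(rbind, out))
}
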