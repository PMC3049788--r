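# Non-exonic block construction, nearest-block distances, the sampled
# null, the rank-sum test and quantile comparisons.

test_that("exon subtraction splits blocks and inherits scores", {
  cons <- data.frame(chrom = "c1", start = 0L, end = 100L, score = 600,
                     stringsAsFactors = FALSE)
  ex <- data.frame(chrom = "c1", start = 40L, end = 60L,
                   stringsAsFactors = FALSE)
  b <- build_nonexonic_blocks(cons, ex)
  expect_equal(b$start, c(0L, 60L))
  expect_equal(b$end, c(40L, 100L))
  expect_equal(b$score, c(600, 600))

  # block fully inside an exon disappears
  ex2 <- data.frame(chrom = "c1", start = 0L, end = 100L)
  expect_equal(nrow(build_nonexonic_blocks(cons, ex2)), 0L)

  # no exons: identity
  b3 <- build_nonexonic_blocks(cons, ex[0, ])
  expect_equal(b3$start, cons$start)
  expect_equal(b3$end, cons$end)
})

test_that("exon subtraction matches a per-bp oracle and conserves length", {
  set.seed(77)
  for (i in 1:60) {
    n_c <- sample(1:6, 1); n_e <- sample(0:6, 1)
    mk <- function(n) {
      s <- sort(sample(0:1900, n))
      data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                 start = s, end = s + sample(10:120, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    cons <- mk(n_c); cons$score <- sample(525:710, n_c)
    ex <- mk(n_e)[, c("chrom", "start", "end")]
    got <- build_nonexonic_blocks(cons, ex)
    want <- oracle_subtract(cons, ex)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score)
  }
})

test_that("nearest block is chosen center-to-center with ties to smaller start", {
  blocks <- data.frame(chrom = "c1", start = c(300L, 900L),
                       end = c(400L, 1100L), score = c(600, 700),
                       stringsAsFactors = FALSE)
  # centers at 350 and 1000
  q <- data.frame(chrom = "c1", start = 100L, end = 200L)  # center 150
  nb <- nearest_block(q, blocks)
  expect_equal(nb$distance, 200)
  expect_equal(nb$score, 600)

  # coincident centers give distance 0
  q2 <- data.frame(chrom = "c1", start = 340L, end = 360L)
  expect_equal(nearest_block(q2, blocks)$distance, 0)

  # equidistant: block with the smaller start wins
  blocks3 <- data.frame(chrom = "c1", start = c(0L, 1200L),
                        end = c(100L, 1300L), score = c(1, 2),
                        stringsAsFactors = FALSE)  # centers 50, 1250
  q3 <- data.frame(chrom = "c1", start = 600L, end = 700L)  # center 650
  nb3 <- nearest_block(q3, blocks3)
  expect_equal(nb3$distance, 600)
  expect_equal(nb3$score, 1)

  # chromosome without blocks -> NA
  q4 <- data.frame(chrom = "cZ", start = 0L, end = 10L)
  expect_true(is.na(nearest_block(q4, blocks)$distance))
})

test_that("nearest block agrees with the all-pairs oracle", {
  set.seed(99)
  for (i in 1:40) {
    nb <- sample(1:40, 1)
    s <- sort(sample(0:50000, nb))
    blocks <- data.frame(chrom = sample(c("c1", "c2"), nb, replace = TRUE),
                         start = s, end = s + sample(5:500, nb, TRUE),
                         score = sample(525:710, nb, TRUE),
                         stringsAsFactors = FALSE)
    qs <- sample(0:50000, 25)
    q <- data.frame(chrom = sample(c("c1", "c2"), 25, TRUE),
                    start = qs, end = qs + sample(5:400, 25, TRUE),
                    stringsAsFactors = FALSE)
    got <- nearest_block(q, blocks)
    for (j in seq_len(nrow(q))) {
      want <- oracle_nearest(q[j, ], blocks)
      expect_equal(got$distance[j], want$distance)
      if (!is.na(want$distance))
        expect_equal(blocks$start[got$block[j]], want$start)
    }
  }
})

test_that("distance samples have one value per member and log exclusions", {
  bt <- fake_bait()
  members <- data.frame(chrom = c("c1", "c1", "cZ"),
                        start = c(100L, 500L, 0L), end = c(200L, 600L, 10L),
                        count = c(60L, 70L, 80L), stringsAsFactors = FALSE)
  blocks <- data.frame(chrom = "c1", start = 0L, end = 100L, score = 600,
                       stringsAsFactors = FALSE)
  ds <- distance_sample(cir_from_members(members, bt), blocks, "experiment")
  expect_length(ds$values, 2L)
  expect_equal(ds$n_excluded, 1L)

  pooled <- pool_distance_samples(ds, ds)
  expect_length(pooled$values, 4L)
  expect_equal(pooled$n_excluded, 2L)
})

test_that("null sampling is deterministic, exhaustive at full size, and bounded", {
  idx <- digest_genome(generate_genome(small_cfg(seed = 9L)))
  n <- nrow(fragments(idx))
  a <- sample_null_fragments(idx, null_config(50L, seed = 4L))
  b <- sample_null_fragments(idx, null_config(50L, seed = 4L))
  expect_identical(a, b)
  full <- sample_null_fragments(idx, null_config(n, seed = 4L))
  expect_equal(sort(paste(full$chrom, full$start)),
               sort(paste(fragments(idx)$chrom, fragments(idx)$start)))
  expect_error(sample_null_fragments(idx, null_config(n + 1L, seed = 4L)),
               "without replacement")
  expect_equal(null_config(seed = 1L)$n_samples, 10000L)
})

test_that("rank-sum test matches exact enumeration and handles identity", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)

  # normal approximation tracks exact enumeration at moderate n
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:1000, 8); y <- sample(2000:3000, 8) / 7
    exact_p <- oracle_wilcoxon_p(x, y)
    approx_p <- stats::wilcox.test(x, y, exact = FALSE,
                                   correct = TRUE)$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, exact_p)
  }

  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("Q-Q points use type-7 quantiles and respect scaling", {
  x <- c(3, 9, 1, 7, 5)
  qq <- qq_points(x, x, 11L)
  expect_equal(qq$qx, qq$qy)
  qq2 <- qq_points(x, 2 * x, 7L)
  expect_equal(qq2$qy, 2 * qq2$qx)
  qq3 <- qq_points(x, x, 2L)
  expect_equal(qq3$qx, c(min(x), max(x)))
})

test_that("nearest-block scores feed the same rank-sum machinery", {
  blocks <- data.frame(chrom = "c1", start = c(0L, 1000L),
                       end = c(100L, 1100L), score = c(710, 525),
                       stringsAsFactors = FALSE)
  frags <- data.frame(chrom = "c1", start = c(10L, 40L), end = c(30L, 90L),
                      stringsAsFactors = FALSE)
  sc <- nearest_block_scores(frags, blocks)
  expect_equal(sc$scores, c(710, 710))
  cmp <- nearest_block_scores(frags, blocks, compare = c(710, 710))
  expect_equal(cmp$test$p_value, 1)
})
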