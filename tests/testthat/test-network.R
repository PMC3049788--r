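# Bait-bait proximity edges, gene proximity, overlap statistics, circos
# links.

mk_members <- function(chrom, starts, counts = rep(60L, length(starts))) {
  data.frame(chrom = rep_len(chrom, length(starts)), start = starts,
             end = starts + 100L, count = counts, stringsAsFactors = FALSE)
}

test_that("proximity edges connect members within the window, directed, no self", {
  btA <- fake_bait(chrom = "c1", start = 0L, end = 200L, id = "CNC6")
  btB <- fake_bait(chrom = "c1", start = 50000L, end = 50200L, id = "CNC5")
  # member centered 3 kb from bait B's center (50100)
  csA <- cir_from_members(mk_members("c1", 53000L), btA)
  edges <- bait_proximity_edges(list(csA), list(btA, btB), window = 5000L)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$source_bait_id, "CNC6")
  expect_equal(edges$target_bait_id, "CNC5")
  expect_equal(edges$distance, abs(53050 - 50100))

  # fragment near its own bait never makes a self edge
  cs_self <- cir_from_members(mk_members("c1", 300L), btA)
  expect_equal(nrow(bait_proximity_edges(list(cs_self), list(btA, btB),
                                         window = 5000L)), 0L)

  # 6 kb away at a 5 kb window: no edge
  cs_far <- cir_from_members(mk_members("c1", 56050L), btA)
  expect_equal(nrow(bait_proximity_edges(list(cs_far), list(btA, btB),
                                         window = 5000L)), 0L)

  # monotone in the window
  e1 <- bait_proximity_edges(list(csA, cs_far), list(btA, btB), 3000L)
  e2 <- bait_proximity_edges(list(csA, cs_far), list(btA, btB), 5000L)
  e3 <- bait_proximity_edges(list(csA, cs_far), list(btA, btB), 8000L)
  expect_true(nrow(e1) <= nrow(e2) && nrow(e2) <= nrow(e3))
  key <- function(e) paste(e$source_bait_id, e$target_bait_id, e$start)
  expect_true(all(key(e1) %in% key(e2)) && all(key(e2) %in% key(e3)))
})

test_that("genes qualify by interval gap with a strict window boundary", {
  bt <- fake_bait(chrom = "c1")
  cs <- cir_from_members(mk_members("c1", c(20000L, 21000L)), bt)
  genes <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                      start = c(20050L, 31101L, 5000L, 20000L),
                      end = c(20060L, 31200L, 9999L, 20100L),
                      name = c("OVL", "JUST_OUT", "NEAR", "WRONG_CHR"),
                      stringsAsFactors = FALSE)
  # member [21000,21100): gene JUST_OUT gap = 31101-21100 = 10001 -> excluded
  # gene NEAR gap to [20000,20100) = 20000-9999 = 10001 -> excluded
  got <- genes_near_cirs(cs, genes, window = 10000L)
  expect_equal(got, "OVL")
  got2 <- genes_near_cirs(cs, genes, window = 10001L)
  expect_equal(got2, c("JUST_OUT", "NEAR", "OVL"))

  # de-duplication across members
  genes3 <- genes[rep(1, 1), ]
  cs2 <- cir_from_members(mk_members("c1", c(20000L, 20010L)), bt)
  expect_equal(genes_near_cirs(cs2, genes3, 10000L), "OVL")
})

test_that("gene proximity matches a brute-force gap computation", {
  set.seed(123)
  bt <- fake_bait(chrom = "c1")
  for (i in 1:25) {
    ms <- sample(0:100000, sample(3:20, 1))
    cs <- cir_from_members(mk_members("c1", ms), bt)
    gs <- sample(0:100000, sample(3:30, 1))
    genes <- data.frame(chrom = "c1", start = gs,
                        end = gs + sample(50:5000, length(gs), TRUE),
                        name = paste0("g", seq_along(gs)),
                        stringsAsFactors = FALSE)
    w <- sample(c(0L, 1000L, 10000L), 1)
    got <- genes_near_cirs(cs, genes, w)
    want <- genes$name[vapply(seq_len(nrow(genes)), function(j)
      any(vapply(seq_along(ms), function(k)
        oracle_gap(genes$start[j], genes$end[j], ms[k], ms[k] + 100L),
        0L) <= w), TRUE)]
    expect_equal(got, sort(unique(want)))
  }
})

test_that("overlap test equals the closed-form tail and complement identity", {
  u <- paste0("g", 1:10)
  r <- geneset_overlap_test(u[1:2], u[1:5], u)
  expect_equal(r$p_value, choose(5, 2) / choose(10, 2))

  r0 <- geneset_overlap_test(u[6:7], u[1:5], u)  # k = 0
  expect_true(r0$p_value >= 1 - 1e-12)

  rd <- geneset_overlap_test(character(), u[1:5], u)
  expect_equal(rd$p_value, 1)
  expect_true(rd$degenerate)

  expect_error(geneset_overlap_test("a", "a", character()), "universe")
  expect_error(geneset_overlap_test("zz", u[1:5], u), "outside universe")

  # complement identity against the lower tail
  for (i in 1:20) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    kk <- max(0, K + n - N):min(K, n)
    k <- sample(rep(kk, 2), 1)
    p_up <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_lo <- stats::phyper(k - 1, K, N - K, n)
    expect_lt(abs((p_up + p_lo) - 1), 1e-12)
  }
})

test_that("circos links round-trip and write a header for empty input", {
  bt <- fake_bait(chrom = "c1", start = 0L, end = 200L, id = "A")
  cs <- cir_from_members(mk_members("c2", c(500L, 900L), c(60L, 70L)), bt)
  p <- withr::local_tempfile(fileext = ".links")
  export_circos_links(cs, p)
  got <- read_circos_links(p)
  expect_equal(nrow(got), 2L)
  expect_equal(got$chromA, c("c1", "c1"))
  expect_equal(got$startB, c(500L, 900L))
  expect_equal(got$count, c(60L, 70L))

  empty <- cir_from_members(mk_members("c2", integer()), bt)
  export_circos_links(empty, p)
  expect_equal(readLines(p), "# chrA startA endA chrB startB endB count")
  expect_equal(nrow(read_circos_links(p)), 0L)

  # edge-table flavour
  btB <- fake_bait(chrom = "c2", start = 400L, end = 700L, id = "B")
  edges <- bait_proximity_edges(list(cs), list(bt, btB), window = 5000L)
  export_circos_links(edges, p, baits = list(bt, btB))
  got2 <- read_circos_links(p)
  expect_equal(nrow(got2), nrow(edges))
  expect_equal(got2$chromB, edges$chrom)
})
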