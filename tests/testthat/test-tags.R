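# PSL parsing, alignment filtering, fragment assignment and the tabular
# count dialect.

psl_line <- function(matches = 36, rep_matches = 0, q_insert = 0,
                     t_insert = 0, strand = "+", qname = "r1", qsize = 36,
                     qstart = 0, qend = 36, tname = "c1", tsize = 1000,
                     tstart = 100, tend = 136, blocks = NULL) {
  if (is.null(blocks))
    blocks <- list(count = 1, sizes = sprintf("%d,", matches),
                   qs = sprintf("%d,", qstart), ts = sprintf("%d,", tstart))
  paste(matches, 0, rep_matches, 0, 0, q_insert, 0, t_insert, strand,
        qname, qsize, qstart, qend, tname, tsize, tstart, tend,
        blocks$count, blocks$sizes, blocks$qs, blocks$ts, sep = "\t")
}

psl_header <- c("psLayout version 3", "",
                paste("match", "mis-", "rep.", "N's", "Q gap", "Q gap",
                      "T gap", "T gap", "strand", "Q", sep = "\t"),
                paste("", "match", "match", "", "count", "bases", "count",
                      "bases", "", "name", sep = "\t"),
                strrep("-", 80))

test_that("PSL records map to tags with match length, gaps and hit counts", {
  p <- withr::local_tempfile(fileext = ".psl")
  writeLines(c(psl_header,
               psl_line(matches = 36, qname = "rA"),
               psl_line(matches = 30, qname = "rB", tstart = 300, tend = 330),
               psl_line(matches = 30, qname = "rB", tstart = 600, tend = 630)),
             p)
  tags <- parse_psl(p)
  expect_equal(nrow(tags), 3L)
  expect_equal(tags$match_length[1], 36L)
  expect_equal(tags$max_gap[1], 0L)
  expect_equal(tags$hit_count, c(1L, 2L, 2L))
  expect_equal(tags$leading_seq[1], "GATC")

  # gap computed from block structure: two blocks separated by 2 nt
  p2 <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_line(matches = 36, t_insert = 2, tend = 138,
                      blocks = list(count = 2, sizes = "18,18,",
                                    qs = "0,18,", ts = "100,120,")), p2)
  expect_equal(parse_psl(p2)$max_gap, 2L)
})

test_that("header-only PSL yields zero tags and malformed records name their line", {
  p <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_header, p)
  expect_equal(nrow(parse_psl(p)), 0L)

  p2 <- withr::local_tempfile(fileext = ".psl")
  writeLines(c(psl_line(), "1\t2\t3"), p2)
  expect_error(parse_psl(p2), "line 2")
})

test_that("filtering applies the match/gap/prefix/uniqueness criteria", {
  base <- data.frame(read_id = "r", chrom = "c1", start = 0L, end = 36L,
                     strand = "+", match_length = 36L, max_gap = 0L,
                     hit_count = 1L, leading_seq = "GATC",
                     stringsAsFactors = FALSE)
  short <- transform(base, match_length = 28L)
  gapped <- transform(base, max_gap = 2L)
  multi <- transform(base, hit_count = 2L)
  noprefix <- transform(base, leading_seq = "")
  borderline <- transform(base, match_length = 29L, max_gap = 1L)
  tags <- rbind(base, short, gapped, multi, noprefix, borderline)

  kept <- filter_tags(tags, filter_config())
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$match_length, c(36L, 29L))

  # idempotence and subset property
  expect_equal(nrow(filter_tags(kept, filter_config())), nrow(kept))
  expect_true(all(paste(kept$match_length, kept$max_gap) %in%
                    paste(tags$match_length, tags$max_gap)))
})

test_that("tags are assigned by strand-appropriate fragment boundary", {
  idx <- tiny_index()   # fragments [0,2) [2,8) [8,14)
  tags <- data.frame(read_id = c("a", "b", "c"), chrom = "c1",
                     start = c(8L, 2L, 9L), end = c(14L, 8L, 13L),
                     strand = c("+", "-", "+"),
                     match_length = 29L, max_gap = 0L, hit_count = 1L,
                     leading_seq = "GATC", stringsAsFactors = FALSE)
  lib <- assign_tags(tags, idx)
  expect_equal(lib$total_tags, 2L)
  expect_equal(lib$unassigned, 1L)          # start 9 has no boundary at tol 0
  expect_equal(lib$counts$start, c(2L, 8L)) # - tag end 8 -> [2,8); + tag -> [8,14)

  # conservation: assigned + unassigned == input
  expect_equal(lib$total_tags + lib$unassigned, nrow(tags))

  # unknown chromosome is dropped and counted
  tags2 <- transform(tags[1, ], chrom = "cZ")
  lib2 <- assign_tags(tags2, idx)
  expect_equal(lib2$unassigned, 1L)
  expect_equal(lib2$total_tags, 0L)
})

test_that("synthetic PSL round-trips through parse/filter/assign with injected rejects", {
  cfg <- small_cfg(seed = 5L, total_tags = 200L)
  gen <- generate_genome(cfg)
  idx <- digest_genome(gen)
  bt <- generate_baits(cfg, idx)[[1]]
  lib <- generate_library(cfg, idx, NULL, bt)
  p <- withr::local_tempfile(fileext = ".psl")
  write_synthetic_psl(lib, idx, p, n_short = 3L, n_gapped = 2L, n_multi = 2L)
  tags <- parse_psl(p)
  kept <- filter_tags(tags, filter_config())
  expect_equal(nrow(tags), 200L + 3L + 2L + 4L)
  expect_equal(nrow(kept), 200L)
  lib2 <- assign_tags(kept, idx, bait_id = bt$bait_id)
  expect_equal(lib2$unassigned, 0L)  # boundary-anchored reads all recover
  m1 <- lib$counts[order(lib$counts$chrom, lib$counts$start), ]
  m2 <- lib2$counts[order(lib2$counts$chrom, lib2$counts$start), ]
  expect_equal(m2$count, m1$count)
  expect_equal(m2$start, m1$start)
})

test_that("count tables group by bait, round-trip, and validate", {
  libA <- lib_from(data.frame(chrom = "c1", start = c(0L, 8L),
                              end = c(2L, 14L), count = c(5L, 60L)), "CNC1")
  libB <- lib_from(data.frame(chrom = "c1", start = 2L, end = 8L,
                              count = 7L), "CNC2")
  p <- withr::local_tempfile(fileext = ".txt")
  write_counts_table(list(libA, libB), p)
  libs <- read_counts_table(p)
  expect_named(libs, c("CNC1", "CNC2"))
  expect_equal(nrow(libs$CNC1$counts), 2L)
  expect_equal(libs$CNC1$counts$start, libA$counts$start)
  expect_equal(libs$CNC1$counts$count, libA$counts$count)
  expect_equal(libs$CNC2$total_tags, 7L)

  # 1-based dialect: DpnIIStart is start + 1
  raw <- read.delim(p)
  expect_equal(raw$DpnIIStart, c(1L, 9L, 3L))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("BaitID\tChr\tDpnIIStart\tDpnIIEnd\tNumbReads",
               "B\tc1\t1\t10\t-3"), bad)
  expect_error(read_counts_table(bad), "line 2")

  # the same bait in two files is a collision, not a merge
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_counts_table(list(libA), p2)
  expect_error(read_counts_table(c(p, p2)), "more than one file")
})
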