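# Interaction networks: bait-bait proximity edges, gene-proximity sets and
# the hypergeometric gene-set overlap test; circos link export.

#' Bait-bait proximity edges
#'
#' A directed edge A -> B exists when the library of bait A contains a
#' member fragment whose center lies within `window` bp (center to center)
#' of bait B's fragment center, with A != B. Self-edges are excluded.
#'
#' @param cir_sets List of `cir_set`s (already thresholded).
#' @param baits List of [bait()]s (targets; typically the baits of the same
#'   libraries).
#' @param window Maximum center-to-center distance in bp (default 5000).
#' @return data.frame of edges: `source_bait_id`, `target_bait_id`,
#'   `chrom`, `start`, `end` (supporting fragment), `count`, `distance`.
#' @export
bait_proximity_edges <- function(cir_sets, baits, window = 5000L) {
  bait_df <- data.frame(
    bait_id = vapply(baits, function(b) as.character(b$bait_id), ""),
    chrom = vapply(baits, function(b) b$fragment$chrom, ""),
    center = vapply(baits, function(b) fragment_center(b$fragment), 0),
    stringsAsFactors = FALSE)
  rows <- list()
  for (cs in cir_sets) {
    m <- cs$members
    if (!nrow(m)) next
    mc <- fragment_center(m)
    for (j in seq_len(nrow(bait_df))) {
      if (identical(as.character(cs$bait$bait_id), bait_df$bait_id[j])) next
      near <- which(m$chrom == bait_df$chrom[j] &
                    abs(mc - bait_df$center[j]) <= window)
      if (!length(near)) next
      rows[[length(rows) + 1L]] <- data.frame(
        source_bait_id = as.character(cs$bait$bait_id),
        target_bait_id = bait_df$bait_id[j],
        chrom = m$chrom[near], start = m$start[near], end = m$end[near],
        count = m$count[near],
        distance = abs(mc[near] - bait_df$center[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(source_bait_id = character(),
                      target_bait_id = character(), chrom = character(),
                      start = integer(), end = integer(), count = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$source_bait_id, out$target_bait_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes near called interaction fragments
#'
#' A gene qualifies when the minimal gap between its interval and any
#' member fragment is at most `window` bp (overlap counts as gap 0).
#' Returned gene ids are de-duplicated and sorted.
#'
#' @param cirs A `cir_set`.
#' @param genes data.frame of gene models (`chrom`, `start`, `end`, `name`;
#'   a BED6 read with [read_bed()] works directly).
#' @param window Maximum gap in bp (default 10000).
#' @return Character vector of gene ids.
#' @export
genes_near_cirs <- function(cirs, genes, window = 10000L) {
  m <- cirs$members
  if (!nrow(m) || !nrow(genes)) return(character())
  ids <- genes$name %||% as.character(seq_len(nrow(genes)))
  levs <- unique(c(genes$chrom, m$chrom))
  g_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = levs),
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  m_gr <- GenomicRanges::GRanges(factor(m$chrom, levels = levs),
                                 IRanges::IRanges(m$start + 1L, m$end))
  hits <- GenomicRanges::findOverlaps(g_gr, m_gr, maxgap = window,
                                      ignore.strand = TRUE)
  sort(unique(ids[S4Vectors::queryHits(hits)]))
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability `P[X >= k]` of observing at least the seen
#' overlap between a query gene list and a gene set, drawing `n` genes
#' from a universe of `N` containing `K` set members; exact summation.
#'
#' @param query_genes Character vector of query gene ids (subset of
#'   `universe`).
#' @param gene_set Character vector of set gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all gene ids.
#' @return Object of class `overlap_result`: `k`, `n`, `K`, `N`,
#'   `p_value`, `degenerate` (TRUE when the query is empty).
#' @export
geneset_overlap_test <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query_genes <- unique(query_genes)
  gene_set <- unique(gene_set)
  if (!all(query_genes %in% universe)) stop("query genes outside universe")
  if (!all(gene_set %in% universe)) stop("gene set outside universe")
  k <- length(intersect(query_genes, gene_set))
  n <- length(query_genes); K <- length(gene_set); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, n = n, K = K, N = N, p_value = p,
                 degenerate = n == 0L),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of n = %d (set %d of %d), P = %.4g%s\n",
              x$k, x$n, x$K, x$N, x$p_value,
              if (x$degenerate) " [degenerate: empty query]" else ""))
  invisible(x)
}

#' Export links in the circos link-file dialect
#'
#' One line per link with two positional interval columns
#' (`chrA startA endA chrB startB endB count`), stably ordered. Accepts
#' either an edge table from [bait_proximity_edges()] (links bait fragment
#' to supporting fragment) or a `cir_set` (links bait fragment to every
#' member).
#'
#' @param x Edge data.frame or `cir_set`.
#' @param path Output path.
#' @param baits When `x` is an edge table: list of [bait()]s to resolve
#'   source coordinates.
#' @export
export_circos_links <- function(x, path, baits = NULL) {
  header <- "# chrA startA endA chrB startB endB count"
  if (inherits(x, "cir_set")) {
    b <- x$bait$fragment
    m <- x$members
    lines <- if (nrow(m)) paste(b$chrom, b$start, b$end,
                                m$chrom, m$start, m$end, m$count,
                                sep = "\t") else character()
  } else {
    if (nrow(x) && is.null(baits))
      stop("baits required to resolve edge source coordinates")
    lines <- character()
    if (nrow(x)) {
      bmap <- stats::setNames(lapply(baits, `[[`, "fragment"),
                              vapply(baits, function(b)
                                as.character(b$bait_id), ""))
      src <- do.call(rbind, bmap[x$source_bait_id])
      lines <- paste(src$chrom, src$start, src$end,
                     x$chrom, x$start, x$end, x$count, sep = "\t")
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a circos link file written by [export_circos_links()]
#'
#' @param path Path to the link file.
#' @return data.frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `count`.
#' @export
read_circos_links <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chromA = character(), startA = integer(),
                      endA = integer(), chromB = character(),
                      startB = integer(), endB = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chromA = vapply(f, `[[`, "", 1),
             startA = as.integer(vapply(f, `[[`, "", 2)),
             endA = as.integer(vapply(f, `[[`, "", 3)),
             chromB = vapply(f, `[[`, "", 4),
             startB = as.integer(vapply(f, `[[`, "", 5)),
             endB = as.integer(vapply(f, `[[`, "", 6)),
             count = as.integer(vapply(f, `[[`, "", 7)),
             stringsAsFactors = FALSE)
}
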