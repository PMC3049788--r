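# End-to-end pipeline: structured configuration, the digestion ->
# counting -> calling -> statistics -> network workflow, and provenance.

#' Pipeline configuration
#'
#' Collects the input paths and analysis parameters of a full run. All
#' parameter defaults are the standard analysis constants: tag threshold
#' 50, one excluded flanking fragment per side, minimum match 29 nt,
#' maximum gap 1 nt, 5 kb bait-proximity window, 10 kb gene window and a
#' 10000-fragment simulation null.
#'
#' @param genome_fasta Path to the reference FASTA.
#' @param counts_table Path(s) to tabular count files (BaitID/Chr/
#'   DpnIIStart/DpnIIEnd/NumbReads); the count-table entry mode.
#' @param psl Named character vector `bait_id -> PSL path`; the raw
#'   alignment entry mode (ignored when `counts_table` is given).
#' @param baits_table Path to a TSV with columns `BaitID`, `Kind`, `Chr`,
#'   `Start`, `End` (1-based inclusive).
#' @param conserved_bed,exons_bed,genes_bed Annotation BED paths
#'   (`conserved_bed` must carry scores).
#' @param out_dir Output directory.
#' @param threshold,n_flank,min_match,max_gap,window_bait,window_gene,null_size
#'   Analysis parameters.
#' @param seed RNG seed for the simulation null.
#' @param counts_one_based Coordinate convention of the counts table.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(genome_fasta = NULL, counts_table = NULL,
                            psl = NULL, baits_table = NULL,
                            conserved_bed = NULL, exons_bed = NULL,
                            genes_bed = NULL, out_dir = "cnc4c-out",
                            threshold = 50L, n_flank = 1L, min_match = 29L,
                            max_gap = 1L, window_bait = 5000L,
                            window_gene = 10000L, null_size = 10000L,
                            seed = 1L, counts_one_based = TRUE) {
  structure(list(genome_fasta = genome_fasta, counts_table = counts_table,
                 psl = psl, baits_table = baits_table,
                 conserved_bed = conserved_bed, exons_bed = exons_bed,
                 genes_bed = genes_bed, out_dir = out_dir,
                 threshold = as.integer(threshold),
                 n_flank = as.integer(n_flank),
                 min_match = as.integer(min_match),
                 max_gap = as.integer(max_gap),
                 window_bait = as.integer(window_bait),
                 window_gene = as.integer(window_gene),
                 null_size = as.integer(null_size),
                 seed = as.integer(seed),
                 counts_one_based = isTRUE(counts_one_based)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Round-trips exactly: `read_pipeline_config(write_pipeline_config(cfg))`
#' equals `cfg`.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, TRUE)])
}

#' Read a bait definition table
#'
#' TSV with columns `BaitID`, `Kind`, `Chr`, `Start`, `End` (1-based
#' inclusive). Each bait is mapped to the restriction fragment containing
#' the midpoint of its interval.
#'
#' @param path Path to the TSV.
#' @param index A `fragment_index`.
#' @return Named list of [bait()]s.
#' @export
read_baits_table <- function(path, index) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("BaitID", "Kind", "Chr", "Start", "End")
  if (!all(need %in% names(tab)))
    stop(sprintf("'%s': missing columns %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  baits <- lapply(seq_len(nrow(tab)), function(i) {
    mid <- ((tab$Start[i] - 1L) + tab$End[i]) %/% 2L
    frag <- locate_fragment(index, tab$Chr[i], mid)
    bait(tab$BaitID[i], frag, kind = tab$Kind[i])
  })
  stats::setNames(baits, tab$BaitID)
}

#' Run the full analysis pipeline
#'
#' Executes digestion, library loading (count-table mode, or PSL mode with
#' filtering and fragment assignment), interaction calling, cis/trans
#' summaries, the conservation-proximity comparison of the pooled
#' experiment sample against a sampled simulation null, bait-bait
#' proximity edges and gene-proximity sets, and writes all stage outputs
#' plus the resolved configuration to `cfg$out_dir`. A failure in one
#' library is collected and reported without aborting the other libraries.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a result bundle: `index`, `baits`, `libraries`,
#'   `cirs`, `summaries` (data.frame), `blocks`, `distance_test`,
#'   `qq` (data.frame), `edges`, `genes_near`, `errors` (named list),
#'   `log` (per-stage record counts).
#' @export
run_pipeline <- function(cfg) {
  for (p in c("genome_fasta", "baits_table")) {
    if (is.null(cfg[[p]])) stop(sprintf("missing mandatory input: %s", p))
    if (!file.exists(cfg[[p]]))
      stop(sprintf("%s does not exist: %s", p, cfg[[p]]))
  }
  if (is.null(cfg$counts_table) && is.null(cfg$psl))
    stop("missing mandatory input: counts_table or psl")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  genome <- read_genome_fasta(cfg$genome_fasta)
  index <- digest_genome(genome)
  log$n_fragments <- nrow(index$fragments)
  baits <- read_baits_table(cfg$baits_table, index)

  if (!is.null(cfg$counts_table)) {
    libs <- read_counts_table(cfg$counts_table,
                              one_based = cfg$counts_one_based)
    log$entry_mode <- "counts-table"
  } else {
    fcfg <- filter_config(min_match = cfg$min_match, max_gap = cfg$max_gap)
    libs <- list()
    for (bid in names(cfg$psl)) {
      tags <- parse_psl(cfg$psl[[bid]])
      kept <- filter_tags(tags, fcfg)
      log[[paste0("tags_", bid)]] <- c(parsed = nrow(tags),
                                       kept = nrow(kept),
                                       rejected = nrow(tags) - nrow(kept))
      libs[[bid]] <- assign_tags(kept, index, bait_id = bid)
    }
    log$entry_mode <- "psl"
  }

  errors <- list()
  cirs <- list()
  summaries <- list()
  for (bid in names(libs)) {
    res <- tryCatch({
      if (is.null(baits[[bid]]))
        stop(sprintf("no bait definition for library '%s'", bid))
      cs <- call_cirs(libs[[bid]], baits[[bid]], index,
                      threshold = cfg$threshold, n_flank = cfg$n_flank)
      list(cir = cs, summary = cis_trans_summary(cs))
    }, error = function(e) e)
    if (inherits(res, "error")) { errors[[bid]] <- conditionMessage(res); next }
    cirs[[bid]] <- res$cir
    summaries[[bid]] <- as.data.frame(unclass(res$summary))
    export_bedgraph(libs[[bid]],
                    file.path(cfg$out_dir, paste0(bid, ".bedgraph")),
                    transform = "log2")
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame()
  if (nrow(summaries))
    utils::write.table(summaries,
                       file.path(cfg$out_dir, "cis_trans_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  blocks <- NULL; dtest <- NULL; qq <- NULL
  if (!is.null(cfg$conserved_bed)) {
    conserved <- read_bed(cfg$conserved_bed)
    exons <- if (!is.null(cfg$exons_bed)) read_bed(cfg$exons_bed)
             else conserved[0, c("chrom", "start", "end")]
    blocks <- build_nonexonic_blocks(conserved, exons)
    log$n_blocks <- nrow(blocks)
    samples <- lapply(cirs[vapply(cirs, function(cs)
      nrow(cs$members) > 0L, TRUE)], distance_sample, blocks = blocks,
      label = "experiment")
    if (length(samples)) {
      pooled <- do.call(pool_distance_samples, unname(samples))
      nulls <- sample_null_fragments(
        index, null_config(min(cfg$null_size, nrow(index$fragments)),
                           seed = cfg$seed))
      sim <- distance_sample(nulls, blocks, "simulation")
      if (length(pooled$values) >= 2L) {
        dtest <- wilcoxon_rank_sum(pooled, sim)
        qq <- qq_points(pooled, sim)
        utils::write.table(
          data.frame(label = c(rep("experiment", length(pooled$values)),
                               rep("simulation", length(sim$values))),
                     distance = c(pooled$values, sim$values)),
          file.path(cfg$out_dir, "distance_samples.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(qq, file.path(cfg$out_dir, "qq_points.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(sprintf(
          "statistic\tp_value\tmethod\tn1\tn2\n%g\t%g\t%s\t%d\t%d",
          dtest$statistic, dtest$p_value, dtest$method, dtest$n1, dtest$n2),
          file.path(cfg$out_dir, "wilcoxon.tsv"))
      }
    }
  }

  edges <- bait_proximity_edges(cirs, baits, window = cfg$window_bait)
  utils::write.table(edges, file.path(cfg$out_dir, "bait_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_circos_links(edges, file.path(cfg$out_dir, "bait_edges.circos"),
                      baits = baits)
  genes_near <- NULL
  if (!is.null(cfg$genes_bed)) {
    genes <- read_bed(cfg$genes_bed)
    genes_near <- lapply(cirs, genes_near_cirs, genes = genes,
                         window = cfg$window_gene)
    gn <- data.frame(
      bait_id = rep(names(genes_near), lengths(genes_near)),
      gene = unlist(genes_near, use.names = FALSE))
    utils::write.table(gn, file.path(cfg$out_dir, "genes_near_cirs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  write_pipeline_config(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  if (length(errors))
    writeLines(paste(names(errors), unlist(errors), sep = "\t"),
               file.path(cfg$out_dir, "errors.tsv"))
  invisible(list(index = index, baits = baits, libraries = libs,
                 cirs = cirs, summaries = summaries, blocks = blocks,
                 distance_test = dtest, qq = qq, edges = edges,
                 genes_near = genes_near, errors = errors, log = log))
}
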