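# Tag processing: PSL parsing, alignment-quality filtering, assignment of
# accepted tags to restriction fragments, and the tabular count dialect
# (BaitID / Chr / DpnIIStart / DpnIIEnd / NumbReads).

#' Parse blat PSL alignments
#'
#' Reads 21-column PSL records (the blat output dialect), one aligned tag
#' per (read, locus) pair. The optional 5-line header is skipped.
#' `match_length` is `matches + repMatches`; `max_gap` is the largest
#' per-gap insertion on either the query or target side, computed from the
#' block structure when present, otherwise from the total insert-base
#' counts. `hit_count` is the number of records sharing a read id.
#' Because PSL does not carry read sequences, the leading-nucleotide check
#' is approximated: a tag whose alignment starts at query position 0 is
#' credited with `leading_seq = prefix` (4C reads are primed to start at
#' the restriction site, so a full-length alignment necessarily starts with
#' it).
#'
#' @param path Path to a PSL file.
#' @param prefix Nucleotides assumed at the start of every sequenced read
#'   (default `"GATC"`, the DpnII site).
#' @return data.frame of aligned tags with columns `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `match_length`, `max_gap`, `hit_count`,
#'   `leading_seq`, `q_start`.
#' @export
parse_psl <- function(path, prefix = "GATC") {
  lines <- readLines(path)
  empty_tags <- data.frame(read_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), match_length = integer(),
                           max_gap = integer(), hit_count = integer(),
                           leading_seq = character(), q_start = integer(),
                           stringsAsFactors = FALSE)
  if (!length(lines)) return(empty_tags)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_rec <- vapply(fields, function(f)
    length(f) == 21L && grepl("^[0-9]+$", f[[1]]), logical(1))
  first <- which(is_rec)[1]
  if (is.na(first)) return(empty_tags)
  # anything before the first record is header; afterwards malformed
  # non-empty lines are rejected with their line number
  body <- seq(first, length(lines))
  bad <- body[!is_rec[body] & nzchar(lines[body])]
  if (length(bad)) stop_line(bad[1], "malformed PSL record (expected 21 columns)")
  recs <- fields[is_rec]
  col <- function(k) vapply(recs, `[[`, "", k)
  num <- function(k) as.integer(col(k))
  block_gaps <- function(sizes, starts) {
    bs <- as.integer(strsplit(sizes, ",", fixed = TRUE)[[1]])
    st <- as.integer(strsplit(starts, ",", fixed = TRUE)[[1]])
    if (length(bs) < 2L) return(0L)
    max(st[-1L] - (st[-length(st)] + bs[-length(bs)]))
  }
  n <- length(recs)
  max_gap <- integer(n)
  bc <- num(18)
  for (i in seq_len(n)) {
    f <- recs[[i]]
    if (!is.na(bc[i]) && bc[i] >= 1L && nzchar(f[[19]])) {
      max_gap[i] <- max(block_gaps(f[[19]], f[[20]]),
                        block_gaps(f[[19]], f[[21]]))
    } else {
      max_gap[i] <- max(as.integer(f[[6]]), as.integer(f[[8]]))
    }
  }
  q_start <- num(12)
  out <- data.frame(read_id = col(10),
                    chrom = col(14),
                    start = num(16),
                    end = num(17),
                    strand = substr(col(9), 1L, 1L),
                    match_length = num(1) + num(3),
                    max_gap = max_gap,
                    hit_count = 0L,
                    leading_seq = ifelse(q_start == 0L, prefix, ""),
                    q_start = q_start,
                    stringsAsFactors = FALSE)
  out$hit_count <- as.integer(ave(seq_len(n), out$read_id, FUN = length))
  out
}

#' Alignment filter configuration
#'
#' Defaults are the quality criteria used for 4C tag mapping: minimum match
#' length 29 nt, no gap larger than 1 nt, reads must begin with the DpnII
#' site, and multi-mapping reads are discarded.
#'
#' @param min_match Minimum aligned match length (nt).
#' @param max_gap Largest tolerated single gap (nt).
#' @param required_prefix Required leading nucleotides of the read.
#' @param require_unique Discard reads aligning to more than one locus.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_match = 29L, max_gap = 1L,
                          required_prefix = "GATC", require_unique = TRUE) {
  stopifnot(min_match >= 1L, max_gap >= 0L)
  structure(list(min_match = as.integer(min_match),
                 max_gap = as.integer(max_gap),
                 required_prefix = toupper(required_prefix),
                 require_unique = isTRUE(require_unique)),
            class = "filter_config")
}

#' Filter aligned tags
#'
#' Keeps exactly the tags satisfying all criteria of `cfg`; input order is
#' preserved. Idempotent: filtering a filtered set changes nothing.
#'
#' @param tags data.frame from [parse_psl()] (or equivalent).
#' @param cfg A [filter_config()].
#' @return Subset of `tags`; attribute `"rejected"` carries the per-rule
#'   rejection counts.
#' @export
filter_tags <- function(tags, cfg = filter_config()) {
  keep_match <- tags$match_length >= cfg$min_match
  keep_gap <- tags$max_gap <= cfg$max_gap
  keep_prefix <- tags$leading_seq == cfg$required_prefix
  keep_unique <- if (cfg$require_unique) tags$hit_count == 1L else TRUE
  keep <- keep_match & keep_gap & keep_prefix & keep_unique
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(short_match = sum(!keep_match),
                             gapped = sum(!keep_gap),
                             bad_prefix = sum(!keep_prefix),
                             multi_hit = sum(!(tags$hit_count == 1L |
                                               !cfg$require_unique)))
  out
}

new_library_counts <- function(counts, bait_id = NA_character_,
                               replicate_id = NA_integer_,
                               crosslinked = NA, unassigned = 0L) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  rownames(counts) <- NULL
  structure(list(bait_id = bait_id,
                 replicate_id = replicate_id,
                 crosslinked = crosslinked,
                 counts = counts,
                 total_tags = sum(counts$count),
                 unassigned = unassigned),
            class = "library_counts")
}

#' Construct a per-fragment count library
#'
#' @param counts data.frame with columns `chrom`, `start`, `end`, `count`
#'   (one row per fragment, 0-based half-open coordinates).
#' @param bait_id,replicate_id,crosslinked Library metadata.
#' @param unassigned Number of tags that could not be assigned.
#' @return An object of class `library_counts`.
#' @export
library_counts <- function(counts, bait_id = NA_character_,
                           replicate_id = NA_integer_, crosslinked = NA,
                           unassigned = 0L) {
  new_library_counts(counts, bait_id, replicate_id, crosslinked, unassigned)
}

#' @export
print.library_counts <- function(x, ...) {
  cat(sprintf(
    "library_counts: bait %s, %d fragments, %d tags (%d unassigned)\n",
    x$bait_id, nrow(x$counts), x$total_tags, x$unassigned))
  invisible(x)
}

#' Assign filtered tags to restriction fragments
#'
#' Each accepted tag begins at a restriction-site boundary, so a tag on the
#' `+` strand is assigned to the fragment whose `start` equals the tag
#' start, and a `-` strand tag to the fragment whose `end` equals the tag
#' end. A boundary mismatch up to `tolerance` bp snaps to the nearest
#' boundary; other tags (and tags on unknown chromosomes) are counted as
#' unassigned and dropped, so assigned + unassigned equals the input count.
#'
#' @param tags Filtered tag data.frame ([filter_tags()]).
#' @param index A `fragment_index`.
#' @param tolerance Maximum boundary mismatch in bp (default 0).
#' @param bait_id,replicate_id,crosslinked Library metadata.
#' @return A `library_counts` over the fragments of `index`.
#' @export
assign_tags <- function(tags, index, tolerance = 0L,
                        bait_id = NA_character_, replicate_id = NA_integer_,
                        crosslinked = NA) {
  f <- index$fragments
  hit <- integer(nrow(f))
  unassigned <- 0L
  for (ch in unique(tags$chrom)) {
    rows <- index$rows[[ch]]
    t_ch <- tags[tags$chrom == ch, , drop = FALSE]
    if (is.null(rows)) { unassigned <- unassigned + nrow(t_ch); next }
    bound <- ifelse(t_ch$strand == "-", t_ch$end, t_ch$start)
    # + strand anchors to fragment starts, - strand to fragment ends
    starts <- f$start[rows]; ends <- f$end[rows]
    for (i in seq_along(bound)) {
      anchor <- if (t_ch$strand[i] == "-") ends else starts
      j <- findInterval(bound[i], anchor)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(anchor)))
      d <- abs(anchor[cand] - bound[i])
      k <- cand[which.min(d)]
      if (min(d) <= tolerance) hit[rows[k]] <- hit[rows[k]] + 1L
      else unassigned <- unassigned + 1L
    }
  }
  keep <- hit > 0L
  counts <- data.frame(chrom = f$chrom[keep], start = f$start[keep],
                       end = f$end[keep], ordinal = f$ordinal[keep],
                       count = hit[keep], stringsAsFactors = FALSE)
  new_library_counts(counts, bait_id, replicate_id, crosslinked, unassigned)
}

#' Read a tabular fragment-count file
#'
#' Tab-separated table with columns `BaitID`, `Chr`, `DpnIIStart`,
#' `DpnIIEnd`, `NumbReads`; rows are grouped by `BaitID` into one
#' `library_counts` per bait. Coordinates are treated as 1-based inclusive
#' by default (`one_based = FALSE` reads them as 0-based half-open).
#' A negative or non-integer `NumbReads` is rejected with its line number;
#' the same `BaitID` appearing in more than one input file is an error.
#'
#' @param paths One or more file paths.
#' @param one_based Coordinate convention of the files.
#' @return Named list of `library_counts`, keyed by `BaitID`.
#' @export
read_counts_table <- function(paths, one_based = TRUE) {
  all_libs <- list()
  for (path in paths) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("BaitID", "Chr", "DpnIIStart", "DpnIIEnd", "NumbReads")
    if (!all(need %in% names(tab)))
      stop(sprintf("'%s': missing columns %s", path,
                   paste(setdiff(need, names(tab)), collapse = ", ")))
    nr <- suppressWarnings(as.numeric(tab$NumbReads))
    bad <- is.na(nr) | nr < 0 | nr != floor(nr)
    if (any(bad))
      stop_line(which(bad)[1] + 1L, "NumbReads must be a non-negative integer")
    tab$NumbReads <- as.integer(nr)
    for (bid in unique(tab$BaitID)) {
      if (bid %in% names(all_libs))
        stop(sprintf("BaitID '%s' appears in more than one file", bid))
      rows <- tab[tab$BaitID == bid, , drop = FALSE]
      counts <- data.frame(chrom = rows$Chr,
                           start = rows$DpnIIStart - as.integer(one_based),
                           end = rows$DpnIIEnd,
                           count = rows$NumbReads,
                           stringsAsFactors = FALSE)
      all_libs[[bid]] <- new_library_counts(counts, bait_id = bid)
    }
  }
  all_libs
}

#' Write libraries as a tabular fragment-count file
#'
#' Inverse of [read_counts_table()]; round-trips exactly.
#'
#' @param libs List of `library_counts` (or a single one).
#' @param path Output path.
#' @param one_based Coordinate convention to write.
#' @export
write_counts_table <- function(libs, path, one_based = TRUE) {
  if (inherits(libs, "library_counts")) libs <- list(libs)
  rows <- do.call(rbind, lapply(libs, function(l) {
    data.frame(BaitID = l$bait_id,
               Chr = l$counts$chrom,
               DpnIIStart = l$counts$start + as.integer(one_based),
               DpnIIEnd = l$counts$end,
               NumbReads = l$counts$count,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
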