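# Genome model: chromosomes, in-silico restriction digestion, interval I/O.
# Coordinates are 0-based half-open throughout the package; BED I/O is
# native, the 1-based tabular dialects are converted at the boundary.

#' Construct a genome index
#'
#' A genome index records chromosome names and lengths, optionally together
#' with the nucleotide sequences (uppercase A/C/G/T/N). Sequences are
#' required for in-silico digestion ([digest_genome()]); a length-only index
#' is enough for interval bookkeeping.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences; coerced to uppercase character.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#'   Derived from `sequences` when those are supplied.
#' @return An object of class `genome_index` with elements `chrom_names`,
#'   `chrom_lengths` and `sequences` (possibly `NULL`).
#' @export
genome_index <- function(sequences = NULL, chrom_lengths = NULL) {
  if (is.null(sequences) && is.null(chrom_lengths))
    stop("supply sequences or chrom_lengths")
  if (!is.null(sequences)) {
    nm <- names(sequences)
    sequences <- stats::setNames(toupper(as.character(sequences)), nm)
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        !all(nzchar(names(sequences))))
      stop("sequences must be named by chromosome")
    lens <- nchar(sequences)
    if (!is.null(chrom_lengths) &&
        !identical(unname(lens[names(chrom_lengths)]),
                   as.integer(unname(chrom_lengths))))
      stop("chrom_lengths disagree with sequence lengths")
    chrom_lengths <- lens
  }
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 sequences = sequences),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d chromosome(s), %.0f bp total, sequences %s\n",
              length(x$chrom_names), sum(as.double(x$chrom_lengths)),
              if (is.null(x$sequences)) "absent" else "present"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return A `genome_index` with sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome_index(sequences = as.character(ss))
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome_index` with sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequences)) stop("sequences required")
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' In-silico restriction digestion
#'
#' Cuts every chromosome at the start of each occurrence of the recognition
#' site (DpnII cleaves 5' of GATC, so the fragment downstream of a cut
#' begins with the site). Fragments are the maximal intervals between
#' consecutive cuts plus the chromosome ends; a zero-length fragment arising
#' from a site at position 0 is dropped. Occurrences containing `N` never
#' match.
#'
#' @param genome A `genome_index` with sequences.
#' @param site Recognition sequence, default `"GATC"` (DpnII).
#' @return An object of class `fragment_index`: the genome, the enzyme site
#'   and a data.frame of fragments with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `ordinal` (0-based index within chromosome).
#' @export
digest_genome <- function(genome, site = "GATC") {
  if (is.null(genome$sequences)) stop("sequences required")
  site <- toupper(site)
  if (!nzchar(site)) stop("recognition site must be non-empty")
  per_chrom <- lapply(genome$chrom_names, function(ch) {
    s <- genome$sequences[[ch]]
    L <- nchar(s)
    m <- Biostrings::matchPattern(site, Biostrings::DNAString(s),
                                  fixed = TRUE)
    cuts <- BiocGenerics::start(m) - 1L    # 0-based cut positions
    b <- sort(unique(c(0L, cuts, L)))      # duplicate 0 collapses -> drop
    data.frame(chrom = ch,
               start = b[-length(b)],
               end = b[-1L],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  frags$ordinal <- unlist(lapply(per_chrom, function(d) seq_len(nrow(d)) - 1L),
                          use.names = FALSE)
  rownames(frags) <- NULL
  new_fragment_index(genome, frags, site)
}

new_fragment_index <- function(genome, frags, site) {
  structure(list(genome = genome, fragments = frags, site = site,
                 rows = split(seq_len(nrow(frags)), frags$chrom)),
            class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  cat(sprintf("fragment_index: %d fragments (%s) on %d chromosome(s)\n",
              nrow(x$fragments), x$site, length(x$genome$chrom_names)))
  invisible(x)
}

#' Fragment table of a fragment index
#'
#' @param index A `fragment_index`.
#' @return data.frame with columns `chrom`, `start`, `end`, `ordinal`.
#' @export
fragments <- function(index) index$fragments

#' Locate the restriction fragment containing a position
#'
#' Binary-search lookup of the unique fragment with `start <= pos < end`.
#'
#' @param index A `fragment_index`.
#' @param chrom Chromosome name.
#' @param pos 0-based position, `0 <= pos < chrom_length`.
#' @return One-row data.frame (`chrom`, `start`, `end`, `ordinal`).
#' @export
locate_fragment <- function(index, chrom, pos) {
  rows <- index$rows[[chrom]]
  if (is.null(rows)) stop(sprintf("unknown chromosome '%s'", chrom))
  L <- index$genome$chrom_lengths[[chrom]]
  if (pos < 0 || pos >= L)
    stop(sprintf("position %d out of range [0, %d) on '%s'", pos, L, chrom))
  starts <- index$fragments$start[rows]
  i <- findInterval(pos, starts)
  index$fragments[rows[i], , drop = FALSE]
}

#' Fragment (or interval) center
#'
#' Floor midpoint `floor((start + end) / 2)`, the convention used for all
#' center-to-center distances in the package.
#'
#' @param frag data.frame with `start` and `end` columns (vectorised).
#' @return Numeric vector of center coordinates.
#' @export
fragment_center <- function(frag) {
  (frag$start + frag$end) %/% 2
}

#' Read a BED file
#'
#' BED3/BED6, 0-based half-open, `track`/`browser`/comment lines ignored.
#' A record with `start >= end` or a malformed field is rejected with an
#' error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  idx <- which(!skip)
  if (!length(idx))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop_line(idx[which(ncols < 3)[1]], "expected at least 3 BED fields")
  nc <- min(ncols)
  get <- function(k) vapply(fields, `[[`, "", k)
  out <- data.frame(chrom = get(1),
                    start = suppressWarnings(as.integer(get(2))),
                    end = suppressWarnings(as.integer(get(3))),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop_line(idx[which(is.na(out$start) | is.na(out$end))[1]],
              "non-numeric BED coordinate")
  bad <- out$start >= out$end
  if (any(bad)) stop_line(idx[which(bad)[1]], "start >= end")
  if (nc >= 4) out$name <- get(4)
  if (nc >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6) out$strand <- get(6)
  out
}

#' Write intervals as BED
#'
#' Writes BED3 or (when `name`/`score`/`strand` columns are present) BED6;
#' round-trips with [read_bed()].
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- list(x$chrom, x$start, x$end)
  extra <- c("name", "score", "strand")
  present <- extra %in% names(x)
  if (any(present)) {
    upto <- max(which(present))
    defaults <- list(".", 0, ".")
    for (k in seq_len(upto))
      cols[[3 + k]] <- if (present[k]) x[[extra[k]]] else defaults[[k]]
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Export a fragment index as BED4
#'
#' One record per fragment, `name = "chrom:ordinal"`.
#'
#' @param index A `fragment_index`.
#' @param path Output path.
#' @export
write_fragment_bed <- function(index, path) {
  f <- index$fragments
  write_bed(data.frame(chrom = f$chrom, start = f$start, end = f$end,
                       name = paste0(f$chrom, ":", f$ordinal),
                       stringsAsFactors = FALSE), path)
}
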