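# CIR calling: bait-flanking exclusion, tag-count thresholding, cis/trans
# summaries, replicate reproducibility, and track exports.

#' Define a bait (viewpoint) fragment
#'
#' @param bait_id Identifier of the bait.
#' @param fragment One-row data.frame (`chrom`, `start`, `end`, `ordinal`),
#'   typically from [locate_fragment()].
#' @param kind `"CNC"`, `"nonCNC"` or `"control-locus"`.
#' @param conservation_score Optional conservation score of the most
#'   conserved element contained in the bait fragment.
#' @param lod Optional log-odds score of that element.
#' @return An object of class `bait`.
#' @export
bait <- function(bait_id, fragment, kind = c("CNC", "nonCNC", "control-locus"),
                 conservation_score = NA_real_, lod = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(fragment), nrow(fragment) == 1L,
            all(c("chrom", "start", "end") %in% names(fragment)))
  structure(list(bait_id = bait_id, kind = kind, fragment = fragment,
                 conservation_score = conservation_score, lod = lod),
            class = "bait")
}

bait_flank_set <- function(bait, index, n_flank) {
  rows <- index$rows[[bait$fragment$chrom]]
  if (is.null(rows)) stop("bait chromosome absent from fragment index")
  o <- index$fragments$ordinal[rows]
  b_ord <- bait$fragment$ordinal
  if (is.null(b_ord) || is.na(b_ord)) {
    hit <- which(index$fragments$start[rows] == bait$fragment$start)
    if (!length(hit)) stop("bait fragment not found in index")
    b_ord <- o[hit[1]]
  }
  sel <- o >= (b_ord - n_flank) & o <= (b_ord + n_flank)
  index$fragments[rows[sel], , drop = FALSE]
}

#' Remove the bait fragment and its flanking fragments
#'
#' The fragments directly flanking the bait are over-represented in a 4C
#' library (partial digestion, proximity ligation) and are excluded before
#' interaction calling. Removes the bait fragment plus `n_flank` fragments
#' on each side (fewer at a chromosome end).
#'
#' @param lib A `library_counts`.
#' @param bait A [bait()].
#' @param index The `fragment_index` the library was counted on.
#' @param n_flank Fragments removed on each side of the bait (default 1).
#' @return `library_counts` without the excluded fragments; attribute
#'   `"excluded_flanking"` records the removed fragments.
#' @export
exclude_bait_flanking <- function(lib, bait, index, n_flank = 1L) {
  stopifnot(n_flank >= 0L)
  excl <- bait_flank_set(bait, index, n_flank)
  key <- function(d) paste(d$chrom, d$start, d$end)
  drop <- key(lib$counts) %in% key(excl)
  out <- new_library_counts(lib$counts[!drop, , drop = FALSE],
                            bait_id = lib$bait_id,
                            replicate_id = lib$replicate_id,
                            crosslinked = lib$crosslinked,
                            unassigned = lib$unassigned)
  attr(out, "excluded_flanking") <- excl
  out
}

#' Call interacting regions (CIRs)
#'
#' A CIR is a restriction fragment observed at least `threshold` times in a
#' bait's library, after exclusion of the bait fragment and its direct
#' flanks. Members are sorted by chromosome (genome order) and start.
#'
#' @param lib A `library_counts`.
#' @param bait A [bait()].
#' @param index The `fragment_index` the library was counted on.
#' @param threshold Minimum tag count (default 50).
#' @param n_flank Flanking fragments excluded on each side (default 1).
#' @return Object of class `cir_set` with elements `bait`, `threshold`,
#'   `members` (data.frame incl. `count`) and `excluded_flanking`.
#' @export
call_cirs <- function(lib, bait, index, threshold = 50L, n_flank = 1L) {
  lib2 <- exclude_bait_flanking(lib, bait, index, n_flank)
  m <- lib2$counts[lib2$counts$count >= threshold, , drop = FALSE]
  chrom_rank <- match(m$chrom, index$genome$chrom_names)
  m <- m[order(chrom_rank, m$start), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(bait = bait, threshold = as.integer(threshold),
                 members = m,
                 excluded_flanking = attr(lib2, "excluded_flanking")),
            class = "cir_set")
}

#' @export
print.cir_set <- function(x, ...) {
  cat(sprintf("cir_set: bait %s, %d members at threshold >= %d\n",
              x$bait$bait_id, nrow(x$members), x$threshold))
  invisible(x)
}

#' Cis/trans interaction summary
#'
#' Percentage of tags (and of fragments) in members lying on a chromosome
#' different from the bait's. Computed over the threshold-passing members
#' of a `cir_set`; pass a `library_counts` plus `bait` for the
#' unthresholded variant.
#'
#' @param x A `cir_set`, or a `library_counts`.
#' @param bait Required when `x` is a `library_counts`.
#' @return List of class `cis_trans_summary`: `bait_id`, `trans_tag_pct`,
#'   `trans_frag_pct`, `n_members`, `n_tags`.
#' @export
cis_trans_summary <- function(x, bait = NULL) {
  if (inherits(x, "cir_set")) {
    m <- x$members; bait <- x$bait
  } else if (inherits(x, "library_counts")) {
    if (is.null(bait)) stop("bait required for a library_counts input")
    m <- x$counts
  } else stop("x must be a cir_set or library_counts")
  n_members <- nrow(m)
  n_tags <- sum(m$count)
  if (n_members == 0L) {
    tt <- 0; tf <- 0
  } else {
    is_trans <- m$chrom != bait$fragment$chrom
    tt <- 100 * sum(m$count[is_trans]) / n_tags
    tf <- 100 * sum(is_trans) / n_members
  }
  structure(list(bait_id = bait$bait_id, trans_tag_pct = tt,
                 trans_frag_pct = tf, n_members = n_members,
                 n_tags = n_tags),
            class = "cis_trans_summary")
}

#' @export
print.cis_trans_summary <- function(x, ...) {
  cat(sprintf(
    "bait %s: %.1f%% trans tags (%.1f%% trans fragments), %d members, %d tags\n",
    x$bait_id, x$trans_tag_pct, x$trans_frag_pct, x$n_members, x$n_tags))
  invisible(x)
}

#' Replicate reproducibility of called CIRs
#'
#' Percentage of experiment-1 member fragments also called in experiment 2
#' (fragment identity = identical coordinates). Asymmetric by definition:
#' the denominator is experiment 1. The symmetric Jaccard index is attached
#' as attribute `"jaccard"`.
#'
#' @param cirs1,cirs2 `cir_set`s for the same bait on the same index.
#' @return Percentage (numeric scalar).
#' @export
replicate_reproducibility <- function(cirs1, cirs2) {
  key <- function(m) paste(m$chrom, m$start, m$end)
  k1 <- key(cirs1$members); k2 <- key(cirs2$members)
  if (!length(k1))
    stop("reproducibility undefined: experiment 1 has no members")
  ov <- sum(k1 %in% k2)
  out <- 100 * ov / length(k1)
  attr(out, "jaccard") <- ov / length(union(k1, k2))
  out
}

#' Export per-fragment counts as bedGraph
#'
#' One line per nonzero fragment; `transform = "log2"` writes
#' `log2(count)` (the scale used for browser tracks of 4C signal).
#'
#' @param lib A `library_counts`.
#' @param path Output path.
#' @param transform `"none"` or `"log2"`.
#' @export
export_bedgraph <- function(lib, path, transform = c("none", "log2")) {
  transform <- match.arg(transform)
  d <- lib$counts[lib$counts$count > 0, , drop = FALSE]
  val <- if (transform == "log2") log2(d$count) else d$count
  writeLines(paste(d$chrom, d$start, d$end, val, sep = "\t"), path)
  invisible(path)
}
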