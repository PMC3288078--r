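# Interval primitives. Intervals are rows of a data.frame with columns
# seq_id (character), start, end (integer, 0-based half-open).

.empty_intervals <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct a table of genomic intervals
#'
#' Intervals are strandless, 0-based, half-open `[start, end)` on a named
#' sequence. This is the atom of all peak and feature algebra in the package.
#'
#' @param seq_id Character vector of sequence (chromosome) names.
#' @param start,end Integer vectors; `0 <= start < end` required.
#' @return A data.frame with columns `seq_id`, `start`, `end`.
#' @export
genomic_interval <- function(seq_id, start, end) {
  n <- max(length(seq_id), length(start), length(end))
  seq_id <- rep_len(as.character(seq_id), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("invalid interval(s) at position(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  data.frame(seq_id = seq_id, start = start, end = end, stringsAsFactors = FALSE)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
.gr0 <- function(df) {
  if (nrow(df) == 0L) return(GRanges())
  GRanges(df$seq_id, IRanges(df$start + 1L, df$end))
}

# GRanges -> data.frame (0-based half-open), sorted by (seq_id, start)
.bed0 <- function(gr) {
  df <- data.frame(seq_id = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$seq_id, df$start, df$end), , drop = FALSE]
}

.sort_intervals <- function(df) {
  df <- df[order(df$seq_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge overlapping intervals
#'
#' Collapses intervals sharing at least one base. Abutting half-open
#' intervals (`end == start`) are left separate. The result is sorted by
#' `(seq_id, start)`.
#'
#' @param df Interval data.frame (`seq_id`, `start`, `end`).
#' @return Canonical interval data.frame.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(.empty_intervals())
  out <- .bed0(reduce(.gr0(df), min.gapwidth = 0L))
  rownames(out) <- NULL
  out
}

#' Test whether two intervals overlap
#'
#' Overlap means at least one shared base: same `seq_id`,
#' `a$start < b$end` and `b$start < a$end`. Vectorised with recycling.
#'
#' @param a,b Interval data.frames.
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  a$seq_id[ia] == b$seq_id[ib] &
    a$start[ia] < b$end[ib] &
    b$start[ib] < a$end[ia]
}

# indices of `query` rows overlapping >= min_bp bases of any `subject` row
.overlap_any <- function(query, subject, min_bp = 1L) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  countOverlaps(.gr0(query), .gr0(subject), minoverlap = as.integer(min_bp)) > 0L
}

# total number of bases of df (after merging) falling inside `within`
.covered_bases <- function(df, within) {
  if (nrow(df) == 0L || nrow(within) == 0L) return(0)
  sum(width(GenomicRanges::intersect(reduce(.gr0(df)), reduce(.gr0(within)))))
}
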