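#' Construct a PeakSet
#'
#' A PeakSet is the canonical container for the peak calls of one
#' (mark, condition) track: a set of strandless intervals that is sorted and
#' self-merged on construction, so members are pairwise non-overlapping.
#'
#' @param intervals Interval data.frame (`seq_id`, `start`, `end`).
#' @param mark One of `"H3Ac"`, `"S5P_RNAPII"`, `"Sp1"`.
#' @param condition One of `"minus_LPS"`, `"plus_LPS"`.
#' @param label Free-text provenance label.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(intervals, mark = "H3Ac", condition = "minus_LPS",
                     label = "") {
  mark <- match.arg(mark, MARKS)
  condition <- match.arg(condition, CONDITIONS)
  if (nrow(intervals)) {
    genomic_interval(intervals$seq_id, intervals$start, intervals$end)
  }
  merged <- merge_intervals(intervals)
  n_merged <- nrow(intervals) - nrow(merged)
  if (n_merged > 0L) {
    message("peak_set: self-merge collapsed ", n_merged, " interval(s) [",
            mark, "/", condition, "]")
  }
  structure(list(intervals = merged, mark = mark, condition = condition,
                 label = label, n_merged = n_merged),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet:", x$mark, "/", x$condition,
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  ", nrow(x$intervals), "intervals on",
      length(unique(x$intervals$seq_id)), "sequence(s)\n")
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$intervals)

.as_intervals <- function(x) {
  if (inherits(x, "PeakSet")) x$intervals else x
}
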