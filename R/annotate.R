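# Genomic-feature annotation of peaks: promoter / exon / intron /
# intergenic with any-overlap precedence, CpG-island splits, and the
# expected per-base genome composition baseline.

#' Classify peaks by genomic feature
#'
#' Precedence is promoter > exon > intron > intergenic; a class is assigned
#' if the peak overlaps >= 1 bp of any feature of that class. "Intron" means
#' within a gene's transcribed span (min exon start to max exon end) without
#' touching a promoter or exon.
#'
#' @param peaks A `PeakSet` or interval data.frame.
#' @param promoters Promoter windows from [promoter_windows()].
#' @param tss A `tss_table` carrying exon structure.
#' @return Character vector (one class per peak).
#' @export
classify_peaks <- function(peaks, promoters, tss) {
  df <- .as_intervals(peaks)
  if (nrow(df) == 0L) return(character(0))
  in_prom <- .overlap_any(df, promoters)
  in_exon <- .overlap_any(df, .all_exons(tss))
  in_span <- .overlap_any(df, .gene_spans(tss))
  ifelse(in_prom, "promoter",
         ifelse(in_exon, "exon",
                ifelse(in_span, "intron", "intergenic")))
}

#' Percentage of peaks located in promoters
#'
#' @param peaks A `PeakSet` or interval data.frame.
#' @param promoters Promoter windows.
#' @return Percentage in `[0, 100]`, or `NA` for an empty set.
#' @export
promoter_fraction <- function(peaks, promoters) {
  df <- .as_intervals(peaks)
  if (nrow(df) == 0L) return(NA_real_)
  100 * mean(.overlap_any(df, promoters))
}

#' Split peaks by CpG-island co-localization
#'
#' High-CpG peaks overlap (>= 1 bp) at least one island; the rest are
#' low-CpG. The two parts partition the input.
#'
#' @param peaks A `PeakSet` or interval data.frame.
#' @param islands CpG island intervals (`PeakSet` or data.frame),
#'   canonicalized.
#' @return List with `high` and `low` interval data.frames (plus the marks
#'   of the input when it is a `PeakSet`).
#' @export
cpg_split <- function(peaks, islands) {
  df <- .as_intervals(peaks)
  isl <- merge_intervals(.as_intervals(islands))
  hi <- .overlap_any(df, isl)
  if (length(hi) == 0L) hi <- logical(0)
  list(high = df[hi, , drop = FALSE], low = df[!hi, , drop = FALSE])
}

#' Expected genome composition over feature classes
#'
#' Classifies every base of the genome with the same precedence used for
#' peaks and returns the fraction of bases per class. Fractions sum to 1.
#'
#' @param tss A `tss_table`.
#' @param promoters Promoter windows.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @return Named numeric vector over promoter/exon/intron/intergenic.
#' @export
genome_composition <- function(tss, promoters, seq_lengths) {
  total <- sum(as.numeric(seq_lengths))
  stopifnot(total > 0)
  genome <- data.frame(seq_id = names(seq_lengths), start = 0L,
                       end = as.integer(seq_lengths),
                       stringsAsFactors = FALSE)
  clamp <- function(df) {
    if (nrow(df) == 0L) return(.empty_intervals())
    .bed0(GenomicRanges::intersect(reduce(.gr0(df), min.gapwidth = 0L),
                                   .gr0(genome)))
  }
  prom <- clamp(promoters)
  exon <- clamp(.all_exons(tss))
  span <- clamp(.gene_spans(tss))
  p <- .covered_bases(prom, genome)
  e_only <- sum(width(GenomicRanges::setdiff(.gr0(exon), .gr0(prom))))
  i_only <- sum(width(GenomicRanges::setdiff(
    GenomicRanges::setdiff(.gr0(span), .gr0(prom)), .gr0(exon))))
  frac <- c(promoter = p, exon = e_only, intron = i_only,
            intergenic = total - p - e_only - i_only) / total
  frac
}

# Per-class Table-1-shaped summary for one mark comparison.
.mark_summary <- function(cmp, promoters, islands) {
  classes <- list(
    minus_total = cmp$minus$intervals,
    plus_total = cmp$plus$intervals,
    common_minus = cmp$members[cmp$members$condition == "minus_LPS",
                               c("seq_id", "start", "end")],
    common_plus = cmp$members[cmp$members$condition == "plus_LPS",
                              c("seq_id", "start", "end")],
    unique_minus = cmp$unique_minus,
    unique_plus = cmp$unique_plus)
  rows <- lapply(names(classes), function(nm) {
    df <- classes[[nm]]
    sp <- cpg_split(df, islands)
    data.frame(
      class = nm, n = nrow(df),
      mean_length = if (nrow(df)) mean(df$end - df$start) else NA_real_,
      pct_in_promoter = promoter_fraction(df, promoters),
      n_high_cpg = nrow(sp$high),
      pct_high_in_promoter = promoter_fraction(sp$high, promoters),
      n_low_cpg = nrow(sp$low),
      pct_low_in_promoter = promoter_fraction(sp$low, promoters),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(class = "common_components",
                               n = nrow(cmp$components), mean_length = NA,
                               pct_in_promoter = NA, n_high_cpg = NA,
                               pct_high_in_promoter = NA, n_low_cpg = NA,
                               pct_low_in_promoter = NA))
  rownames(out) <- NULL
  out
}
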