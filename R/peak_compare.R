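# Condition-wise peak comparison: replicate intersection, the
# common/unique partition via connected components of the cross-condition
# overlap graph, envelope-based widening calls, and length summaries.

#' Replicated peaks between two biological replicates
#'
#' Returns the intervals of `rep1` (the reference) that overlap at least
#' `min_overlap_bp` bases of some interval of `rep2`, self-merged. With
#' `symmetric = TRUE` the union of both directions is taken instead.
#'
#' @param rep1,rep2 `PeakSet`s of the same mark and condition.
#' @param min_overlap_bp Minimum shared bases (default 1).
#' @param symmetric Take the union of both filter directions.
#' @return A `PeakSet`.
#' @export
replicated_peaks <- function(rep1, rep2, min_overlap_bp = 1L,
                             symmetric = FALSE) {
  if (rep1$mark != rep2$mark || rep1$condition != rep2$condition) {
    stop("replicate PeakSets must share mark and condition (got ",
         rep1$mark, "/", rep1$condition, " vs ", rep2$mark, "/", rep2$condition, ")")
  }
  keep1 <- .overlap_any(rep1$intervals, rep2$intervals, min_overlap_bp)
  out <- rep1$intervals[keep1, , drop = FALSE]
  if (symmetric) {
    keep2 <- .overlap_any(rep2$intervals, rep1$intervals, min_overlap_bp)
    out <- rbind(out, rep2$intervals[keep2, , drop = FALSE])
  }
  peak_set(out, rep1$mark, rep1$condition,
           paste0("replicated(", rep1$label, ",", rep2$label, ")"))
}

#' Compare the peak sets of the two conditions
#'
#' Peaks overlapping (>= 1 bp) a peak of the other condition are grouped
#' into connected components of the bipartite overlap graph ("common"
#' peaks); all others are unique to their condition. Because overlaps can be
#' many-to-many, per-condition common counts and the component count are all
#' reported: they need not agree, which is why common-peak counts from the
#' two conditions are not additive.
#'
#' @param minus,plus `PeakSet`s of the same mark, conditions `minus_LPS`
#'   and `plus_LPS`.
#' @return An object of class `peak_comparison`: list with `components`
#'   (one row per component: per-condition envelope extents and member
#'   counts), `members` (one row per common peak with its component id),
#'   `unique_minus`, `unique_plus` (interval data.frames), the input
#'   `PeakSet`s, and `counts`.
#' @export
compare_conditions <- function(minus, plus) {
  if (minus$mark != plus$mark) stop("PeakSets must share a mark")
  im <- minus$intervals; ip <- plus$intervals
  in_m <- .overlap_any(im, ip)
  in_p <- .overlap_any(ip, im)
  unique_minus <- im[!in_m, , drop = FALSE]
  unique_plus <- ip[!in_p, , drop = FALSE]
  cm <- im[in_m, , drop = FALSE]
  cp <- ip[in_p, , drop = FALSE]
  rownames(unique_minus) <- rownames(unique_plus) <- NULL
  rownames(cm) <- rownames(cp) <- NULL

  if (nrow(cm)) {
    # connected components = maximal overlap-connected blocks of the union:
    # within one condition peaks never overlap (self-merged), so shared
    # bases always bridge conditions.
    blocks <- merge_intervals(rbind(cm, cp))
    bm <- findOverlaps(.gr0(cm), .gr0(blocks))
    bp <- findOverlaps(.gr0(cp), .gr0(blocks))
    comp_of_m <- subjectHits(bm)[order(queryHits(bm))]
    comp_of_p <- subjectHits(bp)[order(queryHits(bp))]
    members <- rbind(
      data.frame(component = comp_of_m, condition = "minus_LPS", cm,
                 stringsAsFactors = FALSE),
      data.frame(component = comp_of_p, condition = "plus_LPS", cp,
                 stringsAsFactors = FALSE))
    ext <- function(d) {
      c(start = min(d$start), end = max(d$end))
    }
    ids <- sort(unique(members$component))
    components <- do.call(rbind, lapply(ids, function(k) {
      mm <- members[members$component == k & members$condition == "minus_LPS", ]
      pp <- members[members$component == k & members$condition == "plus_LPS", ]
      data.frame(component = k, seq_id = mm$seq_id[1],
                 extent_minus_start = min(mm$start), extent_minus_end = max(mm$end),
                 extent_plus_start = min(pp$start), extent_plus_end = max(pp$end),
                 n_minus = nrow(mm), n_plus = nrow(pp),
                 stringsAsFactors = FALSE)
    }))
    rownames(components) <- rownames(members) <- NULL
  } else {
    members <- data.frame(component = integer(0), condition = character(0),
                          .empty_intervals(), stringsAsFactors = FALSE)
    components <- data.frame(component = integer(0), seq_id = character(0),
                             extent_minus_start = integer(0),
                             extent_minus_end = integer(0),
                             extent_plus_start = integer(0),
                             extent_plus_end = integer(0),
                             n_minus = integer(0), n_plus = integer(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(
    mark = minus$mark, minus = minus, plus = plus,
    components = components, members = members,
    unique_minus = unique_minus, unique_plus = unique_plus,
    counts = c(n_components = nrow(components),
               n_common_minus = nrow(cm), n_common_plus = nrow(cp),
               n_unique_minus = nrow(unique_minus),
               n_unique_plus = nrow(unique_plus))),
    class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("peak_comparison [", x$mark, "]\n", sep = "")
  print(x$counts)
  invisible(x)
}

# Core of the widening call, vectorised over components. Growth of the
# +LPS envelope beyond the -LPS envelope on each genomic side; shrinkage
# never yields a direction.
.extension_call <- function(em_start, em_end, ep_start, ep_end, strand,
                            min_extension_bp = 200L) {
  left <- pmax(0L, em_start - ep_start)
  right <- pmax(0L, ep_end - em_end)
  up <- ifelse(strand == "+", left, right)
  down <- ifelse(strand == "+", right, left)
  up_hit <- up >= min_extension_bp
  down_hit <- down >= min_extension_bp
  ifelse(up_hit & down_hit, "both",
         ifelse(up_hit, "upstream",
                ifelse(down_hit, "downstream", "none")))
}

#' Direction of chromatin expansion of a common peak component
#'
#' Compares the per-condition envelope extents of a component and calls,
#' relative to the strand of the supplied TSS, whether the +LPS envelope
#' grew upstream only (`"upstream"`), downstream only (`"downstream"`),
#' both (`"both"`) or neither (`"none"`). Growth below `min_extension_bp`
#' (default 200 bp, one SICER-style window) is ignored, and shrinkage never
#' produces a direction.
#'
#' @param component One row of the `components` table of a
#'   [compare_conditions()] result.
#' @param tss One row of a `tss_table` on the same sequence.
#' @param min_extension_bp Minimum growth (bp) to count as expansion.
#' @return One of `"upstream"`, `"downstream"`, `"both"`, `"none"`.
#' @export
extension_call <- function(component, tss, min_extension_bp = 200L) {
  if (component$seq_id != tss$seq_id) {
    stop("component on ", component$seq_id, " but TSS of ", tss$gene_id,
         " on ", tss$seq_id)
  }
  .extension_call(component$extent_minus_start, component$extent_minus_end,
                  component$extent_plus_start, component$extent_plus_end,
                  tss$strand, min_extension_bp)
}

#' Per-class peak counts and mean lengths
#'
#' Arithmetic mean interval lengths per class of a comparison, plus the
#' widening ratio (mean +LPS common member length over mean -LPS common
#' member length). Empty classes report `NA`, never 0.
#'
#' @param result A `peak_comparison`.
#' @return List with `table` (one row per class: n, mean_length) and
#'   `widening_ratio`.
#' @export
length_summary <- function(result) {
  mlen <- function(df) if (nrow(df) == 0L) NA_real_ else mean(df$end - df$start)
  memb <- function(cond) {
    d <- result$members[result$members$condition == cond, , drop = FALSE]
    d
  }
  cm <- memb("minus_LPS"); cp <- memb("plus_LPS")
  tab <- data.frame(
    class = c("minus_total", "plus_total", "common_minus", "common_plus",
              "unique_minus", "unique_plus"),
    n = c(length(result$minus), length(result$plus), nrow(cm), nrow(cp),
          nrow(result$unique_minus), nrow(result$unique_plus)),
    mean_length = c(mlen(result$minus$intervals), mlen(result$plus$intervals),
                    mlen(cm), mlen(cp), mlen(result$unique_minus),
                    mlen(result$unique_plus)),
    stringsAsFactors = FALSE)
  ratio <- if (nrow(cm) && nrow(cp)) mlen(cp) / mlen(cm) else NA_real_
  list(table = tab, widening_ratio = ratio)
}
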