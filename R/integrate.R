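# Gene-by-gene integration of the peak comparison, CpG, TATA and
# expression tracks into per-TSS feature profiles, and the two-group
# promoter-architecture classification of regulated genes.

.occ_status <- function(window, minus, plus) {
  in_m <- if (is.null(minus)) FALSE else
    any(.overlap_any(window, .as_intervals(minus)))
  in_p <- if (is.null(plus)) FALSE else
    any(.overlap_any(window, .as_intervals(plus)))
  if (in_m && in_p) "both" else if (in_m) "minus_only" else
    if (in_p) "plus_only" else "none"
}

#' Build per-TSS feature profiles
#'
#' For every annotated TSS this records: whether a common H3Ac peak
#' component overlaps the promoter window (and, if so, the direction of
#' its expansion), the per-condition occupancy of S5P RNAPII and Sp1 in
#' the window, CpG-island presence, the TATA-box scan result for the core
#' promoter, the gene's differential-expression result, the group label
#' from [classify_group()], and a consistency score (fraction of the
#' secondary features CpG / TATA / Sp1 that match the assigned group's
#' modal pattern). When several H3Ac components overlap one window the one
#' covering most of the window is used (logged).
#'
#' @param tss A `tss_table`.
#' @param h3ac_cmp A `peak_comparison` for H3Ac.
#' @param s5p,sp1 Lists with `minus` and `plus` `PeakSet`s (either may be
#'   `NULL`).
#' @param cpg_islands CpG island intervals.
#' @param tata Result of [scan_tata()], or a named logical vector by
#'   `tss_id`.
#' @param de A `de_result` or `NULL`.
#' @param upstream_bp,downstream_bp Promoter window extents.
#' @param min_extension_bp Passed to the expansion call.
#' @param seq_lengths Optional named lengths for window clamping.
#' @return A data.frame of class `tss_profile`, one row per TSS.
#' @export
build_profiles <- function(tss, h3ac_cmp, s5p = NULL, sp1 = NULL,
                           cpg_islands = NULL, tata = NULL, de = NULL,
                           upstream_bp = 2000L, downstream_bp = 1000L,
                           min_extension_bp = 200L, seq_lengths = NULL) {
  prom <- promoter_windows(tss, upstream_bp, downstream_bp, seq_lengths)
  comp <- h3ac_cmp$components
  # component hull (both conditions) for promoter-overlap tests
  hull <- if (nrow(comp)) data.frame(
    seq_id = comp$seq_id,
    start = pmin(comp$extent_minus_start, comp$extent_plus_start),
    end = pmax(comp$extent_minus_end, comp$extent_plus_end),
    stringsAsFactors = FALSE) else .empty_intervals()
  tata_flag <- if (is.list(tata) && !is.null(tata$tata)) tata$tata else tata
  isl <- if (is.null(cpg_islands)) .empty_intervals() else
    merge_intervals(.as_intervals(cpg_islands))
  n_ties <- 0L
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    w <- prom[i, c("seq_id", "start", "end")]
    h3ac_common <- FALSE
    extension <- "none"
    if (nrow(hull)) {
      ov <- which(overlaps(hull, w[rep(1, nrow(hull)), ]))
      if (length(ov)) {
        h3ac_common <- TRUE
        if (length(ov) > 1L) {
          cover <- vapply(ov, function(k) {
            min(hull$end[k], w$end) - max(hull$start[k], w$start)
          }, numeric(1))
          n_ties <<- n_ties + 1L
          ov <- ov[which.max(cover)]
        }
        extension <- extension_call(comp[ov, ], tss[i, ], min_extension_bp)
      }
    }
    s5p_status <- .occ_status(w, s5p$minus, s5p$plus)
    sp1_status <- .occ_status(w, sp1$minus, sp1$plus)
    cpg <- any(.overlap_any(w, isl))
    tt <- if (is.null(tata_flag)) FALSE else
      isTRUE(unname(tata_flag[tss$tss_id[i]]))
    data.frame(gene_id = tss$gene_id[i], tss_id = tss$tss_id[i],
               seq_id = tss$seq_id[i], strand = tss$strand[i],
               tss_pos = tss$tss_pos[i],
               h3ac_common = h3ac_common, extension = extension,
               s5p_status = s5p_status, sp1_status = sp1_status,
               cpg = cpg, tata = tt, stringsAsFactors = FALSE)
  })
  if (n_ties > 0L) {
    message("build_profiles: ", n_ties,
            " promoter window(s) overlapped several H3Ac components; ",
            "kept the largest-overlap component")
  }
  out <- do.call(rbind, rows)
  if (!is.null(de)) {
    j <- match(out$gene_id, de$gene_id)
    out$p_value <- de$p_value[j]
    out$fold_change <- de$fold_change[j]
    out$de_call <- ifelse(is.na(j), "null", de$call[j])
  } else {
    out$p_value <- NA_real_; out$fold_change <- NA_real_
    out$de_call <- "null"
  }
  out$group <- classify_group(out$de_call, out$h3ac_common)
  out$consistency <- consistency_score(out)
  class(out) <- c("tss_profile", "data.frame")
  out
}

#' Promoter-architecture group of a regulated gene
#'
#' Regulated genes (DE call `up` or `down`) are split on the one hard
#' decider: presence of a common H3Ac peak in the annotated promoter.
#' With promoter H3Ac the gene is group `"2"` (broad, CpG-rich,
#' TATA-less architecture); without it, group `"1"` (sharp, CpG-poor,
#' TATA-driven architecture). Non-regulated genes are `"unassigned"`.
#' CpG, TATA and Sp1 are reported as consistency diagnostics, not
#' deciders — a TATA-containing, CpG-poor promoter still lands in group 2
#' when it carries a common H3Ac peak.
#'
#' @param de_call Character vector (`up`/`down`/`null`) or a `tss_profile`.
#' @param h3ac_common Logical vector (ignored when a profile is given).
#' @return Character vector over `"1"`, `"2"`, `"unassigned"`.
#' @export
classify_group <- function(de_call, h3ac_common = NULL) {
  if (is.data.frame(de_call)) {
    h3ac_common <- de_call$h3ac_common
    de_call <- de_call$de_call
  }
  ifelse(de_call %in% c("up", "down"),
         ifelse(h3ac_common, "2", "1"), "unassigned")
}

#' Fraction of secondary features matching the group's modal pattern
#'
#' Group 1 modal pattern: no CpG island, TATA present, no Sp1.
#' Group 2 modal pattern: CpG island, no TATA, Sp1 present.
#' `NA` for unassigned profiles.
#'
#' @param profiles A `tss_profile`.
#' @return Numeric vector in `[0, 1]`.
#' @export
consistency_score <- function(profiles) {
  with(profiles, ifelse(
    group == "1",
    ((!cpg) + tata + (sp1_status == "none")) / 3,
    ifelse(group == "2",
           (cpg + (!tata) + (sp1_status != "none")) / 3,
           NA_real_)))
}

#' Gene-level roll-up of per-TSS groups
#'
#' @param profiles A `tss_profile`.
#' @return data.frame gene_id, group (`"1"`, `"2"`, `"mixed"` or
#'   `"unassigned"`).
#' @export
gene_group_rollup <- function(profiles) {
  by_gene <- split(profiles$group, profiles$gene_id)
  g <- vapply(by_gene, function(gr) {
    gr <- setdiff(unique(gr), "unassigned")
    if (length(gr) == 0L) "unassigned" else
      if (length(gr) == 1L) gr else "mixed"
  }, "")
  data.frame(gene_id = names(g), group = unname(g), stringsAsFactors = FALSE)
}

#' Cross-mark co-localization summary
#'
#' For each class of mark A's peaks (all -LPS, all +LPS, common members,
#' unique -LPS, unique +LPS): the count and fraction overlapping any B
#' peak of the matching condition (the common class is tested against the
#' union of B), and of the overlapping ones, the fraction in promoters.
#'
#' @param a A `peak_comparison` for mark A.
#' @param b A `peak_comparison` for mark B, or a list with `minus`/`plus`
#'   `PeakSet`s.
#' @param promoters Promoter windows.
#' @return data.frame: class, n, n_overlap, frac_overlap, n_in_promoter,
#'   frac_in_promoter.
#' @export
colocalization_summary <- function(a, b, promoters) {
  b_minus <- .as_intervals(if (inherits(b, "peak_comparison")) b$minus else b$minus)
  b_plus <- .as_intervals(if (inherits(b, "peak_comparison")) b$plus else b$plus)
  b_union <- merge_intervals(rbind(b_minus, b_plus))
  a_common <- a$members[, c("seq_id", "start", "end")]
  classes <- list(
    minus_total = list(a$minus$intervals, b_minus),
    plus_total = list(a$plus$intervals, b_plus),
    common = list(a_common, b_union),
    unique_minus = list(a$unique_minus, b_minus),
    unique_plus = list(a$unique_plus, b_plus))
  rows <- lapply(names(classes), function(nm) {
    q <- classes[[nm]][[1]]; s <- classes[[nm]][[2]]
    ov <- .overlap_any(q, s)
    hit <- q[ov, , drop = FALSE]
    in_prom <- if (nrow(hit)) .overlap_any(hit, promoters) else logical(0)
    data.frame(class = nm, n = nrow(q), n_overlap = nrow(hit),
               frac_overlap = if (nrow(q)) nrow(hit) / nrow(q) else NA_real_,
               n_in_promoter = sum(in_prom),
               frac_in_promoter = if (nrow(hit)) mean(in_prom) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stimulus-unique intragenic peaks in genes with open promoters
#'
#' Qualifying peaks are +LPS-unique H3Ac peaks classified exon or intron
#' that do not overlap any CpG island. Of these, counts how many lie in a
#' host gene (a gene whose transcribed span they overlap) whose promoter
#' window overlaps a common H3Ac component.
#'
#' @param h3ac_cmp A `peak_comparison` for H3Ac.
#' @param tss A `tss_table`.
#' @param promoters Promoter windows.
#' @param cpg_islands CpG island intervals.
#' @return List with `n_qualifying`, `n_in_open_genes` and the qualifying
#'   peak table (`detail`).
#' @export
intragenic_unique_analysis <- function(h3ac_cmp, tss, promoters,
                                       cpg_islands) {
  up <- h3ac_cmp$unique_plus
  if (nrow(up) == 0L) {
    return(list(n_qualifying = 0L, n_in_open_genes = 0L,
                detail = .empty_intervals()))
  }
  cls <- classify_peaks(up, promoters, tss)
  isl <- merge_intervals(.as_intervals(cpg_islands))
  qual <- up[cls %in% c("exon", "intron") & !.overlap_any(up, isl), ,
             drop = FALSE]
  if (nrow(qual) == 0L) {
    return(list(n_qualifying = 0L, n_in_open_genes = 0L, detail = qual))
  }
  spans <- .gene_spans(tss)
  comp <- h3ac_cmp$components
  hull <- if (nrow(comp)) data.frame(
    seq_id = comp$seq_id,
    start = pmin(comp$extent_minus_start, comp$extent_plus_start),
    end = pmax(comp$extent_minus_end, comp$extent_plus_end),
    stringsAsFactors = FALSE) else .empty_intervals()
  open_gene <- vapply(seq_len(nrow(qual)), function(k) {
    host <- spans$gene_id[overlaps(spans, qual[rep(k, nrow(spans)), ])]
    if (length(host) == 0L) return(FALSE)
    pw <- promoters[promoters$gene_id %in% host, , drop = FALSE]
    nrow(pw) > 0L && any(.overlap_any(pw, hull))
  }, logical(1))
  qual$in_open_gene <- open_gene
  list(n_qualifying = nrow(qual), n_in_open_genes = sum(open_gene),
       detail = qual)
}
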