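#' Construct a table of transcription start sites
#'
#' One row per annotated TSS; a gene with alternative promoters contributes
#' several rows sharing its `gene_id`. `tss_pos` is the 0-based coordinate of
#' the TSS base itself. Exons, when supplied, are 0-based half-open and must
#' be consistent with the TSS: for `+` genes the TSS equals the smallest exon
#' start, for `-` genes the largest exon end minus one.
#'
#' @param gene_id Character vector.
#' @param seq_id Character vector of sequence names.
#' @param strand `"+"` or `"-"` per TSS.
#' @param tss_pos Integer vector of 0-based TSS positions.
#' @param exon_starts,exon_ends Optional lists of integer vectors
#'   (0-based half-open), one vector per TSS record.
#' @return A data.frame of class `tss_table` with a unique `tss_id` column
#'   and list-columns `exon_starts`, `exon_ends`.
#' @export
tss_table <- function(gene_id, seq_id, strand, tss_pos,
                      exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss_pos <- as.integer(tss_pos)
  if (any(is.na(tss_pos) | tss_pos < 0L)) stop("tss_pos must be >= 0")
  if (is.null(exon_starts)) exon_starts <- rep(list(integer(0)), n)
  if (is.null(exon_ends)) exon_ends <- rep(list(integer(0)), n)
  exon_starts <- lapply(exon_starts, as.integer)
  exon_ends <- lapply(exon_ends, as.integer)
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee)) stop("exon_starts/exon_ends length mismatch for ", gene_id[i])
    if (length(es)) {
      if (any(es >= ee)) stop("empty exon for ", gene_id[i])
      want <- if (strand[i] == "+") min(es) else max(ee) - 1L
      if (tss_pos[i] != want) {
        stop("TSS of ", gene_id[i], " (", tss_pos[i],
             ") inconsistent with exon structure (expected ", want, ")")
      }
    }
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    seq_id = as.character(seq_id),
                    strand = strand, tss_pos = tss_pos,
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  out$tss_id <- if (n == 0L) character(0) else
    make.unique(paste0(out$gene_id, "@", out$tss_pos), sep = "#")
  class(out) <- c("tss_table", "data.frame")
  out
}

#' Strand-aware promoter window around one TSS
#'
#' For a `+` gene the window is `[tss - upstream, tss + downstream)`;
#' for a `-` gene its mirror image around the TSS base,
#' `[tss - downstream + 1, tss + upstream + 1)`. The window is clamped to
#' `[0, seq_length)` when `seq_length` is given.
#'
#' @param tss_pos 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param upstream_bp,downstream_bp Non-negative window extents in bp
#'   (defaults 2000 and 1000, the standard promoter definition here).
#' @param seq_length Optional sequence length for clamping.
#' @param gene_id Used in error messages.
#' @return One-row interval data.frame.
#' @export
make_promoter_window <- function(tss_pos, strand, upstream_bp = 2000L,
                                 downstream_bp = 1000L, seq_length = NULL,
                                 gene_id = "?") {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  if (!is.null(seq_length) && (tss_pos < 0L || tss_pos >= seq_length)) {
    stop("TSS of gene ", gene_id, " at ", tss_pos,
         " lies outside its sequence [0, ", seq_length, ")")
  }
  if (strand == "+") {
    s <- tss_pos - upstream_bp; e <- tss_pos + downstream_bp
  } else if (strand == "-") {
    s <- tss_pos - downstream_bp + 1L; e <- tss_pos + upstream_bp + 1L
  } else stop("strand must be '+' or '-'")
  s <- max(0L, as.integer(s))
  if (!is.null(seq_length)) e <- min(as.integer(seq_length), as.integer(e))
  if (s >= e) stop("degenerate promoter window for gene ", gene_id)
  genomic_interval(NA_character_, s, e)[, c("start", "end")]
}

#' Promoter windows for every TSS of a table
#'
#' @param tss A `tss_table`.
#' @param upstream_bp,downstream_bp Window extents (bp).
#' @param seq_lengths Optional named integer vector of sequence lengths for
#'   clamping.
#' @return Interval data.frame with one row per TSS plus `gene_id`,
#'   `tss_id`, `strand`, `tss_pos` columns.
#' @export
promoter_windows <- function(tss, upstream_bp = 2000L, downstream_bp = 1000L,
                             seq_lengths = NULL) {
  if (nrow(tss) == 0L) {
    out <- .empty_intervals()
    out$gene_id <- out$tss_id <- out$strand <- character(0)
    out$tss_pos <- integer(0)
    return(out)
  }
  win <- lapply(seq_len(nrow(tss)), function(i) {
    L <- if (is.null(seq_lengths)) NULL else
      unname(seq_lengths[[tss$seq_id[i]]])
    make_promoter_window(tss$tss_pos[i], tss$strand[i], upstream_bp,
                         downstream_bp, L, tss$gene_id[i])
  })
  win <- do.call(rbind, win)
  data.frame(seq_id = tss$seq_id, start = win$start, end = win$end,
             gene_id = tss$gene_id, tss_id = tss$tss_id,
             strand = tss$strand, tss_pos = tss$tss_pos,
             stringsAsFactors = FALSE)
}

# all exons of a tss_table as one interval data.frame
.all_exons <- function(tss) {
  keep <- lengths(tss$exon_starts) > 0L
  if (!any(keep)) return(.empty_intervals())
  data.frame(
    seq_id = rep(tss$seq_id[keep], lengths(tss$exon_starts[keep])),
    start = unlist(tss$exon_starts[keep], use.names = FALSE),
    end = unlist(tss$exon_ends[keep], use.names = FALSE),
    stringsAsFactors = FALSE)
}

# transcribed span (min exon start to max exon end) per TSS record with exons
.gene_spans <- function(tss) {
  keep <- lengths(tss$exon_starts) > 0L
  if (!any(keep)) {
    out <- .empty_intervals(); out$gene_id <- character(0); return(out)
  }
  data.frame(
    seq_id = tss$seq_id[keep],
    start = vapply(tss$exon_starts[keep], min, integer(1)),
    end = vapply(tss$exon_ends[keep], max, integer(1)),
    gene_id = tss$gene_id[keep],
    stringsAsFactors = FALSE)
}
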