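# Readers and writers. All on-disk coordinates follow the native convention
# of each format: BED is 0-based half-open (used as-is), gene-model tables
# and GTF are 1-based and converted on load. Readers reject malformed
# records; the only silent-ish repairs are the documented self-merge of
# peaks and upper-casing of FASTA, both logged.

#' Read a BED3 file as a PeakSet
#'
#' Only the first three columns are interpreted; extra columns (scores etc.
#' emitted by peak callers) are ignored. Intervals are sorted and
#' self-merged; the number of merged records is logged.
#'
#' @param path File path.
#' @param mark,condition,label Passed to [peak_set()]; `label` defaults to
#'   the file path.
#' @return A `PeakSet`.
#' @export
read_bed <- function(path, mark = "H3Ac", condition = "minus_LPS",
                     label = path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(peak_set(.empty_intervals(), mark, condition, label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop(path, ": line ", which(lengths(fields) < 3L)[1],
         ": fewer than 3 tab-separated columns")
  }
  seq_id <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(path, ": line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(path, ": line ", bad[1], ": invalid interval (start >= end)")
  }
  peak_set(data.frame(seq_id = seq_id, start = start, end = end,
                      stringsAsFactors = FALSE),
           mark, condition, label)
}

#' Write intervals as BED3
#'
#' @param x A `PeakSet` or interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  df <- .as_intervals(x)
  write.table(df[, c("seq_id", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' `dialect = "table"` expects a TSV with header columns `gene_id`,
#' `seq_id`, `strand`, `tss_pos` (1-based), `exon_starts`, `exon_ends`
#' (comma-separated, 1-based inclusive). `dialect = "gtf_like"` parses the
#' `exon` features of a minimal GTF, grouping by `transcript_id` and taking
#' `gene_id` from the attributes; each transcript yields one TSS record.
#' Coordinates are converted to 0-based half-open.
#'
#' @param path File path.
#' @param dialect `"table"` or `"gtf_like"`.
#' @return A `tss_table`.
#' @export
read_gene_models <- function(path, dialect = c("table", "gtf_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "table") {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = "character", quote = "")
    need <- c("gene_id", "seq_id", "strand", "tss_pos", "exon_starts", "exon_ends")
    if (!all(need %in% names(tb))) {
      stop(path, ": missing column(s): ",
           paste(setdiff(need, names(tb)), collapse = ", "))
    }
    if (!all(tb$strand %in% c("+", "-"))) {
      stop(path, ": strand must be '+' or '-' (line ",
           which(!tb$strand %in% c("+", "-"))[1], ")")
    }
    split_ints <- function(s) {
      if (!nzchar(s) || s == ".") return(integer(0))
      as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    }
    tss_table(tb$gene_id, tb$seq_id, tb$strand,
              as.integer(tb$tss_pos) - 1L,
              lapply(tb$exon_starts, function(s) split_ints(s) - 1L),
              lapply(tb$exon_ends, split_ints))
  } else {
    gtf <- read.table(path, header = FALSE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(gtf) < 9L) stop(path, ": not GTF-like (need 9 columns)")
    gtf <- gtf[gtf[[3]] == "exon", , drop = FALSE]
    if (!all(gtf[[7]] %in% c("+", "-"))) stop(path, ": strand must be '+' or '-'")
    attr_val <- function(a, key) {
      m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))
      vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
    }
    gid <- attr_val(gtf[[9]], "gene_id")
    tid <- attr_val(gtf[[9]], "transcript_id")
    if (anyNA(gid) || anyNA(tid)) stop(path, ": missing gene_id/transcript_id attribute")
    by_tx <- split(seq_len(nrow(gtf)), tid)
    recs <- lapply(by_tx, function(idx) {
      es <- as.integer(gtf[idx, 4]) - 1L   # 1-based -> 0-based
      ee <- as.integer(gtf[idx, 5])        # inclusive -> half-open
      strand <- gtf[idx[1], 7]
      list(gene_id = gid[idx[1]], seq_id = gtf[idx[1], 1], strand = strand,
           tss = if (strand == "+") min(es) else max(ee) - 1L,
           es = sort(es), ee = ee[order(es)])
    })
    tss_table(vapply(recs, `[[`, "", "gene_id"),
              vapply(recs, `[[`, "", "seq_id"),
              vapply(recs, `[[`, "", "strand"),
              vapply(recs, function(r) r$tss, integer(1)),
              lapply(recs, `[[`, "es"), lapply(recs, `[[`, "ee"))
  }
}

#' Write gene models in the tabular dialect
#'
#' Inverse of `read_gene_models(dialect = "table")`; coordinates are written
#' 1-based.
#'
#' @param tss A `tss_table`.
#' @param path Output path.
#' @export
write_gene_models <- function(tss, path) {
  fmt <- function(v) vapply(v, function(x) {
    if (length(x) == 0L) "." else paste(x, collapse = ",")
  }, "")
  out <- data.frame(gene_id = tss$gene_id, seq_id = tss$seq_id,
                    strand = tss$strand, tss_pos = tss$tss_pos + 1L,
                    exon_starts = fmt(lapply(tss$exon_starts, function(x) x + 1L)),
                    exon_ends = fmt(tss$exon_ends),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix with its sample sheet
#'
#' The expression file is a TSV with a `gene_id` column and one column per
#' sample. The sample sheet is a TSV with columns `sample` and `condition`
#' (`minus_LPS`/`plus_LPS`). Rows with missing values are dropped with a
#' logged count; duplicated gene ids are an error.
#'
#' @param path Expression TSV path.
#' @param samples_path Sample-sheet TSV path.
#' @param linear If `TRUE`, values are linear-scale and log2-transformed on
#'   load (values <= 0 are then an error).
#' @return An object of class `ExpressionMatrix`: list with `values`
#'   (gene x sample matrix, log2 scale) and `condition` (named by sample).
#' @export
read_expression <- function(path, samples_path, linear = FALSE) {
  tb <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tb)) stop(path, ": missing gene_id column")
  if (anyDuplicated(tb$gene_id)) {
    stop(path, ": duplicated gene_id (ambiguous aggregation): ",
         tb$gene_id[duplicated(tb$gene_id)][1])
  }
  m <- as.matrix(tb[, setdiff(names(tb), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tb$gene_id
  drop <- rowSums(is.na(m)) > 0L
  if (any(drop)) {
    message("read_expression: dropped ", sum(drop), " row(s) with missing values")
    m <- m[!drop, , drop = FALSE]
  }
  if (linear) {
    if (any(m <= 0)) stop(path, ": non-positive values cannot be log2-transformed")
    m <- log2(m)
  }
  sh <- read.table(samples_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(sh))) {
    stop(samples_path, ": need columns sample, condition")
  }
  if (!all(colnames(m) %in% sh$sample)) {
    stop("sample sheet missing sample(s): ",
         paste(setdiff(colnames(m), sh$sample), collapse = ", "))
  }
  cond <- setNames(sh$condition, sh$sample)[colnames(m)]
  if (!all(cond %in% CONDITIONS)) stop("condition must be one of: ",
                                       paste(CONDITIONS, collapse = ", "))
  if (any(table(factor(cond, CONDITIONS)) < 2L)) {
    stop("each condition needs >= 2 samples for a t-test")
  }
  expression_matrix(m, cond)
}

#' Construct an ExpressionMatrix in memory
#'
#' @param values Numeric gene x sample matrix, log2 scale, with rownames
#'   (gene ids) and colnames (sample labels).
#' @param condition Character vector (per sample) of conditions.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), ncol(values) == length(condition),
            !is.null(rownames(values)))
  structure(list(values = values,
                 condition = setNames(as.character(condition), colnames(values))),
            class = "ExpressionMatrix")
}

#' Read a FASTA file
#'
#' Sequences are normalized to uppercase on load; names are truncated at
#' the first whitespace.
#'
#' @param path FASTA path.
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path)   # DNAStringSet stores bases upper-cased
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences as FASTA
#' @param x Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path)
  invisible(path)
}

# columns of the per-TSS feature table (mirrors the integrated summary
# tables: one row per annotated TSS of a regulated or profiled gene)
.FEATURE_COLS <- c("gene_id", "tss_id", "seq_id", "strand", "tss_pos",
                   "p_value", "fold_change", "de_call", "h3ac_common",
                   "extension", "s5p_status", "sp1_status", "cpg", "tata",
                   "group", "consistency")

#' Write / read the per-TSS feature table
#'
#' Tab-separated with header; floats are printed with 4 significant digits;
#' logicals as YES/NO.
#'
#' @param profiles A `tss_profile` data.frame (see [build_profiles()]).
#' @param path File path.
#' @export
write_feature_table <- function(profiles, path) {
  out <- profiles[, .FEATURE_COLS]
  for (cc in c("p_value", "fold_change", "consistency")) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                        formatC(signif(out[[cc]], 4), format = "g", digits = 4))
  }
  for (cc in c("h3ac_common", "cpg", "tata")) {
    out[[cc]] <- ifelse(out[[cc]], "YES", "NO")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE,
                   colClasses = c(tss_pos = "integer"))
  for (cc in c("h3ac_common", "cpg", "tata")) tb[[cc]] <- tb[[cc]] == "YES"
  for (cc in c("p_value", "fold_change", "consistency")) {
    tb[[cc]] <- suppressWarnings(as.numeric(tb[[cc]]))
  }
  tb$group <- as.character(tb$group)
  class(tb) <- c("tss_profile", "data.frame")
  tb
}
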