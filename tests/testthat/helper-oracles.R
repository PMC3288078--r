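# Independent brute-force oracles used throughout the suite. All of them
# work per base or per pair, never via the package's interval algebra.

# set of 0-based base positions covered by one interval row
.bases <- function(row) {
  paste0(row$seq_id, ":", seq.int(row$start, row$end - 1L))
}

oracle_overlap <- function(a, b) {
  length(intersect(.bases(a), .bases(b))) > 0L
}

# quadratic merge: repeatedly fuse any two rows sharing a base
oracle_merge <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) df[i, , drop = FALSE])
  changed <- TRUE
  while (changed && length(rows) > 1L) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i < j && oracle_overlap(rows[[i]], rows[[j]])) {
          rows[[i]]$start <- min(rows[[i]]$start, rows[[j]]$start)
          rows[[i]]$end <- max(rows[[i]]$end, rows[[j]]$end)
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of the bipartite cross-condition overlap graph,
# by union-find over all pairs (quadratic)
oracle_components <- function(minus, plus) {
  nm <- nrow(minus); np <- nrow(plus)
  parent <- seq_len(nm + np)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[ry] <<- rx
  }
  linked_m <- logical(nm); linked_p <- logical(np)
  for (i in seq_len(nm)) {
    for (j in seq_len(np)) {
      if (oracle_overlap(minus[i, ], plus[j, ])) {
        union_(i, nm + j)
        linked_m[i] <- TRUE; linked_p[j] <- TRUE
      }
    }
  }
  comp_m <- ifelse(linked_m, vapply(seq_len(nm), find, 1L), NA_integer_)
  comp_p <- ifelse(linked_p, vapply(seq_len(np), function(j) find(nm + j), 1L),
                   NA_integer_)
  list(comp_minus = comp_m, comp_plus = comp_p,
       n_components = length(unique(stats::na.omit(c(comp_m, comp_p)))))
}

# per-base feature map classification with promoter > exon > intron
oracle_classify <- function(peak, promoters, exons, spans) {
  hit <- function(feat) {
    nrow(feat) > 0L && any(vapply(seq_len(nrow(feat)), function(i) {
      oracle_overlap(peak, feat[i, ])
    }, logical(1)))
  }
  if (hit(promoters)) "promoter" else if (hit(exons)) "exon" else
    if (hit(spans)) "intron" else "intergenic"
}

# per-base genome composition loop
oracle_composition <- function(seq_lengths, promoters, exons, spans) {
  counts <- c(promoter = 0, exon = 0, intron = 0, intergenic = 0)
  memb <- function(feat, s, pos) {
    any(feat$seq_id == s & feat$start <= pos & pos < feat$end)
  }
  for (s in names(seq_lengths)) {
    for (pos in 0:(seq_lengths[[s]] - 1L)) {
      cls <- if (memb(promoters, s, pos)) "promoter" else
        if (memb(exons, s, pos)) "exon" else
          if (memb(spans, s, pos)) "intron" else "intergenic"
      counts[cls] <- counts[cls] + 1
    }
  }
  counts / sum(counts)
}

random_intervals <- function(n, n_seq = 3, max_pos = 900, max_len = 60) {
  s <- as.integer(floor(runif(n, 0, max_pos)))
  genomic_interval(paste0("chr", sample.int(n_seq, n, replace = TRUE)),
                   s, s + as.integer(ceiling(runif(n, 1, max_len))))
}

random_peakset <- function(n, mark = "H3Ac", condition = "minus_LPS", ...) {
  suppressMessages(peak_set(random_intervals(n, ...), mark, condition))
}

# direct evaluation of the similarity formula, independent of the package
# scanner: per-offset loop over substrings
oracle_scan_max <- function(freqs, seq) {
  W <- ncol(freqs)
  info <- apply(freqs, 2, function(f) {
    t <- f * log(4 * f); t[f == 0] <- 0; sum(t) / log(4)
  })
  denom <- sum(info * apply(freqs, 2, max))
  score1 <- function(s) {
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    f <- ifelse(is.na(idx), 0, freqs[cbind(idx, seq_len(W))])
    sum(info * f) / denom
  }
  n <- nchar(seq) - W + 1L
  if (n < 1L) return(numeric(0))
  max(vapply(seq_len(n), function(k) score1(substr(seq, k, k + W - 1L)),
             numeric(1)))
}

# small three-gene model used by several annotation tests
toy_genes <- function() {
  tss_table(
    gene_id = c("gA", "gB"),
    seq_id = c("chr1", "chr1"),
    strand = c("+", "-"),
    tss_pos = c(5000L, 20000L),
    exon_starts = list(c(5000L, 6500L), c(18000L, 19500L)),
    exon_ends = list(c(5800L, 7200L), c(18900L, 20001L)))
}

.sort_df <- function(df) {
  df <- df[order(df$seq_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_df <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

fixture_profiles <- function() {
  read.table(system.file("extdata", "macrophage_lps_regulated_promoters.tsv",
                         package = "chromintegrate"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
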