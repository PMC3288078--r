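# Matrix-similarity TATA-box scanning in core promoters, in the style of
# consensus-driven matrix scanners. The similarity of a W-mer s to a
# position frequency matrix f with per-position conservation weights Ci is
#
#   sim(s) = sum_j Ci(j) f_j(s_j) / sum_j Ci(j) max_b f_j(b),
#
# with Ci(j) = (1/ln 4) sum_b f_j(b) ln(4 f_j(b)) (0 ln 0 = 0), so that
# sim = 1 exactly for a sequence picking an argmax base everywhere. The
# default TATA matrices are built from the two classical consensus strings
# gTATAAAa and ctATAAAA (case encodes conservation); user-supplied matrices
# can replace them.

.BASES <- c("A", "C", "G", "T")

#' Per-position conservation weights of a frequency matrix
#'
#' `Ci(j) = (1/ln 4) * sum_b f_j(b) * ln(4 f_j(b))`, with `0*ln(0) = 0`;
#' values lie in `[0, 1]` (0 = uniform, 1 = fully conserved).
#'
#' @param freqs 4 x W matrix with rows A, C, G, T; columns sum to 1.
#' @return Numeric vector of length W.
#' @export
info_weights <- function(freqs) {
  apply(freqs, 2, function(f) {
    t <- f * log(4 * f)
    t[f == 0] <- 0
    sum(t) / log(4)
  })
}

#' Build a position weight matrix
#'
#' @param freqs 4 x W numeric matrix, rows named A, C, G, T, columns
#'   summing to 1.
#' @param name Matrix name.
#' @return An object of class `pwm`: list with `name`, `freqs`, `info`
#'   (conservation weights) and `width`.
#' @export
pwm <- function(freqs, name = "matrix") {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L) stop("need 4 rows (A, C, G, T)")
  rownames(freqs) <- .BASES
  if (any(freqs < 0) || any(abs(colSums(freqs) - 1) > 1e-9)) {
    stop("per-position frequencies must be >= 0 and sum to 1")
  }
  structure(list(name = name, freqs = freqs, info = info_weights(freqs),
                 width = ncol(freqs)),
            class = "pwm")
}

#' Build a matrix from a case-encoded consensus string
#'
#' Uppercase positions are treated as strongly conserved (dominant base
#' frequency 0.85, others 0.05); lowercase as weakly conserved (0.40 vs
#' 0.20 each).
#'
#' @param consensus String over `A,C,G,T,a,c,g,t`.
#' @param name Matrix name (defaults to the consensus).
#' @return A `pwm`.
#' @export
matrix_from_consensus <- function(consensus, name = consensus) {
  ch <- strsplit(consensus, "")[[1]]
  if (!all(ch %in% c(.BASES, tolower(.BASES)))) {
    stop("consensus must be over A,C,G,T (case encodes conservation)")
  }
  W <- length(ch)
  freqs <- matrix(0, 4, W, dimnames = list(.BASES, NULL))
  for (j in seq_len(W)) {
    strong <- ch[j] %in% .BASES
    dom <- toupper(ch[j])
    freqs[, j] <- if (strong) 0.05 else 0.20
    freqs[dom, j] <- if (strong) 0.85 else 0.40
  }
  pwm(freqs, name)
}

#' Default TATA-box matrices
#'
#' Two classical TATA consensus matrices, built with
#' [matrix_from_consensus()]: `VTATA.01` (`gTATAAAa`) and `VTATA.02`
#' (`ctATAAAA`).
#'
#' @return List of `pwm` objects.
#' @export
default_tata_matrices <- function() {
  list(matrix_from_consensus("gTATAAAa", "VTATA.01"),
       matrix_from_consensus("ctATAAAA", "VTATA.02"))
}

#' Matrix similarity of one W-mer
#'
#' Conservation-weighted per-position frequency score in `[0, 1]`; equals 1
#' iff the sequence picks an argmax base at every position with positive
#' weight. Positions with `N` contribute 0.
#'
#' @param pwm A `pwm`.
#' @param s Character string of length `pwm$width` over A,C,G,T,N.
#' @return Similarity in `[0, 1]`.
#' @export
matrix_similarity <- function(pwm, s) {
  ch <- strsplit(toupper(s), "")[[1]]
  if (length(ch) != pwm$width) {
    stop("sequence length ", length(ch), " != matrix width ", pwm$width)
  }
  idx <- match(ch, .BASES)
  f <- ifelse(is.na(idx), 0,
              pwm$freqs[cbind(idx, seq_len(pwm$width))])
  denom <- sum(pwm$info * apply(pwm$freqs, 2, max))
  sum(pwm$info * f) / denom
}

# Fast scan of one matrix over all offsets of a sequence string.
# Returns numeric vector of per-offset similarities (length nchar - W + 1).
.scan_scores <- function(pwm, seq) {
  ch <- match(strsplit(toupper(seq), "")[[1]], .BASES)
  W <- pwm$width
  n <- length(ch) - W + 1L
  if (n < 1L) return(numeric(0))
  wf <- pwm$freqs * rep(pwm$info, each = 4L)   # Ci(j) * f_j(b)
  denom <- sum(pwm$info * apply(pwm$freqs, 2, max))
  scores <- numeric(n)
  for (j in seq_len(W)) {
    b <- ch[j:(j + n - 1L)]
    contrib <- ifelse(is.na(b), 0, wf[cbind(b, j)])
    scores <- scores + contrib
  }
  scores / denom
}

#' The argmax sequence of a matrix
#' @param pwm A `pwm`.
#' @return Character string picking the highest-frequency base everywhere.
#' @export
consensus_sequence <- function(pwm) {
  paste(.BASES[apply(pwm$freqs, 2, which.max)], collapse = "")
}

#' Scan core promoters for TATA boxes
#'
#' Extracts the sense-strand sequence of the `-window_up/+window_down`
#' window around each TSS (reverse complement for `-` genes), slides each
#' matrix over all offsets, and reports hits with similarity at or above
#' the cutoff. Scanning is sense-strand only by default, since the TATA box
#' is an orientation-dependent core-promoter element; `both_strands = TRUE`
#' also scans the reverse complement.
#'
#' @param tss A `tss_table`.
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param window_up,window_down Core-promoter window extents (defaults 150
#'   and 50 bp).
#' @param cutoff Matrix-similarity cutoff (default 0.9).
#' @param matrices List of `pwm` (default [default_tata_matrices()]).
#' @param both_strands Also scan the antisense strand.
#' @return List with `tata` (named logical per `tss_id`) and `hits` (data
#'   frame: tss_id, gene_id, matrix, offset (window-relative, sense
#'   orientation), strand_of_scan, similarity, match), hits sorted by
#'   decreasing similarity within TSS.
#' @export
scan_tata <- function(tss, genome, window_up = 150L, window_down = 50L,
                      cutoff = 0.9, matrices = default_tata_matrices(),
                      both_strands = FALSE) {
  seqs <- if (is.character(genome)) genome else
    setNames(as.character(genome), names(genome))
  hits <- list()
  tata <- setNames(logical(nrow(tss)), tss$tss_id)
  for (i in seq_len(nrow(tss))) {
    sid <- tss$seq_id[i]
    if (!sid %in% names(seqs)) stop("no sequence for ", sid)
    L <- nchar(seqs[[sid]])
    t0 <- tss$tss_pos[i]
    if (tss$strand[i] == "+") {
      s0 <- t0 - window_up; e0 <- t0 + window_down
    } else {
      s0 <- t0 - window_down + 1L; e0 <- t0 + window_up + 1L
    }
    cs0 <- max(0L, s0); ce0 <- min(L, e0)
    if (cs0 > s0 || ce0 < e0) {
      warning("core window of ", tss$gene_id[i], " clamped to sequence bounds")
    }
    if (ce0 - cs0 < 1L) next
    win <- substr(seqs[[sid]], cs0 + 1L, ce0)
    if (tss$strand[i] == "-") {
      win <- as.character(reverseComplement(DNAStringSet(win)))
    }
    strands <- if (both_strands) c("sense", "antisense") else "sense"
    for (strand_of_scan in strands) {
      sq <- if (strand_of_scan == "sense") win else
        as.character(reverseComplement(DNAStringSet(win)))
      for (m in matrices) {
        sc <- .scan_scores(m, sq)
        hit <- which(sc >= cutoff)
        if (length(hit)) {
          hits[[length(hits) + 1L]] <- data.frame(
            tss_id = tss$tss_id[i], gene_id = tss$gene_id[i],
            matrix = m$name, offset = hit - 1L,
            strand_of_scan = strand_of_scan, similarity = sc[hit],
            match = substring(sq, hit, hit + m$width - 1L),
            stringsAsFactors = FALSE)
          tata[i] <- TRUE
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(tss_id = character(0), gene_id = character(0),
               matrix = character(0), offset = integer(0),
               strand_of_scan = character(0), similarity = numeric(0),
               match = character(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$tss_id, -hits$similarity), , drop = FALSE]
  rownames(hits) <- NULL
  list(tata = tata, hits = hits)
}

#' Read / write matrices in a simple text format
#'
#' One block per matrix: a `>name` line followed by one row per position
#' with four whitespace-separated frequencies (A C G T order).
#'
#' @param path File path.
#' @return List of `pwm` objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop(path, ": no '>name' header lines")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    rows <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    vals <- t(vapply(strsplit(rows, "\\s+"),
                     function(x) as.numeric(x[1:4]), numeric(4)))
    out[[k]] <- pwm(t(vals), sub("^>\\s*", "", lines[heads[k]]))
  }
  out
}

#' @rdname read_pwms
#' @param pwms List of `pwm` objects to write.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    writeLines(paste0(">", m$name), con)
    write.table(format(t(m$freqs), digits = 10), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
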