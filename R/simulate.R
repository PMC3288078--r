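# Synthetic two-condition chromatin + expression worlds with planted
# ground truth. Genes are laid out in well-separated slots so planted
# features cannot collide and every planted structure is re-detectable by
# the downstream stages in the noiseless limit.

#' Simulation configuration
#'
#' Defaults encode the stimulated-macrophage world the pipeline targets:
#' 4 replicates per condition, a 2-fold widening of common acetylation
#' islands upon stimulation, a peak-class mix dominated by common peaks,
#' and regulated genes split between the two promoter architectures
#' (group 1: TATA box, no promoter H3Ac, CpG-poor; group 2: promoter
#' H3Ac + CpG island, TATA-less).
#'
#' @param seed RNG seed (integer).
#' @param n_sequences Number of chromosomes to emit.
#' @param n_genes Total genes.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes.
#' @param frac_group1 Fraction of regulated genes with group-1
#'   architecture (the rest are group 2; the two fractions sum to 1).
#' @param fc_up,fc_down Planted linear fold changes (>= 1).
#' @param replicate_sd Log2-scale replicate noise SD.
#' @param n_replicates Replicates per condition.
#' @param mean_peak_len_minus Mean unstimulated H3Ac peak length (bp);
#'   lengths are drawn uniformly within +/-25%.
#' @param widen_factor Common-peak length multiplier upon stimulation
#'   (default 2, the observed approximate doubling).
#' @param frac_common,frac_unique_minus,frac_unique_plus Peak-class mix
#'   (must sum to 1); unique-peak counts are derived from the planted
#'   common count via these fractions.
#' @param extension_direction_mix Named probabilities over
#'   `upstream`/`downstream`/`both`/`none` for widened common peaks.
#' @param bg_h3ac Probability that an unregulated gene carries a common
#'   promoter H3Ac peak (background architecture mix).
#' @param n_intragenic_open,n_intragenic_closed Numbers of +LPS-unique
#'   intragenic H3Ac peaks planted in genes with / without an open
#'   (common-peak) promoter.
#' @param tata_offset Motif start relative to the TSS for planted TATA
#'   boxes (default -30, inside the -150/+50 core window).
#' @param cpg_island_len Planted island length (bp).
#' @param upstream_bp,downstream_bp Promoter window extents.
#' @param gene_length,n_exons Gene geometry (3 exons from a fixed
#'   template).
#' @param seq_length Optional per-sequence length override; must be at
#'   least the computed minimum.
#' @param tata_cutoff Similarity cutoff used when scrubbing background
#'   TATA-like 8-mers from non-TATA core promoters.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_sequences = 1L, n_genes = 60L,
                       n_up = 20L, n_down = 5L, frac_group1 = 0.5,
                       fc_up = 4, fc_down = 4, replicate_sd = 0.25,
                       n_replicates = 4L, mean_peak_len_minus = 1000L,
                       widen_factor = 2,
                       frac_common = 0.8, frac_unique_minus = 0.15,
                       frac_unique_plus = 0.05,
                       extension_direction_mix = c(upstream = 0.3,
                                                   downstream = 0.3,
                                                   both = 0.3, none = 0.1),
                       bg_h3ac = 0.7,
                       n_intragenic_open = 7L, n_intragenic_closed = 3L,
                       tata_offset = -30L, cpg_island_len = 600L,
                       upstream_bp = 2000L, downstream_bp = 1000L,
                       gene_length = 4000L, n_exons = 3L,
                       seq_length = NULL, tata_cutoff = 0.9) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$extension_direction_mix) - 1) > 1e-9 ||
      !all(names(cfg$extension_direction_mix) %in% EXTENSIONS)) {
    stop("extension_direction_mix must be named over ",
         paste(EXTENSIONS, collapse = "/"), " and sum to 1")
  }
  if (abs(frac_common + frac_unique_minus + frac_unique_plus - 1) > 1e-9) {
    stop("frac_common + frac_unique_minus + frac_unique_plus must be 1")
  }
  if (frac_common <= 0) stop("frac_common must be > 0")
  if (frac_group1 < 0 || frac_group1 > 1) stop("frac_group1 must be in [0,1]")
  if (n_up + n_down > n_genes) stop("more regulated genes than genes")
  if (fc_up < 1 || fc_down < 1) stop("planted fold changes must be >= 1")
  # geometry: maximum one-sided reach of a widened peak from its TSS
  lmax <- ceiling(1.25 * mean_peak_len_minus)
  cfg$max_reach <- ceiling(lmax / 2 + (widen_factor - 1) * lmax)
  cfg$slot <- 4L * as.integer(upstream_bp + downstream_bp + gene_length +
                              cfg$max_reach + 200L)
  if ((n_intragenic_open + n_intragenic_closed) > 0L &&
      0.4 * gene_length <= downstream_bp + 200L) {
    stop("config error: gene_length too short to host intragenic unique ",
         "peaks outside the promoter window")
  }
  if (1500 + 1.25 * mean_peak_len_minus * (1 + widen_factor) >= cfg$slot / 4) {
    stop("config error: peaks too long for the free zone of one gene slot")
  }
  n_per_seq <- ceiling(n_genes / n_sequences)
  min_len <- n_per_seq * cfg$slot
  if (is.null(seq_length)) {
    cfg$seq_length <- min_len
  } else if (seq_length < min_len) {
    stop("config error: seq_length ", seq_length, " cannot fit ", n_per_seq,
         " gene slot(s) of ", cfg$slot, " bp")
  }
  cfg$n_per_seq <- n_per_seq
  class(cfg) <- "sim_config"
  cfg
}

.draw_len <- function(n, mean_len) {
  as.integer(round(runif(n, 0.75, 1.25) * mean_len))
}

#' Simulate a synthetic chromatin + expression data set
#'
#' Generates a genome, gene models, CpG islands, per-mark per-condition
#' peak tracks, and a replicated log2 expression matrix, with full ground
#' truth. When `outdir` is given every piece is also written in the
#' package's on-disk formats (FASTA, tabular gene models, BED, TSV).
#' Identical configurations produce byte-identical outputs.
#'
#' Planting rules: group-2 regulated genes get a promoter CpG island and a
#' common H3Ac peak whose +LPS extent is the -LPS extent widened by
#' `widen_factor` in a direction drawn from `extension_direction_mix`
#' (always containing the -LPS interval), plus S5P RNAPII occupancy in
#' both conditions; group-1 regulated genes get a TATA consensus written
#' at `tata_offset` in the core promoter, no promoter H3Ac, no island.
#' Unregulated genes draw their architecture from a background mix.
#' Core-promoter windows of all non-TATA genes are scrubbed of chance
#' TATA-like 8-mers so motif ground truth is exact.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @return A `chromsim` list: `tss`, `genome`, `cpg`, `peaks`
#'   (`$h3ac$minus` etc. as `PeakSet`s), `expr`, `truth` (`$genes`,
#'   `$peaks`, `$intragenic`), `config`, and `paths` when written.
#' @export
simulate_chromatin <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- cfg$n_genes
  gene_id <- sprintf("gene%03d", seq_len(n))
  seq_of <- sprintf("chr%d", ((seq_len(n) - 1L) %/% cfg$n_per_seq) + 1L)
  slot_in_seq <- (seq_len(n) - 1L) %% cfg$n_per_seq
  tss_pos <- as.integer(slot_in_seq * cfg$slot + cfg$slot %/% 2L)
  strand <- rep(c("+", "-"), length.out = n)

  # --- regulation and architecture assignment -------------------------
  regulation <- rep("null", n)
  if (cfg$n_up > 0L) regulation[seq_len(cfg$n_up)] <- "up"
  if (cfg$n_down > 0L) {
    regulation[cfg$n_up + seq_len(cfg$n_down)] <- "down"
  }
  reg_idx <- which(regulation != "null")
  n_g1 <- round(cfg$frac_group1 * length(reg_idx))
  group <- rep(NA_character_, n)
  # interleave so both groups appear among up and down genes
  ord <- order(seq_along(reg_idx) %% 2L, seq_along(reg_idx))
  group[reg_idx] <- "2"
  if (n_g1 > 0L) group[reg_idx[ord][seq_len(n_g1)]] <- "1"

  null_idx <- which(regulation == "null")
  n_open <- cfg$n_intragenic_open; n_closed <- cfg$n_intragenic_closed
  if (n_open + n_closed > length(null_idx)) {
    stop("config error: not enough unregulated genes to host ",
         n_open + n_closed, " intragenic unique peaks")
  }
  host_open <- null_idx[seq_len(n_open)]
  host_closed <- null_idx[n_open + seq_len(n_closed)]
  rest_null <- setdiff(null_idx, c(host_open, host_closed))

  has_h3ac <- logical(n)
  has_h3ac[group %in% "2"] <- TRUE
  has_h3ac[host_open] <- TRUE
  has_h3ac[rest_null] <- runif(length(rest_null)) < cfg$bg_h3ac

  dirs <- names(cfg$extension_direction_mix)
  draw_dir <- function(k) {
    if (k == 0L) character(0) else
      sample(dirs, k, replace = TRUE, prob = cfg$extension_direction_mix)
  }
  extension <- rep("none", n)
  extension[has_h3ac] <- draw_dir(sum(has_h3ac))
  # open intragenic hosts must not be widened toward the gene body
  fix <- host_open[!extension[host_open] %in% c("none", "upstream")]
  extension[fix] <- "upstream"

  has_cpg <- logical(n)
  has_cpg[group %in% "2"] <- TRUE
  has_cpg[regulation == "null" & has_h3ac] <-
    runif(sum(regulation == "null" & has_h3ac)) < 0.7
  has_tata <- !is.na(group) & group == "1"

  s5p_status <- rep("none", n)
  s5p_status[group %in% "2"] <- "both"
  s5p_status[group %in% "1"] <-
    ifelse(runif(sum(group %in% "1")) < 0.4, "plus_only", "none")
  nh <- regulation == "null" & has_h3ac
  s5p_status[nh] <- ifelse(runif(sum(nh)) < 0.5, "both", "none")
  sp1_status <- rep("none", n)
  sp1_status[group %in% "2"] <-
    ifelse(runif(sum(group %in% "2")) < 0.3, "both", "none")
  sp1_status[nh] <- ifelse(runif(sum(nh)) < 0.3, "both", "none")

  # --- gene models (3-exon template, mirrored on the - strand) --------
  g <- cfg$gene_length
  tmpl <- rbind(c(0, 0.2), c(0.375, 0.575), c(0.8, 1)) * g
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- tss_pos[i]
    if (strand[i] == "+") {
      exon_starts[[i]] <- as.integer(t0 + tmpl[, 1])
      exon_ends[[i]] <- as.integer(t0 + tmpl[, 2])
    } else {
      exon_starts[[i]] <- rev(as.integer(t0 + 1L - tmpl[, 2]))
      exon_ends[[i]] <- rev(as.integer(t0 + 1L - tmpl[, 1]))
    }
  }
  tss <- tss_table(gene_id, seq_of, strand, tss_pos, exon_starts, exon_ends)

  # --- planted intervals ----------------------------------------------
  up_side_is_left <- strand == "+"
  cpg <- .empty_intervals()
  half_isl <- cfg$cpg_island_len %/% 2L
  for (i in which(has_cpg)) {
    cpg <- rbind(cpg, data.frame(seq_id = seq_of[i],
                                 start = tss_pos[i] - half_isl,
                                 end = tss_pos[i] - half_isl + cfg$cpg_island_len))
  }

  h3ac_minus <- .empty_intervals(); h3ac_plus <- .empty_intervals()
  peak_truth <- list()
  Lm <- .draw_len(n, cfg$mean_peak_len_minus)
  for (i in which(has_h3ac)) {
    t0 <- tss_pos[i]
    ms <- t0 - Lm[i] %/% 2L; me <- ms + Lm[i]
    E <- as.integer(round((cfg$widen_factor - 1) * Lm[i]))
    dir <- extension[i]
    e_up <- switch(dir, upstream = E, both = E %/% 2L, 0L)
    e_down <- switch(dir, downstream = E, both = E - E %/% 2L, 0L)
    e_left <- if (up_side_is_left[i]) e_up else e_down
    e_right <- if (up_side_is_left[i]) e_down else e_up
    ps <- ms - e_left; pe <- me + e_right
    h3ac_minus <- rbind(h3ac_minus, data.frame(seq_id = seq_of[i],
                                               start = ms, end = me))
    h3ac_plus <- rbind(h3ac_plus, data.frame(seq_id = seq_of[i],
                                             start = ps, end = pe))
    peak_truth[[length(peak_truth) + 1L]] <- data.frame(
      mark = "H3Ac", class = "common", gene_id = gene_id[i],
      direction = dir, seq_id = seq_of[i],
      minus_start = ms, minus_end = me, plus_start = ps, plus_end = pe,
      stringsAsFactors = FALSE)
  }

  # unique peak budget from the class mix
  n_common <- sum(has_h3ac)
  n_u_minus <- as.integer(round(n_common * cfg$frac_unique_minus /
                                  cfg$frac_common))
  n_u_plus_total <- as.integer(round(n_common * cfg$frac_unique_plus /
                                       cfg$frac_common))
  n_intra <- n_open + n_closed
  n_u_plus_inter <- max(0L, n_u_plus_total - n_intra)
  if (n_u_minus > n || n_u_plus_inter > n) {
    stop("config error: unique-peak budget exceeds slot capacity")
  }

  fz_start <- function(i) as.integer((slot_in_seq[i]) * cfg$slot + 1000L)
  add_unique <- function(df, idx, offset, mean_len) {
    L <- .draw_len(length(idx), mean_len)
    rbind(df, data.frame(seq_id = seq_of[idx],
                         start = fz_start(idx) + offset,
                         end = fz_start(idx) + offset + L,
                         stringsAsFactors = FALSE))
  }
  if (n_u_minus > 0L) {
    idx <- seq_len(n_u_minus)
    before <- nrow(h3ac_minus)
    h3ac_minus <- add_unique(h3ac_minus, idx, 0L, cfg$mean_peak_len_minus)
    peak_truth[[length(peak_truth) + 1L]] <- data.frame(
      mark = "H3Ac", class = "unique_minus", gene_id = NA_character_,
      direction = NA_character_, seq_id = seq_of[idx],
      minus_start = h3ac_minus$start[before + seq_along(idx)],
      minus_end = h3ac_minus$end[before + seq_along(idx)],
      plus_start = NA_integer_, plus_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (n_u_plus_inter > 0L) {
    idx <- seq_len(n_u_plus_inter)
    off <- as.integer(ceiling(1.25 * cfg$mean_peak_len_minus) + 500L)
    before <- nrow(h3ac_plus)
    h3ac_plus <- add_unique(h3ac_plus, idx, off,
                            cfg$mean_peak_len_minus * cfg$widen_factor)
    peak_truth[[length(peak_truth) + 1L]] <- data.frame(
      mark = "H3Ac", class = "unique_plus", gene_id = NA_character_,
      direction = NA_character_, seq_id = seq_of[idx],
      minus_start = NA_integer_, minus_end = NA_integer_,
      plus_start = h3ac_plus$start[before + seq_along(idx)],
      plus_end = h3ac_plus$end[before + seq_along(idx)],
      stringsAsFactors = FALSE)
  }
  # intragenic +LPS-unique peaks inside exon 2, clear of the promoter
  for (i in c(host_open, host_closed)) {
    t0 <- tss_pos[i]
    if (strand[i] == "+") {
      s <- as.integer(t0 + 0.4 * g); e <- as.integer(t0 + 0.5 * g)
    } else {
      s <- as.integer(t0 - 0.5 * g); e <- as.integer(t0 - 0.4 * g)
    }
    h3ac_plus <- rbind(h3ac_plus, data.frame(seq_id = seq_of[i],
                                             start = s, end = e))
    peak_truth[[length(peak_truth) + 1L]] <- data.frame(
      mark = "H3Ac", class = "unique_plus", gene_id = gene_id[i],
      direction = NA_character_, seq_id = seq_of[i],
      minus_start = NA_integer_, minus_end = NA_integer_,
      plus_start = s, plus_end = e, stringsAsFactors = FALSE)
  }

  s5p_minus <- .empty_intervals(); s5p_plus <- .empty_intervals()
  sp1_minus <- .empty_intervals(); sp1_plus <- .empty_intervals()
  for (i in seq_len(n)) {
    w <- data.frame(seq_id = seq_of[i], start = tss_pos[i] - 150L,
                    end = tss_pos[i] + 150L)
    if (s5p_status[i] %in% c("both", "minus_only")) s5p_minus <- rbind(s5p_minus, w)
    if (s5p_status[i] %in% c("both", "plus_only")) s5p_plus <- rbind(s5p_plus, w)
    w2 <- data.frame(seq_id = seq_of[i], start = tss_pos[i] - 500L,
                     end = tss_pos[i] - 200L)
    if (sp1_status[i] %in% c("both", "minus_only")) sp1_minus <- rbind(sp1_minus, w2)
    if (sp1_status[i] %in% c("both", "plus_only")) sp1_plus <- rbind(sp1_plus, w2)
  }

  # --- genome sequence -------------------------------------------------
  seq_names <- sprintf("chr%d", seq_len(cfg$n_sequences))
  genome_chars <- lapply(seq_names, function(s) {
    sample(.BASES, cfg$seq_length, replace = TRUE)
  })
  names(genome_chars) <- seq_names
  # cosmetic CG enrichment inside planted islands
  for (k in seq_len(nrow(cpg))) {
    rng <- (cpg$start[k] + 1L):cpg$end[k]
    genome_chars[[cpg$seq_id[k]]][rng] <-
      rep(c("C", "G"), length.out = length(rng))
  }
  # scrub chance TATA-like 8-mers from non-TATA core windows
  mats <- default_tata_matrices()
  core <- function(i) {
    t0 <- tss_pos[i]
    if (strand[i] == "+") c(t0 - 150L, t0 + 50L) else c(t0 - 49L, t0 + 151L)
  }
  for (i in which(!has_tata)) {
    rng <- core(i); sid <- seq_of[i]
    for (iter in 1:50) {
      win <- paste(genome_chars[[sid]][(rng[1] + 1L):rng[2]], collapse = "")
      if (strand[i] == "-") {
        win <- as.character(reverseComplement(DNAStringSet(win)))
      }
      sc <- pmax(.scan_scores(mats[[1]], win), .scan_scores(mats[[2]], win))
      bad <- which(sc >= cfg$tata_cutoff)
      if (length(bad) == 0L) break
      # redraw the offending 8-mers from C/G only (cannot look TATA-like)
      for (b in bad) {
        if (strand[i] == "+") {
          pos <- rng[1] + b - 1L + seq_len(8L)
        } else {
          pos <- rng[2] - b - 7L + seq_len(8L)
        }
        genome_chars[[sid]][pos] <- sample(c("C", "G"), 8L, replace = TRUE)
      }
    }
  }
  # plant the TATA consensus on the sense strand of group-1 genes
  for (i in which(has_tata)) {
    motif <- strsplit("GTATAAAA", "")[[1]]
    t0 <- tss_pos[i]
    if (strand[i] == "+") {
      pos <- t0 + cfg$tata_offset + seq_len(8L)   # 0-based start + 1..8
      genome_chars[[seq_of[i]]][pos] <- motif
    } else {
      pos <- t0 - cfg$tata_offset - 7L + seq_len(8L)
      genome_chars[[seq_of[i]]][pos] <- rev(chartr("ACGT", "TGCA", motif))
    }
  }
  genome <- DNAStringSet(vapply(genome_chars, paste, "", collapse = ""))
  names(genome) <- seq_names

  # --- expression matrix ----------------------------------------------
  nr <- cfg$n_replicates
  mu <- rnorm(n, 7, 1)
  shift <- ifelse(regulation == "up", log2(cfg$fc_up) / 2,
                  ifelse(regulation == "down", -log2(cfg$fc_down) / 2, 0))
  vals <- matrix(0, n, 2L * nr,
                 dimnames = list(gene_id,
                                 c(sprintf("M%d", seq_len(nr)),
                                   sprintf("P%d", seq_len(nr)))))
  for (j in seq_len(nr)) {
    vals[, j] <- rnorm(n, mu - shift, cfg$replicate_sd)
  }
  for (j in seq_len(nr)) {
    vals[, nr + j] <- rnorm(n, mu + shift, cfg$replicate_sd)
  }
  cond <- c(rep("minus_LPS", nr), rep("plus_LPS", nr))
  expr <- expression_matrix(vals, cond)

  mk <- function(df, mark, condition) {
    suppressMessages(peak_set(df, mark, condition, label = "simulated"))
  }
  truth_genes <- data.frame(
    gene_id = gene_id, seq_id = seq_of, strand = strand, tss_pos = tss_pos,
    regulation = regulation,
    group = ifelse(is.na(group), "unassigned", group),
    h3ac_common = has_h3ac, extension = extension, s5p_status = s5p_status,
    sp1_status = sp1_status, cpg = has_cpg, tata = has_tata,
    mu = mu, fc = ifelse(regulation == "up", cfg$fc_up,
                         ifelse(regulation == "down", cfg$fc_down, 1)),
    stringsAsFactors = FALSE)
  truth_peaks <- do.call(rbind, peak_truth)
  out <- structure(list(
    config = cfg, tss = tss, genome = genome, cpg = cpg,
    peaks = list(
      h3ac = list(minus = mk(h3ac_minus, "H3Ac", "minus_LPS"),
                  plus = mk(h3ac_plus, "H3Ac", "plus_LPS")),
      s5p = list(minus = mk(s5p_minus, "S5P_RNAPII", "minus_LPS"),
                 plus = mk(s5p_plus, "S5P_RNAPII", "plus_LPS")),
      sp1 = list(minus = mk(sp1_minus, "Sp1", "minus_LPS"),
                 plus = mk(sp1_plus, "Sp1", "plus_LPS"))),
    expr = expr,
    truth = list(genes = truth_genes, peaks = truth_peaks,
                 intragenic = list(n_qualifying = n_intra,
                                   n_in_open_genes = n_open))),
    class = "chromsim")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(genome, p("genome.fa"))
    write_gene_models(tss, p("genes.tsv"))
    write_bed(merge_intervals(cpg), p("cpg.bed"))
    for (m in names(out$peaks)) {
      write_bed(out$peaks[[m]]$minus, p(paste0(m, "_minus.bed")))
      write_bed(out$peaks[[m]]$plus, p(paste0(m, "_plus.bed")))
    }
    ex <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(ex, p("expr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample = colnames(vals), condition = cond),
                p("samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth_genes, p("truth_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth_peaks, p("truth_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- setNames(
      file.path(outdir, c("genome.fa", "genes.tsv", "cpg.bed", "expr.tsv",
                          "samples.tsv", "truth_genes.tsv", "truth_peaks.tsv")),
      c("genome", "genes", "cpg", "expr", "samples", "truth_genes",
        "truth_peaks"))
  }
  out
}
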