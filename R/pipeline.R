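# End-to-end orchestration: simulate or load inputs, compare peak tracks
# across conditions per mark, annotate, scan core promoters, call
# differential expression, and integrate into the per-TSS feature table
# plus summary reports.

.default_params <- function() {
  list(upstream_bp = 2000L, downstream_bp = 1000L,
       tata_window_up = 150L, tata_window_down = 50L, tata_cutoff = 0.9,
       fc_threshold = 2, alpha = 0.05, test = "student",
       min_extension_bp = 200L)
}

#' Run the full integration pipeline
#'
#' The configuration is a list (or a path to a JSON file) with either a
#' `simulate` block (arguments for [sim_config()]) or an `inputs` block
#' naming files: `h3ac_minus`, `h3ac_plus` (BEDs; likewise optional
#' `s5p_*`, `sp1_*`), `genes` (tabular gene models), `cpg` (BED),
#' `genome` (FASTA), `expr` + `samples` (TSVs). A `params` block can
#' override the defaults (promoter window, core-promoter window, cutoff,
#' fold-change threshold, alpha, minimum extension). All reports are
#' written to `outdir` and every number in them is recomputed from the
#' stage outputs; identical config and seed give identical files.
#'
#' @param config List or path to a JSON config file.
#' @param outdir Output directory (default from config, else required).
#' @return Invisibly, a list with all intermediate stage objects
#'   (`comparisons`, `profiles`, `de`, `summaries`, `coloc`, paths).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("missing key: outdir")
  params <- utils::modifyList(.default_params(), as.list(config$params))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    out <- df
    num <- vapply(out, is.numeric, logical(1)) &
      !vapply(out, is.integer, logical(1))
    out[num] <- lapply(out[num], function(x) {
      ifelse(is.na(x), "NA", formatC(signif(x, 4), format = "g", digits = 4))
    })
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, as.list(config$simulate))
    sim <- simulate_chromatin(cfg, file.path(outdir, "sim"))
    tss <- sim$tss; genome <- sim$genome; cpg <- sim$cpg
    tracks <- sim$peaks; expr <- sim$expr
  } else {
    inp <- config$inputs
    need <- c("h3ac_minus", "h3ac_plus", "genes", "cpg", "genome",
              "expr", "samples")
    miss <- setdiff(need, names(inp))
    if (length(miss)) stop("missing input key(s): ", paste(miss, collapse = ", "))
    sim <- NULL
    tss <- read_gene_models(inp$genes)
    genome <- read_fasta(inp$genome)
    cpg <- read_bed(inp$cpg)$intervals
    rd <- function(key, mark, cond) {
      if (is.null(inp[[key]])) NULL else read_bed(inp[[key]], mark, cond)
    }
    tracks <- list(
      h3ac = list(minus = rd("h3ac_minus", "H3Ac", "minus_LPS"),
                  plus = rd("h3ac_plus", "H3Ac", "plus_LPS")),
      s5p = list(minus = rd("s5p_minus", "S5P_RNAPII", "minus_LPS"),
                 plus = rd("s5p_plus", "S5P_RNAPII", "plus_LPS")),
      sp1 = list(minus = rd("sp1_minus", "Sp1", "minus_LPS"),
                 plus = rd("sp1_plus", "Sp1", "plus_LPS")))
    expr <- read_expression(inp$expr, inp$samples,
                            linear = isTRUE(config$linear))
  }
  seq_lengths <- setNames(Biostrings::width(genome), names(genome))
  prom <- promoter_windows(tss, params$upstream_bp, params$downstream_bp,
                           seq_lengths)
  log_lines <- c(
    paste0("chromintegrate ", as.character(packageVersion("chromintegrate"))),
    paste0("run at (deterministic content; timestamp omitted)"),
    paste0("params: ", jsonlite::toJSON(params, auto_unbox = TRUE)),
    paste0("genes: ", nrow(tss), " TSS records; genome: ",
           length(genome), " sequence(s)"))

  comparisons <- list()
  summaries <- list()
  for (m in c("h3ac", "s5p", "sp1")) {
    tr <- tracks[[m]]
    if (is.null(tr$minus) || is.null(tr$plus) ||
        (length(tr$minus) + length(tr$plus)) == 0L) next
    cmp <- compare_conditions(tr$minus, tr$plus)
    comparisons[[m]] <- cmp
    summaries[[m]] <- .mark_summary(cmp, prom, cpg)
    emit(summaries[[m]], paste0("summary_", m, ".tsv"))
    log_lines <- c(log_lines, paste0(
      m, ": ", length(tr$minus), " -LPS / ", length(tr$plus),
      " +LPS peaks -> ", cmp$counts[["n_components"]], " components, ",
      cmp$counts[["n_unique_minus"]], "/", cmp$counts[["n_unique_plus"]],
      " unique"))
  }
  if (is.null(comparisons$h3ac)) stop("missing input: H3Ac peak tracks")

  coloc <- NULL
  if (!is.null(comparisons$s5p)) {
    coloc <- colocalization_summary(comparisons$s5p, comparisons$h3ac, prom)
    emit(coloc, "coloc.tsv")
  }

  tata <- scan_tata(tss, genome, params$tata_window_up,
                    params$tata_window_down, params$tata_cutoff)
  emit(tata$hits, "tata_hits.tsv")
  de <- differential_expression(expr, params$fc_threshold, params$alpha,
                                params$test)
  emit(de, "de.tsv")
  des <- summarize_de(de)
  log_lines <- c(log_lines,
                 paste0("differential expression: ", des$n_up, " up, ",
                        des$n_down, " down of ", nrow(de), " genes"),
                 paste0("tata: ", sum(tata$tata), " of ", nrow(tss),
                        " TSS windows with a hit"))

  profiles <- build_profiles(
    tss, comparisons$h3ac, s5p = tracks$s5p, sp1 = tracks$sp1,
    cpg_islands = cpg, tata = tata, de = de,
    upstream_bp = params$upstream_bp, downstream_bp = params$downstream_bp,
    min_extension_bp = params$min_extension_bp, seq_lengths = seq_lengths)
  write_feature_table(profiles, file.path(outdir, "feature_table.tsv"))
  written <- c(written, file.path(outdir, "feature_table.tsv"))
  intra <- intragenic_unique_analysis(comparisons$h3ac, tss, prom, cpg)
  log_lines <- c(log_lines, paste0(
    "intragenic +LPS-unique H3Ac peaks off CpG: ", intra$n_qualifying,
    ", of which in open-promoter genes: ", intra$n_in_open_genes))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  ok <- TRUE
  invisible(list(tss = tss, promoters = prom, comparisons = comparisons,
                 summaries = summaries, coloc = coloc, tata = tata,
                 de = de, profiles = profiles, intragenic = intra,
                 sim = sim, params = params, outdir = outdir))
}
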