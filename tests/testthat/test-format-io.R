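test_that("read_bed parses, merges and rejects", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t250"), p)
  ps <- suppressMessages(read_bed(p))
  expect_equal(ps$intervals, data.frame(seq_id = "chr1", start = 100L,
                                        end = 250L))
  writeLines(character(0), p)
  expect_equal(nrow(read_bed(p)$intervals), 0L)

  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), p)
  expect_error(read_bed(p), "line 2")
  writeLines("chr1\tx\t20", p)
  expect_error(read_bed(p), "non-numeric")
  writeLines("chr1\t100", p)
  expect_error(read_bed(p), "3 tab-separated")
  # extra columns from peak callers are ignored
  writeLines("chr1\t5\t50\tpeak_1\t999", p)
  expect_equal(read_bed(p)$intervals$end, 50L)
})

test_that("gene-model table dialect converts 1-based coordinates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tseq_id\tstrand\ttss_pos\texon_starts\texon_ends",
               "geneA\tchr1\t+\t1001\t1001,1501\t1200,2000"), p)
  tb <- read_gene_models(p)
  expect_equal(tb$tss_pos, 1000L)
  expect_equal(tb$exon_starts[[1]], c(1000L, 1500L))
  expect_equal(tb$exon_ends[[1]], c(1200L, 2000L))
  writeLines(c("gene_id\tseq_id\tstrand\ttss_pos\texon_starts\texon_ends",
               "geneA\tchr1\t*\t1001\t.\t."), p)
  expect_error(read_gene_models(p), "strand")
})

test_that("gene models round-trip through the table dialect", {
  set.seed(31)
  n <- 50
  tss <- lapply(seq_len(n), function(i) {
    strand <- sample(c("+", "-"), 1)
    es <- sort(sample(1000:5000, 3)) * 2L
    ee <- es + sample(100:400, 3)
    t0 <- if (strand == "+") min(es) else max(ee) - 1L
    list(g = sprintf("g%02d", i), s = sample(c("chr1", "chr2"), 1),
         st = strand, t = t0, es = es, ee = ee)
  })
  tb <- tss_table(vapply(tss, `[[`, "", "g"), vapply(tss, `[[`, "", "s"),
                  vapply(tss, `[[`, "", "st"),
                  vapply(tss, function(x) x$t, integer(1)),
                  lapply(tss, `[[`, "es"), lapply(tss, `[[`, "ee"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(tb, p)
  back <- read_gene_models(p)
  expect_equal(back, tb)
})

test_that("gtf_like dialect yields one TSS record per transcript", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
          'gene_id "gA"; transcript_id "gA.1";', sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".",
          'gene_id "gA"; transcript_id "gA.1";', sep = "\t"),
    paste("chr1", "src", "exon", 501, 700, ".", "-", ".",
          'gene_id "gB"; transcript_id "gB.1";', sep = "\t")), p)
  tb <- read_gene_models(p, dialect = "gtf_like")
  tb <- tb[order(tb$gene_id), ]
  expect_equal(tb$tss_pos, c(100L, 699L))
  expect_equal(tb$exon_starts[[1]], c(100L, 300L))
})

test_that("expression reader applies the sample sheet and rejects ambiguity", {
  pe <- withr::local_tempfile(fileext = ".tsv")
  ps <- withr::local_tempfile(fileext = ".tsv")
  vals <- matrix(rnorm(16), 2, 8,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  write.table(data.frame(gene_id = rownames(vals), vals), pe, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = paste0("s", 1:8),
                         condition = rep(c("minus_LPS", "plus_LPS"), each = 4)),
              ps, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_expression(pe, ps)
  expect_equal(dim(m$values), c(2L, 8L))
  expect_equal(unname(m$condition[c("s1", "s8")]), c("minus_LPS", "plus_LPS"))

  # duplicated gene ids are ambiguous
  write.table(data.frame(gene_id = c("g1", "g1"), vals), pe, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(pe, ps), "duplicated")

  # NA rows are dropped with a message; linear mode rejects <= 0
  d <- data.frame(gene_id = c("g1", "g2"), vals)
  d[1, 3] <- NA
  write.table(d, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(m2 <- read_expression(pe, ps), "dropped 1")
  expect_equal(nrow(m2$values), 1L)
  d <- data.frame(gene_id = "g1", t(c(1, 2, 0.5, 4, 0, 2, 3, 1)))
  names(d)[-1] <- paste0("s", 1:8)
  write.table(d, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(pe, ps, linear = TRUE), "non-positive")
})

test_that("FASTA loads upper-cased", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgtACGT"), p)
  x <- read_fasta(p)
  expect_equal(as.character(x[["s1"]]), "ACGTACGT")
  expect_equal(names(x), "s1")
})

test_that("feature table round-trips all fields", {
  set.seed(41)
  n <- 20
  pr <- data.frame(
    gene_id = sprintf("g%02d", 1:n), tss_id = sprintf("g%02d@1", 1:n),
    seq_id = "chr1", strand = sample(c("+", "-"), n, TRUE),
    tss_pos = sample.int(1e6, n),
    p_value = signif(runif(n), 4), fold_change = signif(runif(n, -8, 8), 4),
    de_call = sample(c("up", "down", "null"), n, TRUE),
    h3ac_common = sample(c(TRUE, FALSE), n, TRUE),
    extension = sample(c("upstream", "downstream", "both", "none"), n, TRUE),
    s5p_status = sample(c("none", "minus_only", "plus_only", "both"), n, TRUE),
    sp1_status = sample(c("none", "both"), n, TRUE),
    cpg = sample(c(TRUE, FALSE), n, TRUE),
    tata = sample(c(TRUE, FALSE), n, TRUE),
    group = sample(c("1", "2", "unassigned"), n, TRUE),
    consistency = signif(runif(n), 4),
    stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(pr, p)
  back <- read_feature_table(p)
  expect_equal(as.data.frame(back), pr, ignore_attr = TRUE)
})

test_that("matrix text format round-trips", {
  mats <- default_tata_matrices()
  p <- withr::local_tempfile(fileext = ".txt")
  write_pwms(mats, p)
  back <- read_pwms(p)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$freqs, mats[[1]]$freqs, tolerance = 1e-9)
  expect_equal(back[[1]]$name, "VTATA.01")
})
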