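# small helper: a one-gene world with configurable tracks
one_gene_world <- function(strand = "+", t0 = 50000L) {
  tss_table("gX", "chr1", strand, t0)
}

mkps <- function(df, mark, cond) {
  suppressMessages(peak_set(df, mark, cond))
}

test_that("profiles reproduce the two published archetypes", {
  tss <- one_gene_world()
  t0 <- tss$tss_pos[1]
  empty_cmp <- compare_conditions(mkps(.empty_df(), "H3Ac", "minus_LPS"),
                                  mkps(.empty_df(), "H3Ac", "plus_LPS"))
  # sharp-promoter archetype: no promoter H3Ac, S5P appearing upon
  # stimulation, no Sp1, no CpG island, TATA box present, up-regulated
  de <- data.frame(gene_id = "gX", delta_log2 = log2(29.6),
                   fold_change = 29.6, p_value = 5e-4, call = "up",
                   stringsAsFactors = FALSE)
  pr <- build_profiles(
    tss, empty_cmp,
    s5p = list(minus = NULL,
               plus = mkps(genomic_interval("chr1", t0 - 100, t0 + 100),
                           "S5P_RNAPII", "plus_LPS")),
    sp1 = NULL, cpg_islands = NULL,
    tata = setNames(TRUE, tss$tss_id), de = de)
  expect_false(pr$h3ac_common)
  expect_equal(pr$extension, "none")
  expect_equal(pr$s5p_status, "plus_only")
  expect_equal(pr$sp1_status, "none")
  expect_false(pr$cpg)
  expect_true(pr$tata)
  expect_equal(pr$group, "1")
  expect_equal(pr$consistency, 1)

  # broad-promoter archetype: common H3Ac widened on both sides, S5P only
  # before stimulation, no CpG island, TATA present, strongly up-regulated
  h3 <- compare_conditions(
    mkps(genomic_interval("chr1", t0 - 500, t0 + 500), "H3Ac", "minus_LPS"),
    mkps(genomic_interval("chr1", t0 - 900, t0 + 900), "H3Ac", "plus_LPS"))
  pr2 <- build_profiles(
    tss, h3,
    s5p = list(minus = mkps(genomic_interval("chr1", t0 - 100, t0 + 100),
                            "S5P_RNAPII", "minus_LPS"), plus = NULL),
    sp1 = NULL, cpg_islands = NULL,
    tata = setNames(TRUE, tss$tss_id),
    de = transform(de, fold_change = 47.2))
  expect_true(pr2$h3ac_common)
  expect_equal(pr2$extension, "both")
  expect_equal(pr2$s5p_status, "minus_only")
  expect_equal(pr2$group, "2")   # promoter H3Ac decides, despite the TATA

  # empty tracks give the all-negative profile
  pr3 <- build_profiles(tss, empty_cmp)
  expect_false(pr3$h3ac_common)
  expect_equal(pr3$s5p_status, "none")
  expect_equal(pr3$group, "unassigned")
})

test_that("classify_group depends only on regulation and promoter H3Ac", {
  expect_equal(classify_group("up", TRUE), "2")
  expect_equal(classify_group("down", TRUE), "2")
  expect_equal(classify_group("up", FALSE), "1")
  expect_equal(classify_group("null", TRUE), "unassigned")
  # purity: permuting every secondary feature never changes the group
  set.seed(181)
  for (k in 1:50) {
    pr <- data.frame(de_call = sample(c("up", "down", "null"), 1),
                     h3ac_common = sample(c(TRUE, FALSE), 1))
    g <- classify_group(pr$de_call, pr$h3ac_common)
    pr$cpg <- sample(c(TRUE, FALSE), 1)
    pr$tata <- sample(c(TRUE, FALSE), 1)
    pr$sp1_status <- sample(c("none", "both"), 1)
    expect_equal(classify_group(pr), g)
  }
})

test_that("the transcribed published feature rows classify to their groups", {
  fx <- fixture_profiles()
  got <- classify_group(fx$de_call, fx$h3ac_common == "YES")
  expect_equal(got, as.character(fx$expected_group))
  # the tie-break row: TATA-positive, CpG-poor, but promoter H3Ac present
  il1b <- fx[fx$gene_id == "IL1B", ]
  expect_equal(il1b$tata, "YES")
  expect_equal(il1b$cpg, "NO")
  expect_equal(classify_group("up", il1b$h3ac_common == "YES"), "2")
})

test_that("gene-level roll-up flags disagreeing alternative TSSs", {
  pr <- data.frame(gene_id = c("a", "a", "b", "c", "c"),
                   group = c("1", "2", "2", "unassigned", "1"))
  ru <- gene_group_rollup(pr)
  expect_equal(ru$group[ru$gene_id == "a"], "mixed")
  expect_equal(ru$group[ru$gene_id == "b"], "2")
  expect_equal(ru$group[ru$gene_id == "c"], "1")
})

test_that("colocalization fractions match a quadratic overlap filter", {
  # trivial cases
  a <- compare_conditions(mkps(.empty_df(), "S5P_RNAPII", "minus_LPS"),
                          mkps(genomic_interval("c", 0, 100),
                               "S5P_RNAPII", "plus_LPS"))
  b <- list(minus = mkps(.empty_df(), "H3Ac", "minus_LPS"),
            plus = mkps(genomic_interval("c", 90, 200), "H3Ac", "plus_LPS"))
  cs <- colocalization_summary(a, b, .empty_df())
  expect_equal(cs$frac_overlap[cs$class == "unique_plus"], 1)
  b0 <- list(minus = b$minus,
             plus = mkps(genomic_interval("c", 500, 600), "H3Ac", "plus_LPS"))
  cs0 <- colocalization_summary(a, b0, .empty_df())
  expect_equal(cs0$frac_overlap[cs0$class == "unique_plus"], 0)

  set.seed(191)
  am <- random_peakset(60, "S5P_RNAPII", "minus_LPS")
  ap <- random_peakset(60, "S5P_RNAPII", "plus_LPS")
  bm <- random_peakset(40, "H3Ac", "minus_LPS")
  bp <- random_peakset(40, "H3Ac", "plus_LPS")
  acmp <- compare_conditions(am, ap)
  cs <- colocalization_summary(acmp, list(minus = bm, plus = bp), .empty_df())
  brute <- function(q, s) {
    if (nrow(q) == 0) return(NA_real_)
    mean(vapply(seq_len(nrow(q)), function(i) {
      any(vapply(seq_len(nrow(s)), function(j) {
        oracle_overlap(q[i, ], s[j, ])
      }, logical(1)))
    }, logical(1)))
  }
  expect_equal(cs$frac_overlap[cs$class == "minus_total"],
               brute(am$intervals, bm$intervals))
  expect_equal(cs$frac_overlap[cs$class == "unique_plus"],
               brute(acmp$unique_plus, bp$intervals))
  expect_equal(cs$frac_overlap[cs$class == "common"],
               brute(acmp$members[, c("seq_id", "start", "end")],
                     rbind(bm$intervals, bp$intervals)))
  ok <- !is.na(cs$frac_overlap)
  expect_true(all(cs$frac_overlap[ok] >= 0 & cs$frac_overlap[ok] <= 1))
})

test_that("intragenic unique analysis counts open-promoter hosts", {
  # no unique peaks at all
  tss <- toy_genes()
  prom <- promoter_windows(tss)
  cmp0 <- compare_conditions(mkps(.empty_df(), "H3Ac", "minus_LPS"),
                             mkps(.empty_df(), "H3Ac", "plus_LPS"))
  r0 <- intragenic_unique_analysis(cmp0, tss, prom, .empty_df())
  expect_equal(c(r0$n_qualifying, r0$n_in_open_genes), c(0L, 0L))

  # gA (+, tss 5000) gets a common promoter peak; a +LPS-unique peak sits
  # in gA's exon 2 [6500,7200); gB has no promoter component, with a
  # unique peak in its exon [18000,18900)
  cmp <- compare_conditions(
    mkps(genomic_interval("chr1", 4500, 5200), "H3Ac", "minus_LPS"),
    mkps(genomic_interval("chr1", c(4300, 6600, 18100),
                          c(5200, 6900, 18400)), "H3Ac", "plus_LPS"))
  r <- intragenic_unique_analysis(cmp, tss, prom, .empty_df())
  expect_equal(r$n_qualifying, 2L)
  expect_equal(r$n_in_open_genes, 1L)
  # a CpG island over one peak disqualifies it
  r2 <- intragenic_unique_analysis(cmp, tss, prom,
                                   genomic_interval("chr1", 6800, 6950))
  expect_equal(r2$n_qualifying, 1L)
  expect_equal(r2$n_in_open_genes, 0L)
})

test_that("planted intragenic ground truth is recovered from a simulation", {
  sim <- simulate_chromatin(sim_config(seed = 7, n_genes = 50, n_up = 10,
                                       n_down = 2, n_intragenic_open = 10,
                                       n_intragenic_closed = 5))
  cmp <- compare_conditions(sim$peaks$h3ac$minus, sim$peaks$h3ac$plus)
  prom <- promoter_windows(sim$tss)
  r <- intragenic_unique_analysis(cmp, sim$tss, prom, sim$cpg)
  expect_equal(r$n_qualifying, 15L)
  expect_equal(r$n_in_open_genes, 10L)
})
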