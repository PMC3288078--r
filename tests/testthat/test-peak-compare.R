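test_that("replicated_peaks keeps reference peaks confirmed by the replicate", {
  r1 <- suppressMessages(peak_set(genomic_interval("c", 0, 100)))
  r2 <- suppressMessages(peak_set(genomic_interval("c", 50, 60)))
  expect_equal(replicated_peaks(r1, r2)$intervals,
               data.frame(seq_id = "c", start = 0L, end = 100L))
  r3 <- suppressMessages(peak_set(genomic_interval("c", 200, 300)))
  expect_equal(nrow(replicated_peaks(r1, r3)$intervals), 0L)
  bad <- suppressMessages(peak_set(genomic_interval("c", 0, 10),
                                   condition = "plus_LPS"))
  expect_error(replicated_peaks(r1, bad), "mark and condition")
})

test_that("replicated_peaks equals the all-pairs overlap filter", {
  set.seed(51)
  for (k in 1:4) {
    r1 <- random_peakset(500, max_pos = 5000, max_len = 30)
    r2 <- random_peakset(500, max_pos = 5000, max_len = 30)
    got <- replicated_peaks(r1, r2)$intervals
    keep <- vapply(seq_len(nrow(r1$intervals)), function(i) {
      any(vapply(seq_len(nrow(r2$intervals)), function(j) {
        oracle_overlap(r1$intervals[i, ], r2$intervals[j, ])
      }, logical(1)))
    }, logical(1))
    expect_equal(got, merge_intervals(r1$intervals[keep, , drop = FALSE]))
  }
})

mkpair <- function(minus_df, plus_df) {
  list(minus = suppressMessages(peak_set(minus_df, "H3Ac", "minus_LPS")),
       plus = suppressMessages(peak_set(plus_df, "H3Ac", "plus_LPS")))
}

test_that("compare_conditions handles simple and chained overlap", {
  tr <- mkpair(genomic_interval("c", 100, 200), genomic_interval("c", 150, 400))
  cmp <- compare_conditions(tr$minus, tr$plus)
  expect_equal(unname(cmp$counts),
               c(1L, 1L, 1L, 0L, 0L))
  ls <- length_summary(cmp)
  expect_equal(ls$table$mean_length[ls$table$class == "common_minus"], 100)
  expect_equal(ls$table$mean_length[ls$table$class == "common_plus"], 250)
  expect_equal(ls$widening_ratio, 2.5)

  # many-to-one chain: 2 minus + 1 plus in one component
  tr <- mkpair(genomic_interval("c", c(0, 60), c(50, 100)),
               genomic_interval("c", 40, 70))
  cmp <- compare_conditions(tr$minus, tr$plus)
  expect_equal(nrow(cmp$components), 1L)
  expect_equal(cmp$components$n_minus, 2L)
  expect_equal(cmp$components$n_plus, 1L)
  expect_equal(cmp$components$extent_minus_start, 0L)
  expect_equal(cmp$components$extent_minus_end, 100L)
})

test_that("common/unique partition matches the union-find oracle", {
  set.seed(61)
  for (k in 1:3) {
    minus <- random_peakset(80, max_pos = 1200, max_len = 40)
    plus <- random_peakset(80, max_pos = 1200, max_len = 40,
                           condition = "plus_LPS")
    cmp <- compare_conditions(minus, plus)
    orc <- oracle_components(minus$intervals, plus$intervals)
    # partition: every peak in exactly one class
    expect_equal(cmp$counts[["n_common_minus"]] + cmp$counts[["n_unique_minus"]],
                 nrow(minus$intervals))
    expect_equal(cmp$counts[["n_common_plus"]] + cmp$counts[["n_unique_plus"]],
                 nrow(plus$intervals))
    expect_equal(cmp$counts[["n_components"]], orc$n_components)
    expect_equal(cmp$counts[["n_common_minus"]], sum(!is.na(orc$comp_minus)))
    expect_equal(cmp$counts[["n_common_plus"]], sum(!is.na(orc$comp_plus)))
    expect_equal(cmp$unique_minus,
                 .sort_df(minus$intervals[is.na(orc$comp_minus), ]))
    expect_equal(cmp$unique_plus,
                 .sort_df(plus$intervals[is.na(orc$comp_plus), ]))
    # same component membership as the oracle
    got_m <- cmp$members[cmp$members$condition == "minus_LPS", ]
    key <- paste(got_m$seq_id, got_m$start)
    okey <- paste(minus$intervals$seq_id, minus$intervals$start)[!is.na(orc$comp_minus)]
    expect_setequal(key, okey)
  }
})

test_that("compare_conditions is symmetric under condition swap", {
  set.seed(71)
  minus <- random_peakset(60)
  plus <- random_peakset(60, condition = "plus_LPS")
  cmp <- compare_conditions(minus, plus)
  swapped <- compare_conditions(
    suppressMessages(peak_set(plus$intervals, "H3Ac", "minus_LPS")),
    suppressMessages(peak_set(minus$intervals, "H3Ac", "plus_LPS")))
  expect_equal(cmp$counts[["n_components"]], swapped$counts[["n_components"]])
  expect_equal(cmp$unique_minus, swapped$unique_plus)
  expect_equal(cmp$unique_plus, swapped$unique_minus)
  # component count bounded by per-condition common counts
  expect_lte(cmp$counts[["n_components"]],
             min(cmp$counts[["n_common_minus"]], cmp$counts[["n_common_plus"]]))
})

test_that("extension_call reads growth strand-aware and ignores shrinkage", {
  comp <- data.frame(component = 1L, seq_id = "c",
                     extent_minus_start = 3000L, extent_minus_end = 3500L,
                     extent_plus_start = 2500L, extent_plus_end = 3500L)
  tss <- tss_table("g", "c", "+", 3200L)
  expect_equal(extension_call(comp, tss[1, ], 200L), "upstream")
  tssm <- tss_table("g", "c", "-", 3200L)
  expect_equal(extension_call(comp, tssm[1, ], 200L), "downstream")
  comp$extent_plus_start <- 3000L
  expect_equal(extension_call(comp, tss[1, ], 200L), "none")
  comp$extent_plus_start <- 2500L; comp$extent_plus_end <- 4000L
  expect_equal(extension_call(comp, tss[1, ], 200L), "both")
  # below the threshold
  comp$extent_plus_start <- 2900L; comp$extent_plus_end <- 3500L
  expect_equal(extension_call(comp, tss[1, ], 200L), "none")
  # shrinkage never yields a direction
  comp$extent_plus_start <- 3300L; comp$extent_plus_end <- 3400L
  expect_equal(extension_call(comp, tss[1, ], 200L), "none")
  comp$seq_id <- "other"
  expect_error(extension_call(comp, tss[1, ], 200L), "other")
})

test_that("planted containment with enough growth never calls none", {
  set.seed(81)
  for (k in 1:50) {
    ms <- sample(5000:6000, 1); me <- ms + sample(300:800, 1)
    grow_l <- sample(c(0, 250:600), 1); grow_r <- sample(c(0, 250:600), 1)
    if (grow_l + grow_r == 0) grow_l <- 300
    comp <- data.frame(component = 1L, seq_id = "c",
                       extent_minus_start = ms, extent_minus_end = me,
                       extent_plus_start = ms - grow_l,
                       extent_plus_end = me + grow_r)
    tss <- tss_table("g", "c", sample(c("+", "-"), 1), ms)
    expect_false(extension_call(comp, tss[1, ], 200L) == "none")
  }
})

test_that("length_summary reports NA for empty classes, never 0", {
  tr <- mkpair(.empty_df(), .empty_df())
  cmp <- compare_conditions(tr$minus, tr$plus)
  ls <- length_summary(cmp)
  expect_true(all(is.na(ls$table$mean_length)))
  expect_true(is.na(ls$widening_ratio))
})
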