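test_that("the locked two-of-three rule calls samples as specified", {
  neg <- call_trimeth(c(C9orf50 = 0, KCNQ5 = 0, CLIP4 = 0))
  expect_false(neg$trimeth_positive)
  pos <- call_trimeth(c(C9orf50 = 3, KCNQ5 = 0, CLIP4 = 1))
  expect_true(pos$trimeth_positive)
  expect_equal(unname(pos$marker_calls), c(TRUE, FALSE, TRUE))
  # one positive marker is not enough, whatever its load
  one <- call_trimeth(c(C9orf50 = 0.0, KCNQ5 = 0.0, CLIP4 = 7.2))
  expect_false(one$trimeth_positive)
  # any methylated DNA counts: no copy-number floor
  tiny <- call_trimeth(c(C9orf50 = 1e-9, KCNQ5 = 0.1, CLIP4 = 0))
  expect_true(tiny$trimeth_positive)
  expect_error(call_trimeth(c(C9orf50 = 1, KCNQ5 = 2)),
               "incomplete panel.*CLIP4")
})

test_that("adding a positive marker never flips a positive sample negative", {
  set.seed(51)
  for (i in 1:50) {
    copies <- stats::setNames(rpois(3, 1) * rbinom(3, 1, 0.5),
                              TRIMETH_MARKERS)
    before <- call_trimeth(copies)$trimeth_positive
    zeros <- which(copies == 0)
    if (length(zeros)) {
      j <- zeros[sample.int(length(zeros), 1)]
      copies[j] <- 5
      after <- call_trimeth(copies)$trimeth_positive
      expect_true(!before || after)
    }
  }
})

test_that("cohort metrics are exact counting, permutation-invariant, and correctly rounded", {
  sam <- samples_from_stage_counts(
    stage_n = c(I = 10, II = 20, III = 10, IV = 5),
    stage_positives = c(I = 7, II = 18, III = 9, IV = 5),
    n_controls = 30, controls_negative = 29)
  m <- cohort_metrics(sam, markers = NULL)
  expect_equal(m$sensitivity$count, 39)
  expect_equal(m$sensitivity$n, 45)
  expect_equal(m$sensitivity$pct, 100 * 39 / 45)
  expect_equal(m$specificity$pct, 100 * 29 / 30)
  expect_equal(m$sensitivity$pct_rounded,
               round_half_up(m$sensitivity$pct))
  expect_true(m$sensitivity$ci_pct[["lower"]] <= m$sensitivity$pct)
  expect_true(m$sensitivity$ci_pct[["upper"]] >= m$sensitivity$pct)
  set.seed(52)
  m2 <- cohort_metrics(sam[sample(nrow(sam)), ], markers = NULL)
  expect_equal(m2$sensitivity, m$sensitivity)
  expect_equal(m2$stage_sensitivity, m$stage_sensitivity)
  # Wilson intervals are available and narrower here
  mw <- cohort_metrics(sam, markers = NULL, ci_method = "wilson")
  expect_lt(diff(mw$specificity$ci_pct), diff(m$specificity$ci_pct))
})

test_that("empty strata are omitted with a warning and degenerate cohorts error", {
  sam <- samples_from_stage_counts(c(I = 5, II = 0, III = 0, IV = 0),
                                   c(I = 4, II = 0, III = 0, IV = 0),
                                   10, 10)
  expect_warning(m <- cohort_metrics(sam, markers = NULL), "stratum omitted")
  expect_equal(m$stage_sensitivity$stage, "I")
  cases_only <- sam[sam$status == "case", ]
  expect_error(cohort_metrics(cases_only, markers = NULL),
               "at least one case and one control")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic, ties included", {
  set.seed(53)
  for (i in 1:25) {
    n1 <- sample(1:100, 1); n0 <- sample(1:100, 1)
    # heavy ties: discrete counts, as marker copies are
    cases <- rpois(n1, sample(c(0.2, 1, 5), 1))
    controls <- rpois(n0, 0.3)
    df <- data.frame(status = rep(c("case", "control"), c(n1, n0)),
                     copies_M = c(cases, controls))
    roc <- marker_roc(df, "M")
    expect_equal(roc$auc, oracle_auc_pairs(cases, controls),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles perfect separation, the null, and degenerate scores", {
  df <- data.frame(status = rep(c("case", "control"), each = 20),
                   copies_M = c(rnorm(20, 10), rnorm(20, -10)))
  expect_equal(marker_roc(df, "M")$auc, 1.0)
  set.seed(54)
  null_scores <- rpois(2000, 1)
  dfn <- data.frame(status = sample(rep(c("case", "control"), 1000)),
                    copies_M = null_scores)
  expect_lt(abs(marker_roc(dfn, "M")$auc - 0.5), 0.05)
  dfc <- data.frame(status = rep(c("case", "control"), each = 5),
                    copies_M = rep(1, 10))
  expect_warning(roc <- marker_roc(dfc, "M"), "degenerate")
  expect_equal(roc$auc, 0.5)
})

test_that("ROC matches an established implementation on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(55)
  df <- data.frame(status = rep(c("case", "control"), c(60, 80)),
                   copies_M = c(rpois(60, 3), rpois(80, 0.3)))
  ours <- marker_roc(df, "M")$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = df$status == "case", predictor = df$copies_M)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("the operating point is the any-methylated-DNA threshold", {
  df <- data.frame(status = rep(c("case", "control"), c(10, 10)),
                   copies_M = c(rep(c(0, 2), 5), rep(0, 9), 4))
  roc <- marker_roc(df, "M")
  expect_equal(roc$operating_point$sensitivity, 0.5)
  expect_equal(roc$operating_point$specificity, 0.9)
})

test_that("median methylated load has seeded bootstrap intervals", {
  x <- c(rlnorm(50, 0, 1), rep(0, 40))
  g <- rep(c("case", "control"), c(50, 40))
  s1 <- summarize_methylated_load(x, g, seed = 9L)
  s2 <- summarize_methylated_load(x, g, seed = 9L)
  expect_identical(s1, s2)
  expect_equal(s1$median[s1$group == "control"], 0)
  expect_true(all(s1$lower <= s1$median & s1$median <= s1$upper))
  single <- summarize_methylated_load(3.2, "case")
  expect_equal(single$lower, 3.2)
  expect_equal(single$upper, 3.2)
})

test_that("printed percentages are recovered consistently", {
  expect_equal(positives_from_printed_pct(16, 63), 10L)
  expect_equal(positives_from_printed_pct(c(68, 22, 7), c(81, 77, 86)),
               c(55L, 17L, 6L))
  expect_error(positives_from_printed_pct(10, 99), "not consistent")
})
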