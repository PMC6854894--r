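test_that("cohort generation is reproducible with the declared structure", {
  spec <- cohort_gen_spec(n_cases_per_stage = c(I = 5, II = 10, III = 5,
                                                IV = 2),
                          n_controls = 20, seed = 4L)
  a <- generate_cohort(spec)
  expect_identical(a, generate_cohort(spec))
  expect_equal(sum(a$status == "case"), 22L)
  expect_equal(sum(a$status == "control"), 20L)
  expect_true(all(a$stage[a$status == "control"] == "none"))
  expect_true(all(a$stage[a$status == "case"] != "none"))
  cnt <- as.matrix(a[paste0("copies_", TRIMETH_MARKERS)])
  expect_true(all(cnt >= 0))
  expect_true(all(a$tumour_fraction[a$status == "control"] == 0))
})

test_that("controls with zero false-positive rates are TriMeth negative", {
  spec <- cohort_gen_spec(n_cases_per_stage = c(I = 0, II = 0, III = 0,
                                                IV = 0),
                          n_controls = 50,
                          marker_fp_rate = c(C9orf50 = 0, KCNQ5 = 0,
                                             CLIP4 = 0),
                          seed = 6L)
  co <- score_cohort(generate_cohort(spec))
  expect_true(all(as.matrix(co[paste0("copies_", TRIMETH_MARKERS)]) == 0))
  expect_false(any(co$trimeth_positive))
})

test_that("control per-marker positivity converges to the fp rates", {
  fp <- c(C9orf50 = 0.09, KCNQ5 = 0.05, CLIP4 = 0.01)
  spec <- cohort_gen_spec(n_cases_per_stage = c(I = 0, II = 0, III = 0,
                                                IV = 0),
                          n_controls = 20000, marker_fp_rate = fp,
                          seed = 10L)
  co <- generate_cohort(spec)
  for (m in names(fp)) {
    emp <- mean(co[[paste0("copies_", m)]] > 0)
    se <- sqrt(fp[[m]] * (1 - fp[[m]]) / nrow(co))
    expect_lt(abs(emp - fp[[m]]), 4 * se)
  }
})

test_that("fully sensitive markers with high tumour fractions saturate sensitivity", {
  spec <- cohort_gen_spec(n_cases_per_stage = c(I = 30, II = 30, III = 30,
                                                IV = 30),
                          n_controls = 10,
                          tumour_fraction_meanlog =
                            log(c(I = 0.5, II = 0.5, III = 0.5, IV = 0.5)),
                          tumour_fraction_sdlog = 0.1,
                          marker_sensitivity = c(C9orf50 = 1, KCNQ5 = 1,
                                                 CLIP4 = 1),
                          seed = 2L)
  co <- score_cohort(generate_cohort(spec))
  expect_true(all(co$trimeth_positive[co$status == "case"]))
})

test_that("the fixed-volume design gives per-sample inputs proportional to cfDNA", {
  spec <- cohort_gen_spec(n_cases_per_stage = c(I = 2, II = 2, III = 2,
                                                IV = 2),
                          n_controls = 5, input_mode = "fixed_volume",
                          plasma_ml = 16, bs_recovery = 0.541,
                          n_reactions = 2, seed = 8L)
  co <- generate_cohort(spec)
  expect_equal(co$input_copies,
               co$cfdna_copies_per_ml * 16 * 0.541 / 2)
  fixed <- generate_cohort(cohort_gen_spec(
    n_cases_per_stage = c(I = 2, II = 2, III = 2, IV = 2),
    n_controls = 5, seed = 8L))
  expect_true(all(fixed$input_copies == 4500))
})
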