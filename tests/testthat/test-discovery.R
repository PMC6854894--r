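make_matrix <- function(values_by_group, cpg_ids) {
  groups <- rep(names(values_by_group),
                vapply(values_by_group, ncol, 1L))
  values <- do.call(cbind, unname(values_by_group))
  colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  rownames(values) <- cpg_ids
  new_beta_matrix(values, stats::setNames(groups, colnames(values)))
}

test_that("a perfect marker is retained with unit scores; a blood-methylated CpG is excluded", {
  vals <- list(
    CRC = matrix(c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9), nrow = 2, ncol = 3),
    PBL = matrix(c(0.0, 0.9, 0.0, 0.9, 0.0, 0.9), nrow = 2, ncol = 3),
    lung = matrix(c(0.0, 0.9, 0.0, 0.9, 0.0, 0.9), nrow = 2, ncol = 3))
  bm <- make_matrix(vals, c("cgGOOD", "cgBLOOD"))
  r <- filter_candidates(bm)
  expect_equal(r$cpg, "cgGOOD")
  expect_equal(r$crc_sensitivity, 1)
  expect_equal(r$cross_cancer_specificity, 1)
  expect_equal(r$composite_score, 1)
})

test_that("rankings are invariant to row and column permutations", {
  bm <- generate_beta_matrix(beta_gen_spec(n_cpg = 60, n_markers = 5,
                                           seed = 21L))
  r0 <- filter_candidates(bm)
  set.seed(1)
  perm_s <- sample(ncol(bm$values))
  perm_c <- sample(nrow(bm$values))
  bm2 <- new_beta_matrix(bm$values[perm_c, perm_s],
                         bm$groups[perm_s])
  r1 <- filter_candidates(bm2)
  expect_equal(r0$cpg, r1$cpg)
  expect_equal(r0$composite_score, r1$composite_score)
})

test_that("missing required groups raise a configuration error", {
  vals <- list(CRC = matrix(0.5, 2, 3))
  bm <- make_matrix(vals, c("cg1", "cg2"))
  expect_error(filter_candidates(bm), "'PBL'")
})

test_that("the assay funnel reproduces the worked triage decisions", {
  calls <- function(pos, n) rep(c(TRUE, FALSE), c(pos, n - pos))
  pbl <- rbind(A = calls(3, 27), B = calls(0, 27), C = calls(0, 27))
  tissue <- rbind(B = calls(34, 36), C = calls(33, 36))
  case_p <- rbind(B = calls(22, 30))
  ctrl_p <- rbind(B = calls(0, 30))
  res <- assay_funnel(pbl, tissue, case_p, ctrl_p)
  stage <- stats::setNames(res$stage_passed, res$assay)
  expect_equal(stage[["A"]], "excluded_pbl")     # 3/27 = 11.1% > 7.5%
  expect_equal(stage[["B"]], "selected")         # 94.4%, 73.3%, 100% spec
  expect_equal(stage[["C"]], "excluded_tissue")  # 91.7% <= 93%
  expect_equal(res$pbl_pos_frac[res$assay == "A"], 3 / 27)
  expect_true(is.na(res$tissue_sens[res$assay == "A"]))
})

test_that("the funnel is idempotent on its own survivors and bounds are strict", {
  calls <- function(pos, n) rep(c(TRUE, FALSE), c(pos, n - pos))
  # exactly at the bounds: 7.5% PBL is tolerated, 93% tissue is not enough
  pbl <- rbind(X = calls(3, 40), Y = calls(0, 40))
  tissue <- rbind(X = calls(93, 100), Y = calls(94, 100))
  case_p <- rbind(Y = calls(71, 100))
  ctrl_p <- rbind(Y = calls(0, 100))
  res <- assay_funnel(pbl, tissue, case_p, ctrl_p)
  expect_equal(res$stage_passed[res$assay == "X"], "excluded_tissue")
  expect_equal(res$stage_passed[res$assay == "Y"], "selected")
  survivors <- res$assay[res$stage_passed == "selected"]
  res2 <- assay_funnel(pbl[survivors, , drop = FALSE],
                       tissue[survivors, , drop = FALSE],
                       case_p[survivors, , drop = FALSE],
                       ctrl_p[survivors, , drop = FALSE])
  expect_equal(res2$stage_passed, "selected")
  # any control-plasma positive breaks the 100% specificity requirement
  res3 <- assay_funnel(pbl["Y", , drop = FALSE],
                       tissue["Y", , drop = FALSE],
                       case_p, rbind(Y = calls(1, 100)))
  expect_equal(res3$stage_passed, "excluded_plasma")
})

test_that("assays absent from later stages are reported as not evaluated", {
  calls <- function(pos, n) rep(c(TRUE, FALSE), c(pos, n - pos))
  pbl <- rbind(A = calls(0, 27))
  res <- assay_funnel(pbl)
  expect_equal(res$stage_passed, "not_evaluated")
  expect_error(assay_funnel(rbind(A = c(2, 0, 1))),
               "positive/negative")
})
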