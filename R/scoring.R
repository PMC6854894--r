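#' The locked TriMeth marker panel
#'
#' @format character vector of the three panel markers.
#' @export
TRIMETH_MARKERS <- c("C9orf50", "KCNQ5", "CLIP4")

#' Apply the locked two-of-three TriMeth rule to one sample
#'
#' A marker is called positive if it detected any methylated DNA
#' (strictly more than zero copies; no copy-number floor). The sample
#' is TriMeth-positive if two or more of the three markers are
#' positive. The rule is locked: there is no tunable threshold.
#'
#' @param marker_copies named numeric vector of detected methylated
#'   copies for exactly the three panel markers
#'   (`C9orf50`, `KCNQ5`, `CLIP4`).
#' @param markers panel definition (default [TRIMETH_MARKERS]).
#' @return a list with `marker_copies`, `marker_calls` (named logical),
#'   and `trimeth_positive`.
#' @export
call_trimeth <- function(marker_copies, markers = TRIMETH_MARKERS) {
  missing <- setdiff(markers, names(marker_copies))
  if (length(missing))
    stop(sprintf(
      "incomplete panel: marker(s) %s missing; sample not evaluable",
      paste(missing, collapse = ", ")), call. = FALSE)
  copies <- marker_copies[markers]
  if (any(!is.finite(copies)) || any(copies < 0))
    stop("marker copies must be finite and non-negative", call. = FALSE)
  calls <- copies > 0
  list(marker_copies = copies, marker_calls = calls,
       trimeth_positive = sum(calls) >= 2L)
}

#' Score every sample of a cohort table
#'
#' @param results data.frame with one `copies_<marker>` column per
#'   panel marker (as written by [generate_cohort()] or the
#'   quantification stage).
#' @param markers panel definition.
#' @return `results` with added logical columns `call_<marker>` and
#'   `trimeth_positive`.
#' @export
score_cohort <- function(results, markers = TRIMETH_MARKERS) {
  cols <- paste0("copies_", markers)
  missing <- setdiff(cols, names(results))
  if (length(missing))
    stop(sprintf("missing marker columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  calls <- results[cols] > 0
  colnames(calls) <- paste0("call_", markers)
  results <- cbind(results, calls)
  results$trimeth_positive <- rowSums(calls) >= 2L
  results
}

proportion_ci <- function(x, n, method, conf) {
  switch(method,
         "clopper-pearson" = clopper_pearson(x, n, conf),
         "wilson" = wilson_interval(x, n, conf))
}

#' Sensitivity, specificity and stage stratification for a scored cohort
#'
#' Computes the panel's diagnostic performance: sensitivity (positives
#' among cases), specificity (negatives among controls), both with 95%
#' confidence intervals; sensitivity stratified by tumour stage; and,
#' when marker copy columns are present, per-marker sensitivity,
#' specificity and empirical AUC. Percentages are reported both exact
#' and half-up rounded to integers (the printed style).
#'
#' @param results data.frame with columns `status` (`case`/`control`),
#'   `trimeth_positive` (logical), optionally `stage` (`I`-`IV`; `none`
#'   for controls) and `copies_<marker>` columns.
#' @param markers panel definition for per-marker metrics; set `NULL`
#'   to skip.
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param conf confidence level.
#' @return an object of class `cohort_metrics`: lists `sensitivity` and
#'   `specificity` (`positives`/`negatives`, `n`, `pct`, `pct_rounded`,
#'   `ci_pct`), data.frame `stage_sensitivity`, and data.frame
#'   `per_marker` (or `NULL`).
#' @export
cohort_metrics <- function(results, markers = TRIMETH_MARKERS,
                           ci_method = c("clopper-pearson", "wilson"),
                           conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("status", "trimeth_positive") %in% names(results)))
  cases <- results[results$status == "case", , drop = FALSE]
  controls <- results[results$status == "control", , drop = FALSE]
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("cohort_metrics needs at least one case and one control",
         call. = FALSE)

  prop_summary <- function(x, n) {
    ci <- proportion_ci(x, n, ci_method, conf)
    pct <- 100 * x / n
    list(count = x, n = n, pct = pct,
         pct_rounded = round_half_up(pct),
         ci_pct = 100 * ci)
  }
  sens <- prop_summary(sum(cases$trimeth_positive), nrow(cases))
  spec <- prop_summary(sum(!controls$trimeth_positive), nrow(controls))

  stage_sens <- NULL
  if ("stage" %in% names(results)) {
    stages <- intersect(c("I", "II", "III", "IV"), unique(cases$stage))
    empty <- setdiff(c("I", "II", "III", "IV"), stages)
    if (length(empty))
      warning(sprintf("no cases in stage(s) %s; stratum omitted",
                      paste(empty, collapse = ", ")))
    stage_sens <- do.call(rbind, lapply(stages, function(s) {
      sub <- cases[cases$stage == s, , drop = FALSE]
      p <- prop_summary(sum(sub$trimeth_positive), nrow(sub))
      data.frame(stage = s, positives = p$count, n = p$n, pct = p$pct,
                 pct_rounded = p$pct_rounded,
                 lower_pct = p$ci_pct[["lower"]],
                 upper_pct = p$ci_pct[["upper"]])
    }))
  }

  per_marker <- NULL
  if (!is.null(markers) &&
      all(paste0("copies_", markers) %in% names(results))) {
    per_marker <- do.call(rbind, lapply(markers, function(m) {
      col <- paste0("copies_", m)
      roc <- marker_roc(results, m)
      data.frame(marker = m,
                 sensitivity_pct = 100 * mean(cases[[col]] > 0),
                 specificity_pct = 100 * mean(controls[[col]] == 0),
                 auc = roc$auc)
    }))
  }
  structure(list(sensitivity = sens, specificity = spec,
                 stage_sensitivity = stage_sens, per_marker = per_marker,
                 ci_method = ci_method, conf = conf),
            class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf("TriMeth cohort metrics (%s CIs, %.0f%%)\n", x$ci_method,
              100 * x$conf))
  cat(sprintf("  sensitivity: %d%% (%d/%d; CI %.1f-%.1f)\n",
              x$sensitivity$pct_rounded, x$sensitivity$count,
              x$sensitivity$n, x$sensitivity$ci_pct[["lower"]],
              x$sensitivity$ci_pct[["upper"]]))
  cat(sprintf("  specificity: %d%% (%d/%d; CI %.1f-%.1f)\n",
              x$specificity$pct_rounded, x$specificity$count,
              x$specificity$n, x$specificity$ci_pct[["lower"]],
              x$specificity$ci_pct[["upper"]]))
  if (!is.null(x$stage_sensitivity))
    for (i in seq_len(nrow(x$stage_sensitivity)))
      with(x$stage_sensitivity[i, ],
           cat(sprintf("  stage %-3s  %d%% (%d/%d)\n", stage, pct_rounded,
                       positives, n)))
  if (!is.null(x$per_marker))
    for (i in seq_len(nrow(x$per_marker)))
      with(x$per_marker[i, ],
           cat(sprintf("  %-8s sens %.0f%%, spec %.0f%%, AUC %.2f\n",
                       marker, sensitivity_pct, specificity_pct, auc)))
  invisible(x)
}

#' Reconstruct a scored cohort from stage-level counts
#'
#' Builds a minimal sample table (one row per patient or control, with
#' `status`, `stage` and `trimeth_positive`) from per-stage case counts
#' and positives plus control counts, so that count-level published
#' results can be pushed through [cohort_metrics()] exactly like
#' sample-level data. Positive counts may also be recovered from
#' printed integer sensitivities via [positives_from_printed_pct()].
#'
#' @param stage_n named vector (stages `I`-`IV`) of cases per stage.
#' @param stage_positives named vector of TriMeth-positive cases per
#'   stage.
#' @param n_controls number of controls.
#' @param controls_negative number of TriMeth-negative controls.
#' @param cohort label stored on every row.
#' @return a data.frame suitable for [cohort_metrics()]
#'   (`markers = NULL`).
#' @export
samples_from_stage_counts <- function(stage_n, stage_positives,
                                      n_controls, controls_negative,
                                      cohort = "counts") {
  stopifnot(identical(names(stage_n), names(stage_positives)),
            all(stage_positives <= stage_n),
            controls_negative <= n_controls)
  rows <- lapply(names(stage_n), function(s) {
    n <- stage_n[[s]]; p <- stage_positives[[s]]
    if (n == 0) return(NULL)
    data.frame(cohort = cohort, status = "case", stage = s,
               trimeth_positive = rep(c(TRUE, FALSE), c(p, n - p)))
  })
  ctrl <- if (n_controls > 0)
    data.frame(cohort = cohort, status = "control", stage = "none",
               trimeth_positive = rep(c(FALSE, TRUE),
                                      c(controls_negative,
                                        n_controls - controls_negative)))
  out <- do.call(rbind, c(rows, list(ctrl)))
  out$sample_id <- sprintf("%s_%04d", cohort, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Recover integer positives from a printed percentage
#'
#' Published stage sensitivities are integer percentages of known
#' denominators; the underlying count is the half-up rounding of
#' `pct/100 * n`. The recovered count is checked to re-print as `pct`.
#'
#' @param n denominators.
#' @param pct printed integer percentages.
#' @return integer counts.
#' @export
positives_from_printed_pct <- function(n, pct) {
  k <- round_half_up(pct / 100 * n)
  bad <- round_half_up(100 * k / n) != pct
  if (any(bad))
    stop(sprintf(
      "printed percentage %s%% of %d is not consistent with any count",
      paste(pct[bad], collapse = ","), n[bad][1L]), call. = FALSE)
  stats::setNames(as.integer(k), names(n))
}

#' Empirical ROC curve and AUC for one marker
#'
#' Uses the detected methylated copies per reaction as the score.
#' The curve is traced over all score thresholds with ties collapsed;
#' the AUC is the trapezoidal area, which (ties handled by the half
#' rule) equals the normalized Mann-Whitney U statistic. The
#' "any methylated DNA" operating point (score > 0) is annotated.
#'
#' @param results data.frame with `status` and `copies_<marker>`.
#' @param marker marker name.
#' @return a list: `points` (data.frame `threshold`, `fpr`, `tpr`),
#'   `auc`, `operating_point` (list `sensitivity`, `specificity`), and
#'   `marker`.
#' @export
marker_roc <- function(results, marker) {
  col <- paste0("copies_", marker)
  stopifnot(col %in% names(results), "status" %in% names(results))
  scores <- results[[col]]
  is_case <- results$status == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs at least one case and one control", call. = FALSE)
  if (length(unique(scores)) == 1L)
    warning(sprintf("degenerate scores for %s: all values equal; AUC = 0.5",
                    marker))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_case[ord]
  # collapse ties: one ROC vertex per distinct score
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  thr <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc,
       operating_point = list(
         sensitivity = mean(scores[is_case] > 0),
         specificity = mean(scores[!is_case] == 0)),
       marker = marker)
}

#' Median methylated load per group with bootstrap confidence intervals
#'
#' @param x numeric vector (e.g. methylated fragments per ml plasma).
#' @param group factor/character of the same length.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `lower`, `upper`. A single-observation group gets a degenerate
#'   interval at its value.
#' @export
summarize_methylated_load <- function(x, group, n_boot = 2000L,
                                      conf = 0.95, seed = 1L) {
  stopifnot(length(x) == length(group))
  alpha <- (1 - conf) / 2
  with_seed(derive_seed(seed, "load-boot"), {
    do.call(rbind, lapply(split(x, group), function(v) {
      if (length(v) == 1L) {
        ci <- c(v, v)
      } else {
        meds <- vapply(seq_len(n_boot), function(i)
          stats::median(sample(v, replace = TRUE)), numeric(1))
        ci <- unname(stats::quantile(meds, c(alpha, 1 - alpha)))
      }
      data.frame(n = length(v), median = stats::median(v),
                 lower = ci[1L], upper = ci[2L])
    })) -> out
    out$group <- rownames(out)
    rownames(out) <- NULL
    out[, c("group", "n", "median", "lower", "upper")]
  })
}
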