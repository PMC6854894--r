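#' Configuration of the CpG discovery filter
#'
#' Thresholds for the marker-discovery funnel on a beta-value matrix:
#' exclude CpGs methylated in blood cells, exclude CpGs with low
#' methylation in CRC tumours, rank survivors by CRC sensitivity times
#' cross-cancer specificity.
#'
#' @param beta_hyper beta above which a sample counts as hypermethylated
#'   (default 0.35, the cut used to describe the winning markers).
#' @param crc_frac_min minimum fraction of CRC samples hypermethylated
#'   (default 0.97; the winners were hypermethylated in > 97% of
#'   tumours).
#' @param pbl_beta_max beta above which a PBL sample counts as showing
#'   blood methylation (default 0.05).
#' @param pbl_frac_max maximum tolerated fraction of PBL samples above
#'   `pbl_beta_max` (default 0, i.e. markers must be blank in blood).
#' @param top_k number of ranked CpGs to report (default 50).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(beta_hyper = 0.35, crc_frac_min = 0.97,
                          pbl_beta_max = 0.05, pbl_frac_max = 0,
                          top_k = 50L) {
  for (nm in c("beta_hyper", "crc_frac_min", "pbl_beta_max",
               "pbl_frac_max"))
    assert_scalar_num(get(nm), nm, 0, 1)
  assert_count(top_k, "top_k", lo = 1)
  structure(list(beta_hyper = beta_hyper, crc_frac_min = crc_frac_min,
                 pbl_beta_max = pbl_beta_max, pbl_frac_max = pbl_frac_max,
                 top_k = as.integer(top_k)),
            class = "filter_config")
}

#' Filter and rank CpG marker candidates on a beta-value matrix
#'
#' Applies the discovery funnel: (1) blood exclusion — drop CpGs whose
#' fraction of PBL samples with beta above `pbl_beta_max` exceeds
#' `pbl_frac_max`; (2) CRC hypermethylation — drop CpGs hypermethylated
#' (beta > `beta_hyper`) in fewer than `crc_frac_min` of CRC samples;
#' (3) rank survivors by `crc_sensitivity * cross_cancer_specificity`
#' (descending), ties broken by lower PBL positivity then CpG id, and
#' truncate to `top_k`. Normal-mucosa methylation is reported but never
#' used for exclusion.
#'
#' @param matrix a `beta_matrix` (see [new_beta_matrix()]); groups must
#'   include `CRC` and `PBL`. Groups other than `CRC`, `PBL`, and
#'   `normal_mucosa` are treated as other-cancer types.
#' @param config a [filter_config()].
#' @return a data.frame (class `candidate_ranking`), one row per
#'   retained CpG in rank order: `cpg`, `crc_sensitivity`,
#'   `pbl_positivity`, `cross_cancer_specificity`,
#'   `mucosa_positivity`, `composite_score`, `rank`. Empty (with a
#'   warning) if no CpG survives.
#' @export
filter_candidates <- function(matrix, config = filter_config()) {
  stopifnot(inherits(matrix, "beta_matrix"))
  groups <- matrix$groups
  for (g in c("CRC", "PBL"))
    if (!any(groups == g))
      stop(sprintf("beta matrix must contain at least one '%s' sample", g),
           call. = FALSE)
  v <- matrix$values
  frac_above <- function(cols, thr)
    rowMeans(v[, cols, drop = FALSE] > thr)

  crc_sens <- frac_above(which(groups == "CRC"), config$beta_hyper)
  pbl_pos <- frac_above(which(groups == "PBL"), config$pbl_beta_max)
  other <- setdiff(unique(groups), c("CRC", "PBL", "normal_mucosa"))
  if (length(other)) {
    per_type <- vapply(other, function(g)
      frac_above(which(groups == g), config$beta_hyper),
      numeric(nrow(v)))
    cc_spec <- 1 - rowMeans(per_type)
  } else {
    cc_spec <- rep(1, nrow(v))
  }
  mucosa <- if (any(groups == "normal_mucosa"))
    frac_above(which(groups == "normal_mucosa"), config$beta_hyper)
  else rep(NA_real_, nrow(v))

  keep <- pbl_pos <= config$pbl_frac_max & crc_sens >= config$crc_frac_min
  if (!any(keep)) {
    warning("no CpG survived the discovery filter; returning empty ranking")
    out <- data.frame(cpg = character(), crc_sensitivity = numeric(),
                      pbl_positivity = numeric(),
                      cross_cancer_specificity = numeric(),
                      mucosa_positivity = numeric(),
                      composite_score = numeric(), rank = integer())
    class(out) <- c("candidate_ranking", class(out))
    return(out)
  }
  out <- data.frame(cpg = rownames(v)[keep],
                    crc_sensitivity = crc_sens[keep],
                    pbl_positivity = pbl_pos[keep],
                    cross_cancer_specificity = cc_spec[keep],
                    mucosa_positivity = mucosa[keep],
                    row.names = NULL)
  out$composite_score <- out$crc_sensitivity * out$cross_cancer_specificity
  ord <- order(-out$composite_score, out$pbl_positivity, out$cpg)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, config$top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' Triage candidate assays through the PBL / tissue / plasma funnel
#'
#' Applies the ordered assay-validation funnel with the printed strict
#' cut-offs: an assay positive in more than 7.5% of PBL samples is
#' excluded; a survivor must detect methylated DNA in more than 93% of
#' tumour tissues to proceed; a survivor is selected if positive in more
#' than 70% of CRC plasma samples and in none of the control plasmas
#' (100% specificity). Assays absent from a later-stage call table are
#' reported at the last stage they reached.
#'
#' @param pbl_calls,tissue_calls,plasma_case_calls,plasma_control_calls
#'   logical matrices (assay x sample; `TRUE` = any methylated signal),
#'   with assay rownames. Later-stage tables may cover fewer assays.
#' @param thresholds named list of funnel cut-offs: `pbl_max` (default
#'   0.075), `tissue_min` (0.93), `plasma_sens_min` (0.70),
#'   `plasma_spec_min` (1.00).
#' @return a data.frame (class `assay_funnel_result`), one row per assay
#'   in `pbl_calls`: fractions at each stage reached (NA beyond) and
#'   `stage_passed` in `excluded_pbl`, `excluded_tissue`,
#'   `excluded_plasma`, `selected`, or `not_evaluated` for assays
#'   missing from the next stage's table.
#' @export
assay_funnel <- function(pbl_calls, tissue_calls = NULL,
                         plasma_case_calls = NULL,
                         plasma_control_calls = NULL,
                         thresholds = list(pbl_max = 0.075,
                                           tissue_min = 0.93,
                                           plasma_sens_min = 0.70,
                                           plasma_spec_min = 1.00)) {
  check_calls <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.matrix(x)) x <- as.matrix(x)
    if (is.null(rownames(x)))
      stop(sprintf("%s must have assay rownames", what), call. = FALSE)
    if (ncol(x) == 0L)
      stop(sprintf("%s is empty", what), call. = FALSE)
    if (!is.logical(x)) {
      if (!all(x %in% c(0, 1)))
        stop(sprintf("%s contains values other than positive/negative",
                     what), call. = FALSE)
      x <- x > 0
    }
    x
  }
  pbl_calls <- check_calls(pbl_calls, "pbl_calls")
  tissue_calls <- check_calls(tissue_calls, "tissue_calls")
  plasma_case_calls <- check_calls(plasma_case_calls, "plasma_case_calls")
  plasma_control_calls <- check_calls(plasma_control_calls,
                                      "plasma_control_calls")
  assays <- rownames(pbl_calls)
  res <- data.frame(assay = assays,
                    pbl_pos_frac = rowMeans(pbl_calls),
                    tissue_sens = NA_real_, plasma_sens = NA_real_,
                    plasma_spec = NA_real_,
                    stage_passed = NA_character_)
  for (i in seq_along(assays)) {
    a <- assays[i]
    if (res$pbl_pos_frac[i] > thresholds$pbl_max) {
      res$stage_passed[i] <- "excluded_pbl"; next
    }
    if (is.null(tissue_calls) || !a %in% rownames(tissue_calls)) {
      res$stage_passed[i] <- "not_evaluated"; next
    }
    res$tissue_sens[i] <- mean(tissue_calls[a, ])
    if (res$tissue_sens[i] <= thresholds$tissue_min) {
      res$stage_passed[i] <- "excluded_tissue"; next
    }
    if (is.null(plasma_case_calls) ||
        !a %in% rownames(plasma_case_calls) ||
        is.null(plasma_control_calls) ||
        !a %in% rownames(plasma_control_calls)) {
      res$stage_passed[i] <- "not_evaluated"; next
    }
    res$plasma_sens[i] <- mean(plasma_case_calls[a, ])
    res$plasma_spec[i] <- mean(!plasma_control_calls[a, ])
    res$stage_passed[i] <-
      if (res$plasma_sens[i] > thresholds$plasma_sens_min &&
          res$plasma_spec[i] >= thresholds$plasma_spec_min)
        "selected" else "excluded_plasma"
  }
  rownames(res) <- NULL
  class(res) <- c("assay_funnel_result", class(res))
  res
}
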