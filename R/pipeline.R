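#' Configuration for an end-to-end synthetic pipeline run
#'
#' Bundles every stage's parameters: the cohort design (fixed 4500-copy
#' input or fixed 16 ml plasma volume), the droplet plate geometry, the
#' caller settings, and the CI method. One master seed drives every
#' source of randomness; identical config and seed give byte-identical
#' outputs.
#'
#' @param cohort a [cohort_gen_spec()]; its `input_mode` selects the
#'   cohort design.
#' @param droplets_per_well droplets per simulated well.
#' @param wells_per_plate test wells per simulated plate (a positive
#'   control is added to each plate).
#' @param negative_mode,positive_mode,spread_neg,spread_pos,rain_fraction,well_shift_range
#'   plate amplitude parameters, see [plate_gen_spec()].
#' @param ci_method proportion CI method, see [cohort_metrics()].
#' @param write_plates write per-droplet amplitude CSVs (large; off by
#'   default).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_gen_spec(),
                            droplets_per_well = 16218L,
                            wells_per_plate = 46L,
                            negative_mode = 2000, positive_mode = 8000,
                            spread_neg = 300, spread_pos = 300,
                            rain_fraction = 0.01,
                            well_shift_range = c(-600, 600),
                            ci_method = "clopper-pearson",
                            write_plates = FALSE,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_gen_spec"))
  assert_count(wells_per_plate, "wells_per_plate", lo = 1)
  structure(list(cohort = cohort,
                 droplets_per_well = as.integer(droplets_per_well),
                 wells_per_plate = as.integer(wells_per_plate),
                 negative_mode = negative_mode,
                 positive_mode = positive_mode,
                 spread_neg = spread_neg, spread_pos = spread_pos,
                 rain_fraction = rain_fraction,
                 well_shift_range = well_shift_range,
                 ci_method = ci_method,
                 write_plates = isTRUE(write_plates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic TriMeth pipeline
#'
#' Simulates a stage-structured plasma cohort, partitions each sample's
#' per-marker methylated templates onto droplet plates, classifies the
#' droplets against each plate's fully methylated positive control,
#' quantifies copies per well by Poisson statistics, applies the locked
#' two-of-three rule, and writes cohort metrics plus a run manifest
#' (thresholds, droplet counts, controls — the digital-PCR reporting
#' fields) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `cohort` (scored sample table),
#'   `metrics` (a [cohort_metrics()] object), `plate_info` (per-plate
#'   thresholds and bandwidths), `load_summary`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort_spec <- config$cohort
  cohort_spec$seed <- derive_seed(config$seed, "cohort")
  truth <- stage("simulate_cohort", generate_cohort(cohort_spec))
  write_cohort(truth, file.path(out_dir, "cohort_truth.csv"))

  markers <- names(cohort_spec$marker_sensitivity)
  est <- matrix(NA_real_, nrow = nrow(truth), ncol = length(markers),
                dimnames = list(truth$sample_id, markers))
  plate_info <- list()
  all_calls <- list()
  stage("call_droplets", {
    for (m in markers) {
      idx_chunks <- split(seq_len(nrow(truth)),
                          ceiling(seq_len(nrow(truth)) /
                                    config$wells_per_plate))
      for (p in seq_along(idx_chunks)) {
        idx <- idx_chunks[[p]]
        copies <- round(truth[[paste0("copies_", m)]][idx])
        names(copies) <- truth$sample_id[idx]
        pspec <- plate_gen_spec(
          true_copies_per_well = copies,
          droplets_per_well = config$droplets_per_well,
          negative_mode = config$negative_mode,
          positive_mode = config$positive_mode,
          spread_neg = config$spread_neg,
          spread_pos = config$spread_pos,
          rain_fraction = config$rain_fraction,
          well_shift_range = config$well_shift_range,
          channel = m,
          seed = derive_seed(config$seed, sprintf("plate-%s-%d", m, p)))
        plate <- generate_plate(pspec)
        if (config$write_plates)
          write_plate(plate, file.path(out_dir,
                                       sprintf("plate_%s_%02d.csv", m, p)))
        res <- call_plate(plate)
        calls <- res$calls
        calls$plate <- sprintf("%s_%02d", m, p)
        all_calls[[length(all_calls) + 1L]] <- calls
        plate_info[[length(plate_info) + 1L]] <- data.frame(
          plate = sprintf("%s_%02d", m, p), marker = m,
          threshold = res$fit$minimum, bandwidth = res$fit$bandwidth,
          neg_median = res$fit$neg_median,
          median_droplets = stats::median(calls$N),
          control_well = plate$control_well)
        test <- calls[calls$well != plate$control_well, ]
        est[test$well, m] <- vapply(seq_len(nrow(test)), function(i)
          poisson_concentration(test$P[i], test$N[i]), numeric(1))
      }
    }
  })

  quant <- stage("quantify", {
    q <- truth[c("sample_id", "cohort", "status", "stage",
                 "cfdna_copies_per_ml", "input_copies")]
    for (m in markers) q[[paste0("copies_", m)]] <- est[, m]
    # methylated fragments per ml: detected copies across both
    # reactions over the effective plasma volume analysed
    eff_ml <- cohort_spec$n_reactions * truth$input_copies /
      (truth$cfdna_copies_per_ml * cohort_spec$bs_recovery)
    q$methylated_per_ml <- rowSums(est) / eff_ml
    q
  })
  utils::write.csv(quant, file.path(out_dir, "quantified.csv"),
                   row.names = FALSE)

  scored <- stage("score", score_cohort(quant, markers))
  metrics <- stage("metrics",
                   cohort_metrics(scored, markers,
                                  ci_method = config$ci_method))
  load_summary <- summarize_methylated_load(
    scored$methylated_per_ml, scored$status,
    seed = derive_seed(config$seed, "load"))

  calls_df <- do.call(rbind, all_calls)
  utils::write.csv(calls_df, file.path(out_dir, "well_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(scored, file.path(out_dir, "scored.csv"),
                   row.names = FALSE)
  plate_df <- do.call(rbind, plate_info)
  metrics_json <- list(
    sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    stage_sensitivity = metrics$stage_sensitivity,
    per_marker = metrics$per_marker,
    load_summary = load_summary)
  jsonlite::write_json(metrics_json, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "trimeth",
    seed = config$seed,
    cohort = list(input_mode = cohort_spec$input_mode,
                  input_copies = cohort_spec$input_copies,
                  plasma_ml = cohort_spec$plasma_ml,
                  n_cases = sum(truth$status == "case"),
                  n_controls = sum(truth$status == "control")),
    droplets_per_well = config$droplets_per_well,
    plates = plate_df,
    controls_per_plate = "positive_control",
    ci_method = config$ci_method)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = scored, metrics = metrics,
                 plate_info = plate_df, load_summary = load_summary,
                 out_dir = out_dir))
}
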