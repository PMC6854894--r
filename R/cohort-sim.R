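#' Specification for a synthetic stage-structured plasma cohort
#'
#' Emulates a case/control liquid-biopsy cohort: per-sample cell-free
#' DNA concentration drawn on the log scale (defaults matched to the
#' reported distribution, median 968 copies/ml spanning roughly
#' 210-23,798), a stage-dependent circulating tumour fraction, and for
#' each of the three panel markers the number of methylated template
#' molecules delivered to a reaction — a Poisson draw with mean
#' `input_copies * tumour_fraction * marker indicator`. Controls carry
#' independent per-marker false-positive signals.
#'
#' @param n_cases_per_stage named integer vector over stages
#'   `I`,`II`,`III`,`IV`.
#' @param n_controls number of control samples.
#' @param cfdna_meanlog,cfdna_sdlog log-normal parameters of cfDNA
#'   copies per ml plasma.
#' @param tumour_fraction_meanlog named per-stage `meanlog` of the
#'   log-normal tumour fraction. Not reported by stage in the source
#'   data; defaults are free parameters chosen so detection rises with
#'   stage in a realistic range (median fractions 0.05-0.5%).
#' @param tumour_fraction_sdlog common `sdlog` of the tumour fraction.
#' @param marker_sensitivity named per-marker probability that a tumour
#'   is methylated at that marker (tissue-level).
#' @param marker_fp_rate named per-marker control false-positive
#'   probability; defaults are the complements of the reported
#'   single-marker specificities 91%, 95% and 99%.
#' @param input_copies bisulfite-converted cfDNA copies delivered per
#'   reaction (fixed-input design, default 4500).
#' @param input_mode `"fixed_input"`: every reaction receives exactly
#'   `input_copies` template equivalents (the test-cohort design).
#'   `"fixed_volume"`: the sample's whole eluate from `plasma_ml` ml of
#'   plasma is split into `n_reactions` reactions, so the per-reaction
#'   input is `cfdna_copies_per_ml * plasma_ml * bs_recovery /
#'   n_reactions` and varies between samples (the validation-cohort
#'   design).
#' @param plasma_ml plasma volume per sample in the fixed-volume design
#'   (default 16).
#' @param bs_recovery fraction of cfDNA copies surviving bisulfite
#'   conversion in the fixed-volume design (default 0.541, the reported
#'   validation-cohort recovery).
#' @param n_reactions reactions the eluate is split into (default 2,
#'   one per duplex).
#' @param seed integer seed.
#' @return an object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_cases_per_stage = c(I = 41, II = 143,
                                                  III = 55, IV = 17),
                            n_controls = 178,
                            cfdna_meanlog = log(968),
                            cfdna_sdlog = 0.85,
                            tumour_fraction_meanlog =
                              log(c(I = 5e-4, II = 1e-3,
                                    III = 2e-3, IV = 5e-3)),
                            tumour_fraction_sdlog = 1.2,
                            marker_sensitivity = c(C9orf50 = 0.97,
                                                   KCNQ5 = 0.97,
                                                   CLIP4 = 0.97),
                            marker_fp_rate = c(C9orf50 = 0.09,
                                               KCNQ5 = 0.05,
                                               CLIP4 = 0.01),
                            input_copies = 4500,
                            input_mode = c("fixed_input", "fixed_volume"),
                            plasma_ml = 16,
                            bs_recovery = 0.541,
                            n_reactions = 2L,
                            seed = 1L) {
  input_mode <- match.arg(input_mode)
  stages <- c("I", "II", "III", "IV")
  if (!all(stages %in% names(n_cases_per_stage)))
    stop("n_cases_per_stage must name stages I-IV", call. = FALSE)
  assert_count(n_controls, "n_controls", lo = 0)
  assert_count(input_copies, "input_copies", lo = 1)
  if (any(marker_fp_rate < 0 | marker_fp_rate > 1) ||
      any(marker_sensitivity < 0 | marker_sensitivity > 1))
    stop("marker rates must lie in [0, 1]", call. = FALSE)
  if (!identical(names(marker_sensitivity), names(marker_fp_rate)))
    stop("marker_sensitivity and marker_fp_rate must name the same markers",
         call. = FALSE)
  structure(list(n_cases_per_stage = n_cases_per_stage[stages],
                 n_controls = as.integer(n_controls),
                 cfdna_meanlog = cfdna_meanlog,
                 cfdna_sdlog = cfdna_sdlog,
                 tumour_fraction_meanlog = tumour_fraction_meanlog[stages],
                 tumour_fraction_sdlog = tumour_fraction_sdlog,
                 marker_sensitivity = marker_sensitivity,
                 marker_fp_rate = marker_fp_rate,
                 input_copies = as.integer(input_copies),
                 input_mode = input_mode,
                 plasma_ml = plasma_ml,
                 bs_recovery = bs_recovery,
                 n_reactions = as.integer(n_reactions),
                 seed = as.integer(seed)),
            class = "cohort_gen_spec")
}

#' Generate a synthetic plasma cohort with per-marker template counts
#'
#' @param spec a [cohort_gen_spec()].
#' @return a data.frame with one row per sample: `sample_id`, `cohort`
#'   (`"synthetic"`), `status` (`case`/`control`), `stage` (`I`-`IV`,
#'   `none` for controls), `cfdna_copies_per_ml`, `tumour_fraction`
#'   (ground truth, 0 for controls), `input_copies`, and one
#'   `copies_<marker>` column per marker holding the methylated template
#'   molecules delivered to the simulated reaction.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  markers <- names(spec$marker_sensitivity)
  stages <- rep(names(spec$n_cases_per_stage),
                times = spec$n_cases_per_stage)
  n_case <- length(stages)
  n <- n_case + spec$n_controls
  with_seed(spec$seed, {
    status <- c(rep("case", n_case), rep("control", spec$n_controls))
    stage <- c(stages, rep("none", spec$n_controls))
    cfdna <- stats::rlnorm(n, spec$cfdna_meanlog, spec$cfdna_sdlog)
    tf <- numeric(n)
    if (n_case > 0)
      tf[seq_len(n_case)] <- stats::rlnorm(
        n_case, spec$tumour_fraction_meanlog[stages],
        spec$tumour_fraction_sdlog)
    input <- if (spec$input_mode == "fixed_input")
      rep(spec$input_copies, n)
    else
      cfdna * spec$plasma_ml * spec$bs_recovery / spec$n_reactions
    counts <- matrix(0L, nrow = n, ncol = length(markers),
                     dimnames = list(NULL, paste0("copies_", markers)))
    for (j in seq_along(markers)) {
      m <- markers[j]
      if (n_case > 0) {
        methylated <- stats::rbinom(n_case, 1L,
                                    spec$marker_sensitivity[[m]])
        lambda <- input[seq_len(n_case)] * tf[seq_len(n_case)] * methylated
        counts[seq_len(n_case), j] <- stats::rpois(n_case, lambda)
      }
      if (spec$n_controls > 0) {
        fp <- stats::rbinom(spec$n_controls, 1L, spec$marker_fp_rate[[m]])
        # a false-positive control carries at least one template molecule
        counts[n_case + seq_len(spec$n_controls), j] <-
          fp * (1L + stats::rpois(spec$n_controls, 0.3))
      }
    }
    out <- data.frame(sample_id = sprintf("P%04d", seq_len(n)),
                      cohort = "synthetic",
                      status = status, stage = stage,
                      cfdna_copies_per_ml = cfdna,
                      tumour_fraction = tf,
                      input_copies = input)
    cbind(out, as.data.frame(counts))
  })
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param file CSV path.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
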