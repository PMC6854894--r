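#' Poisson concentration of target molecules in a well
#'
#' Inverts the Poisson partitioning of template molecules among
#' droplets: with `N` total droplets of which `P` are positive, the
#' expected number of molecules in the well is
#' `c = -N * log(1 - P/N)`.
#'
#' @param call a `well_call` from [call_droplets()], or the number of
#'   positive droplets `P` (with `N` given separately).
#' @param N total droplet count when `call` is numeric.
#' @param conf if non-`NULL`, a confidence level for an interval on the
#'   copies from the standard partition variance
#'   `Var(c) ~ N * p / (1 - p)` with `p = P/N`; off by default.
#' @return copies per well (a single non-negative number), with an
#'   attribute `conf_int` when `conf` is set. Zero exactly when `P = 0`.
#'   A saturated well (`P = N`) is an error: the formula diverges and
#'   the sample must be diluted.
#' @export
poisson_concentration <- function(call, N = NULL, conf = NULL) {
  if (inherits(call, "well_call")) {
    P <- call$P; N <- call$N
  } else {
    P <- call
    if (is.null(N)) stop("N must be supplied when P is given directly",
                         call. = FALSE)
  }
  stopifnot(length(P) == 1L, length(N) == 1L, N > 0, P >= 0, P <= N)
  if (P == N)
    stop(sprintf(
      "well saturated (P = N = %d): concentration diverges; dilute the sample",
      N), call. = FALSE)
  cc <- -N * log1p(-P / N)
  if (!is.null(conf)) {
    p <- P / N
    se <- if (P > 0) sqrt(N * p / (1 - p)) else 0
    z <- stats::qnorm(1 - (1 - conf) / 2)
    attr(cc, "conf_int") <- c(lower = max(0, cc - z * se),
                              upper = cc + z * se)
  }
  cc
}

#' Convert copies per well to copies per millilitre plasma
#'
#' @param c_well copies detected in the well.
#' @param eluate_fraction_analyzed fraction of the sample's eluate that
#'   went into the well, in `(0, 1]`.
#' @param plasma_volume_ml plasma volume the eluate derives from.
#' @return copies per millilitre plasma.
#' @export
copies_per_ml <- function(c_well, eluate_fraction_analyzed,
                          plasma_volume_ml) {
  assert_scalar_num(eluate_fraction_analyzed, "eluate_fraction_analyzed")
  if (eluate_fraction_analyzed <= 0 || eluate_fraction_analyzed > 1)
    stop("eluate_fraction_analyzed must lie in (0, 1]", call. = FALSE)
  if (any(plasma_volume_ml <= 0))
    stop("plasma volume must be positive", call. = FALSE)
  c_well / eluate_fraction_analyzed / plasma_volume_ml
}

#' Native DNA quantity from the two reference assays
#'
#' DNA is quantified by two reference assays on different chromosomes
#' (the cytosine-free CF assay and the Chr3 assay); the reported
#' quantity is their arithmetic mean.
#'
#' @param cf_copies,chr3_copies non-negative copy estimates.
#' @return the mean of the two.
#' @export
native_quantity <- function(cf_copies, chr3_copies) {
  stopifnot(all(cf_copies >= 0), all(chr3_copies >= 0))
  (cf_copies + chr3_copies) / 2
}

#' Recovery after bisulfite conversion
#'
#' The CF assay quantifies DNA irrespective of methylation and
#' bisulfite state, so recovery is the CF quantity after conversion
#' divided by the CF quantity before, as a percentage.
#'
#' @param cf_after,cf_before CF copy estimates after and before
#'   conversion.
#' @return percent recovery.
#' @export
bs_recovery <- function(cf_after, cf_before) {
  stopifnot(all(cf_after >= 0))
  if (any(cf_before <= 0))
    stop("recovery undefined: CF quantity before conversion must be positive",
         call. = FALSE)
  100 * cf_after / cf_before
}

#' Purification efficiency from the CPP1 spike-in
#'
#' A fixed amount of soybean CPP1 DNA fragments is spiked into each
#' plasma sample before extraction; efficiency is the percent recovered.
#'
#' @param cpp1_recovered,cpp1_spiked copy counts.
#' @return percent recovery.
#' @export
purification_efficiency <- function(cpp1_recovered, cpp1_spiked) {
  stopifnot(all(cpp1_recovered >= 0))
  if (any(cpp1_spiked <= 0))
    stop("spiked CPP1 quantity must be positive", call. = FALSE)
  100 * cpp1_recovered / cpp1_spiked
}

#' Lymphocyte DNA contamination flag
#'
#' Positivity of the B-cell (rearranged IGH) assay marks contamination
#' with lymphocyte DNA. Contaminated samples are flagged, never
#' excluded.
#'
#' @param pbc_positive logical.
#' @return a list with `flagged` and `excluded` (always `FALSE`).
#' @export
contamination_flag <- function(pbc_positive) {
  stopifnot(is.logical(pbc_positive), length(pbc_positive) == 1L)
  list(flagged = pbc_positive, excluded = FALSE)
}

#' Plan the ddPCR input for a plasma sample
#'
#' Given a sample's bisulfite-converted cfDNA concentration and the
#' plasma volume available, computes how many reactions of
#' `target_per_reaction` copies the sample supports, whether the
#' per-reaction input clears the configured minimum, and the smallest
#' ctDNA fraction theoretically detectable at that input
#' (`100 / target_per_reaction` percent — one methylated molecule among
#' the input copies).
#'
#' @param bs_cfdna_copies_per_ml copies of BS-cfDNA per ml plasma.
#' @param plasma_ml plasma volume in ml.
#' @param target_per_reaction copies per reaction (default 4500, the
#'   fixed-input design).
#' @param n_reactions number of reactions the material is split into
#'   (default 2, one per duplex).
#' @param min_per_reaction minimum copies per reaction to justify a
#'   negative call (default 5000).
#' @return a list: `total_copies`, `copies_per_reaction`,
#'   `reactions_supported` (at the target input),
#'   `min_detectable_fraction_pct`, `sufficient_input`.
#' @export
plan_input <- function(bs_cfdna_copies_per_ml, plasma_ml,
                       target_per_reaction = 4500,
                       n_reactions = 2L, min_per_reaction = 5000) {
  stopifnot(bs_cfdna_copies_per_ml > 0, plasma_ml > 0,
            target_per_reaction > 0, n_reactions >= 1)
  total <- bs_cfdna_copies_per_ml * plasma_ml
  per_reaction <- total / n_reactions
  list(total_copies = total,
       copies_per_reaction = per_reaction,
       reactions_supported = floor(total / target_per_reaction),
       min_detectable_fraction_pct = 100 / target_per_reaction,
       sufficient_input = per_reaction >= min_per_reaction)
}
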