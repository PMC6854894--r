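#' Specification for a synthetic 450K-style beta-value matrix
#'
#' Describes a group-structured methylation matrix: a handful of "true
#' marker" CpGs that are hypermethylated in CRC tumours and essentially
#' unmethylated in peripheral blood leukocytes (PBL), embedded in
#' background CpGs whose beta values are moderate and group-unspecific.
#' Beta values are drawn from Beta distributions parameterized by mean
#' and concentration (shape1 = mean * conc, shape2 = (1 - mean) * conc).
#'
#' @param n_cpg total number of CpG rows (markers + background).
#' @param group_sizes named integer vector, samples per group; must
#'   include at least `CRC` and `PBL`. Additional names are treated as
#'   other-cancer types except `normal_mucosa`.
#' @param n_markers number of designated true-marker CpGs.
#' @param marker_profile named list mapping group name to
#'   `c(mean, conc)` Beta parameters for marker CpGs. Groups absent from
#'   the list fall back to `background_profile`.
#' @param background_profile named list mapping group name to
#'   `c(mean, conc)` for background CpGs; a `.default` entry covers
#'   unlisted groups.
#' @param seed integer seed; generation is bit-reproducible.
#' @return an object of class `beta_gen_spec`.
#' @details Defaults emulate the marker behaviour reported for the
#'   discovery arrays: marker CpGs with mean beta 0.65 in CRC (so that
#'   essentially all tumours exceed the 0.35 hypermethylation cut) and
#'   essentially zero in PBL (mean 0.005, tightly concentrated, so that
#'   whole PBL panels stay below the 0.05 blood cut); background CpGs
#'   with mean 0.3 in every group, which blood-excludes them.
#' @export
beta_gen_spec <- function(n_cpg = 510,
                          group_sizes = c(CRC = 40, PBL = 40,
                                          normal_mucosa = 10,
                                          breast = 15, lung = 15),
                          n_markers = 10,
                          marker_profile = list(
                            CRC = c(mean = 0.65, conc = 30),
                            PBL = c(mean = 0.005, conc = 200),
                            normal_mucosa = c(mean = 0.05, conc = 30),
                            .default = c(mean = 0.03, conc = 50)),
                          background_profile = list(
                            .default = c(mean = 0.30, conc = 8)),
                          seed = 1L) {
  assert_count(n_cpg, "n_cpg", lo = 1)
  assert_count(n_markers, "n_markers", lo = 0)
  if (n_cpg < n_markers)
    stop("n_cpg must be at least the number of designated markers",
         call. = FALSE)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector", call. = FALSE)
  if (any(group_sizes < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  check_profile <- function(p, what) {
    for (nm in names(p)) {
      m <- p[[nm]][["mean"]]; k <- p[[nm]][["conc"]]
      if (!is.finite(m) || m <= 0 || m >= 1)
        stop(sprintf("%s mean for group '%s' must lie in (0, 1)", what, nm),
             call. = FALSE)
      if (!is.finite(k) || k <= 0)
        stop(sprintf("%s concentration for group '%s' must be positive",
                     what, nm), call. = FALSE)
    }
  }
  check_profile(marker_profile, "marker_profile")
  check_profile(background_profile, "background_profile")
  structure(list(n_cpg = as.integer(n_cpg),
                 group_sizes = group_sizes,
                 n_markers = as.integer(n_markers),
                 marker_profile = marker_profile,
                 background_profile = background_profile,
                 seed = as.integer(seed)),
            class = "beta_gen_spec")
}

profile_for <- function(profile, group) {
  if (!is.null(profile[[group]])) profile[[group]] else profile[[".default"]]
}

#' Generate a synthetic beta-value matrix with planted markers
#'
#' @param spec a [beta_gen_spec()].
#' @return a `beta_matrix` list with elements `values` (CpG x sample
#'   matrix of beta in `[0,1]`), `groups` (named character vector,
#'   sample id -> group label), and `true_markers` (CpG ids of the
#'   planted markers, the ground truth for recovery tests).
#' @export
generate_beta_matrix <- function(spec) {
  stopifnot(inherits(spec, "beta_gen_spec"))
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n_samp <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  names(groups) <- sample_ids
  cpg_ids <- sprintf("cg%08d", seq_len(spec$n_cpg))
  marker_idx <- seq_len(spec$n_markers)

  values <- with_seed(spec$seed, {
    m <- matrix(NA_real_, nrow = spec$n_cpg, ncol = n_samp,
                dimnames = list(cpg_ids, sample_ids))
    for (g in unique(groups)) {
      cols <- which(groups == g)
      bp <- profile_for(spec$background_profile, g)
      m[, cols] <- stats::rbeta(spec$n_cpg * length(cols),
                                bp[["mean"]] * bp[["conc"]],
                                (1 - bp[["mean"]]) * bp[["conc"]])
      if (spec$n_markers > 0) {
        mp <- profile_for(spec$marker_profile, g)
        m[marker_idx, cols] <- stats::rbeta(
          spec$n_markers * length(cols),
          mp[["mean"]] * mp[["conc"]],
          (1 - mp[["mean"]]) * mp[["conc"]])
      }
    }
    m
  })
  new_beta_matrix(values, groups,
                  true_markers = cpg_ids[marker_idx])
}

#' Construct a beta matrix container
#'
#' @param values numeric CpG x sample matrix with row and column names;
#'   all values in `[0,1]`.
#' @param groups named character vector mapping every sample id to one
#'   group label.
#' @param true_markers optional character vector of planted marker CpG
#'   ids (simulation ground truth).
#' @return a `beta_matrix` object.
#' @export
new_beta_matrix <- function(values, groups, true_markers = character()) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop("values must be a matrix with CpG rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate CpG or sample ids", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  if (!setequal(names(groups), colnames(values)))
    stop("groups must label exactly the samples in the matrix",
         call. = FALSE)
  structure(list(values = values,
                 groups = groups[colnames(values)],
                 true_markers = true_markers),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Write / read a beta matrix as tab-delimited text
#'
#' The matrix is written as a TSV with CpG rows and a header of sample
#' ids; group labels go to a sidecar two-column TSV (`sample`, `group`).
#'
#' @param x a `beta_matrix`.
#' @param file path of the matrix TSV; the sidecar gets suffix
#'   `.groups.tsv`.
#' @return `write_beta_matrix`: the input, invisibly.
#'   `read_beta_matrix`: a `beta_matrix`.
#' @export
write_beta_matrix <- function(x, file) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(cpg = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gf <- paste0(file, ".groups.tsv")
  utils::write.table(data.frame(sample = names(x$groups),
                                group = unname(x$groups)),
                     gf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_beta_matrix
#' @param groups_file optional explicit path to the group sidecar.
#' @export
read_beta_matrix <- function(file, groups_file = paste0(file, ".groups.tsv")) {
  if (!file.exists(file))
    stop(sprintf("beta matrix not found: '%s'", file), call. = FALSE)
  df <- utils::read.delim(file, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1L]]
  gdf <- utils::read.delim(groups_file)
  groups <- stats::setNames(as.character(gdf$group), gdf$sample)
  new_beta_matrix(values, groups)
}
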