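# Count strict local maxima/minima of a density evaluated on a grid.
# A flat run (plateau) counts as a single extremum at its midpoint.
grid_extrema <- function(y) {
  d <- diff(y)
  nz <- which(d != 0)
  if (length(nz) < 2L)
    return(list(n_max = 0L, max_idx = integer(),
                n_min = 0L, min_idx = integer()))
  s <- sign(d[nz])
  chg <- which(s[-1L] != s[-length(s)])
  max_idx <- integer(); min_idx <- integer()
  for (j in chg) {
    # extremum spans grid indices (nz[j] + 1) .. nz[j + 1]; midpoint
    pos <- as.integer(floor((nz[j] + 1L + nz[j + 1L]) / 2))
    if (s[j] > 0) max_idx <- c(max_idx, pos) else min_idx <- c(min_idx, pos)
  }
  list(n_max = length(max_idx), max_idx = max_idx,
       n_min = length(min_idx), min_idx = min_idx)
}

count_modes <- function(x, bw, grid_size) {
  dens <- stats::density(x, bw = bw, n = grid_size)
  grid_extrema(dens$y)$n_max
}

#' Fit the positive-control droplet density and locate the threshold
#'
#' Implements the plate-wise threshold definition: a Gaussian kernel
#' density estimate of the fully methylated positive control's droplet
#' amplitudes, at the smallest bandwidth for which the density has
#' exactly two maxima (the negative and positive populations) and one
#' minimum between them. The amplitude at that minimum becomes the
#' classification threshold for every well on the plate, and the median
#' of control droplets below it becomes the normalization reference.
#'
#' The number of maxima of a Gaussian KDE is non-increasing in the
#' bandwidth, so the smallest two-mode bandwidth is found by bisection
#' between an under-smoothed (> 2 modes) and an over-smoothed (<= 2
#' modes) bracket.
#'
#' @param control a `droplet_well` with role `positive_control`.
#' @param grid_size density evaluation grid (default 512 points spanning
#'   the amplitude range plus three bandwidths on each side).
#' @param bandwidth_bounds search interval for the bandwidth; default
#'   1% to 100% of the control amplitude standard deviation.
#' @param rel_tol relative tolerance of the bisection (default 1e-3).
#' @param dip_frac bimodality guard: the density at the minimum must be
#'   below `dip_frac` times the lower of the two maxima, otherwise the
#'   control is rejected as not genuinely bimodal (a unimodal control
#'   can transiently show two shallow ripples during smoothing).
#' @return an object of class `control_density_fit` with elements
#'   `bandwidth`, `bracket_lo` (largest bandwidth checked with > 2
#'   maxima, for tolerance auditing), `eval_grid`, `density`, `maxima`
#'   (two amplitudes), `minimum` (threshold amplitude), `neg_median`,
#'   `well_id`, `channel`.
#' @export
fit_control_density <- function(control, grid_size = 512L,
                                bandwidth_bounds = NULL,
                                rel_tol = 1e-3, dip_frac = 0.5) {
  stopifnot(inherits(control, "droplet_well"))
  if (control$role != "positive_control")
    stop("threshold fitting requires the plate's positive control well",
         call. = FALSE)
  x <- control$amplitudes
  if (length(x) < 10L)
    stop(sprintf("control well '%s' has too few droplets", control$well_id),
         call. = FALSE)
  sdx <- stats::sd(x)
  if (sdx == 0)
    control_failure(control, "zero amplitude spread")
  if (is.null(bandwidth_bounds)) bandwidth_bounds <- c(0.01, 1) * sdx
  h_lo <- bandwidth_bounds[1L]; h_hi <- bandwidth_bounds[2L]
  stopifnot(h_lo > 0, h_hi > h_lo)

  n_lo <- count_modes(x, h_lo, grid_size)
  n_hi <- count_modes(x, h_hi, grid_size)
  if (n_hi > n_lo)
    stop("mode count increased with bandwidth; degenerate control density",
         call. = FALSE)
  if (n_hi > 2)
    control_failure(control, "more than two populations at the largest bandwidth")
  if (n_lo <= 2) {
    # already at most two modes at the lower bound
    if (n_lo == 2) { h <- h_lo; bracket_lo <- NA_real_ }
    else control_failure(control, "unimodal at every bandwidth in bounds")
  } else {
    lo <- h_lo; hi <- h_hi
    while ((hi - lo) / lo > rel_tol) {
      mid <- sqrt(lo * hi)
      if (count_modes(x, mid, grid_size) > 2) lo <- mid else hi <- mid
    }
    h <- hi; bracket_lo <- lo
    if (count_modes(x, h, grid_size) != 2)
      control_failure(control,
                      "mode count skips two; no two-mode bandwidth found")
  }

  dens <- stats::density(x, bw = h, n = grid_size)
  ex <- grid_extrema(dens$y)
  if (ex$n_max != 2)
    control_failure(control, "density is not two-moded at the fitted bandwidth")
  between <- ex$min_idx[ex$min_idx > ex$max_idx[1L] &
                          ex$min_idx < ex$max_idx[2L]]
  if (length(between) != 1L)
    control_failure(control, "no single minimum between the two maxima")
  y_min <- dens$y[between]
  y_max <- dens$y[ex$max_idx]
  if (y_min >= dip_frac * min(y_max))
    control_failure(control, sprintf(
      "populations not separated (dip %.2f of lower maximum)",
      y_min / min(y_max)))
  minimum <- dens$x[between]
  neg <- x[x < minimum]
  if (length(neg) == 0L)
    control_failure(control, "no droplets below the minimum point")
  structure(list(bandwidth = h, bracket_lo = bracket_lo,
                 rel_tol = rel_tol,
                 eval_grid = dens$x, density = dens$y,
                 maxima = dens$x[ex$max_idx], minimum = minimum,
                 neg_median = stats::median(neg),
                 well_id = control$well_id, channel = control$channel),
            class = "control_density_fit")
}

control_failure <- function(control, why) {
  stop(sprintf("control failure in well '%s' (%s): %s",
               control$well_id, control$channel, why), call. = FALSE)
}

#' @export
print.control_density_fit <- function(x, ...) {
  cat(sprintf(paste0("control_density_fit [%s/%s]: bw %.1f, maxima %.0f/",
                     "%.0f, threshold %.1f, neg median %.1f\n"),
              x$well_id, x$channel, x$bandwidth, x$maxima[1L], x$maxima[2L],
              x$minimum, x$neg_median))
  invisible(x)
}

#' Normalize a well to the control's negative-population median
#'
#' Every test well is shifted additively so that the median of its
#' negative population matches the median of the positive control's
#' negative population. A well's own negative population is taken as
#' its droplets below the control-defined minimum point (before
#' shifting); wells where fewer than `min_neg_frac` of droplets fall
#' below that point have no identifiable negative population, are
#' flagged, and are left unshifted.
#'
#' @param well a `droplet_well`.
#' @param fit a [fit_control_density()] result from the same plate and
#'   channel.
#' @param min_neg_frac minimum fraction of droplets below the minimum
#'   needed to identify a negative population (default 0.05).
#' @return a list with `well` (shifted `droplet_well`), `shift`
#'   (additive offset applied), and `flags` (character vector, possibly
#'   `"no_negative_population"`).
#' @export
normalize_well <- function(well, fit, min_neg_frac = 0.05) {
  stopifnot(inherits(well, "droplet_well"),
            inherits(fit, "control_density_fit"))
  neg <- well$amplitudes[well$amplitudes < fit$minimum]
  if (length(neg) < min_neg_frac * length(well$amplitudes)) {
    return(list(well = well, shift = 0,
                flags = "no_negative_population"))
  }
  shift <- fit$neg_median - stats::median(neg)
  out <- well
  out$amplitudes <- well$amplitudes + shift
  list(well = out, shift = shift, flags = character())
}

#' Classify the droplets of a normalized well
#'
#' Droplets with amplitude strictly above the control-defined minimum
#' point are positive; the threshold is identical for all wells of a
#' plate and channel.
#'
#' @param well a normalized `droplet_well` (or the list returned by
#'   [normalize_well()], whose shift and flags are then carried over).
#' @param fit the plate's [fit_control_density()].
#' @param shift,flags normalization metadata recorded on the call when
#'   `well` is a bare `droplet_well`.
#' @return an object of class `well_call`: `well_id`, `channel`, `N`
#'   (total droplets), `P` (positive droplets), `threshold`, `shift`,
#'   `flags`.
#' @export
call_droplets <- function(well, fit, shift = 0, flags = character()) {
  if (is.list(well) && !inherits(well, "droplet_well") &&
      all(c("well", "shift", "flags") %in% names(well))) {
    shift <- well$shift; flags <- well$flags; well <- well$well
  }
  stopifnot(inherits(well, "droplet_well"),
            inherits(fit, "control_density_fit"))
  structure(list(well_id = well$well_id, channel = well$channel,
                 N = length(well$amplitudes),
                 P = sum(well$amplitudes > fit$minimum),
                 threshold = fit$minimum, shift = shift, flags = flags),
            class = "well_call")
}

#' @export
print.well_call <- function(x, ...) {
  cat(sprintf("well_call %s/%s: P = %d of N = %d (threshold %.1f, shift %+.1f)%s\n",
              x$well_id, x$channel, x$P, x$N, x$threshold, x$shift,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"),
                                          "]") else ""))
  invisible(x)
}

#' Call every well of a plate against its positive control
#'
#' Convenience wrapper running [fit_control_density()] on the plate's
#' positive control, then [normalize_well()] and [call_droplets()] on
#' every well.
#'
#' @param plate a `droplet_plate` from [generate_plate()] or
#'   [read_plate()].
#' @param ... passed to [fit_control_density()].
#' @return a list with `fit` (the control fit) and `calls`, a
#'   data.frame with one row per well: `well`, `channel`, `N`, `P`,
#'   `threshold`, `shift`, `flags` (`;`-separated).
#' @export
call_plate <- function(plate, ...) {
  stopifnot(inherits(plate, "droplet_plate"))
  ctrl <- plate$wells[[plate$control_well]]
  if (is.null(ctrl))
    stop(sprintf("control well '%s' not found on plate",
                 plate$control_well), call. = FALSE)
  fit <- fit_control_density(ctrl, ...)
  rows <- lapply(plate$wells, function(w) {
    cl <- call_droplets(normalize_well(w, fit), fit)
    data.frame(well = cl$well_id, channel = cl$channel, N = cl$N,
               P = cl$P, threshold = cl$threshold, shift = cl$shift,
               flags = paste(cl$flags, collapse = ";"))
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(fit = fit, calls = calls)
}
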