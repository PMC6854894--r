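#' Specification for a synthetic ddPCR amplitude plate
#'
#' Emulates a QuantaSoft-style amplitude export: every droplet of every
#' well carries one fluorescence value. Empty droplets scatter around a
#' negative mode, template-occupied droplets around a positive mode, and
#' a small fraction of occupied droplets amplify partially and land
#' uniformly between the modes ("rain"). Each well receives an additive
#' plate-position offset; a fully methylated positive-control well with
#' high template load is always present, as on the study's plates.
#'
#' @param true_copies_per_well named non-negative numeric vector mapping
#'   well id to the number of target molecules loaded into the well.
#' @param droplets_per_well droplets per well; the default matches the
#'   observed median partition count of 16,218.
#' @param negative_mode,positive_mode amplitude modes (arbitrary
#'   fluorescence units) of the empty and occupied populations.
#' @param spread_neg,spread_pos amplitude standard deviations.
#' @param rain_fraction fraction of occupied droplets that amplify
#'   partially; must lie in `[0, 0.05]`.
#' @param well_shift_range length-2 interval from which each well's
#'   additive offset is drawn.
#' @param control_well id of the positive-control well (created with
#'   `control_copies` template molecules if absent from
#'   `true_copies_per_well`).
#' @param control_copies template load of the positive control; default
#'   one molecule per droplet, i.e. ~63% occupancy, giving two ample
#'   populations for density fitting.
#' @param channel channel label written to the export.
#' @param seed integer seed.
#' @return an object of class `plate_gen_spec`.
#' @export
plate_gen_spec <- function(true_copies_per_well,
                           droplets_per_well = 16218L,
                           negative_mode = 2000, positive_mode = 8000,
                           spread_neg = 300, spread_pos = 300,
                           rain_fraction = 0.01,
                           well_shift_range = c(-600, 600),
                           control_well = "CTRL",
                           control_copies = droplets_per_well,
                           channel = "ch1",
                           seed = 1L) {
  if (is.null(names(true_copies_per_well)) ||
      any(!nzchar(names(true_copies_per_well))))
    stop("true_copies_per_well must be a named vector of well ids",
         call. = FALSE)
  if (any(true_copies_per_well < 0))
    stop("true copies must be non-negative", call. = FALSE)
  assert_scalar_num(rain_fraction, "rain_fraction", 0, 0.05)
  assert_count(droplets_per_well, "droplets_per_well", lo = 10)
  if (positive_mode <= negative_mode + 4 * max(spread_neg, spread_pos))
    stop("positive_mode must exceed negative_mode by more than 4 spreads",
         call. = FALSE)
  stopifnot(length(well_shift_range) == 2L,
            well_shift_range[1] <= well_shift_range[2])
  if (!control_well %in% names(true_copies_per_well)) {
    true_copies_per_well <- c(true_copies_per_well,
                              stats::setNames(control_copies, control_well))
  }
  structure(list(true_copies_per_well = true_copies_per_well,
                 droplets_per_well = as.integer(droplets_per_well),
                 negative_mode = negative_mode,
                 positive_mode = positive_mode,
                 spread_neg = spread_neg, spread_pos = spread_pos,
                 rain_fraction = rain_fraction,
                 well_shift_range = well_shift_range,
                 control_well = control_well,
                 channel = channel,
                 seed = as.integer(seed)),
            class = "plate_gen_spec")
}

#' Construct a droplet well
#'
#' @param well_id,channel identifiers.
#' @param amplitudes numeric vector of per-droplet fluorescence values.
#' @param role one of `test`, `positive_control`, `negative_control`,
#'   `no_template_control`.
#' @return a `droplet_well` object.
#' @export
new_droplet_well <- function(well_id, channel, amplitudes,
                             role = c("test", "positive_control",
                                      "negative_control",
                                      "no_template_control")) {
  role <- match.arg(role)
  if (length(amplitudes) == 0L)
    stop(sprintf("well '%s' has no droplets", well_id), call. = FALSE)
  if (any(!is.finite(amplitudes)))
    stop(sprintf("well '%s' has non-finite amplitudes", well_id),
         call. = FALSE)
  structure(list(well_id = well_id, channel = channel,
                 amplitudes = as.numeric(amplitudes), role = role),
            class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("droplet_well %s/%s [%s]: %d droplets, median %.0f\n",
              x$well_id, x$channel, x$role, length(x$amplitudes),
              stats::median(x$amplitudes)))
  invisible(x)
}

# Poisson partitioning: k molecules fall independently and uniformly
# into N droplets; returns the number of occupied droplets.
partition_occupied <- function(k, n_droplets) {
  if (k == 0) return(0L)
  length(unique(sample.int(n_droplets, k, replace = TRUE)))
}

#' Generate a synthetic droplet plate
#'
#' Molecules are assigned to droplets by Poisson partitioning — the same
#' statistical model the downstream concentration formula
#' `c = -N log(1 - P/N)` inverts — so the occupied-droplet fraction of a
#' well with `k` molecules concentrates around `1 - exp(-k/N)`.
#'
#' @param spec a [plate_gen_spec()].
#' @return a `droplet_plate` list: `wells` (named list of
#'   [new_droplet_well()] objects), `truth` (data.frame with per-well
#'   `true_copies`, `occupied` droplets, additive `shift`), `channel`,
#'   and `control_well`.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_gen_spec"))
  ids <- names(spec$true_copies_per_well)
  n <- spec$droplets_per_well
  with_seed(spec$seed, {
    shifts <- stats::runif(length(ids), spec$well_shift_range[1],
                           spec$well_shift_range[2])
    names(shifts) <- ids
    wells <- vector("list", length(ids))
    names(wells) <- ids
    occupied <- integer(length(ids))
    names(occupied) <- ids
    for (w in ids) {
      k <- spec$true_copies_per_well[[w]]
      occ <- partition_occupied(k, n)
      occupied[[w]] <- occ
      amp <- stats::rnorm(n, spec$negative_mode, spec$spread_neg)
      if (occ > 0) {
        pos_idx <- seq_len(occ)   # droplet order is exchangeable
        amp[pos_idx] <- stats::rnorm(occ, spec$positive_mode,
                                     spec$spread_pos)
        n_rain <- stats::rbinom(1L, occ, spec$rain_fraction)
        if (n_rain > 0) {
          rain_idx <- sample(pos_idx, n_rain)
          amp[rain_idx] <- stats::runif(n_rain, spec$negative_mode,
                                        spec$positive_mode)
        }
      }
      role <- if (w == spec$control_well) "positive_control" else "test"
      wells[[w]] <- new_droplet_well(w, spec$channel, amp + shifts[[w]],
                                     role = role)
    }
    structure(list(wells = wells,
                   truth = data.frame(well = ids,
                                      true_copies =
                                        unname(spec$true_copies_per_well),
                                      occupied = unname(occupied),
                                      shift = unname(shifts)),
                   channel = spec$channel,
                   control_well = spec$control_well),
              class = "droplet_plate")
  })
}

#' Write / read a droplet plate as an amplitude CSV
#'
#' One droplet per row with columns `well`, `channel`, `amplitude`,
#' mirroring vendor amplitude exports. The well role is not part of the
#' vendor dialect; `read_plate` takes the control well id explicitly.
#'
#' @param plate a `droplet_plate` (or bare list of `droplet_well`s).
#' @param file CSV path.
#' @export
write_plate <- function(plate, file) {
  wells <- if (inherits(plate, "droplet_plate")) plate$wells else plate
  df <- do.call(rbind, lapply(wells, function(w)
    data.frame(well = w$well_id, channel = w$channel,
               amplitude = w$amplitudes)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(plate)
}

#' @rdname write_plate
#' @param control_well well id of the plate's positive control.
#' @export
read_plate <- function(file, control_well) {
  if (!file.exists(file))
    stop(sprintf("amplitude CSV not found: '%s' (call-droplets stage)",
                 file), call. = FALSE)
  df <- utils::read.csv(file)
  need <- c("well", "channel", "amplitude")
  if (!all(need %in% names(df)))
    stop(sprintf("amplitude CSV '%s' must have columns %s", file,
                 paste(need, collapse = ", ")), call. = FALSE)
  wells <- lapply(split(df, list(df$well, df$channel), drop = TRUE),
                  function(d) {
    role <- if (d$well[1L] == control_well) "positive_control" else "test"
    new_droplet_well(as.character(d$well[1L]), as.character(d$channel[1L]),
                     d$amplitude, role = role)
  })
  names(wells) <- vapply(wells, `[[`, "", "well_id")
  structure(list(wells = wells, truth = NULL,
                 channel = df$channel[1L], control_well = control_well),
            class = "droplet_plate")
}
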