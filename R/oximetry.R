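# Stern-Volmer quenching calibration and lifetime -> oxygen conversion with
# per-timepoint empty-chamber reference normalization.

#' Calibrate the Stern-Volmer quenching constant
#'
#' From lifetimes measured in nitrogen-flushed (0% O2) and air-equilibrated
#' (ambient) environments: `Kq = (tauN - tauA) / (tauA * O2A)`. The unquenched
#' lifetime is the nitrogen reference (`tau0 = tauN`), since at zero oxygen
#' the relation `tau0 = tau * (1 + Kq * O2)` reduces to `tau0 = tauN`.
#' Oxygen is expressed in percent throughout, so `Kq` carries per-percent
#' units.
#'
#' @param tau_n nitrogen-reference lifetime in ns.
#' @param tau_a air-reference lifetime in ns (must be below `tau_n`).
#' @param o2_a ambient oxygen tension in % O2 (default 20.9).
#' @return An object of class `sv_calibration` with fields `kq`, `tau_n`,
#'   `tau_a`, `o2_a`, `tau0`.
#' @export
calibrate_kq <- function(tau_n, tau_a, o2_a = 20.9) {
  stopifnot(tau_a > 0, o2_a > 0)
  if (tau_n <= tau_a)
    stop("calibration error: nitrogen lifetime must exceed air lifetime (quenching shortens tau)")
  structure(list(kq = (tau_n - tau_a) / (tau_a * o2_a),
                 tau_n = tau_n, tau_a = tau_a, o2_a = o2_a, tau0 = tau_n),
            class = "sv_calibration")
}

#' @export
print.sv_calibration <- function(x, ...) {
  cat(sprintf("Stern-Volmer calibration: Kq = %.6f per %% O2 (tauN = %g ns, tauA = %g ns at %g%%)\n",
              x$kq, x$tau_n, x$tau_a, x$o2_a))
  invisible(x)
}

#' Oxygen tension from lifetime
#'
#' `O2 = (tau0 / tau - 1) / Kq`. Negative results (tau above the reference
#' tau0) are returned unclipped and counted in the `n_negative` attribute so
#' reference-drift problems surface in QC rather than being masked.
#'
#' @param tau lifetime in ns (vector or matrix; `NA` passes through).
#' @param calib an `sv_calibration`.
#' @param tau0 unquenched lifetime in ns; defaults to the calibration value,
#'   but during device analysis the per-timepoint empty-chamber value from
#'   [reference_tau0()] supersedes it.
#' @return Oxygen tension in % O2, same shape as `tau`, with attribute
#'   `n_negative`.
#' @export
o2_from_lifetime <- function(tau, calib, tau0 = calib$tau0) {
  stopifnot(inherits(calib, "sv_calibration"), tau0 > 0)
  if (any(tau <= 0, na.rm = TRUE)) stop("lifetime must be positive")
  o2 <- (tau0 / tau - 1) / calib$kq
  attr(o2, "n_negative") <- sum(o2 < 0, na.rm = TRUE)
  o2
}

#' Per-timepoint unquenched lifetime from the empty-chamber reference
#'
#' The mean lifetime over dye-filled chambers without spheroids (`tauE`) is
#' taken as the reading at ambient oxygen for that device and timepoint, so
#' the unquenched lifetime becomes `tau0 = tauE * (1 + Kq * O2A)`. Recomputing
#' this per timepoint cancels any multiplicative lifetime drift common to all
#' chambers (e.g. photoquenching of the small dye volume).
#'
#' @param tau_e empty-chamber mean lifetime in ns.
#' @param calib an `sv_calibration`.
#' @return Unquenched lifetime in ns.
#' @export
reference_tau0 <- function(tau_e, calib) {
  stopifnot(inherits(calib, "sv_calibration"), tau_e > 0)
  tau_e * (1 + calib$kq * calib$o2_a)
}

#' Oxygen map and per-chamber means for one timepoint
#'
#' Computes the empty-chamber reference lifetime (pixel-weighted mean of
#' `tau_phase` over the interiors of all empty chambers), derives the
#' per-timepoint `tau0` via [reference_tau0()], converts every valid pixel to
#' oxygen tension, and aggregates chamber means over interior pixels (within
#' 90% of the chamber radius, excluding wall artifacts).
#'
#' @param lifetimes a `lifetime_image` with `tau_phase` filled.
#' @param chambers a [chamber_map] from [detect_chambers()].
#' @param calib an `sv_calibration`.
#' @param timepoint_min acquisition time recorded in the output (minutes).
#' @param interior_fraction fraction of the chamber radius treated as
#'   interior.
#' @param allow_global_calibration set TRUE to fall back to `calib$tau0` when
#'   the map has no empty chamber; without this flag that situation errors.
#' @return A list with the per-pixel `o2` matrix, `chamber_means` data frame
#'   (chamber_id, occupancy, timepoint_min, mean_o2_pct, n_pixels,
#'   n_negative), and the `tau_e` and `tau0` used.
#' @export
o2_map <- function(lifetimes, chambers, calib, timepoint_min = 0,
                   interior_fraction = 0.9, allow_global_calibration = FALSE) {
  stopifnot(inherits(lifetimes, "lifetime_image"), inherits(chambers, "chamber_map"),
            inherits(calib, "sv_calibration"))
  tau <- lifetimes$tau_phase
  interiors <- .chamber_interiors(chambers, dim(tau), interior_fraction)
  empty <- chambers$chambers$occupancy == "empty"
  if (!any(empty)) {
    if (!allow_global_calibration)
      stop("chamber map labels no empty chamber: supply one or set allow_global_calibration = TRUE to use the global Stern-Volmer tau0")
    tau_e <- NA_real_
    tau0 <- calib$tau0
  } else {
    sel <- interiors %in% chambers$chambers$chamber_id[empty]
    px <- tau[sel & lifetimes$valid_mask]
    if (length(px) == 0L) stop("no valid pixels in empty-chamber interiors")
    tau_e <- mean(px)
    tau0 <- reference_tau0(tau_e, calib)
  }
  o2 <- o2_from_lifetime(tau, calib, tau0 = tau0)
  cm <- chambers$chambers
  res <- lapply(seq_len(nrow(cm)), function(i) {
    sel <- interiors == cm$chamber_id[i] & lifetimes$valid_mask
    vals <- o2[sel]
    data.frame(chamber_id = cm$chamber_id[i], occupancy = cm$occupancy[i],
               timepoint_min = timepoint_min,
               mean_o2_pct = if (length(vals)) mean(vals) else NA_real_,
               n_pixels = length(vals), n_negative = sum(vals < 0))
  })
  list(o2 = o2, chamber_means = do.call(rbind, res), tau_e = tau_e, tau0 = tau0)
}

# Label matrix of chamber interiors (within interior_fraction of the radius).
.chamber_interiors <- function(chambers, shape, interior_fraction) {
  lab <- matrix(0L, shape[1], shape[2])
  cm <- chambers$chambers
  for (i in seq_len(nrow(cm))) {
    d <- .pixel_dist(shape, c(cm$center_row[i], cm$center_col[i]))
    lab[d <= cm$radius_px[i] * interior_fraction] <- cm$chamber_id[i]
  }
  lab
}

#' Run the lifetime -> oxygen conversion over a whole time-lapse series
#'
#' Applies [estimate_lifetimes()] and [o2_map()] at every timepoint of a
#' stack series, recomputing the empty-chamber reference each time.
#'
#' @param stack a [phase_stack_series()].
#' @param chambers a [chamber_map].
#' @param calib an `sv_calibration`.
#' @param ... passed to [o2_map()].
#' @return A list with `chamber_means` (one row per chamber per timepoint) and
#'   `reference` (data frame of per-timepoint tau_e and tau0).
#' @export
analyze_oxygen <- function(stack, chambers, calib, ...) {
  stopifnot(inherits(stack, "phase_stack_series"))
  nt <- dim(stack$intensities)[1]
  means <- vector("list", nt)
  refs <- vector("list", nt)
  for (j in seq_len(nt)) {
    lt <- estimate_lifetimes(stack, j)
    om <- o2_map(lt, chambers, calib, timepoint_min = stack$timepoints[j], ...)
    means[[j]] <- om$chamber_means
    refs[[j]] <- data.frame(timepoint_min = stack$timepoints[j],
                            tau_e_ns = om$tau_e, tau0_ns = om$tau0)
  }
  list(chamber_means = do.call(rbind, means), reference = do.call(rbind, refs))
}
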