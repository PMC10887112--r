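# Forward simulator: scenes, kinetics, and rendering of every input the
# pipeline consumes (phase-step FLIM stacks, brightfield, live/dead channels),
# with ground truth carried alongside so downstream stages have recovery
# targets.

#' Describe a microwell scene
#'
#' A scene is a grid of cylindrical microwells (chambers) etched into the
#' device floor, each either empty (dye only) or holding a single spheroid.
#' Coordinates are pixel units of the rendered image; physical dimensions are
#' micrometres.
#'
#' @param image_shape integer(2), image size as (rows, cols) in pixels.
#' @param pixel_size physical pixel pitch in micrometres per pixel.
#' @param chamber_centers numeric matrix with one `(row, col)` pixel
#'   coordinate per chamber.
#' @param chamber_diameter chamber diameter in micrometres (device design
#'   value, default 200).
#' @param chamber_height chamber depth in micrometres (default 300).
#' @param occupancy character vector, one of `"empty"` or `"spheroid"` per
#'   chamber. Defaults to all empty.
#' @param spheroid_diameter spheroid diameter in micrometres, recycled across
#'   occupied chambers. Must be smaller than `chamber_diameter`.
#' @param rng_seed integer seed recorded with the scene and used by renderers
#'   that draw random numbers.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_shape, pixel_size, chamber_centers,
                         chamber_diameter = 200, chamber_height = 300,
                         occupancy = NULL, spheroid_diameter = 115,
                         rng_seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape > 0L),
            pixel_size > 0, chamber_diameter > 0, chamber_height > 0)
  chamber_centers <- matrix(as.numeric(chamber_centers), ncol = 2L)
  n <- nrow(chamber_centers)
  if (is.null(occupancy)) occupancy <- rep("empty", n)
  stopifnot(length(occupancy) == n, all(occupancy %in% c("empty", "spheroid")))
  spheroid_diameter <- rep_len(as.numeric(spheroid_diameter), n)
  occ <- occupancy == "spheroid"
  if (any(occ) && any(spheroid_diameter[occ] >= chamber_diameter))
    stop("spheroid_diameter must be smaller than chamber_diameter for every occupied chamber")
  if (n > 1L) {
    d <- as.matrix(stats::dist(chamber_centers)) * pixel_size
    diag(d) <- Inf
    if (any(d < chamber_diameter))
      stop("chamber footprints overlap: centers closer than one chamber diameter")
  }
  structure(list(
    image_shape = image_shape, pixel_size = pixel_size,
    chamber_centers = chamber_centers,
    chamber_diameter = chamber_diameter, chamber_height = chamber_height,
    occupancy = occupancy, spheroid_diameter = spheroid_diameter,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

#' Describe the homodyne FD-FLIM acquisition
#'
#' Defaults follow the instrument settings used for ruthenium-dye oximetry:
#' 250 kHz modulation, 16 phase steps, 500 ms exposure, and an hour-long time
#' lapse at 5 min intervals.
#'
#' @param modulation_frequency excitation/gain modulation frequency in Hz.
#' @param n_phase_steps number of equally spaced relative phase steps (>= 3).
#' @param exposure_time exposure per phase step in seconds.
#' @param n_timepoints number of time-lapse frames.
#' @param time_interval minutes between frames.
#' @param photon_budget expected photons per pixel per phase-step frame at the
#'   DC level; `Inf` disables shot noise.
#' @param read_noise_sd additive Gaussian read noise (photon equivalents).
#' @param system_modulation_depth instrument modulation depth in (0, 1].
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(modulation_frequency = 250e3, n_phase_steps = 16L,
                               exposure_time = 0.5, n_timepoints = 13L,
                               time_interval = 5, photon_budget = 1e4,
                               read_noise_sd = 0, system_modulation_depth = 1) {
  stopifnot(modulation_frequency > 0, n_phase_steps >= 3L, exposure_time > 0,
            n_timepoints >= 1L, time_interval > 0, photon_budget > 0,
            read_noise_sd >= 0,
            system_modulation_depth > 0, system_modulation_depth <= 1)
  structure(list(
    modulation_frequency = modulation_frequency,
    n_phase_steps = as.integer(n_phase_steps),
    exposure_time = exposure_time,
    n_timepoints = as.integer(n_timepoints),
    time_interval = time_interval,
    photon_budget = photon_budget,
    read_noise_sd = read_noise_sd,
    system_modulation_depth = system_modulation_depth
  ), class = "acquisition_config")
}

#' Describe chamber oxygen-consumption kinetics
#'
#' Chamber oxygen follows a mono-exponential approach to a plateau after an
#' optional onset delay:
#' `O2(t) = plateau + (initial - plateau) * exp(-rate * max(0, t - delay))`.
#' The default rate is chosen so the untreated trajectory falls from 19.2% to
#' 13.9% O2 over the first 25 minutes.
#'
#' @param o2_initial chamber oxygen tension at t = 0 (% O2).
#' @param o2_plateau asymptotic oxygen tension (% O2).
#' @param rate_constant first-order rate (1/min).
#' @param onset_delay minutes before consumption starts (0 for untreated and
#'   5-FU scenarios; > 0 emulates oligomycin-suppressed respiration).
#' @param tau_e_start device lifetime (ns) read in an air-equilibrated chamber
#'   at the start of the series.
#' @param reference_drift ns lost by the empty-chamber lifetime over the whole
#'   series (applied as a linear, spatially uniform shift of the unquenched
#'   lifetime; exercises the per-timepoint reference normalization).
#' @param gradient_core_fraction oxygen at the spheroid core as a fraction of
#'   the chamber (rim) value; 1 renders a well-mixed chamber.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(o2_initial = 19.2, o2_plateau = 13.8,
                          rate_constant = log(54) / 25, onset_delay = 0,
                          tau_e_start = 371.3, reference_drift = 6.4,
                          gradient_core_fraction = 1) {
  stopifnot(o2_plateau >= 0, o2_plateau <= o2_initial, o2_initial <= 20.9,
            rate_constant >= 0, onset_delay >= 0, tau_e_start > 0,
            gradient_core_fraction > 0, gradient_core_fraction <= 1)
  structure(list(
    o2_initial = o2_initial, o2_plateau = o2_plateau,
    rate_constant = rate_constant, onset_delay = onset_delay,
    tau_e_start = tau_e_start, reference_drift = reference_drift,
    gradient_core_fraction = gradient_core_fraction
  ), class = "kinetics_spec")
}

#' Chamber oxygen tension at a given time
#'
#' @param kinetics a [kinetics_spec()].
#' @param timepoint minutes since chamber sealing (vectorized).
#' @return Oxygen tension in % O2.
#' @export
chamber_o2 <- function(kinetics, timepoint) {
  stopifnot(inherits(kinetics, "kinetics_spec"), all(timepoint >= 0))
  t_eff <- pmax(0, timepoint - kinetics$onset_delay)
  kinetics$o2_plateau +
    (kinetics$o2_initial - kinetics$o2_plateau) * exp(-kinetics$rate_constant * t_eff)
}

# Distance (px) of every pixel center from a point, as a full matrix.
.pixel_dist <- function(shape, center) {
  dr <- (seq_len(shape[1]) - center[1])^2
  dc <- (seq_len(shape[2]) - center[2])^2
  sqrt(outer(dr, dc, `+`))
}

#' Ground-truth oxygen map for a scene at one timepoint
#'
#' Empty chambers hold ambient oxygen (20.9%) at all times; occupied chambers
#' follow the mono-exponential kinetics, optionally with a radial linear ramp
#' inside the spheroid footprint from the chamber value at the rim down to
#' `gradient_core_fraction` of it at the core. Pixels outside every chamber are
#' `NA` (background flag).
#'
#' @param scene a [scene_config()].
#' @param kinetics a [kinetics_spec()] applied to every occupied chamber.
#' @param timepoint minutes since sealing.
#' @return Numeric matrix of % O2 with `NA` background.
#' @export
simulate_oxygen_field <- function(scene, kinetics, timepoint) {
  stopifnot(inherits(scene, "scene_config"), timepoint >= 0)
  o2 <- matrix(NA_real_, scene$image_shape[1], scene$image_shape[2])
  r_ch <- scene$chamber_diameter / 2 / scene$pixel_size
  level <- chamber_o2(kinetics, timepoint)
  for (i in seq_len(nrow(scene$chamber_centers))) {
    d <- .pixel_dist(scene$image_shape, scene$chamber_centers[i, ])
    inside <- d <= r_ch
    if (scene$occupancy[i] == "empty") {
      o2[inside] <- 20.9
    } else {
      o2[inside] <- level
      r_sp <- scene$spheroid_diameter[i] / 2 / scene$pixel_size
      sp <- d <= r_sp
      if (kinetics$gradient_core_fraction < 1 && any(sp)) {
        core <- kinetics$gradient_core_fraction * level
        o2[sp] <- core + (level - core) * d[sp] / r_sp
      }
    }
  }
  o2
}

#' Lifetime of the oxygen-sensitive dye at a given oxygen tension
#'
#' Inverse Stern-Volmer relation: `tau = tau0 / (1 + Kq * O2)`, strictly
#' decreasing in oxygen.
#'
#' @param o2 oxygen tension in % O2 (vector or matrix; `NA` passes through).
#' @param calib an [sv_calibration] from [calibrate_kq()].
#' @param tau0 optional unquenched lifetime (ns) overriding `calib$tau0`, e.g.
#'   a drifted device value.
#' @return Lifetime in ns, same shape as `o2`.
#' @export
lifetime_from_oxygen <- function(o2, calib, tau0 = calib$tau0) {
  stopifnot(inherits(calib, "sv_calibration"), calib$kq > 0, tau0 > 0)
  if (any(o2 < 0, na.rm = TRUE)) stop("oxygen tension must be non-negative")
  tau0 / (1 + calib$kq * o2)
}

# Unquenched device lifetime at time t under linear empty-chamber drift:
# the air-equilibrated reading moves tau_e_start -> tau_e_start - drift over
# [0, t_end], and tau0 scales with it.
.device_tau0 <- function(kinetics, calib, timepoint, t_end) {
  frac <- if (t_end > 0) timepoint / t_end else 0
  tau_e <- kinetics$tau_e_start - kinetics$reference_drift * frac
  tau_e * (1 + calib$kq * calib$o2_a)
}

#' Render a single-timepoint homodyne phase stack
#'
#' The expected intensity at phase step k is
#' `I_k = DC * (1 + m_sys * m(tau) * cos(theta_k - phi(tau)))` with
#' `phi = atan(omega * tau)`, `m = 1/sqrt(1 + (omega * tau)^2)` and
#' `omega = 2 * pi * modulation_frequency`. Phase steps are equally spaced,
#' `theta_k = 2 * pi * k / K`. Poisson shot noise is applied when the photon
#' budget is finite, followed by additive Gaussian read noise; with
#' `photon_budget = Inf` and `read_noise_sd = 0` the stack is noise free.
#' Background pixels (`NA` lifetime) carry zero signal.
#'
#' @param lifetime_map matrix of lifetimes in ns (`NA` = no dye).
#' @param acq an [acquisition_config()].
#' @return Numeric array `(phase_step, row, col)` of photon-equivalent counts.
#' @export
render_phase_stack <- function(lifetime_map, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (any(lifetime_map <= 0, na.rm = TRUE)) stop("lifetimes must be positive where dye is present")
  K <- acq$n_phase_steps
  theta <- 2 * pi * seq_len(K) / K
  omega <- 2 * pi * acq$modulation_frequency
  wt <- omega * lifetime_map * 1e-9
  phi <- atan(wt)
  m <- 1 / sqrt(1 + wt^2)
  dc <- ifelse(is.na(lifetime_map), 0, acq$photon_budget)
  if (!is.finite(acq$photon_budget)) dc <- ifelse(is.na(lifetime_map), 0, 1)
  nr <- nrow(lifetime_map); nc <- ncol(lifetime_map)
  stack <- array(0, dim = c(K, nr, nc))
  m[is.na(m)] <- 0; phi[is.na(phi)] <- 0
  for (k in seq_len(K)) {
    mu <- dc * (1 + acq$system_modulation_depth * m * cos(theta[k] - phi))
    if (is.finite(acq$photon_budget)) {
      mu[] <- stats::rpois(length(mu), mu)
    }
    if (acq$read_noise_sd > 0) {
      mu <- mu + stats::rnorm(length(mu), sd = acq$read_noise_sd)
      mu[mu < 0] <- 0
    }
    stack[k, , ] <- mu
  }
  attr(stack, "phase_angles") <- theta
  stack
}

#' Render a brightfield image of the scene
#'
#' Occupied chambers contain a dark disk of the configured spheroid diameter
#' centred in the chamber on a bright background with mild linear shading and
#' Gaussian noise; empty chambers are indistinguishable from background.
#'
#' @param scene a [scene_config()].
#' @param background_level background intensity in `[0, 1]`.
#' @param spheroid_level disk intensity in `[0, 1]`.
#' @param shading peak-to-peak amplitude of a left-to-right linear shading.
#' @param noise_sd Gaussian noise SD.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_brightfield <- function(scene, background_level = 0.85,
                               spheroid_level = 0.25, shading = 0.03,
                               noise_sd = 0.01) {
  stopifnot(inherits(scene, "scene_config"))
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  img <- matrix(background_level, nr, nc)
  if (shading > 0)
    img <- img + matrix(seq(-shading / 2, shading / 2, length.out = nc),
                        nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(scene$chamber_centers))) {
    if (scene$occupancy[i] != "spheroid") next
    r_sp <- scene$spheroid_diameter[i] / 2 / scene$pixel_size
    d <- .pixel_dist(scene$image_shape, scene$chamber_centers[i, ])
    img[d <= r_sp] <- spheroid_level
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Render a live/dead fluorescence channel pair
#'
#' Places `n_cells` disjoint cell-sized disks within the spheroid footprints
#' of the scene; `round(dead_fraction * n_cells)` emit in the red channel only
#' (dead, ethidium-homodimer-like), the remainder in the green channel only
#' (live, calcein-like). Placement is random sequential with a minimum
#' centre-to-centre spacing of one cell diameter plus two pixels, which
#' guarantees rasterized disks are disjoint even under 8-connectivity.
#'
#' @param scene a [scene_config()] with at least one occupied chamber.
#' @param dead_fraction proportion of dead cells in `[0, 1]`.
#' @param n_cells total number of cells to place (>= 1).
#' @param cell_radius cell disk radius in pixels.
#' @param spot_level,background_level,noise_sd channel rendering parameters.
#' @param max_tries proposal budget for rejection placement before erroring.
#' @return A list with matrices `green` and `red`, ground-truth `live_count`,
#'   `dead_count`, and the placed `centers`.
#' @export
render_viability_pair <- function(scene, dead_fraction, n_cells,
                                  cell_radius = 2, spot_level = 0.9,
                                  background_level = 0.05, noise_sd = 0.02,
                                  max_tries = 5000L * n_cells) {
  stopifnot(inherits(scene, "scene_config"),
            dead_fraction >= 0, dead_fraction <= 1, n_cells >= 1)
  occ <- which(scene$occupancy == "spheroid")
  if (length(occ) == 0L) stop("scene has no spheroid-occupied chamber to place cells in")
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  allowed <- matrix(FALSE, nr, nc)
  for (i in occ) {
    r_sp <- scene$spheroid_diameter[i] / 2 / scene$pixel_size - cell_radius
    d <- .pixel_dist(scene$image_shape, scene$chamber_centers[i, ])
    allowed[d <= r_sp] <- TRUE
  }
  cand <- which(allowed, arr.ind = TRUE)
  if (nrow(cand) == 0L) stop("spheroid footprint too small for the requested cell radius")
  min_d2 <- (2 * cell_radius + 2)^2
  centers <- matrix(NA_real_, n_cells, 2L)
  placed <- 0L
  for (try in seq_len(max_tries)) {
    p <- cand[sample.int(nrow(cand), 1L), ]
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - p[1])^2 + (centers[seq_len(placed), 2] - p[2])^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- p
    if (placed == n_cells) break
  }
  if (placed < n_cells)
    stop(sprintf("could not place %d disjoint cells (placed %d) within the retry budget",
                 n_cells, placed))
  n_dead <- round(dead_fraction * n_cells)
  is_dead <- rep(FALSE, n_cells)
  if (n_dead > 0) is_dead[sample.int(n_cells, n_dead)] <- TRUE
  draw <- function(idx) {
    ch <- matrix(background_level, nr, nc)
    for (i in idx) {
      d <- .pixel_dist(scene$image_shape, centers[i, ])
      ch[d <= cell_radius] <- spot_level
    }
    if (noise_sd > 0) ch <- ch + stats::rnorm(length(ch), sd = noise_sd)
    pmin(pmax(ch, 0), 1)
  }
  list(green = draw(which(!is_dead)), red = draw(which(is_dead)),
       live_count = n_cells - n_dead, dead_count = n_dead, centers = centers)
}

#' Simulate a full time-lapse FD-FLIM device acquisition
#'
#' Renders the complete phase-step stack series for a scene: chamber oxygen
#' follows the kinetics, the dye lifetime follows the inverse Stern-Volmer
#' relation, and a linear empty-chamber lifetime drift (photoquenching-like,
#' common to all chambers) multiplies the unquenched lifetime so that the
#' per-timepoint reference normalization has something real to cancel.
#'
#' @param scene a [scene_config()].
#' @param acq an [acquisition_config()].
#' @param kinetics a [kinetics_spec()].
#' @param calib an [sv_calibration]; defaults to the printed dye calibration
#'   (381/533 ns at 20.9%/0% O2).
#' @param seed integer seed; defaults to `scene$rng_seed`.
#' @return A list of class `flim_device_sim` with the `stack`
#'   ([phase_stack_series]), the `scene`, `acq`, `kinetics`, `calib`, and a
#'   `ground_truth` data frame (chamber_id, timepoint_min, chamber_o2_pct,
#'   tau_ns, occupancy).
#' @export
simulate_device <- function(scene, acq, kinetics,
                            calib = calibrate_kq(533, 381, 20.9),
                            seed = scene$rng_seed) {
  stopifnot(inherits(scene, "scene_config"), inherits(acq, "acquisition_config"),
            inherits(kinetics, "kinetics_spec"))
  set.seed(seed)
  tp <- (seq_len(acq$n_timepoints) - 1L) * acq$time_interval
  t_end <- max(tp)
  K <- acq$n_phase_steps
  arr <- array(0, dim = c(acq$n_timepoints, K, scene$image_shape[1], scene$image_shape[2]))
  gt <- vector("list", acq$n_timepoints)
  for (j in seq_along(tp)) {
    o2 <- simulate_oxygen_field(scene, kinetics, tp[j])
    tau0_dev <- .device_tau0(kinetics, calib, tp[j], t_end)
    tau <- lifetime_from_oxygen(o2, calib, tau0 = tau0_dev)
    arr[j, , , ] <- render_phase_stack(tau, acq)
    lvl <- ifelse(scene$occupancy == "spheroid", chamber_o2(kinetics, tp[j]), 20.9)
    gt[[j]] <- data.frame(
      chamber_id = seq_along(scene$occupancy), timepoint_min = tp[j],
      chamber_o2_pct = lvl,
      tau_ns = tau0_dev / (1 + calib$kq * lvl),
      occupancy = scene$occupancy
    )
  }
  stack <- phase_stack_series(arr, phase_angles = 2 * pi * seq_len(K) / K,
                              modulation_frequency = acq$modulation_frequency,
                              timepoints = tp)
  structure(list(stack = stack, scene = scene, acq = acq, kinetics = kinetics,
                 calib = calib, seed = as.integer(seed),
                 ground_truth = do.call(rbind, gt)),
            class = "flim_device_sim")
}

#' Preset treatment-group kinetics scenarios
#'
#' Returns a kinetics spec plus between-chamber heterogeneity parameters for
#' the three experimental groups. Untreated spheroids fall from 19.2% toward a
#' 13.8% plateau within ~25 min; 5-FU-treated spheroids start near 19.9% and
#' settle at a higher plateau (~15.8%); oligomycin-treated spheroids hold
#' their initial tension for ~20 min (ATP-synthase inhibition) and then
#' decline slowly toward ~14% at 60 min.
#'
#' @param group one of `"untreated"`, `"5FU"`, `"oligomycin"`.
#' @return A list with elements `kinetics` ([kinetics_spec()]), `initial_sd`,
#'   `plateau_sd`, `rate_cv`, and `noise_sd` (per-timepoint measurement noise
#'   in % O2).
#' @export
group_scenario <- function(group = c("untreated", "5FU", "oligomycin")) {
  group <- match.arg(group)
  switch(group,
    untreated = list(
      kinetics = kinetics_spec(o2_initial = 19.2, o2_plateau = 13.8,
                               rate_constant = log(54) / 25, onset_delay = 0),
      initial_sd = 0.4, plateau_sd = 1.0, rate_cv = 0.15, noise_sd = 0.15),
    "5FU" = list(
      kinetics = kinetics_spec(o2_initial = 19.9, o2_plateau = 15.8,
                               rate_constant = log(54) / 25, onset_delay = 0),
      initial_sd = 0.7, plateau_sd = 1.4, rate_cv = 0.20, noise_sd = 0.15),
    oligomycin = list(
      kinetics = kinetics_spec(o2_initial = 19.9, o2_plateau = 13.8,
                               rate_constant = log(6.1 / 0.2) / 40,
                               onset_delay = 20),
      initial_sd = 0.3, plateau_sd = 1.9, rate_cv = 0.25, noise_sd = 0.15))
}

#' Simulate a cohort of per-chamber oxygen time series
#'
#' Draws `n` chambers from a group scenario with between-chamber jitter of the
#' initial tension, plateau and rate, plus per-timepoint measurement noise.
#' This is the series-level counterpart of [simulate_device()] used for group
#' comparison studies where image rendering is unnecessary.
#'
#' @param scenario a [group_scenario()] result (or compatible list).
#' @param n number of chambers.
#' @param timepoints acquisition times in minutes.
#' @param group_label label stored in the output.
#' @param chamber_offset added to chamber ids (keeps ids unique across groups).
#' @return Data frame with columns chamber_id, group, timepoint_min, o2.
#' @export
simulate_oxygen_series <- function(scenario, n, timepoints = seq(0, 60, by = 5),
                                   group_label = "untreated", chamber_offset = 0L) {
  stopifnot(n >= 1)
  base <- scenario$kinetics
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ini <- min(20.9, stats::rnorm(1, base$o2_initial, scenario$initial_sd))
    pla <- max(0, stats::rnorm(1, base$o2_plateau, scenario$plateau_sd))
    pla <- min(pla, ini)
    rate <- base$rate_constant * exp(stats::rnorm(1, 0, scenario$rate_cv))
    k <- kinetics_spec(o2_initial = ini, o2_plateau = pla, rate_constant = rate,
                       onset_delay = base$onset_delay,
                       tau_e_start = base$tau_e_start,
                       reference_drift = base$reference_drift)
    o2 <- chamber_o2(k, timepoints) + stats::rnorm(length(timepoints), 0, scenario$noise_sd)
    out[[i]] <- data.frame(chamber_id = i + chamber_offset, group = group_label,
                           timepoint_min = timepoints, o2 = pmin(pmax(o2, 0), 20.9))
  }
  do.call(rbind, out)
}
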