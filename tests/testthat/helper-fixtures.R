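# Shared fixtures: everything is generated in code, no stored data.

ref_calib <- function() calibrate_kq(533, 381, 20.9)

# Single-timepoint series rendered from a lifetime map.
stack_from_map <- function(tau_map, acq) {
  st <- render_phase_stack(tau_map, acq)
  phase_stack_series(array(st, c(1L, dim(st))), attr(st, "phase_angles"),
                     acq$modulation_frequency, timepoints = 0)
}

# Uniform-lifetime noise-free stack.
uniform_stack <- function(tau_ns, n = 8L, K = 16L, photon_budget = Inf) {
  acq <- acquisition_config(n_phase_steps = K, n_timepoints = 1L,
                            photon_budget = photon_budget)
  stack_from_map(matrix(tau_ns, n, n), acq)
}

# A 2 x 3 grid of 200 um chambers at 4 um/px: top row empty references,
# bottom row spheroid-occupied (the standard device used across tests).
six_chamber_scene <- function(occupancy = c("empty", "empty", "empty",
                                            "spheroid", "spheroid", "spheroid"),
                              spheroid_diameter = 115, seed = 1L) {
  scene_config(c(160L, 240L), pixel_size = 4,
               chamber_centers = rbind(c(45, 45), c(45, 120), c(45, 195),
                                       c(115, 45), c(115, 120), c(115, 195)),
               occupancy = occupancy, spheroid_diameter = spheroid_diameter,
               rng_seed = seed)
}

# Minimal two-chamber scene (one reference, one spheroid) for cheap runs.
two_chamber_scene <- function(seed = 1L) {
  scene_config(c(96L, 168L), pixel_size = 4,
               chamber_centers = rbind(c(48, 48), c(48, 120)),
               occupancy = c("empty", "spheroid"), spheroid_diameter = 115,
               rng_seed = seed)
}

known_chamber_map <- function(scene) {
  cm <- chamber_map(scene$chamber_centers,
                    radius_px = scene$chamber_diameter / 2 / scene$pixel_size,
                    shape = scene$image_shape)
  set_occupancy(cm, scene$occupancy[order(scene$chamber_centers[, 1],
                                          scene$chamber_centers[, 2])])
}
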