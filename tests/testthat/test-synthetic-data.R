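test_that("scene validation rejects overlapping chambers and oversized spheroids", {
  expect_error(scene_config(c(100, 100), 1, rbind(c(30, 30), c(30, 40)),
                            chamber_diameter = 50),
               "overlap")
  expect_error(scene_config(c(100, 100), 1, rbind(c(50, 50)),
                            occupancy = "spheroid", spheroid_diameter = 250),
               "smaller than chamber_diameter")
})

test_that("chamber kinetics hit the printed untreated anchors and limits", {
  kin <- kinetics_spec()  # 19.2 -> 13.8 plateau, rate set so O2(25) = 13.9
  expect_equal(chamber_o2(kin, 0), 19.2)
  expect_equal(chamber_o2(kin, 25), 13.9, tolerance = 1e-12)
  # zero-rate identity
  flat <- kinetics_spec(o2_initial = 18, o2_plateau = 10, rate_constant = 0)
  expect_equal(chamber_o2(flat, c(0, 30, 60)), rep(18, 3))
  # pre-onset identity
  delayed <- kinetics_spec(o2_initial = 19.9, onset_delay = 20)
  expect_equal(chamber_o2(delayed, 10), 19.9)
})

test_that("oxygen field holds ambient in empty chambers and kinetics in occupied ones", {
  scene <- six_chamber_scene()
  kin <- kinetics_spec()
  for (tp in c(0, 25, 60)) {
    o2 <- simulate_oxygen_field(scene, kin, tp)
    lab <- known_chamber_map(scene)$label_image
    expect_true(all(o2[lab %in% 1:3] == 20.9))
    expect_equal(unique(o2[lab %in% 4:6]), chamber_o2(kin, tp))
    expect_true(all(is.na(o2[lab == 0])))
  }
  # radial gradient: core carries the configured fraction of the rim value
  king <- kinetics_spec(gradient_core_fraction = 0.5)
  o2g <- simulate_oxygen_field(scene, king, 0)
  center <- scene$chamber_centers[4, ]
  expect_equal(o2g[center[1], center[2]], 0.5 * 19.2, tolerance = 1e-12)
})

test_that("lifetime_from_oxygen follows the inverse Stern-Volmer relation", {
  calib <- ref_calib()
  expect_equal(lifetime_from_oxygen(0, calib), calib$tau0)
  expect_equal(lifetime_from_oxygen(20.9, calib), 381, tolerance = 1e-12)
  # direct formula oracle at the reference-normalized tau0
  expect_equal(lifetime_from_oxygen(13.9, calib, tau0 = 519.4),
               519.4 / (1 + calib$kq * 13.9))
  expect_equal(lifetime_from_oxygen(13.9, calib, tau0 = 519.4), 410.5,
               tolerance = 1e-3)
  expect_error(lifetime_from_oxygen(-1, calib), "non-negative")
  # strictly decreasing in O2
  o2 <- seq(0, 20.9, length.out = 50)
  expect_true(all(diff(lifetime_from_oxygen(o2, calib)) < 0))
})

test_that("oxygen -> lifetime -> oxygen round trip is the identity", {
  calib <- ref_calib()
  set.seed(42)
  for (kq in c(0.005, calib$kq, 0.1)) {
    cal <- calibrate_kq(400 * (1 + kq * 20.9), 400, 20.9)
    o2 <- runif(100, 0, 20.9)
    tau <- lifetime_from_oxygen(o2, cal)
    back <- o2_from_lifetime(tau, cal)
    expect_equal(as.vector(back), o2, tolerance = 1e-12)
  }
})

test_that("rendered phase stacks follow the homodyne model exactly when noise free", {
  acq <- acquisition_config(photon_budget = Inf, n_timepoints = 1L)
  omega <- 2 * pi * acq$modulation_frequency
  for (tau in c(381, 533)) {
    st <- render_phase_stack(matrix(tau, 2, 2), acq)
    theta <- attr(st, "phase_angles")
    phi <- atan(omega * tau * 1e-9)
    m <- 1 / sqrt(1 + (omega * tau * 1e-9)^2)
    expect_equal(st[, 1, 1], 1 + m * cos(theta - phi), tolerance = 1e-12)
  }
  # zero-lifetime limit: in phase with excitation, full modulation
  expect_equal(atan(omega * 0), 0)
  # background pixels carry zero signal
  st <- render_phase_stack(matrix(c(400, NA), 1, 2), acq)
  expect_true(all(st[, 1, 2] == 0))
})

test_that("brightfield renders disks of the configured area and leaves empty chambers blank", {
  set.seed(5)
  sc <- scene_config(c(260, 260), 1, rbind(c(130, 130)), occupancy = "spheroid",
                     spheroid_diameter = 114.9)
  bf <- render_brightfield(sc, noise_sd = 0)
  dark <- sum(bf < 0.5)
  expect_lt(abs(dark - pi * (114.9 / 2)^2), 2 * pi * 114.9 / 2 + 10)  # rim rasterization
  # empty chamber indistinguishable from background
  sc0 <- scene_config(c(260, 260), 1, rbind(c(130, 130)))
  bf0 <- render_brightfield(sc0)
  lab <- known_chamber_map(sc0)$label_image
  expect_lt(abs(mean(bf0[lab == 1]) - mean(bf0[lab == 0])), 0.02)
  # degenerate one-pixel disk
  sc1 <- scene_config(c(21, 21), 1, rbind(c(11, 11)), occupancy = "spheroid",
                      spheroid_diameter = 1)
  bf1 <- render_brightfield(sc1, noise_sd = 0, shading = 0)
  expect_equal(sum(bf1 < 0.5), 1)
})

test_that("viability pair honours the rounding rule and the degenerate fractions", {
  sc <- scene_config(c(260, 260), 1, rbind(c(130, 130)), occupancy = "spheroid",
                     spheroid_diameter = 160)
  set.seed(1)
  vp <- render_viability_pair(sc, 0.02, 200)
  expect_equal(vp$dead_count, 4)   # round(0.02 * 200)
  expect_equal(vp$live_count, 196)
  set.seed(2)
  vp0 <- render_viability_pair(sc, 0, 30)
  expect_lt(diff(range(vp0$red)), 0.25)  # background only
  set.seed(3)
  vp1 <- render_viability_pair(sc, 1, 30)
  expect_lt(diff(range(vp1$green)), 0.25)
  expect_error(render_viability_pair(six_chamber_scene(rep("empty", 6)), 0.5, 10),
               "no spheroid")
})

test_that("simulated devices emit ground truth alongside the images", {
  scene <- two_chamber_scene()
  acq <- acquisition_config(n_timepoints = 3L, photon_budget = Inf)
  sim <- simulate_device(scene, acq, kinetics_spec(), seed = 1)
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 2 * 3)
  expect_equal(sort(unique(gt$timepoint_min)), c(0, 5, 10))
  expect_true(all(gt$chamber_o2_pct[gt$occupancy == "empty"] == 20.9))
  expect_equal(gt$chamber_o2_pct[gt$occupancy == "spheroid" & gt$timepoint_min == 0],
               19.2)
})
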