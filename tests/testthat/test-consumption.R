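test_that("series assembly keeps spheroid chambers only and flags missing timepoints", {
  tp <- seq(0, 60, by = 5)
  cm <- rbind(
    data.frame(chamber_id = 1, occupancy = "empty", timepoint_min = tp,
               mean_o2_pct = 20.9),
    data.frame(chamber_id = 2, occupancy = "spheroid", timepoint_min = tp,
               mean_o2_pct = 19 - tp / 20),
    data.frame(chamber_id = 3, occupancy = "spheroid", timepoint_min = tp[-4],
               mean_o2_pct = 19 - tp[-4] / 20))
  s <- assemble_series(cm, groups = c("2" = "untreated", "3" = "5FU"))
  expect_equal(sort(unique(s$chamber_id)), c(2, 3))
  expect_equal(range(s$timepoint_min), c(0, 60))  # hour-long span
  expect_equal(attr(s, "incomplete"), 3L)
  expect_equal(sum(s$chamber_id == 3), 12)
  # all-empty device -> empty result
  s0 <- assemble_series(cm[cm$occupancy == "empty", ])
  expect_equal(nrow(s0), 0)
})

test_that("consumption metrics recover closed-form cases", {
  tp <- seq(0, 60, by = 5)
  # constant series: no consumption
  m0 <- compute_metrics(rep(20.9, 13), tp)
  expect_equal(m0$initial_rate, 0)
  expect_equal(m0$total_drop, 0)
  # exact linear ramp over the rate window
  ramp <- 19 - 0.2 * tp
  expect_equal(compute_metrics(ramp, tp)$initial_rate, 0.2)
  # untreated mono-exponential: plateau and settling match the printed phases
  kin <- kinetics_spec()
  m <- compute_metrics(chamber_o2(kin, tp), tp)
  expect_equal(m$plateau_o2, 13.8, tolerance = 0.05)
  expect_lte(m$time_to_plateau, 30)
  expect_false(m$censored)
  expect_error(compute_metrics(rep(19, 5), seq(0, 20, 5)), "too short")
})

test_that("metrics are invariant to a time-origin shift", {
  tp <- seq(0, 60, by = 5)
  o2 <- chamber_o2(kinetics_spec(), tp)
  a <- compute_metrics(o2, tp)
  b <- compute_metrics(o2, tp + 37)
  expect_equal(b$initial_rate, a$initial_rate)
  expect_equal(b$plateau_o2, a$plateau_o2)
  expect_equal(b$total_drop, a$total_drop)
  expect_equal(b$time_to_plateau, a$time_to_plateau + 37)
})

test_that("molar rate converts units correctly and is linear in volume", {
  expect_equal(molar_rate(0, 9.4), 0)
  expect_equal(molar_rate(0.209, 9.4, 200), 1.88e-14, tolerance = 1e-3)
  expect_equal(molar_rate(0.15, 2 * 9.4), 2 * molar_rate(0.15, 9.4))
})

test_that("group comparison is symmetric and degenerate on identical groups", {
  set.seed(10)
  a <- simulate_oxygen_series(group_scenario("untreated"), 5)
  b <- simulate_oxygen_series(group_scenario("5FU"), 5, chamber_offset = 100)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ba$t, -ab$t)
  expect_equal(ba$p, ab$p)
  same <- compare_groups(a, a)
  expect_true(all(abs(same$t) < 1e-12))
  expect_true(all(same$p > 0.999))
  expect_false(any(same$significant))
  expect_error(compare_groups(a[a$chamber_id == 1, ], b), "at least 2 series")
})

test_that("a 2% O2 separation at SD 0.5 and n = 10 is detected with high power", {
  set.seed(20)
  hits <- replicate(200, {
    a <- data.frame(chamber_id = 1:10, timepoint_min = 0, o2 = rnorm(10, 15, 0.5))
    b <- data.frame(chamber_id = 1:10, timepoint_min = 0, o2 = rnorm(10, 17, 0.5))
    compare_groups(a, b)$significant
  })
  expect_gte(mean(hits), 0.95)
})

test_that("untreated vs oligomycin differs mid-run but converges by an hour", {
  set.seed(11)
  unt <- simulate_oxygen_series(group_scenario("untreated"), 8,
                                group_label = "untreated")
  oli <- simulate_oxygen_series(group_scenario("oligomycin"), 8,
                                group_label = "oligomycin", chamber_offset = 100)
  cmp <- compare_groups(unt, oli)
  expect_true(cmp$significant[cmp$timepoint_min == 20])
  expect_false(cmp$significant[cmp$timepoint_min == 60])
  # oligomycin holds near its initial tension through the onset delay
  expect_gt(cmp$mean_b[cmp$timepoint_min == 20], 19)
})

test_that("simulator-fed metrics recover ground-truth plateau and rate", {
  tp <- seq(0, 60, by = 5)
  kin <- kinetics_spec()
  # noise-free trajectory
  m <- compute_metrics(chamber_o2(kin, tp), tp)
  expect_lt(abs(m$plateau_o2 - kin$o2_plateau), 0.2)
  # initial rate vs the secant slope of the true curve over the same window
  true_slope <- -(chamber_o2(kin, 20) - chamber_o2(kin, 0)) / 20
  expect_lt(abs(m$initial_rate - true_slope) / true_slope, 0.10)
  # replicate noisy chambers stay within Monte-Carlo bounds
  set.seed(30)
  s <- simulate_oxygen_series(group_scenario("untreated"), 50)
  mm <- metrics_by_chamber(s)
  expect_lt(abs(mean(mm$plateau_o2) - 13.8), 0.5)
})
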