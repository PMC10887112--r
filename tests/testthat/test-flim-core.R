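test_that("demodulation recovers phase and modulation exactly on noise-free input", {
  omega <- 2 * pi * 250e3
  for (tau in c(381, 533)) {
    ph <- demodulate(uniform_stack(tau, n = 4))
    expect_equal(ph$phase[1, 1], atan(omega * tau * 1e-9), tolerance = 1e-12)
    expect_equal(ph$modulation[1, 1], 1 / sqrt(1 + (omega * tau * 1e-9)^2),
                 tolerance = 1e-12)
  }
})

test_that("unmodulated and all-zero pixels are flagged invalid", {
  arr <- array(0, c(1, 8, 2, 2))
  arr[1, , 1, 1] <- 5       # constant: no modulation
  arr[1, , 2, 2] <- 3 * (1 + cos(2 * pi * (1:8) / 8 - 0.4))
  s <- phase_stack_series(arr, 2 * pi * (1:8) / 8, 250e3, 0)
  ph <- demodulate(s)
  expect_equal(ph$modulation[1, 1], 0, tolerance = 1e-12)
  expect_false(ph$valid[1, 2])  # all-zero pixel
  expect_false(ph$valid[2, 1])
  lt <- lifetime_from_phase(ph, 250e3)
  expect_false(lt$valid_mask[1, 1])  # phi = 0 -> invalid, not silently zeroed
  expect_true(is.na(lt$tau_phase[1, 1]))
  expect_error(
    phase_stack_series(array(1, c(1, 2, 2, 2)), c(0, pi), 250e3, 0) |>
      demodulate(),
    "at least 3")
})

test_that("simulate -> demodulate -> lifetime round trip is exact for any K and tau", {
  omega <- 2 * pi * 250e3
  for (K in c(3L, 4L, 8L, 16L)) {
    for (tau in c(50, 200, 381, 533, 1000)) {
      s <- uniform_stack(tau, n = 3, K = K)
      lt <- estimate_lifetimes(s)
      expect_lt(abs(lt$tau_phase[1, 1] - tau) / tau, 1e-6)
      # phasor on the universal semicircle: tau_mod agrees with tau_phase
      expect_lt(abs(lt$tau_mod[1, 1] - lt$tau_phase[1, 1]) / tau, 0.01)
    }
  }
})

test_that("lifetime formulas match their closed-form oracles", {
  omega <- 2 * pi * 250e3
  mk_phasor <- function(phase, modulation) {
    structure(list(phase = matrix(phase, 1, 1),
                   modulation = matrix(modulation, 1, 1),
                   dc = matrix(1, 1, 1), valid = matrix(TRUE, 1, 1)),
              class = "phasor_image")
  }
  expect_equal(lifetime_from_phase(mk_phasor(0.5394, 0.9), 250e3)$tau_phase[1, 1],
               tan(0.5394) / omega * 1e9)
  expect_equal(lifetime_from_phase(mk_phasor(0.5394, 0.9), 250e3)$tau_phase[1, 1],
               381, tolerance = 1e-3)
  expect_equal(lifetime_from_phase(mk_phasor(0.6970, 0.9), 250e3)$tau_phase[1, 1],
               533, tolerance = 1e-3)
  expect_equal(lifetime_from_modulation(mk_phasor(0.1, 0.8581), 250e3)$tau_mod[1, 1],
               381, tolerance = 0.1)
  expect_equal(lifetime_from_modulation(mk_phasor(0.1, 0.7668), 250e3)$tau_mod[1, 1],
               533, tolerance = 0.1)
  # unmodulated-lifetime limit: m = 1 -> tau = 0, flagged
  lm1 <- lifetime_from_modulation(mk_phasor(0.1, 1), 250e3)
  expect_equal(lm1$tau_mod[1, 1], 0)
  expect_false(lm1$valid_mask[1, 1])
})

test_that("demodulation is linear: intensity scaling leaves phase and modulation fixed", {
  set.seed(7)
  s <- uniform_stack(420, n = 4, photon_budget = 5e3)
  ph1 <- demodulate(s)
  s2 <- s
  s2$intensities <- s$intensities * 3.7
  ph2 <- demodulate(s2)
  expect_equal(ph2$phase, ph1$phase, tolerance = 1e-12)
  expect_equal(ph2$modulation, ph1$modulation, tolerance = 1e-12)
  expect_equal(ph2$dc, ph1$dc * 3.7, tolerance = 1e-12)
})

test_that("per-pixel lifetime is unbiased and its spread shrinks with photon budget", {
  set.seed(123)
  # 1024 pixel replicates at each budget
  sds <- sapply(c(1e3, 1e4, 1e5), function(b) {
    lt <- estimate_lifetimes(uniform_stack(400, n = 32, photon_budget = b))
    c(sd = qc_lifetime_field(lt), mean = mean(lt$tau_phase, na.rm = TRUE))
  })
  expect_true(all(diff(sds["sd", ]) < 0))
  # unbiased within Monte-Carlo error at 1e4 (SE ~ 3.7/32 ns)
  expect_lt(abs(sds["mean", 2] - 400), 1)
})

test_that("field deviation statistic matches population-SD arithmetic", {
  lt <- structure(list(tau_phase = matrix(c(381, 533), 2, 2), tau_mod = NULL,
                       valid_mask = matrix(TRUE, 2, 2)),
                  class = "lifetime_image")
  expect_equal(qc_lifetime_field(lt), 76)  # (533 - 381) / 2
  # noise-free uniform field -> 0
  expect_equal(qc_lifetime_field(estimate_lifetimes(uniform_stack(400, n = 3))), 0,
               tolerance = 1e-9)
  expect_error(qc_lifetime_field(lt, mask = matrix(FALSE, 2, 2)), "2 valid pixels")
})

test_that("square binning trades resolution for photons", {
  set.seed(5)
  s <- uniform_stack(400, n = 32, photon_budget = 200)
  lt1 <- estimate_lifetimes(s)
  lt4 <- estimate_lifetimes(s, binning = 4L)
  expect_equal(dim(lt4$tau_phase), c(8L, 8L))
  expect_lt(qc_lifetime_field(lt4), qc_lifetime_field(lt1))
})
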