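test_that("arrival detection finds the first zero-crossing after threshold", {
  fs <- 125
  t <- seq(0, 20, by = 1 / fs)
  spec <- excitation_spec("tone_burst", freq_mhz = 0.8)
  delay <- 7.3
  w <- qusfat:::excitation_amplitude(spec, t - delay)
  attr(w, "sample_rate_msps") <- fs
  t0 <- detect_arrival(synth_excitation(spec))
  expect_equal(detect_arrival(w) - t0, delay, tolerance = 0.02)

  # shift equivariance: k extra samples of zeros move the arrival by k/fs
  k <- 40L
  w2 <- c(numeric(k), as.numeric(w))
  attr(w2, "sample_rate_msps") <- fs
  expect_equal(detect_arrival(w2) - detect_arrival(w), k / fs,
               tolerance = 1e-9)

  expect_error(detect_arrival(numeric(100), sample_rate_msps = fs),
               "identically zero")
  expect_error(detect_arrival(w, threshold_fraction = 1.2), "in \\(0, 1\\)")
})

test_that("velocity follows L/(t - dt) with offset cancellation", {
  expect_equal(compute_velocity(80, 52.632), 1520, tolerance = 1e-4)
  expect_equal(compute_velocity(80, 53.632, 1), 1520, tolerance = 1e-4)
  expect_error(compute_velocity(80, 1, 2), "exceed")
  expect_error(compute_velocity(-80, 1), "positive")
})

test_that("window intensity equals the brute-force rectified sum", {
  set.seed(1)
  w <- rnorm(200)
  win <- window_spec(17, 130)
  brute <- 0
  for (i in 17:129) brute <- brute + abs(w[i])
  expect_equal(window_intensity(w, win), brute)
  expect_equal(window_intensity(numeric(50), window_spec(1, 51)), 0)
  expect_equal(window_intensity(c(0, 3, 0), window_spec(2, 3)), 3)
  expect_error(window_spec(5, 5), "start < end")
  expect_error(window_intensity(w, window_spec(190, 220)), "past the end")
})

test_that("attenuation follows 20 log10(I0/I1)/L", {
  expect_equal(compute_attenuation(5, 5, 8), 0)
  expect_equal(compute_attenuation(10, 1, 8), 2.5)
  expect_error(compute_attenuation(0, 1, 8), "positive")
  expect_error(compute_attenuation(1, -1, 8), "positive")
})

test_that("noise-free extraction recovers the generating parameters", {
  m0 <- noise_free(acoustic_model())
  g <- phantom_grid()
  calib <- calibration_record(default_excitations(), m0)
  for (id in c("S00_I00", "S50_I50", "S25_I12")) {
    ph <- g[g$phantom_id == id, ]
    rec <- extract_criteria(simulate_train(ph, m0, 1, 1), calib)
    p <- qusfat:::model_params(m0, ph$sat_pct, ph$imat_pct)
    expect_equal(rec$cr1, p$velocity, tolerance = 1e-3)
    expect_equal(rec$cr2, p$att_08, tolerance = 5e-3)
    expect_equal(rec$cr3, p$att_22, tolerance = 5e-3)
    expect_equal(rec$cr4, rec$cr2 / rec$cr3)   # definitional identity
    expect_gt(rec$cr6, 1)                      # triple pass loses more energy
  }
})

test_that("extraction is scale-covariant", {
  m0 <- noise_free(acoustic_model())
  tr <- simulate_train(phantom_grid()[13, ], m0, 1, 1)
  calib <- calibration_record(default_excitations(), m0)
  a <- extract_criteria(tr, calib)
  tr2 <- tr
  for (wn in c("waveform_08", "waveform_22", "waveform_sweep")) {
    at <- attributes(tr2[[wn]])
    tr2[[wn]] <- tr2[[wn]] * 3.7
    attributes(tr2[[wn]]) <- at
  }
  b <- extract_criteria(tr2, calib)
  expect_equal(b$cr1, a$cr1)                    # timing unchanged
  expect_equal(b$cr6, a$cr6, tolerance = 1e-12) # intensity ratio
  expect_equal(b$cr5, a$cr5 * 3.7, tolerance = 1e-12) # linear in amplitude
  # the attenuation ratio is gain-invariant only when the calibration
  # intensities are measured at the same receiver gain
  calib2 <- calib
  for (cn in c("burst_08", "burst_22", "sweep"))
    calib2[[cn]]$I0 <- calib2[[cn]]$I0 * 3.7
  b2 <- extract_criteria(tr2, calib2)
  expect_equal(b2$cr4, a$cr4, tolerance = 1e-9)
  expect_equal(b2$cr2, a$cr2, tolerance = 1e-9)
})
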