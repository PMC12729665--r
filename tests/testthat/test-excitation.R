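test_that("tone bursts have the prescribed duration and zero-amplitude ends", {
  spec <- excitation_spec("tone_burst", freq_mhz = 0.8)
  w <- synth_excitation(spec)
  # 2 cycles / 0.8 MHz = 2.5 us at 125 Msps -> 313 samples (+/- 1)
  expect_equal(spec$duration_us, 2.5)
  expect_lte(abs(length(w) - 313), 1)
  expect_equal(w[1], 0)
  # the half-sine envelope vanishes exactly at both ends of the burst
  ends <- qusfat:::excitation_amplitude(spec, c(0, spec$duration_us))
  expect_equal(ends, c(0, 0), tolerance = 1e-12)
  expect_equal(max(abs(w)), 1)
})

test_that("sweep energy is concentrated in the 0.5-2.5 MHz band", {
  spec <- excitation_spec("sweep")
  w <- synth_excitation(spec)
  sp <- spectrum_mag(w)
  band <- sp$freq_mhz >= 0.4 & sp$freq_mhz <= 2.6
  expect_gt(sum(sp$magnitude[band]^2) / sum(sp$magnitude^2), 0.95)
})

test_that("spectra behave like a DFT should", {
  spec <- excitation_spec("tone_burst", freq_mhz = 0.8)
  w <- synth_excitation(spec)
  sp <- spectrum_mag(w)
  expect_equal(sp$freq_mhz[which.max(sp$magnitude)], 0.8, tolerance = 0.25)
  # Parseval: sum |X|^2 = n * sum |x|^2 (full spectrum, via symmetry)
  n <- length(w)
  full <- Mod(stats::fft(as.numeric(w)))^2
  expect_equal(sum(full), n * sum(w^2), tolerance = 1e-8)
  expect_true(all(spectrum_mag(numeric(8), 125)$magnitude == 0))
})

test_that("excitation specs validate their inputs", {
  expect_error(excitation_spec("tone_burst", freq_mhz = 0.8,
                               sample_rate_msps = 5), "10x")
  expect_error(excitation_spec("sweep", range_mhz = c(2.5, 0.5)), "increasing")
})
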