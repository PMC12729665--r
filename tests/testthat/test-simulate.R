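model0 <- noise_free(acoustic_model())
grid <- phantom_grid()

test_that("noise-free direct arrival matches the closed-form delay", {
  tr <- simulate_train(grid[grid$phantom_id == "S00_I00", ], model0, 1, 1)
  t_arr <- detect_arrival(tr$waveform_08)
  calib <- calibration_record(default_excitations(), model0)
  onset <- t_arr - calib$burst_08$t0_us
  expect_equal(onset, 80 / 1589 * 1000, tolerance = 0.02)  # 50.35 us

  tr2 <- simulate_train(grid[grid$phantom_id == "S50_I50", ], model0, 1, 1)
  onset2 <- detect_arrival(tr2$waveform_08) - calib$burst_08$t0_us
  expect_equal(onset2, 80 / (1589 - 155.9 * 0.75) * 1000, tolerance = 0.02)
})

test_that("simulation is deterministic and substream-stable", {
  m <- acoustic_model()
  a <- simulate_train(grid[7, ], m, 3, 11)
  b <- simulate_train(grid[7, ], m, 3, 11)
  expect_identical(a$waveform_sweep, b$waveform_sweep)
  expect_identical(a$waveform_08, b$waveform_08)
  # a record does not depend on which other phantoms are simulated
  r_all <- simulate_records(grid[1:4, ], m, repeats = 2, seed = 5)
  r_sub <- simulate_records(grid[2, ], m, repeats = 2, seed = 5)
  expect_equal(r_sub[, paste0("cr", 1:6)],
               r_all[r_all$phantom_id == r_sub$phantom_id[1], paste0("cr", 1:6)],
               ignore_attr = TRUE)
})

test_that("dataset generation yields phantoms x repeats records", {
  man <- dataset_manifest(phantom_grid(levels = c(0, 50)), repeats = 3,
                          seed = 2, model = model0)
  ds <- generate_dataset(man)
  expect_length(ds$trains, 12L)
  expect_equal(nrow(ds$truth), 12L)
  expect_equal(ds$truth$signal_number, 1:12)

  one <- generate_dataset(dataset_manifest(grid[1, ], repeats = 1, seed = 2,
                                           model = model0))
  expect_length(one$trains, 1L)
})

test_that("the sweep waveform always contains the triple-pass arrival", {
  tr <- simulate_train(grid[25, ], model0, 1, 1)
  C <- 1589 - 155.9 * 0.75
  t3 <- 3 * 80 / C * 1000
  n_needed <- (t3 + 10) * tr$sample_rate_msps
  expect_gt(length(tr$waveform_sweep), n_needed)
})

test_that("model validation rejects unphysical configurations", {
  expect_error(acoustic_model(att_08 = c(0.1, -0.01, 0.02)), "non-decreasing")
  expect_error(acoustic_model(velocity_slope = 3000), "positive")
  expect_error(simulate_train(list(phantom_id = "x", sat_pct = 0,
                                   imat_pct = 0, path_length_mm = -5),
                              model0), "path length")
})
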