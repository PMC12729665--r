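test_that("noise-free grid records are recovered at their own coordinates", {
  m0 <- noise_free(acoustic_model())
  rec <- simulate_records(phantom_grid(), m0, repeats = 1, seed = 3)
  fit <- fit_decision_rules(rec)
  pred <- predict(fit, rec)
  # within half a densified cell (1.5625%) of the true node
  expect_lt(max(abs(pred$sat_hat - rec$sat)), 1.5625)
  expect_lt(max(abs(pred$imat_hat - rec$imat)), 1.5625)
  expect_true(all(pred$criteria_used == 6L))
  expect_false(any(pred$fallback))
})

test_that("degenerate disjoint criteria trigger the max-cardinality fallback", {
  rec <- toy_records(reps = 2, noise = 0.5, levels = c(0, 25, 50))
  fit <- fit_decision_rules(rec)
  vals <- rec[1, paste0("cr", 1:6)]
  # push one criterion into a region disjoint from the others
  vals$cr6 <- max(rec$cr6) # feasible only near the high-fat corner
  vals$cr1 <- max(rec$cr1) # velocity feasible only near the origin
  r <- recognize_signal(fit, vals)
  expect_true(r$fallback)
  expect_lt(r$criteria_used, 6L)
  # an impossible value for every criterion is unrecognizable
  vals2 <- vals
  vals2[] <- 1e9
  expect_error(recognize_signal(fit, vals2), "unrecognizable")
})

test_that("object-level aggregation averages the signal estimates", {
  rec <- toy_records(reps = 3, noise = 1, levels = c(0, 25, 50))
  fit <- fit_decision_rules(rec)
  sig <- predict(fit, rec, aggregate = "signal")
  obj <- predict(fit, rec, aggregate = "object")
  expect_equal(nrow(obj), 9L)
  manual <- tapply(sig$sat_hat, sig$phantom_id, mean)
  expect_equal(obj$sat_hat, as.numeric(manual[obj$phantom_id]))
})

test_that("recognition diagnostics surface the region structure", {
  rec <- toy_records(reps = 2, noise = 1, levels = c(0, 25, 50))
  fit <- fit_decision_rules(rec)
  r <- recognize_signal(fit, rec[5, paste0("cr", 1:6)], keep_regions = TRUE)
  expect_s3_class(r$region, "qus_region")
  expect_length(r$criterion_regions, 6L)
  expect_true(r$criteria_used >= 1 && r$criteria_used <= 6)
  # estimate lies inside the bounding box of the final region vertices
  verts <- do.call(rbind, r$region$polygons)
  expect_gte(r$estimate[["sat"]], min(verts$x) - 1e-6)
  expect_lte(r$estimate[["sat"]], max(verts$x) + 1e-6)
})
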