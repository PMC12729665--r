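test_that("Akima interpolation passes through nodes and reproduces lines", {
  x <- c(0, 12.5, 25, 37.5, 50)
  y <- c(2, 5, 4, 8, 7)
  xi <- densify_axis(x)
  v <- akima_interp(x, y, xi)
  expect_equal(v[match(x, xi)], y)
  # straight lines are reproduced exactly (degenerate Akima weights)
  expect_equal(akima_interp(x, 3 + 0.2 * x, xi), 3 + 0.2 * xi)
  expect_error(akima_interp(x, y, c(-1, 10)), "span")
})

test_that("Akima agrees with the pracma reference on generic curves", {
  skip_if_not_installed("pracma")
  x <- c(0, 1, 2.5, 4, 5, 7, 9)
  y <- sin(x) + 0.3 * x
  xi <- seq(0.1, 8.9, by = 0.2)
  expect_equal(akima_interp(x, y, xi), pracma::akimaInterp(x, y, xi),
               tolerance = 1e-10)
})

test_that("axis densification inserts three points per interval", {
  d <- densify_axis(c(0, 12.5, 25, 37.5, 50))
  expect_length(d, 17L)
  expect_equal(d[1:5], c(0, 3.125, 6.25, 9.375, 12.5))
  expect_length(densify_axis(c(0, 50)), 5L)
})

test_that("decision-rule fitting builds valid envelopes", {
  rec <- toy_records(reps = 3, noise = 1)
  fit <- fit_decision_rules(rec)
  expect_s3_class(fit, "qus_dr")
  for (s in fit$surfaces) {
    expect_true(all(s$min_node <= s$max_node))
    expect_true(all(s$min_dense <= s$max_dense + 1e-12))
    expect_length(s$dense, 9L)  # 3 levels -> 9 densified nodes
    # densified surfaces interpolate the original nodes exactly
    idx <- match(s$levels, s$dense)
    expect_equal(s$min_dense[idx, idx], unclass(s$min_node),
                 ignore_attr = TRUE)
  }
  # envelope containment: every training value within its node envelope
  s1 <- fit$surfaces$cr1
  for (i in seq_len(nrow(rec))) {
    ii <- match(rec$sat[i], fit$levels); jj <- match(rec$imat[i], fit$levels)
    expect_gte(rec$cr1[i], s1$min_node[ii, jj])
    expect_lte(rec$cr1[i], s1$max_node[ii, jj])
  }
})

test_that("single record per node collapses the envelope", {
  rec <- toy_records(reps = 1)
  fit <- fit_decision_rules(rec)
  expect_equal(fit$surfaces$cr2$min_node, fit$surfaces$cr2$max_node)
})

test_that("a linear criterion field densifies to the same plane", {
  rec <- toy_records(reps = 1)
  fit <- fit_decision_rules(rec)
  s <- fit$surfaces$cr6  # cr6 = 300 + 4 sat + 6 imat exactly (noise 0)
  plane <- outer(s$dense, s$dense, function(sat, imat) 300 + 4 * sat + 6 * imat)
  expect_equal(s$min_dense, plane, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fitting rejects incomplete grids", {
  rec <- toy_records(reps = 2)
  expect_error(fit_decision_rules(rec[rec$phantom_id != "S00_I25", ]),
               "at least one training record")
  expect_error(fit_decision_rules(rec[rec$imat != 25, ]), "same SAT and IMAT")
})
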