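test_that("phantom grid enumerates every SAT/IMAT combination", {
  g <- phantom_grid()
  expect_equal(nrow(g), 25L)
  expect_setequal(unique(g$sat_pct), c(0, 12.5, 25, 37.5, 50))
  expect_equal(nrow(unique(g[, c("sat_pct", "imat_pct")])), 25L)
  expect_true(all(g$path_length_mm == 80))

  expect_equal(nrow(phantom_grid(levels = 0)), 1L)
  expect_equal(nrow(phantom_grid(levels = c(0, 25, 50))), 9L)
})

test_that("phantom grid rejects bad level lists", {
  expect_error(phantom_grid(levels = numeric(0)), "non-empty")
  expect_error(phantom_grid(levels = c(0, 25, 25)), "strictly increasing")
  expect_error(phantom_grid(levels = c(10, 60)), "within")
  expect_error(phantom_grid(path_length_mm = -1), "positive")
})

test_that("total fat fraction composes SAT (whole volume) with IMAT (muscle)", {
  expect_equal(total_fat_fraction(0, 0), 0)
  expect_equal(total_fat_fraction(50, 50), 75)
  expect_equal(total_fat_fraction(25, 25), 43.75)
  # vectorized and symmetric only at zero SAT
  expect_equal(total_fat_fraction(c(0, 50), c(50, 0)), c(50, 50))
  expect_error(total_fat_fraction(-1, 0), "within")
  expect_error(total_fat_fraction(0, 101), "within")
})
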