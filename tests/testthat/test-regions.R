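test_that("slicing a decision surface matches a dense rasterization oracle", {
  rec <- toy_records(reps = 3, noise = 1, levels = c(0, 12.5, 25, 37.5, 50))
  fit <- fit_decision_rules(rec)
  for (cn in c("cr1", "cr3")) {
    s <- fit$surfaces[[cn]]
    value <- stats::median(rec[[cn]])
    region <- slice_region(value, s)
    oracle <- raster_membership_oracle(s, value)
    pts <- expand.grid(x = oracle$xs, y = oracle$xs)
    inside_poly <- region_contains(region, pts$x, pts$y)
    agree <- mean(inside_poly == as.vector(oracle$inside))
    expect_gte(agree, 0.99)
  }
})

test_that("degenerate slice values give empty or full regions", {
  rec <- toy_records(reps = 2, noise = 0.5,
                     levels = c(0, 12.5, 25, 37.5, 50))
  fit <- fit_decision_rules(rec)
  s <- fit$surfaces$cr1
  below <- slice_region(min(s$min_dense) - 10 * s$range, s)
  expect_true(below$empty)
  expect_equal(below$area, 0)
  # constant envelopes 0..1 sliced at 0.5 -> the full 2500 %^2 domain
  s2 <- s
  s2$min_raster[] <- 0; s2$max_raster[] <- 1
  s2$range <- 1; s2$epsilon <- 0
  full <- slice_region(0.5, s2)
  expect_equal(full$area, 2500, tolerance = 0.01)
})

test_that("region intersection behaves like set intersection", {
  r1 <- region_from_polygons(list(rect_poly(10, 20, 10, 20)))
  r2 <- region_from_polygons(list(rect_poly(15, 25, 10, 20)))
  ri <- intersect_regions(list(r1, r2))
  expect_equal(ri$area, 50, tolerance = 0.5)
  expect_equal(unname(ri$centroid), c(17.5, 15), tolerance = 0.05)
  # identity: intersecting with the full domain changes nothing
  full <- region_from_polygons(list(rect_poly(0, 50, 0, 50)))
  rid <- intersect_regions(list(r1, full))
  expect_equal(rid$area, r1$area, tolerance = 0.5)
  expect_equal(rid$centroid, r1$centroid, tolerance = 0.05)
})

test_that("random polygon intersections agree with a rasterization oracle", {
  set.seed(7)
  for (k in 1:5) {
    p1 <- rect_poly(runif(1, 0, 20), runif(1, 25, 48), runif(1, 0, 20),
                    runif(1, 25, 48))
    p2 <- rect_poly(runif(1, 0, 20), runif(1, 25, 48), runif(1, 0, 20),
                    runif(1, 25, 48))
    ri <- intersect_regions(list(region_from_polygons(list(p1)),
                                 region_from_polygons(list(p2))))
    ov_x <- max(0, min(max(p1$x), max(p2$x)) - max(min(p1$x), min(p2$x)))
    ov_y <- max(0, min(max(p1$y), max(p2$y)) - max(min(p1$y), min(p2$y)))
    true_area <- ov_x * ov_y
    expect_equal(ri$area, true_area,
                 tolerance = max(0.01 * max(true_area, 1), 0.6))
  }
})

test_that("centroids are area-weighted centers of mass", {
  sq <- region_from_polygons(list(rect_poly(0, 1, 0, 1)),
                             xs = seq(0, 2, by = 0.02),
                             ys = seq(0, 2, by = 0.02))
  expect_equal(unname(sq$centroid), c(0.5, 0.5), tolerance = 0.01)
  two <- region_from_polygons(list(rect_poly(5, 15, 5, 15),
                                   rect_poly(25, 35, 25, 35)))
  expect_equal(unname(centroid_estimate(two)), c(20, 20), tolerance = 0.05)
  expect_equal(two$n_components, 2L)

  # Monte-Carlo oracle on an L-shaped polygon
  L <- data.frame(x = c(5, 30, 30, 15, 15, 5), y = c(5, 5, 15, 15, 35, 35))
  rl <- region_from_polygons(list(L))
  set.seed(99)
  px <- runif(2e5, 0, 50); py <- runif(2e5, 0, 50)
  inside <- qusfat:::points_in_polygon(px, py, L$x, L$y)
  expect_equal(unname(rl$centroid), c(mean(px[inside]), mean(py[inside])),
               tolerance = 0.2)
  expect_equal(rl$area, 2500 * mean(inside), tolerance = 12)
})

test_that("empty regions refuse a centroid and intersections need a raster match", {
  rec <- toy_records(reps = 1, levels = c(0, 25, 50))
  fit <- fit_decision_rules(rec)
  s <- fit$surfaces$cr1
  empty <- slice_region(1e6, s)
  expect_error(centroid_estimate(empty), "empty")
  other <- region_from_polygons(list(rect_poly(1, 2, 1, 2)),
                                xs = seq(0, 10, by = 1), ys = seq(0, 10, by = 1))
  expect_error(intersect_regions(list(empty, other)), "common raster")
})

test_that("adding criteria never grows the feasible region", {
  rec <- toy_records(reps = 3, noise = 1, levels = c(0, 12.5, 25, 37.5, 50))
  fit <- fit_decision_rules(rec)
  test_row <- rec[rec$phantom_id == "S25_I25" & rec$repeat_index == 1, ]
  areas <- numeric(0)
  regions <- list()
  for (cn in paste0("cr", 1:6)) {
    regions[[cn]] <- slice_region(test_row[[cn]], fit$surfaces[[cn]])
    inter <- intersect_regions(regions)
    areas <- c(areas, inter$area)
  }
  expect_true(all(diff(areas) <= 1e-9))
})
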