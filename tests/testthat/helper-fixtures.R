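# Shared fixtures: kept deliberately small so the unit tests stay fast.

# axis-aligned rectangle polygon
rect_poly <- function(x0, x1, y0, y1) {
  data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# analytic criterion records on a grid: six linearly independent-ish fields
# plus optional iid noise, `reps` records per node
toy_records <- function(levels = c(0, 25, 50), reps = 2, noise = 0,
                        seed = 42) {
  set.seed(seed)
  g <- expand.grid(sat = levels, imat = levels)
  rec <- do.call(rbind, lapply(seq_len(reps), function(r) {
    d <- g
    d$repeat_index <- r
    d
  }))
  rec$phantom_id <- sprintf("S%02.0f_I%02.0f", rec$sat, rec$imat)
  n <- nrow(rec)
  rec$cr1 <- 1589 - 1.559 * total_fat_fraction(rec$sat, rec$imat) +
    rnorm(n, 0, noise)
  rec$cr2 <- 0.10 + 0.0008 * rec$sat + 0.0002 * rec$imat + rnorm(n, 0, noise / 500)
  rec$cr3 <- 0.60 + 0.0010 * rec$sat + 0.0040 * rec$imat + rnorm(n, 0, noise / 50)
  rec$cr4 <- rec$cr2 / rec$cr3
  rec$cr5 <- 0.40 - 0.003 * rec$sat - 0.002 * rec$imat + rnorm(n, 0, noise / 100)
  rec$cr6 <- 300 + 4 * rec$sat + 6 * rec$imat + rnorm(n, 0, noise * 2)
  rec$signal_number <- seq_len(n)
  rec
}

# dense rasterization membership oracle for a sliced decision surface:
# evaluates min <= value <= max by bilinear interpolation on a fine
# independent grid
raster_membership_oracle <- function(surface, value, n = 400) {
  xs <- seq(min(surface$dense), max(surface$dense), length.out = n)
  lo <- qusfat:::bilinear_grid(surface$dense, surface$dense,
                               surface$min_dense, xs, xs)
  hi <- qusfat:::bilinear_grid(surface$dense, surface$dense,
                               surface$max_dense, xs, xs)
  list(xs = xs,
       inside = value >= (lo - surface$epsilon) & value <= (hi + surface$epsilon))
}

# point-in-region test via the region's polygons (even-odd)
region_contains <- function(region, px, py) {
  inside <- logical(length(px))
  for (p in region$polygons)
    inside <- xor(inside, qusfat:::points_in_polygon(px, py, p$x, p$y))
  inside
}
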