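# --- raster / interpolation helpers -----------------------------------------

# Uniform slicing raster subdividing each densified cell `refine` times.
raster_axis <- function(dense, refine) {
  n <- length(dense)
  seq(dense[1], dense[n], length.out = (n - 1L) * refine + 1L)
}

# Bilinear interpolation of matrix Z (rows ~ gx, cols ~ gy) onto the tensor
# grid xs x ys. Returns length(xs) x length(ys).
bilinear_grid <- function(gx, gy, Z, xs, ys) {
  ix <- pmin(pmax(findInterval(xs, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(ys, gy), 1L), length(gy) - 1L)
  tx <- (xs - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (ys - gy[iy]) / (gy[iy + 1L] - gy[iy])
  Z11 <- Z[ix, iy, drop = FALSE]; Z21 <- Z[ix + 1L, iy, drop = FALSE]
  Z12 <- Z[ix, iy + 1L, drop = FALSE]; Z22 <- Z[ix + 1L, iy + 1L, drop = FALSE]
  wx <- matrix(tx, length(xs), length(ys))
  wy <- matrix(ty, length(xs), length(ys), byrow = TRUE)
  Z11 * (1 - wx) * (1 - wy) + Z21 * wx * (1 - wy) +
    Z12 * (1 - wx) * wy + Z22 * wx * wy
}

# --- polygon primitives -----------------------------------------------------

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Area-weighted centroid of a simple polygon (shoelace form).
polygon_centroid <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cross) / (6 * a), sum((y + y[j]) * cross) / (6 * a))
}

# Even-odd point-in-polygon (ray casting), vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a simple polygon to an axis-aligned box.
clip_polygon_box <- function(x, y, xlim, ylim) {
  clip_edge <- function(px, py, keep, cross_at) {
    if (length(px) == 0L) return(list(x = px, y = py))
    nx <- c(); ny <- c()
    n <- length(px)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a_in <- keep(px[i], py[i]); b_in <- keep(px[j], py[j])
      if (a_in) { nx <- c(nx, px[i]); ny <- c(ny, py[i]) }
      if (a_in != b_in) {
        p <- cross_at(px[i], py[i], px[j], py[j])
        nx <- c(nx, p[1]); ny <- c(ny, p[2])
      }
    }
    list(x = nx, y = ny)
  }
  p <- list(x = x, y = y)
  p <- clip_edge(p$x, p$y, function(x, y) x >= xlim[1], function(x1, y1, x2, y2) {
    t <- (xlim[1] - x1) / (x2 - x1); c(xlim[1], y1 + t * (y2 - y1)) })
  p <- clip_edge(p$x, p$y, function(x, y) x <= xlim[2], function(x1, y1, x2, y2) {
    t <- (xlim[2] - x1) / (x2 - x1); c(xlim[2], y1 + t * (y2 - y1)) })
  p <- clip_edge(p$x, p$y, function(x, y) y >= ylim[1], function(x1, y1, x2, y2) {
    t <- (ylim[1] - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ylim[1]) })
  p <- clip_edge(p$x, p$y, function(x, y) y <= ylim[2], function(x1, y1, x2, y2) {
    t <- (ylim[2] - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ylim[2]) })
  p
}

# --- field polygonization ---------------------------------------------------

# Extract the {field >= 0} region boundary as closed polygons via marching
# contours at level zero. The raster is padded with a strongly negative ring
# so every contour closes, then vertices are clipped back to the domain.
# Returns polygons plus even-odd containment signs, total area and centroid.
polygonize_field <- function(xs, ys, field) {
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  xp <- c(xs[1] - hx, xs, xs[length(xs)] + hx)
  yp <- c(ys[1] - hy, ys, ys[length(ys)] + hy)
  pad <- -10 * max(abs(field), 1)
  fp <- matrix(pad, length(xp), length(yp))
  fp[2:(length(xs) + 1L), 2:(length(ys) + 1L)] <- field
  cl <- grDevices::contourLines(xp, yp, fp, levels = 0)
  if (length(cl) == 0L)
    return(list(polygons = list(), signs = numeric(0), area = 0,
                centroid = c(NA_real_, NA_real_), n_components = 0L))
  xlim <- range(xs); ylim <- range(ys)
  polys <- lapply(cl, function(c0) {
    p <- clip_polygon_box(c0$x, c0$y, xlim, ylim)
    if (length(p$x) >= 3L) data.frame(x = p$x, y = p$y) else NULL
  })
  polys <- Filter(Negate(is.null), polys)
  if (length(polys) == 0L)
    return(list(polygons = list(), signs = numeric(0), area = 0,
                centroid = c(NA_real_, NA_real_), n_components = 0L))
  # containment depth decides outer boundaries (+) vs holes (-)
  depth <- vapply(seq_along(polys), function(i) {
    pt <- c(polys[[i]]$x[1], polys[[i]]$y[1])
    sum(vapply(seq_along(polys), function(j) {
      if (j == i) return(FALSE)
      points_in_polygon(pt[1], pt[2], polys[[j]]$x, polys[[j]]$y)
    }, logical(1)))
  }, integer(1))
  sign <- ifelse(depth %% 2L == 0L, 1, -1)
  a <- vapply(polys, function(p) abs(polygon_signed_area(p$x, p$y)), numeric(1))
  cents <- t(vapply(polys, function(p) polygon_centroid(p$x, p$y), numeric(2)))
  area <- sum(sign * a)
  centroid <- if (area > 1e-12)
    c(sum(sign * a * cents[, 1]) / area, sum(sign * a * cents[, 2]) / area)
  else c(NA_real_, NA_real_)
  list(polygons = polys, signs = sign, area = max(area, 0),
       centroid = centroid, n_components = sum(sign > 0))
}

# --- feasible regions -------------------------------------------------------

#' Feasible region in the SAT-IMAT plane
#'
#' A region is represented both implicitly (a margin field on a common raster,
#' non-negative inside) and explicitly (closed boundary polygons with even-odd
#' holes, total area in percent-squared, area-weighted centroid).
#'
#' @param xs,ys Raster axes in percent.
#' @param field Margin matrix (`length(xs)` x `length(ys)`), `>= 0` inside.
#' @param criteria Character vector of criterion ids that produced the region.
#' @return Object of class `qus_region`.
#' @export
feasible_region <- function(xs, ys, field, criteria = character(0)) {
  geo <- polygonize_field(xs, ys, field)
  structure(list(xs = xs, ys = ys, field = field, criteria = criteria,
                 polygons = geo$polygons, signs = geo$signs,
                 area = geo$area, centroid = geo$centroid,
                 n_components = geo$n_components,
                 empty = geo$n_components == 0L),
            class = "qus_region")
}

#' @export
print.qus_region <- function(x, ...) {
  if (x$empty) {
    cat("Empty feasible region (", paste(x$criteria, collapse = "+"), ")\n")
  } else {
    cat(sprintf("Feasible region [%s]: %d component(s), area %.2f %%^2, centroid (SAT %.2f, IMAT %.2f)\n",
                paste(x$criteria, collapse = "+"), x$n_components, x$area,
                x$centroid[1], x$centroid[2]))
  }
  invisible(x)
}

#' Build a feasible region from explicit polygons
#'
#' Rasterizes a polygon set (even-odd rule) to a signed-distance-like field on
#' the given axes, so that polygon-defined regions compose with sliced regions
#' through [intersect_regions()]. Straight polygon edges are reproduced
#' exactly by the linear signed-distance field.
#'
#' @param polygons List of data frames with `x` (SAT) and `y` (IMAT) columns.
#' @param xs,ys Raster axes (default: 0.25-step axes over \[0, 50\]).
#' @return A [feasible_region()].
#' @export
region_from_polygons <- function(polygons,
                                 xs = seq(0, 50, by = 0.25),
                                 ys = seq(0, 50, by = 0.25)) {
  pts <- expand.grid(x = xs, y = ys)   # x varies fastest, matching matrix rows
  inside <- logical(nrow(pts))
  dmin <- rep(Inf, nrow(pts))
  for (p in polygons) {
    inside <- xor(inside, points_in_polygon(pts$x, pts$y, p$x, p$y))
    n <- length(p$x); j <- c(2:n, 1L)
    for (e in seq_len(n)) {
      ex <- p$x[j[e]] - p$x[e]; ey <- p$y[j[e]] - p$y[e]
      len2 <- ex^2 + ey^2
      if (len2 == 0) next
      t <- pmin(pmax(((pts$x - p$x[e]) * ex + (pts$y - p$y[e]) * ey) / len2, 0), 1)
      d <- sqrt((pts$x - p$x[e] - t * ex)^2 + (pts$y - p$y[e] - t * ey)^2)
      dmin <- pmin(dmin, d)
    }
  }
  # tiny negative bias breaks exact-zero ties for raster nodes lying on edges
  field <- matrix(ifelse(inside, dmin, -dmin) - 1e-9, length(xs), length(ys))
  feasible_region(xs, ys, field, criteria = "polygon")
}

#' Intersect feasible regions
#'
#' Geometric intersection of any number of regions sharing a raster: the
#' point-wise minimum of their margin fields is the margin field of the
#' intersection. Adding a region can never increase the area.
#'
#' @param regions List of [feasible_region()] objects on identical rasters.
#' @return A [feasible_region()] (possibly empty or multi-component).
#' @export
intersect_regions <- function(regions) {
  stopifnot(length(regions) >= 1L,
            all(vapply(regions, inherits, logical(1), "qus_region")))
  xs <- regions[[1]]$xs; ys <- regions[[1]]$ys
  for (r in regions[-1])
    if (length(r$xs) != length(xs) || max(abs(r$xs - xs)) > 1e-9 ||
        max(abs(r$ys - ys)) > 1e-9)
      stop("regions must share a common raster")
  field <- Reduce(pmin, lapply(regions, `[[`, "field"))
  feasible_region(xs, ys, field,
                  criteria = unique(unlist(lapply(regions, `[[`, "criteria"))))
}

#' Slice a decision surface at a measured criterion value
#'
#' The feasible region of one criterion: all (SAT, IMAT) points where the
#' measured value lies between the densified lower and upper envelope
#' surfaces (with the fitted epsilon tolerance). Computed by classifying the
#' bilinear slicing raster and extracting level-zero contours.
#'
#' @param value Measured criterion value.
#' @param surface A `decision_surface` from [fit_decision_rules()].
#' @return A [feasible_region()]; empty regions are valid results.
#' @export
slice_region <- function(value, surface) {
  stopifnot(inherits(surface, "decision_surface"))
  g <- pmin(value - (surface$min_raster - surface$epsilon),
            (surface$max_raster + surface$epsilon) - value) / surface$range
  feasible_region(surface$raster, surface$raster, g,
                  criteria = surface$criterion)
}

#' Centroid of a feasible region
#'
#' Area-weighted center of mass over all components of a region; the final
#' SAT/IMAT estimate of the decision-rule method.
#'
#' @param region A [feasible_region()].
#' @return Named numeric vector `c(sat = ..., imat = ...)`.
#' @export
centroid_estimate <- function(region) {
  stopifnot(inherits(region, "qus_region"))
  if (region$empty) stop("cannot take the centroid of an empty region")
  c(sat = region$centroid[1], imat = region$centroid[2])
}
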