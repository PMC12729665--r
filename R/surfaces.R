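# 1-D Akima spline interpolation.
#
# Classic Akima local cubic: slopes at the nodes are weighted averages of
# neighbouring secant slopes, with two quadratically extrapolated secants at
# each end. When the Akima weight denominator vanishes (locally linear or
# symmetric data) the slope falls back to the mean of the adjacent secants,
# which keeps the scheme exact on straight lines.
akima_slopes <- function(x, y) {
  n <- length(x)
  # standard extension: m0 = 2 m1 - m2, m-1 = 2 m0 - m1 (mirrored at the end)
  m <- diff(y) / diff(x)
  m0 <- 2 * m[1] - m[2]
  mm1 <- 2 * m0 - m[1]
  mn <- 2 * m[n - 1] - m[n - 2]
  mn1 <- 2 * mn - m[n - 1]
  me <- c(mm1, m0, m, mn, mn1)                 # indices shifted by 2
  t <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- me[i]; m2 <- me[i + 1]; m3 <- me[i + 2]; m4 <- me[i + 3]
    w1 <- abs(m4 - m3); w2 <- abs(m2 - m1)
    t[i] <- if (w1 + w2 > 0) (w1 * m2 + w2 * m3) / (w1 + w2)
            else (m2 + m3) / 2
  }
  t
}

#' Akima spline interpolation in one dimension
#'
#' Piecewise-cubic Hermite interpolation with Akima's local slope estimate.
#' Exactly reproduces the data at the nodes and straight lines everywhere
#' (the degenerate equal-secant case uses the mean-secant tie-break).
#' Interpolation only: `xi` must lie within `range(x)`.
#'
#' @param x Strictly increasing node positions (length >= 3).
#' @param y Node values.
#' @param xi Query positions within `[min(x), max(x)]`.
#' @return Interpolated values at `xi`.
#' @export
akima_interp <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n, all(diff(x) > 0))
  if (any(xi < x[1] - 1e-9) || any(xi > x[n] + 1e-9))
    stop("'xi' outside the interpolation span (no extrapolation)")
  t <- akima_slopes(x, y)
  i <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  h <- x[i + 1L] - x[i]
  s <- (xi - x[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[i] + h10 * h * t[i] + h01 * y[i + 1L] + h11 * h * t[i + 1L]
}

#' Densified grid axis
#'
#' Inserts three equally spaced points between each pair of original nodes,
#' taking a 5-level axis to 17 nodes.
#'
#' @param levels Original strictly increasing axis values.
#' @return Densified axis (length `4*(k-1) + 1` for `k` original nodes).
#' @export
densify_axis <- function(levels) {
  k <- length(levels)
  stopifnot(k >= 2L, all(diff(levels) > 0))
  out <- unlist(lapply(seq_len(k - 1L), function(i)
    seq(levels[i], levels[i + 1L], length.out = 5L)[1:4]))
  c(out, levels[k])
}

# Tensor-product Akima densification of a k x k node matrix (rows = SAT axis,
# cols = IMAT axis) onto the densified axes.
densify_surface <- function(z, levels, dense = densify_axis(levels)) {
  k <- length(levels)
  stopifnot(nrow(z) == k, ncol(z) == k)
  tmp <- apply(z, 2L, function(col) akima_interp(levels, col, dense))  # |dense| x k
  t(apply(tmp, 1L, function(row) akima_interp(levels, row, dense)))   # |dense| x |dense|
}

#' Control parameters of the decision-rule estimator
#'
#' @param refine Bilinear raster subdivisions per densified-grid cell used for
#'   feasible-region extraction (default 10, i.e. a 0.3125 percent step on the
#'   reference grid).
#' @param epsilon_frac Envelope tolerance as a fraction of each criterion's
#'   surface range, added symmetrically to the min-max band (default 0.0025).
#'   This is a numerical guard, not a statistical widening: it is the smallest
#'   band that keeps degenerate (zero-width) envelopes detectable on the
#'   slicing raster (half a raster cell times the steepest surface gradient).
#' @return List of class `qus_dr_control`.
#' @export
dr_control <- function(refine = 10L, epsilon_frac = 0.0025) {
  stopifnot(refine >= 1L, epsilon_frac >= 0)
  structure(list(refine = as.integer(refine), epsilon_frac = epsilon_frac),
            class = "qus_dr_control")
}

#' Fit min-max decision-rule surfaces
#'
#' For each evaluation criterion, the envelope of the training data is built
#' on the SAT x IMAT grid: the node-wise minimum and maximum of the criterion
#' over each object's training signals form the lower and upper boundary
#' surfaces. Both are densified with Akima splines, inserting three points per
#' original interval (5 to 17 nodes per axis), and finally sampled onto a
#' bilinear raster used for feasible-region slicing.
#'
#' @param records Criterion record data frame with columns `sat`, `imat` and
#'   `cr1` ... `cr6` (see [simulate_records()]); every grid node needs at
#'   least one record.
#' @param levels Grid levels in percent; inferred from the records by default.
#' @param criteria Criterion column names (default `cr1` ... `cr6`).
#' @param control A [dr_control()].
#' @return Object of class `qus_dr` with one `decision_surface` per criterion
#'   (node and densified min/max matrices, rows = SAT, cols = IMAT) plus the
#'   slicing rasters.
#' @export
fit_decision_rules <- function(records, levels = NULL,
                               criteria = paste0("cr", 1:6),
                               control = dr_control()) {
  stopifnot(all(c("sat", "imat", criteria) %in% names(records)))
  if (is.null(levels)) levels <- sort(unique(records$sat))
  k <- length(levels)
  if (k < 2L) stop("need at least two grid levels per axis")
  if (!setequal(unique(records$imat), levels))
    stop("records do not cover the same SAT and IMAT levels")
  isat <- match(records$sat, levels)
  iimat <- match(records$imat, levels)
  if (anyNA(isat) || anyNA(iimat)) stop("records contain off-grid fractions")
  counts <- table(factor(isat, seq_len(k)), factor(iimat, seq_len(k)))
  if (any(counts == 0))
    stop("every grid node needs at least one training record")
  dense <- densify_axis(levels)
  xs <- raster_axis(dense, control$refine)
  surfaces <- lapply(criteria, function(cn) {
    v <- records[[cn]]
    lo <- tapply(v, list(isat, iimat), min)
    hi <- tapply(v, list(isat, iimat), max)
    lo_d <- densify_surface(lo, levels, dense)
    hi_d <- densify_surface(hi, levels, dense)
    # Akima overshoot can locally swap the densified envelopes; repair
    lo2 <- pmin(lo_d, hi_d); hi2 <- pmax(lo_d, hi_d)
    rng <- max(hi2) - min(lo2)
    if (rng <= 0) rng <- max(abs(hi2), 1)
    structure(list(criterion = cn, levels = levels, dense = dense,
                   min_node = lo, max_node = hi,
                   min_dense = lo2, max_dense = hi2,
                   min_raster = bilinear_grid(dense, dense, lo2, xs, xs),
                   max_raster = bilinear_grid(dense, dense, hi2, xs, xs),
                   raster = xs, range = rng,
                   epsilon = control$epsilon_frac * rng),
              class = "decision_surface")
  })
  names(surfaces) <- criteria
  structure(list(surfaces = surfaces, levels = levels, dense = dense,
                 raster = xs, control = control,
                 n_train = nrow(records)),
            class = "qus_dr")
}

#' @export
print.qus_dr <- function(x, ...) {
  cat(sprintf("Min-max decision-rule estimator: %d criteria on a %dx%d grid\n",
              length(x$surfaces), length(x$levels), length(x$levels)))
  cat(sprintf("  levels: %s %%; densified to %d nodes/axis; raster %d points/axis\n",
              paste(x$levels, collapse = ", "), length(x$dense),
              length(x$raster)))
  cat(sprintf("  trained on %d signals\n", x$n_train))
  invisible(x)
}

#' @export
summary.qus_dr <- function(object, ...) {
  s <- do.call(rbind, lapply(object$surfaces, function(sf)
    data.frame(criterion = sf$criterion,
               min = min(sf$min_node), max = max(sf$max_node),
               median_band = stats::median(sf$max_node - sf$min_node),
               epsilon = sf$epsilon)))
  rownames(s) <- NULL
  s
}
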