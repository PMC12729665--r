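#' Plot decision-rule envelope surfaces
#'
#' Perspective view of the densified min and max envelope surfaces of one
#' criterion over the SAT-IMAT plane.
#'
#' @param x A [fit_decision_rules()] object.
#' @param criterion Criterion id (default `"cr1"`).
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @param ... Further arguments to `persp`.
#' @export
plot.qus_dr <- function(x, criterion = "cr1", theta = 40, phi = 25, ...) {
  s <- x$surfaces[[criterion]]
  if (is.null(s)) stop("unknown criterion: ", criterion)
  zlim <- range(s$min_dense, s$max_dense)
  p <- graphics::persp(s$dense, s$dense, s$max_dense, zlim = zlim,
                       theta = theta, phi = phi, col = "#d9735255",
                       border = "#d97352", xlab = "SAT (%)",
                       ylab = "IMAT (%)", zlab = criterion,
                       main = sprintf("%s min-max envelope", criterion), ...)
  graphics::par(new = TRUE)
  graphics::persp(s$dense, s$dense, s$min_dense, zlim = zlim,
                  theta = theta, phi = phi, col = "#4477aa55",
                  border = "#4477aa", xlab = "", ylab = "", zlab = "", ...)
  invisible(p)
}

#' Plot a feasible region
#'
#' Draws the region polygons in the SAT-IMAT plane, with holes in white and
#' the area-weighted centroid marked.
#'
#' @param x A [feasible_region()].
#' @param truth Optional true `(sat, imat)` point to overlay.
#' @param ... Further arguments to `plot`.
#' @export
plot.qus_region <- function(x, truth = NULL, ...) {
  graphics::plot(NA, xlim = range(x$xs), ylim = range(x$ys),
                 xlab = "SAT (%)", ylab = "IMAT (%)",
                 main = paste("Feasible region:",
                              paste(x$criteria, collapse = "+")), ...)
  if (!x$empty) {
    ord <- order(x$signs, decreasing = TRUE)  # outers first, then holes
    for (i in ord)
      graphics::polygon(x$polygons[[i]]$x, x$polygons[[i]]$y,
                        col = if (x$signs[i] > 0) "#44aa7788" else "white",
                        border = "#226644")
    graphics::points(x$centroid[1], x$centroid[2], pch = 19, col = "red")
  }
  if (!is.null(truth))
    graphics::points(truth[1], truth[2], pch = 15, col = "blue")
  invisible(x)
}

#' Heatmap of the per-object error topology
#'
#' @param errmap Matrix from [error_topology()].
#' @param main Plot title.
#' @param ... Further arguments to [graphics::image()].
#' @return The matrix, invisibly.
#' @export
plot_error_topology <- function(errmap, main = "Recognition error (%)", ...) {
  lv_s <- as.numeric(rownames(errmap))
  lv_i <- as.numeric(colnames(errmap))
  graphics::image(lv_s, lv_i, errmap, col = grDevices::hcl.colors(24, "YlOrRd",
                                                                  rev = TRUE),
                  xlab = "SAT (%)", ylab = "IMAT (%)", main = main, ...)
  for (i in seq_along(lv_s))
    for (j in seq_along(lv_i))
      graphics::text(lv_s[i], lv_i[j], sprintf("%.1f", errmap[i, j]),
                     cex = 0.8)
  invisible(errmap)
}
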