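#' Build the SAT x IMAT phantom grid
#'
#' Constructs the design grid of phantoms used throughout the package: every
#' combination of the given SAT levels (percent of whole phantom volume) and
#' IMAT levels (percent of the muscle compartment). The reference design is a
#' 5 x 5 grid with both factors at 0, 12.5, 25, 37.5 and 50 percent, i.e. 25
#' phantoms.
#'
#' @param levels Numeric vector of fat levels in percent, strictly increasing,
#'   within \[0, 50\]. Used for both axes. Default `c(0, 12.5, 25, 37.5, 50)`.
#' @param path_length_mm Emitter-to-receiver distance in mm (default 80, the
#'   long side of the reference phantom mold).
#' @return A data frame of class `qus_phantom_grid` with one row per phantom:
#'   `phantom_id`, `sat_pct`, `imat_pct`, `grid_row`, `grid_col`,
#'   `path_length_mm`.
#' @examples
#' g <- phantom_grid()
#' nrow(g)  # 25
#' @export
phantom_grid <- function(levels = c(0, 12.5, 25, 37.5, 50), path_length_mm = 80) {
  if (length(levels) < 1L || anyNA(levels))
    stop("'levels' must be a non-empty numeric vector")
  if (any(diff(levels) <= 0))
    stop("'levels' must be strictly increasing")
  if (any(levels < 0 | levels > 50))
    stop("'levels' must lie within [0, 50] percent")
  if (path_length_mm <= 0) stop("'path_length_mm' must be positive")
  g <- expand.grid(sat_pct = levels, imat_pct = levels,
                   KEEP.OUT.ATTRS = FALSE)
  g$grid_row <- match(g$imat_pct, levels)
  g$grid_col <- match(g$sat_pct, levels)
  g$phantom_id <- sprintf("S%02.0f_I%02.0f", g$sat_pct, g$imat_pct)
  g$path_length_mm <- path_length_mm
  g <- g[, c("phantom_id", "sat_pct", "imat_pct", "grid_row", "grid_col",
             "path_length_mm")]
  class(g) <- c("qus_phantom_grid", "data.frame")
  g
}

#' Total adipose fraction from SAT and IMAT
#'
#' SAT is expressed relative to the whole phantom volume while IMAT is relative
#' to the muscle (non-SAT) compartment only, so the two compose as
#' `AT = SAT + IMAT * (1 - SAT/100)`. With both factors at their 50 percent
#' maximum the total fat fraction is 75 percent.
#'
#' @param sat_pct SAT in percent of whole volume, in \[0, 100\].
#' @param imat_pct IMAT in percent of the muscle compartment, in \[0, 100\].
#' @return Total adipose fraction AT in percent. Vectorized.
#' @examples
#' total_fat_fraction(50, 50)   # 75
#' total_fat_fraction(25, 25)   # 43.75
#' @export
total_fat_fraction <- function(sat_pct, imat_pct) {
  if (any(sat_pct < 0 | sat_pct > 100, na.rm = TRUE) ||
      any(imat_pct < 0 | imat_pct > 100, na.rm = TRUE))
    stop("'sat_pct' and 'imat_pct' must lie within [0, 100]")
  sat_pct + imat_pct * (1 - sat_pct / 100)
}
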