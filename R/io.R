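#' Write criterion records to CSV
#'
#' One row per signal train with the canonical column order
#' `signal_number, imat, sat, cr1 ... cr6` (plus `phantom_id` and
#' `repeat_index` when present). Values are written with full precision so
#' that `read_records(write_records(x))` round-trips.
#'
#' @param records Criterion record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("signal_number", "imat", "sat", paste0("cr", 1:6))
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0)
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  extra <- intersect(c("phantom_id", "repeat_index"), names(records))
  out <- records[, c(cols, extra), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read criterion records from CSV
#'
#' Validates the schema (header names and numeric cells) with row-addressed
#' error messages.
#'
#' @param path CSV path written by [write_records()] (or equivalent).
#' @return A `qus_records` data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("signal_number", "imat", "sat", paste0("cr", 1:6))
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("malformed record file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0)
      stop("non-numeric value in column '", cn, "' at data row ", bad[1])
    df[[cn]] <- v
  }
  class(df) <- c("qus_records", "data.frame")
  df
}

#' Serialize decision-rule surfaces to JSON
#'
#' Axes, node envelopes and densified envelopes per criterion; readable with
#' [read_surfaces()].
#'
#' @param fit A [fit_decision_rules()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(fit, path) {
  stopifnot(inherits(fit, "qus_dr"))
  obj <- list(levels = fit$levels, dense = fit$dense,
              control = unclass(fit$control),
              surfaces = lapply(fit$surfaces, function(s)
                list(criterion = s$criterion,
                     min_node = s$min_node, max_node = s$max_node,
                     min_dense = s$min_dense, max_dense = s$max_dense)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read decision-rule surfaces from JSON
#'
#' Rebuilds a usable `qus_dr` object (including the slicing rasters) from a
#' [write_surfaces()] file.
#'
#' @param path JSON path.
#' @return A `qus_dr` object.
#' @export
read_surfaces <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- obj$levels; dense <- obj$dense
  control <- do.call(dr_control, obj$control[c("refine", "epsilon_frac")])
  xs <- raster_axis(dense, control$refine)
  surfaces <- lapply(obj$surfaces, function(s) {
    lo2 <- matrix(unlist(s$min_dense), length(dense), length(dense), byrow = FALSE)
    hi2 <- matrix(unlist(s$max_dense), length(dense), length(dense), byrow = FALSE)
    # row-major JSON matrices come back transposed relative to R's column-major
    if (is.matrix(s$min_dense)) { lo2 <- s$min_dense; hi2 <- s$max_dense }
    rng <- max(hi2) - min(lo2); if (rng <= 0) rng <- max(abs(hi2), 1)
    structure(list(criterion = s$criterion, levels = levels, dense = dense,
                   min_node = s$min_node, max_node = s$max_node,
                   min_dense = lo2, max_dense = hi2,
                   min_raster = bilinear_grid(dense, dense, lo2, xs, xs),
                   max_raster = bilinear_grid(dense, dense, hi2, xs, xs),
                   raster = xs, range = rng,
                   epsilon = control$epsilon_frac * rng),
              class = "decision_surface")
  })
  names(surfaces) <- vapply(surfaces, `[[`, character(1), "criterion")
  structure(list(surfaces = surfaces, levels = levels, dense = dense,
                 raster = xs, control = control, n_train = NA_integer_),
            class = "qus_dr")
}

#' Export a feasible region as GeoJSON-style polygons
#'
#' @param region A [feasible_region()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_region <- function(region, path) {
  stopifnot(inherits(region, "qus_region"))
  obj <- list(criteria = region$criteria, area = region$area,
              centroid = region$centroid,
              polygons = lapply(seq_along(region$polygons), function(i)
                list(role = if (region$signs[i] > 0) "outer" else "hole",
                     coordinates = as.matrix(region$polygons[[i]]))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Save a simulated waveform dataset
#'
#' The signal trains are stored with R's native serialization and the
#' manifest (grid, repeats, seed, model parameters) as a JSON sidecar, so a
#' dataset is regenerable and identifiable from its manifest alone.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qus_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset$trains, file.path(dir, "trains.rds"))
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  man <- dataset$manifest
  jsonlite::write_json(
    list(repeats = man$repeats, seed = man$seed, notes = man$notes,
         levels = sort(unique(man$grid$sat_pct)),
         path_length_mm = man$grid$path_length_mm[1],
         model = unclass(man$model)),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
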