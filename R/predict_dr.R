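# Fast margin field for one criterion value (no polygonization).
criterion_field <- function(surface, value) {
  pmin(value - (surface$min_raster - surface$epsilon),
       (surface$max_raster + surface$epsilon) - value) / surface$range
}

#' Recognize one signal with the decision-rule estimator
#'
#' Slices every fitted criterion surface at the measured values and
#' intersects the feasible regions. If the full intersection is empty, the
#' maximum-cardinality subset of criteria with a non-empty intersection is
#' used instead (ties broken by the smallest resulting area). The estimate is
#' the area-weighted centroid of the final region.
#'
#' @param object A fitted [fit_decision_rules()] model.
#' @param values Named numeric vector (or one-row data frame) of criterion
#'   values, names matching the fitted criteria.
#' @param keep_regions Return the per-criterion regions too (slower).
#' @return List of class `qus_recognition`: `estimate` (sat, imat), `region`,
#'   `criteria_used`, `n_components`, `fallback`, `empty`, and per-criterion
#'   regions when requested. Signals whose every single-criterion region is
#'   empty raise an unrecognizable-object error.
#' @export
recognize_signal <- function(object, values, keep_regions = FALSE) {
  stopifnot(inherits(object, "qus_dr"))
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  crit <- names(object$surfaces)
  if (!all(crit %in% names(values)))
    stop("missing criterion values: ",
         paste(setdiff(crit, names(values)), collapse = ", "))
  fields <- lapply(crit, function(cn)
    criterion_field(object$surfaces[[cn]], values[[cn]]))
  names(fields) <- crit
  nonempty <- vapply(fields, function(f) any(f >= 0), logical(1))
  if (!any(nonempty))
    stop("unrecognizable object: every single-criterion region is empty")
  xs <- object$raster

  pick <- NULL; fallback <- FALSE
  full <- Reduce(pmin, fields)
  if (any(full >= 0)) {
    pick <- crit
    field <- full
  } else {
    fallback <- TRUE
    idx_ok <- which(nonempty)
    for (k in rev(seq_len(length(crit) - 1L))) {
      if (k > length(idx_ok)) next
      subs <- utils::combn(idx_ok, k, simplify = FALSE)
      cand <- list()
      for (s in subs) {
        f <- Reduce(pmin, fields[s])
        npix <- sum(f >= 0)
        if (npix > 0L) cand[[length(cand) + 1L]] <- list(s = s, f = f, n = npix)
      }
      if (length(cand) > 0L) {
        n_inside <- vapply(cand, `[[`, numeric(1), "n")
        best <- cand[[which.min(n_inside)]]   # smallest area among max-cardinality
        pick <- crit[best$s]
        field <- best$f
        break
      }
    }
  }
  region <- feasible_region(xs, xs, field, criteria = pick)
  if (region$empty)
    stop("internal error: selected subset produced an empty region")
  out <- list(estimate = centroid_estimate(region), region = region,
              criteria_used = length(pick), criteria = pick,
              n_components = region$n_components,
              fallback = fallback, empty = FALSE)
  if (keep_regions)
    out$criterion_regions <- lapply(crit, function(cn)
      feasible_region(xs, xs, fields[[cn]], criteria = cn))
  class(out) <- "qus_recognition"
  out
}

#' @export
print.qus_recognition <- function(x, ...) {
  cat(sprintf("Recognition: SAT %.2f%%, IMAT %.2f%% (criteria %d/%s%s, %d component(s))\n",
              x$estimate["sat"], x$estimate["imat"], x$criteria_used,
              paste(x$criteria, collapse = "+"),
              if (x$fallback) ", fallback" else "", x$n_components))
  invisible(x)
}

#' Predict SAT and IMAT for criterion records
#'
#' Applies [recognize_signal()] to every row of a criterion record table.
#' With `aggregate = "object"`, the per-signal estimates of each phantom are
#' averaged into one object-level prediction (the repeat signals of a test
#' object are estimated independently and their estimates pooled).
#'
#' @param object A fitted [fit_decision_rules()] model.
#' @param newdata Criterion records with `cr1` ... `cr6` (and `phantom_id`
#'   for object aggregation).
#' @param aggregate `"signal"` (default) or `"object"`.
#' @param ... Unused.
#' @return Data frame of predictions: `sat_hat`, `imat_hat`, diagnostics
#'   (`criteria_used`, `n_components`, `fallback`), plus ids and truth columns
#'   when present in `newdata`.
#' @export
predict.qus_dr <- function(object, newdata,
                           aggregate = c("signal", "object"), ...) {
  aggregate <- match.arg(aggregate)
  crit <- names(object$surfaces)
  res <- lapply(seq_len(nrow(newdata)), function(i) {
    r <- recognize_signal(object, unlist(newdata[i, crit, drop = FALSE]))
    data.frame(sat_hat = r$estimate[["sat"]], imat_hat = r$estimate[["imat"]],
               criteria_used = r$criteria_used,
               n_components = r$n_components, fallback = r$fallback)
  })
  res <- do.call(rbind, res)
  for (cn in c("signal_number", "phantom_id", "repeat_index", "sat", "imat"))
    if (cn %in% names(newdata)) res[[cn]] <- newdata[[cn]]
  if (aggregate == "object") {
    if (!"phantom_id" %in% names(res))
      stop("object-level aggregation needs a 'phantom_id' column")
    agg <- stats::aggregate(res[, c("sat_hat", "imat_hat")],
                            by = list(phantom_id = res$phantom_id), mean)
    extras <- stats::aggregate(
      res[, c("criteria_used", "fallback"), drop = FALSE],
      by = list(phantom_id = res$phantom_id), mean)
    agg$mean_criteria_used <- extras$criteria_used
    agg$any_fallback <- extras$fallback > 0
    if (all(c("sat", "imat") %in% names(res))) {
      tr <- unique(res[, c("phantom_id", "sat", "imat")])
      agg <- merge(agg, tr, by = "phantom_id", sort = TRUE)
    }
    return(agg)
  }
  res
}
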