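#' Build the five train/test split plans
#'
#' The evaluation protocol reserves 3 of the 15 repeat signals of every
#' object for testing. Splits 1--3 are index-based (fixed repeat-index
#' triples), splits 4--5 draw three random repeats per object with a seeded
#' generator. Train and test are disjoint and every object appears in both.
#'
#' @param records Criterion records with `phantom_id` and `repeat_index`.
#' @param index_sets List of repeat-index triples for the index-based splits
#'   (default `list(1:3, 4:6, 7:9)`).
#' @param n_random Number of random splits (default 2).
#' @param n_test Test signals per object (default 3).
#' @param seed Seed for the random splits (default 101).
#' @return List of class `qus_splits`; each element has `name`, `mode` and a
#'   logical `test` vector aligned with the rows of `records`.
#' @export
make_splits <- function(records, index_sets = list(1:3, 4:6, 7:9),
                        n_random = 2L, n_test = 3L, seed = 101L) {
  stopifnot(all(c("phantom_id", "repeat_index") %in% names(records)))
  reps <- sort(unique(records$repeat_index))
  splits <- list()
  for (k in seq_along(index_sets)) {
    idx <- index_sets[[k]]
    if (!all(idx %in% reps)) stop("index split refers to missing repeats")
    splits[[length(splits) + 1L]] <-
      list(name = sprintf("split%d", k), mode = "by_index",
           test = records$repeat_index %in% idx)
  }
  set.seed(seed)
  ids <- unique(records$phantom_id)
  for (k in seq_len(n_random)) {
    test <- logical(nrow(records))
    for (id in ids) {
      rows <- which(records$phantom_id == id)
      pick <- sample(rows, n_test)
      test[pick] <- TRUE
    }
    splits[[length(splits) + 1L]] <-
      list(name = sprintf("split%d", length(index_sets) + k),
           mode = "random", test = test)
  }
  for (s in splits) {
    per <- tapply(s$test, records$phantom_id, sum)
    if (any(per != n_test))
      stop("split construction failed: uneven test counts")
  }
  structure(splits, class = "qus_splits")
}

#' Individuality statistics of the evaluation criteria
#'
#' For each criterion: whole-dataset mean `M`, SD `SD.m` and coefficient of
#' variation `CV.m = SD.m/M`; the mean per-object SD (`SD.o`) and mean
#' per-object CV (`CV.o`); the index of individuality `II = CV.o/CV.m`; and
#' its reciprocal `RII = 1/II`. Low II (< 0.6) indicates strong
#' between-object discriminating power.
#'
#' @param records Criterion records with `phantom_id` and criterion columns.
#' @param criteria Criterion column names (default `cr1` ... `cr6`).
#' @return Data frame with one row per criterion and columns
#'   `M, SD.m, CV.m, SD.o, CV.o, II, RII` (CVs as fractions).
#' @export
individuality <- function(records, criteria = paste0("cr", 1:6)) {
  stopifnot("phantom_id" %in% names(records),
            all(criteria %in% names(records)))
  if (length(unique(records$phantom_id)) < 2L)
    stop("need at least two objects")
  if (any(table(records$phantom_id) < 2L))
    stop("need at least two records per object")
  rows <- lapply(criteria, function(cn) {
    v <- records[[cn]]
    M <- mean(v); SDm <- stats::sd(v)
    if (M == 0) stop("zero mean for ", cn)
    CVm <- SDm / M
    if (CVm == 0) stop("zero whole-dataset CV for ", cn)
    SDo <- mean(tapply(v, records$phantom_id, stats::sd))
    CVo <- mean(tapply(v, records$phantom_id,
                       function(x) stats::sd(x) / mean(x)))
    II <- CVo / CVm
    data.frame(criterion = cn, M = M, SD.m = SDm, CV.m = CVm,
               SD.o = SDo, CV.o = CVo, II = II,
               RII = if (II > 0) 1 / II else Inf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Object-level regression accuracy metrics
#'
#' Pearson correlation `R`, coefficient of determination `R2`, sum of squared
#' errors `SSE` and standard error of estimate `SEE = sqrt(SSE/(n-2))`, the
#' regression convention with `n` objects.
#'
#' @param truth True values (one per object).
#' @param predictions Predicted values, same length.
#' @return Named list `R`, `R2`, `SSE`, `SEE`, `MAE`, `MAE_sd`, `n`.
#' @export
regression_metrics <- function(truth, predictions) {
  n <- length(truth)
  stopifnot(length(predictions) == n)
  if (n < 3L) stop("need at least 3 objects")
  err <- truth - predictions
  sse <- sum(err^2)
  list(R = stats::cor(truth, predictions),
       R2 = 1 - sse / sum((truth - mean(truth))^2),
       SSE = sse, SEE = sqrt(sse / (n - 2)),
       MAE = mean(abs(err)), MAE_sd = stats::sd(abs(err)), n = n)
}

#' Error topology over the phantom grid
#'
#' Absolute per-object error arranged as a SAT x IMAT matrix, one cell per
#' phantom of the grid.
#'
#' @param predictions Object-level prediction table with `sat`, `imat` truth
#'   columns and a `sat_hat`/`imat_hat` column.
#' @param target `"sat"` or `"imat"`.
#' @param levels Grid levels (inferred by default).
#' @return Matrix of absolute errors, rows = SAT levels, cols = IMAT levels
#'   (dimnames carry the levels).
#' @export
error_topology <- function(predictions, target = c("sat", "imat"),
                           levels = NULL) {
  target <- match.arg(target)
  stopifnot(all(c("sat", "imat") %in% names(predictions)))
  hat <- predictions[[paste0(target, "_hat")]]
  if (is.null(hat)) stop("missing prediction column ", paste0(target, "_hat"))
  if (is.null(levels)) levels <- sort(unique(predictions$sat))
  err <- abs(predictions[[target]] - hat)
  M <- matrix(NA_real_, length(levels), length(levels),
              dimnames = list(sat = levels, imat = levels))
  ii <- match(predictions$sat, levels)
  jj <- match(predictions$imat, levels)
  if (anyNA(ii) || anyNA(jj)) stop("predictions contain off-grid objects")
  M[cbind(ii, jj)] <- err
  if (anyNA(M)) stop("predictions do not cover the full grid")
  M
}

#' Compare decision-rule and network errors across splits
#'
#' Builds the per-split and averaged mean absolute error (+/- SD across
#' objects) table for both methods and both targets, from object-level
#' prediction tables produced on identical partitions.
#'
#' @param pr_results,ann_results Named lists (one element per split) of
#'   object-level prediction tables with `sat`, `imat`, `sat_hat`,
#'   `imat_hat`.
#' @return Data frame with one row per split plus an `average` row and
#'   columns `<method>_<target>_mae` / `_sd`.
#' @export
compare_methods <- function(pr_results, ann_results) {
  stopifnot(length(pr_results) == length(ann_results),
            identical(names(pr_results), names(ann_results)))
  one <- function(tab, method) {
    c(stats::setNames(c(mean(abs(tab$imat - tab$imat_hat)),
                        stats::sd(abs(tab$imat - tab$imat_hat)),
                        mean(abs(tab$sat - tab$sat_hat)),
                        stats::sd(abs(tab$sat - tab$sat_hat))),
                      paste0(method, c("_imat_mae", "_imat_sd",
                                       "_sat_mae", "_sat_sd"))))
  }
  rows <- lapply(seq_along(pr_results), function(k)
    c(one(pr_results[[k]], "pr"), one(ann_results[[k]], "ann")))
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- rbind(tab, colMeans(tab))
  tab <- cbind(split = c(names(pr_results), "average"), tab)
  rownames(tab) <- NULL
  tab
}
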