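records15 <- local({
  rec <- do.call(rbind, lapply(1:15, function(r) {
    d <- expand.grid(sat = c(0, 25, 50), imat = c(0, 25, 50))
    d$repeat_index <- r
    d
  }))
  rec$phantom_id <- sprintf("S%02.0f_I%02.0f", rec$sat, rec$imat)
  set.seed(8)
  for (cn in paste0("cr", 1:6)) rec[[cn]] <- 1 + rec$sat / 50 + rnorm(nrow(rec), 0, 0.05)
  rec
})

test_that("split plans reserve 3 of 15 repeats per object, disjointly", {
  sp <- make_splits(records15, seed = 11)
  expect_length(sp, 5L)
  for (s in sp) {
    expect_equal(sum(s$test), 3L * 9L)
    expect_equal(sum(!s$test), 12L * 9L)
    per <- tapply(s$test, records15$phantom_id, sum)
    expect_true(all(per == 3L))
  }
  expect_equal(sapply(sp, `[[`, "mode"),
               c(rep("by_index", 3), rep("random", 2)))
  # seeded random splits reproduce
  sp2 <- make_splits(records15, seed = 11)
  expect_identical(sp[[5]]$test, sp2[[5]]$test)
  expect_false(identical(make_splits(records15, seed = 12)[[5]]$test,
                         sp[[5]]$test))
})

test_that("individuality indices follow their definitions", {
  ind <- individuality(records15)
  expect_equal(ind$II, ind$CV.o / ind$CV.m)
  expect_equal(ind$II * ind$RII, rep(1, 6))
  # identical repeats within every object -> zero within-object CV -> II = 0
  rec0 <- records15[records15$repeat_index <= 2, ]
  for (cn in paste0("cr", 1:6))
    rec0[[cn]] <- ave(rec0[[cn]], rec0$phantom_id)
  ind0 <- individuality(rec0)
  expect_equal(ind0$II, rep(0, 6))
  expect_true(all(is.infinite(ind0$RII)))
  # one common distribution (within == between variance) -> II near 1
  set.seed(21)
  rec1 <- records15
  for (cn in paste0("cr", 1:6)) rec1[[cn]] <- rnorm(nrow(rec1), 10, 1)
  ind1 <- individuality(rec1)
  expect_true(all(abs(ind1$II - 1) < 0.25))
})

test_that("regression metrics are mutually consistent", {
  truth <- c(0, 12.5, 25, 37.5, 50)
  perfect <- regression_metrics(truth, truth)
  expect_equal(perfect[c("R", "R2", "SSE", "SEE", "MAE")],
               list(R = 1, R2 = 1, SSE = 0, SEE = 0, MAE = 0))
  # 4-point hand computation: errors (1, -2, 0, 1) -> SSE 6
  t4 <- c(10, 20, 30, 40); p4 <- c(9, 22, 30, 39)
  m <- regression_metrics(t4, p4)
  expect_equal(m$SSE, 6)
  expect_equal(m$SEE, sqrt(6 / 2))
  expect_equal(m$R2, 1 - 6 / sum((t4 - 25)^2))
  expect_equal(m$MAE, 1)
  expect_error(regression_metrics(1:2, 1:2), "at least 3")
})

test_that("error topology maps objects onto the grid", {
  pred <- expand.grid(sat = c(0, 25, 50), imat = c(0, 25, 50))
  pred$sat_hat <- pred$sat
  pred$imat_hat <- pred$imat
  M <- error_topology(pred, "sat")
  expect_true(all(M == 0))
  pred$sat_hat[4] <- pred$sat[4] + 7
  M2 <- error_topology(pred, "sat")
  expect_equal(sum(M2 > 0), 1L)
  expect_equal(max(M2), 7)
  expect_equal(as.vector(M2[cbind(match(pred$sat, c(0, 25, 50)),
                                  match(pred$imat, c(0, 25, 50)))]),
               abs(pred$sat - pred$sat_hat))
  expect_error(error_topology(pred[-1, ], "sat"), "cover")
})

test_that("method comparison tables recompute their averages", {
  pred <- expand.grid(sat = c(0, 25, 50), imat = c(0, 25, 50))
  set.seed(5)
  pred$sat_hat <- pred$sat + rnorm(9)
  pred$imat_hat <- pred$imat + rnorm(9)
  prl <- list(split1 = pred, split2 = pred)
  tab <- compare_methods(prl, prl)
  expect_equal(tab$pr_imat_mae, tab$ann_imat_mae)   # identical methods
  avg <- tab[tab$split == "average", -1]
  expect_equal(as.numeric(avg),
               as.numeric(colMeans(tab[tab$split != "average", -1])))
})
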