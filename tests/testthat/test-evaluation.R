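test_that("confusion counts match a brute-force tally", {
  ref <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  cc <- confusion_counts(ref, ref)
  expect_equal(cc, list(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  cc2 <- confusion_counts(!ref, ref)
  expect_equal(c(cc2$TP, cc2$TN), c(0L, 0L))

  set.seed(64)
  p <- matrix(runif(64 * 64) < 0.3, 64, 64)
  r <- matrix(runif(64 * 64) < 0.4, 64, 64)
  cc3 <- confusion_counts(p, r)
  tally <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(p)) {
    k <- if (p[i] && r[i]) "TP" else if (p[i]) "FP" else if (r[i]) "FN" else "TN"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(cc3), tally)
  expect_equal(sum(unlist(cc3)), 64 * 64)
  expect_error(confusion_counts(p, r[1:10, 1:10]), "different dims")
})

test_that("metric formulas are evaluated exactly", {
  m <- seg_metrics(list(TP = 10, FP = 0, FN = 0))
  expect_equal(unlist(m), c(precision = 1, sensitivity = 1, dsc = 1, iou = 1))

  m2 <- seg_metrics(list(TP = 8, FP = 2, FN = 2))
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$dsc, 0.8)
  expect_equal(m2$iou, 2 / 3)

  m3 <- seg_metrics(list(TP = 0, FP = 5, FN = 5))
  expect_equal(unlist(m3), c(precision = 0, sensitivity = 0, dsc = 0, iou = 0))

  # zero denominators signal undefined, never silent 0
  m4 <- seg_metrics(list(TP = 0, FP = 0, FN = 3))
  expect_true(is.na(m4$precision))
  expect_false(is.na(m4$sensitivity))
})

test_that("DSC and IoU satisfy their algebraic identity on a count grid", {
  for (TP in c(1, 3, 10)) for (FP in 0:3) for (FN in 0:3) {
    m <- seg_metrics(list(TP = TP, FP = FP, FN = FN))
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
  }
  # monotonicity: precision falls with FP, sensitivity with FN
  prec <- vapply(0:5, function(fp) seg_metrics(list(TP = 5, FP = fp, FN = 0))$precision, numeric(1))
  sens <- vapply(0:5, function(fn) seg_metrics(list(TP = 5, FP = 0, FN = fn))$sensitivity, numeric(1))
  expect_true(all(diff(prec) <= 0))
  expect_true(all(diff(sens) <= 0))
})

test_that("slide splits reproduce the cohort partition sizes", {
  sp <- split_slides(1:122, train_fraction = 0.377, seed = 5)
  expect_length(sp$train, 46L)
  expect_length(sp$test, 76L)
  expect_setequal(c(sp$train, sp$test), as.character(1:122))

  folds <- split_slides(letters[1:6], k = 3, seed = 2)
  expect_equal(lengths(folds), rep(2L, 3))
  expect_setequal(unlist(folds), letters[1:6])

  # determinism and reorder invariance
  expect_identical(split_slides(1:122, train_fraction = 0.377, seed = 5), sp)
  expect_identical(split_slides(sample(letters[1:6]), k = 3, seed = 2), folds)
  expect_error(split_slides(1:2, k = 3), "cannot make")

  # fold sizes differ by at most one
  f7 <- split_slides(1:7, k = 3, seed = 1)
  expect_lte(diff(range(lengths(f7))), 1L)
})

test_that("Fisher's LSD reproduces the two-group worked example", {
  A <- c(0.90, 0.92, 0.88); B <- c(0.50, 0.55, 0.45)
  res <- lsd_test(list(A = A, B = B))
  p <- res$pairs
  expect_equal(p$mean_diff, 0.40, tolerance = 1e-12)
  expect_equal(res$mse, 0.00145, tolerance = 1e-10)
  expect_equal(p$std_error, 0.031091, tolerance = 1e-4)
  expect_equal(p$t, 12.86, tolerance = 0.01 / 12.86)
  expect_equal(res$df_residual, 4)
  expect_lt(p$p_value, 0.001)
  # two-group LSD == pooled two-sample t-test
  tt <- t.test(A, B, var.equal = TRUE)
  expect_equal(p$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(unname(p$t), unname(tt$statistic), tolerance = 1e-12)
})

test_that("LSD is symmetric and guards degenerate variance", {
  g <- c(0.5, 0.6, 0.7)
  res <- lsd_test(list(X = g, Y = g))
  expect_equal(res$pairs$mean_diff, 0)
  expect_equal(res$pairs$p_value, 1, tolerance = 1e-9)
  expect_error(lsd_test(list(A = c(1, 1), B = c(2, 2))), "degenerate variance")
  expect_error(lsd_test(list(A = c(1, 2))), "two groups")

  # antisymmetry under pair swap: mean_diff(i,j) = -mean_diff(j,i)
  r1 <- lsd_test(list(A = c(0.9, 0.92, 0.88), B = c(0.5, 0.55, 0.45)))
  r2 <- lsd_test(list(B = c(0.5, 0.55, 0.45), A = c(0.9, 0.92, 0.88)))
  expect_equal(r1$pairs$mean_diff, -r2$pairs$mean_diff)

  # three-group pairwise p-values carry the pooled residual df
  r3 <- lsd_test(list(A = c(0.9, 0.92, 0.88), B = c(0.5, 0.55, 0.45),
                      C = c(0.7, 0.72, 0.68)))
  expect_equal(r3$df_residual, 6)
  expect_equal(nrow(r3$pairs), 3)
})

test_that("undefined slide scores are excluded from LSD with a notice", {
  expect_message(
    res <- lsd_test(list(A = c(0.9, 0.92, NA, 0.88), B = c(0.5, 0.55, 0.45))),
    "undefined")
  expect_equal(res$n[["A"]], 3)
})
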