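test_that("confusion counts the four joint outcomes", {
  cc <- confusion(c(1, 0), c(1, 0))
  expect_equal(cc[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, TN = 1L, FN = 0L, FP = 0L)[c("TP", "FN", "TN", "FP")])
  y <- c(1, 1, 0, 0)
  perverse <- confusion(y, 1 - y)
  expect_equal(perverse$TP, 0L)
  expect_equal(perverse$TN, 0L)
  expect_error(confusion(c(1, 0), c(1)), class = "dimension_error")
  expect_error(confusion(c(1, 2), c(1, 0)), class = "data_error")

  set.seed(42)
  yt <- rbinom(1000, 1, 0.3)
  yp <- rbinom(1000, 1, 0.6)
  cc <- confusion(yt, yp)
  loop <- c(TP = 0, FN = 0, TN = 0, FP = 0)
  for (i in 1:1000) {
    key <- if (yt[i] == 1 && yp[i] == 1) "TP" else
      if (yt[i] == 1) "FN" else if (yp[i] == 0) "TN" else "FP"
    loop[key] <- loop[key] + 1
  }
  expect_equal(unlist(cc[names(loop)]), loop, ignore_attr = TRUE)
  expect_equal(cc$TP + cc$FN + cc$TN + cc$FP, 1000L)
})

test_that("threshold metrics match the defining equations", {
  perfect <- compute_metrics(list(TP = 1, FN = 0, TN = 1, FP = 0))
  expect_equal(unname(perfect), rep(1, 5))
  perverse <- compute_metrics(list(TP = 0, FN = 1, TN = 0, FP = 1))
  expect_equal(perverse[["ACC"]], 0)
  expect_equal(perverse[["MCC"]], -1)
  # hand evaluation: 300 / sqrt(100 * 105 * 20 * 15)
  m <- compute_metrics(list(TP = 90, FN = 10, TN = 5, FP = 15))
  expect_equal(m[["MCC"]], 300 / sqrt(3150000), tolerance = 1e-12)
  expect_equal(m[["MCC"]], 0.16903, tolerance = 1e-4)
})

test_that("metrics agree with the literal-ratio oracle on 1000 random tables", {
  set.seed(7)
  for (rep in 1:1000) {
    cnt <- stats::rpois(4, lambda = sample(c(0.5, 3, 40, 400), 1))
    if (sum(cnt) == 0) cnt[1] <- 1
    got <- compute_metrics(list(TP = cnt[1], FN = cnt[2],
                                TN = cnt[3], FP = cnt[4]))
    want <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-13)
  }
})

test_that("MCC and ACC are class-relabeling symmetric; F1 is not", {
  set.seed(8)
  for (rep in 1:50) {
    cnt <- 1 + stats::rpois(4, 20)
    a <- compute_metrics(list(TP = cnt[1], FN = cnt[2],
                              TN = cnt[3], FP = cnt[4]))
    b <- compute_metrics(list(TP = cnt[3], FN = cnt[4],
                              TN = cnt[1], FP = cnt[2]))
    expect_equal(a[["MCC"]], b[["MCC"]], tolerance = 1e-12)
    expect_equal(a[["ACC"]], b[["ACC"]], tolerance = 1e-12)
  }
  asym <- compute_metrics(list(TP = 10, FN = 30, TN = 50, FP = 2))
  swapped <- compute_metrics(list(TP = 50, FN = 2, TN = 10, FP = 30))
  expect_false(isTRUE(all.equal(asym[["F1"]], swapped[["F1"]])))
})

test_that("roc_auc equals the pair-enumeration probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3, 1, 2), c(1, 1, 0, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "undefined_metric_error")

  set.seed(9)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # generates ties
    expect_equal(roc_auc(s, y), oracle_auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("roc_auc reversal identity holds for tie-free scores", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(n)
    expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
})

test_that("pr_auc step integration matches the threshold-loop oracle", {
  expect_equal(pr_auc(c(5, 4, 3, 1, 2), c(1, 1, 0, 0, 0)), 1)
  expect_equal(pr_auc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(pr_auc(1:3, c(0, 0, 0)), class = "undefined_metric_error")

  set.seed(13)
  for (rep in 1:30) {
    n <- 50
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) next
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    expect_equal(pr_auc(s, y), oracle_prauc(s, y), tolerance = 1e-12)
  }
})

test_that("metric_set thresholds at 0.5 and flags undefined ranking metrics", {
  s <- c(0.9, 0.6, 0.4, 0.1)
  y <- c(1, 0, 1, 0)
  ms <- metric_set(s, y)
  expect_named(ms, c("PR", "RE", "ACC", "F1", "MCC", "AUC", "AUPRC"))
  expect_equal(ms[["ACC"]], 0.5)
  expect_equal(ms[["AUC"]], 0.75)
  one_class <- metric_set(c(0.2, 0.7), c(1, 1), allow_undefined = TRUE)
  expect_true(is.na(one_class[["AUC"]]))
  expect_false(is.na(one_class[["ACC"]]))
})

test_that("curve coordinates trace the ROC and PR curves consistently", {
  set.seed(33)
  y <- rbinom(80, 1, 0.4)
  s <- round(rnorm(80) + y, 1)
  cc <- curve_coordinates(s, y)
  expect_equal(names(cc), c("threshold", "tpr", "fpr", "precision", "recall"))
  # thresholds descend; rates are monotone non-decreasing along the curve
  expect_true(all(diff(cc$threshold) < 0))
  expect_true(all(diff(cc$tpr) >= 0))
  expect_true(all(diff(cc$fpr) >= 0))
  expect_equal(cc$tpr[nrow(cc)], 1)
  expect_equal(cc$fpr[nrow(cc)], 1)
  expect_equal(cc$tpr, cc$recall)
  # step integration over these coordinates reproduces pr_auc exactly
  expect_equal(sum(diff(c(0, cc$recall)) * cc$precision), pr_auc(s, y),
               tolerance = 1e-12)
  # trapezoidal integration over the ROC coordinates reproduces roc_auc
  fpr <- c(0, cc$fpr); tpr <- c(0, cc$tpr)
  expect_equal(sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2),
               roc_auc(s, y), tolerance = 1e-12)
  expect_error(curve_coordinates(1:3, c(1, 1, 1)),
               class = "undefined_metric_error")
})
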