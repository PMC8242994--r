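test_that("stratified folds balance both classes across folds", {
  y <- c(rep(1, 757), rep(0, 71))
  folds <- stratified_folds(y, 10, seed = 3)
  expect_setequal(unique(folds), 1:10)
  expect_length(folds, 828)
  neg_per_fold <- table(folds[y == 0])
  pos_per_fold <- table(folds[y == 1])
  expect_true(all(neg_per_fold %in% 7:8))
  expect_true(all(pos_per_fold %in% 75:76))
  # global sizes also differ by at most one
  expect_lte(diff(range(table(folds))), 1)
})

test_that("fold assignment is deterministic and supports leave-one-out", {
  y <- rep(c(0, 1), 10)
  expect_identical(stratified_folds(y, 5, seed = 9),
                   stratified_folds(y, 5, seed = 9))
  loo <- suppressWarnings(stratified_folds(y, 20, seed = 1))
  expect_setequal(loo, 1:20)
  expect_equal(max(table(loo)), 1)
  expect_error(stratified_folds(y, 21), class = "config_error")
  expect_warning(stratified_folds(c(rep(1, 30), 0, 0), 4, seed = 1),
                 regexp = "fewer members")
})

test_that("constant-majority dummy recovers prevalence ACC and zero MCC", {
  ds <- generate_bimodal(sim_config(n = 828, imbalance_ratio = 10.662,
                                    missing_frac = 0, seed = 17))
  rep_dummy <- cross_validate(model_spec("majority"),
                              imbalance_strategy("base"), ds,
                              cv_plan(k = 10, repeats = 2, seed = 5))
  expect_equal(unname(rep_dummy$mean[["ACC"]]), 757 / 828, tolerance = 1e-12)
  expect_equal(unname(rep_dummy$mean[["MCC"]]), 0)
  # the constant score differs slightly between training folds, so the
  # pooled ranking is only approximately uninformative
  expect_lt(abs(rep_dummy$mean[["AUC"]] - 0.5), 0.05)
  expect_equal(nrow(rep_dummy$values), 2)
})

test_that("cross-validation is reproducible bit for bit", {
  ds <- make_small_dataset(80, ratio = 3, seed = 23)
  spec <- model_spec("rf_100")
  a <- cross_validate(spec, imbalance_strategy("cw"), ds,
                      cv_plan(k = 2, repeats = 1, seed = 11))
  b <- cross_validate(spec, imbalance_strategy("cw"), ds,
                      cv_plan(k = 2, repeats = 1, seed = 11))
  expect_identical(a$values, b$values)
})

test_that("fold-wise imputation uses training-fold medians only", {
  # feature 1 of x1: training rows centred near 0, one extreme test value;
  # the held-out missing cell must be filled from the training median
  ds <- make_small_dataset(40, ratio = 3, seed = 31)
  tr <- 1:30
  te <- 31:40
  ds$x1[te[1], 1] <- NA
  ds$x1[te[2], 1] <- 1e6
  med_train <- stats::median(ds$x1[tr, 1])
  med_all <- stats::median(ds$x1[-te[1], 1])
  expect_false(isTRUE(all.equal(med_train, med_all)))
  fitted <- opcnn:::fit_medians(subset_rows(ds, tr), seq_along(tr))
  test_imputed <- opcnn:::apply_medians(subset_rows(ds, te), fitted)
  expect_equal(unname(test_imputed$x1[1, 1]), med_train)
})

test_that("SMOTE augmentation stays inside the training fold", {
  ds <- make_small_dataset(60, ratio = 4, seed = 37)
  folds <- stratified_folds(ds$y, 3, seed = 2)
  for (f in 1:3) {
    tr <- subset_rows(ds, which(folds != f))
    aug <- apply_strategy(tr, imbalance_strategy("smote_cw", seed = f))
    n_tr <- length(tr$y)
    expect_identical(aug$data$x1[seq_len(n_tr), ], tr$x1)
    expect_true(all(aug$data$synthetic[-seq_len(n_tr)]))
    # weights re-derived on augmented counts satisfy the identity
    cb <- class_balance(aug$data)
    expect_equal(aug$weights[["w_pos"]] * cb$n_pos,
                 aug$weights[["w_neg"]] * cb$n_neg, tolerance = 1e-9)
  }
})

test_that("compare_models star-codes Welch tests against the best model", {
  mk_report <- function(vals, label) {
    values <- matrix(vals, ncol = 7,
                     dimnames = list(NULL, c("PR", "RE", "ACC", "F1",
                                             "MCC", "AUC", "AUPRC")))
    structure(list(label = label, strategy = "base", values = values,
                   mean = colMeans(values), sd = apply(values, 2, sd),
                   dropped = integer(7), meta = list()),
              class = "cv_report")
  }
  set.seed(2)
  hi <- rep(0.98, 20) + rnorm(20, sd = 0.01)
  lo <- rep(0.70, 20) + rnorm(20, sd = 0.01)
  names(hi) <- names(lo) <- NULL
  rep_hi <- mk_report(rep(hi, 7), "high")
  rep_lo <- mk_report(rep(lo, 7), "low")
  tab <- compare_models(list(rep_hi, rep_lo), "MCC")
  expect_true(tab$best[tab$label == "high"])
  expect_equal(tab$stars[tab$label == "low"], "***")
  expect_lt(tab$p_value[tab$label == "low"], 0.001)

  same <- compare_models(list(mk_report(rep(0.5, 140), "a"),
                              mk_report(rep(0.5, 140), "b")), "MCC")
  expect_equal(same$p_value[!same$best], 1)
  expect_equal(same$stars[!same$best], "")

  expect_equal(star_code(0.049), "*")
  expect_equal(star_code(0.051), "")
  expect_equal(star_code(0.0099), "**")
  expect_equal(star_code(0.0009), "***")
})

test_that("benchmark_table populates every cell with all seven metrics", {
  ds <- make_small_dataset(200, ratio = 3, seed = 43)
  specs <- list(model_spec("rf_100"), model_spec("majority"))
  bt <- benchmark_table(specs, c("base", "cw"), ds,
                        cv_plan(k = 3, repeats = 2, seed = 7))
  expect_s3_class(bt, "benchmark_table")
  tab <- bt$table
  expect_equal(nrow(tab), 2 * 2 * 7)
  expect_false(anyNA(tab$mean))
  for (metric in unique(tab$metric)) {
    sub <- tab[tab$metric == metric, ]
    expect_equal(sum(sub$best), 1)
    expect_equal(sub$mean[sub$best], max(sub$mean))
  }
  bt2 <- benchmark_table(specs, c("base", "cw"), ds,
                         cv_plan(k = 3, repeats = 2, seed = 7))
  expect_identical(bt$table, bt2$table)
})

test_that("benchmark results serialise to CSV and JSON", {
  ds <- make_small_dataset(80, ratio = 3, seed = 51)
  bt <- benchmark_table(list(model_spec("majority")), "base", ds,
                        cv_plan(k = 2, repeats = 1, seed = 3))
  dir <- tempfile()
  paths <- write_benchmark(bt, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "raw_values.json")))
  back <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_equal(nrow(back), 7)
})
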