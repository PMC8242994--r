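# The experimental protocol: stratified 10-fold cross-validation repeated
# 20 times, mean +/- sd reporting per repeat, and two-sided t-tests with
# star coding against the best model per metric.

#' Cross-validation plan
#'
#' @param k Number of folds (>= 2; default 10).
#' @param repeats Number of independent CV repetitions (default 20).
#' @param seed Base seed; repeat `r` splits folds with seed `seed + r`.
#' @return A list of class `"cv_plan"`.
#' @export
cv_plan <- function(k = 10L, repeats = 20L, seed = 1L) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2L) opcnn_stop("k must be >= 2", "config_error")
  if (repeats < 1L) opcnn_stop("repeats must be >= 1", "config_error")
  structure(list(k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Partitions sample indices into `k` folds so that, within each class and
#' globally, fold sizes differ by at most one. Every sample appears in
#' exactly one test fold. With 757 positives and 71 negatives and k = 10,
#' every fold receives 7 or 8 negatives and 75 or 76 positives.
#'
#' @param y Binary label vector.
#' @param k Number of folds (`2 <= k <= length(y)`).
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- check_binary(y, "y")
  n <- length(y)
  k <- as.integer(k)
  if (k > n) opcnn_stop("k cannot exceed the sample count", "config_error")
  if (k < 2L) opcnn_stop("k must be >= 2", "config_error")
  if (any(tabulate(y + 1, 2) < k)) {
    warning("a class has fewer members than folds; some folds will lack it")
  }
  with_seed(seed, {
    folds <- integer(n)
    perm <- sample.int(k)
    pos <- 0L
    for (cls in sample(c(0L, 1L))) {
      idx <- which(y == cls)
      if (length(idx) == 0L) next
      idx <- if (length(idx) > 1L) sample(idx) else idx
      folds[idx] <- perm[((pos + seq_along(idx) - 1L) %% k) + 1L]
      pos <- pos + length(idx)
    }
    folds
  })
}

#' Model specification for the benchmark harness
#'
#' Bundles a model kind with its architecture and training configuration so
#' that [cross_validate()] can build a fresh model per fold.
#'
#' @param kind One of `"opcnn"`, `"dmnn"`, `"unimodal"`, `"svm_poly3_C10"`,
#'   `"rf_100"`, `"majority"`.
#' @param cfg The architecture config ([opcnn_config()], [dmnn_config()],
#'   [unimodal_config()]); ignored for the non-neural kinds.
#' @param tcfg A [train_config()] for the neural kinds.
#' @param label Display label (defaults to a name derived from the kind).
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(kind = c("opcnn", "dmnn", "unimodal",
                                "svm_poly3_C10", "rf_100", "majority"),
                       cfg = NULL, tcfg = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("opcnn", "dmnn", "unimodal")) {
    cfg <- cfg %||% switch(kind, opcnn = opcnn_config(),
                           dmnn = dmnn_config(), unimodal = unimodal_config())
    expected <- paste0(kind, "_config")
    if (!inherits(cfg, expected)) {
      opcnn_stop(sprintf("cfg must be a %s for kind '%s'", expected, kind),
                 "config_error")
    }
    tcfg <- tcfg %||% train_config()
  }
  label <- label %||% switch(kind,
    opcnn = "OPCNN",
    dmnn = sprintf("DMNN %s/%s", cfg$fusion_level, cfg$fusion_mode),
    unimodal = sprintf("Unimodal (%s)", cfg$modality),
    svm_poly3_C10 = "SVM (poly-3, C=10)",
    rf_100 = "RF (100 trees)",
    majority = "Majority dummy")
  structure(list(kind = kind, cfg = cfg, tcfg = tcfg, label = label),
            class = "model_spec")
}

scale_stats <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(m, st) sweep(sweep(m, 2, st$mu), 2, st$sd, "/")

fit_spec <- function(spec, train, weights, strategy_kind, seed) {
  if (spec$kind %in% c("opcnn", "dmnn", "unimodal")) {
    cfg <- spec$cfg
    cfg$seed <- derive_seed(cfg$seed, seed)
    model <- switch(spec$kind, opcnn = build_opcnn(cfg),
                    dmnn = build_dmnn(cfg), unimodal = build_unimodal(cfg))
    tcfg <- spec$tcfg
    tcfg$seed <- derive_seed(tcfg$seed, seed, 7L)
    tcfg$class_weights <- as.numeric(weights)
    tcfg$loss <- if (all(weights == 1)) "bce" else "weighted_bce"
    fit(model, train, tcfg)
  } else {
    cw <- if (strategy_kind == "base") NULL else weights
    fit_baseline(spec$kind, train, seed = seed, class_weights = cw)
  }
}

#' Repeated stratified cross-validation of one model/strategy pair
#'
#' For every repeat a fresh stratified fold split is drawn (seed =
#' `plan$seed + repeat`). Within each fold, imputation medians and scaling
#' statistics are fit on the training rows only, the imbalance strategy is
#' applied to the training rows only (SMOTE never sees test rows), a fresh
#' model is trained, and the held-out fold is scored. Held-out predictions
#' of all folds are pooled before computing one metric set per repeat
#' (`pool = "per_fold"` averages fold-level metrics instead). Metrics that
#' are undefined in a repeat (degenerate fold composition) are dropped from
#' the summary with a logged count, never imputed as 0.
#'
#' @param spec A [model_spec()].
#' @param strategy An [imbalance_strategy()] (or a strategy kind string).
#' @param data A [bimodal_dataset()] with both classes (may contain
#'   missing values; they are imputed per fold).
#' @param plan A [cv_plan()].
#' @param scale Z-score features using training-fold statistics
#'   (default TRUE).
#' @param impute `"fold"` (fit medians on the training fold; default) or
#'   `"global"` (impute once on the whole table before splitting).
#' @param pool `"pooled"` (default) or `"per_fold"`.
#' @param verbose Print per-repeat progress.
#' @return A `cv_report`: repeat-level metric values, their mean and sd,
#'   and metadata recording every policy used.
#' @export
cross_validate <- function(spec, strategy, data, plan, scale = TRUE,
                           impute = c("fold", "global"),
                           pool = c("pooled", "per_fold"), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "bimodal_dataset"),
            inherits(plan, "cv_plan"))
  impute <- match.arg(impute)
  pool <- match.arg(pool)
  if (is.character(strategy)) strategy <- imbalance_strategy(strategy)
  stopifnot(inherits(strategy, "imbalance_strategy"))
  class_balance(data) # errors if one class absent
  if (impute == "global") data <- impute_median(data)
  n <- length(data$y)
  metric_names <- c("PR", "RE", "ACC", "F1", "MCC", "AUC", "AUPRC")
  values <- matrix(NA_real_, plan$repeats, length(metric_names),
                   dimnames = list(NULL, metric_names))
  for (r in seq_len(plan$repeats)) {
    folds <- stratified_folds(data$y, plan$k, seed = plan$seed + r)
    preds <- rep(NA_real_, n)
    fold_metrics <- NULL
    for (f in seq_len(plan$k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (length(intersect(train_idx, test_idx)) > 0L ||
          length(union(train_idx, test_idx)) != n) {
        opcnn_stop("internal leakage guard tripped: folds do not partition",
                   "leakage_error")
      }
      ds_tr <- subset_rows(data, train_idx)
      ds_te <- subset_rows(data, test_idx)
      if (impute == "fold") {
        med <- fit_medians(ds_tr, seq_along(ds_tr$y))
        ds_tr <- apply_medians(ds_tr, med)
        ds_te <- apply_medians(ds_te, med)
      }
      if (scale) {
        st1 <- scale_stats(ds_tr$x1)
        st2 <- scale_stats(ds_tr$x2)
        ds_tr$x1 <- apply_scale(ds_tr$x1, st1)
        ds_tr$x2 <- apply_scale(ds_tr$x2, st2)
        ds_te$x1 <- apply_scale(ds_te$x1, st1)
        ds_te$x2 <- apply_scale(ds_te$x2, st2)
      }
      strat <- strategy
      strat$seed <- derive_seed(strategy$seed, r, f)
      aug <- apply_strategy(ds_tr, strat)
      model <- fit_spec(spec, aug$data, aug$weights, strategy$kind,
                        seed = derive_seed(plan$seed, r, f, 13L))
      preds[test_idx] <- predict_proba(model, ds_te)
      if (pool == "per_fold") {
        fold_metrics <- rbind(fold_metrics,
                              metric_set(preds[test_idx], data$y[test_idx],
                                         allow_undefined = TRUE))
      }
    }
    values[r, ] <- if (pool == "pooled") {
      metric_set(preds, data$y, allow_undefined = TRUE)
    } else {
      colMeans(fold_metrics, na.rm = TRUE)
    }
    if (verbose) {
      message(sprintf("[%s/%s] repeat %d/%d: MCC = %.4f", spec$label,
                      strategy$kind, r, plan$repeats, values[r, "MCC"]))
    }
  }
  dropped <- colSums(is.na(values))
  structure(list(
    label = spec$label, strategy = strategy$kind, values = values,
    mean = colMeans(values, na.rm = TRUE),
    sd = apply(values, 2, stats::sd, na.rm = TRUE),
    dropped = dropped,
    meta = list(plan = unclass(plan), scale = scale, impute = impute,
                pool = pool, kind = spec$kind)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s strategy), %d x %d-fold CV\n", x$label,
              x$strategy, nrow(x$values), x$meta$plan$k))
  out <- rbind(mean = x$mean, sd = x$sd)
  print(round(out, 4))
  if (any(x$dropped > 0)) {
    cat("repeats dropped per metric:",
        paste(sprintf("%s=%d", names(x$dropped)[x$dropped > 0],
                      x$dropped[x$dropped > 0]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Star code for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise (strict inequalities).
#'
#' @param p A p-value.
#' @return Character string of asterisks.
#' @export
star_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

welch_p <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Compare models against the best performer
#'
#' For the chosen metric, flags the model with the highest mean over
#' repeats as best and tests every other model against it with a two-sided
#' Welch t-test on the repeat-level values, star-coding the p-values
#' (p < 0.05 `*`, p < 0.01 `**`, p < 0.001 `***`). Identical value lists
#' give p = 1 by convention.
#'
#' @param reports List of `cv_report`s with equal repeat counts.
#' @param metric Metric name (default `"MCC"`).
#' @return A data.frame with one row per report: label, strategy, mean, sd,
#'   p_value (NA for the best model), stars, and a `best` flag.
#' @export
compare_models <- function(reports, metric = "MCC") {
  if (length(reports) < 2L) {
    opcnn_stop("compare_models needs at least 2 reports", "config_error")
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "cv_report")))
  reps <- vapply(reports, function(r) nrow(r$values), integer(1))
  if (length(unique(reps)) != 1L) {
    opcnn_stop("all reports must have the same repeat count", "config_error")
  }
  means <- vapply(reports, function(r) r$mean[[metric]], numeric(1))
  best <- which.max(means)
  vals_best <- reports[[best]]$values[, metric]
  rows <- lapply(seq_along(reports), function(i) {
    p <- if (i == best) NA_real_ else
      welch_p(reports[[i]]$values[, metric], vals_best)
    data.frame(label = reports[[i]]$label,
               strategy = reports[[i]]$strategy,
               mean = means[i], sd = reports[[i]]$sd[[metric]],
               p_value = p,
               stars = if (i == best) "" else star_code(p),
               best = i == best, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full benchmark grid
#'
#' Cross-validates every (model, strategy) combination and assembles a
#' long-format table of per-metric means, standard deviations, and star
#' annotations against the per-metric best cell (the best cell is flagged,
#' matching the bold-face convention of benchmark tables). Failures in a
#' cell are logged as warnings and leave NA rows rather than aborting the
#' grid.
#'
#' @param specs List of [model_spec()]s.
#' @param strategies Character vector of strategy kinds, or a list of
#'   [imbalance_strategy()] objects.
#' @param data A [bimodal_dataset()].
#' @param plan A [cv_plan()].
#' @param ... Passed to [cross_validate()] (`scale`, `impute`, `pool`,
#'   `verbose`).
#' @return A list of class `"benchmark_table"` with elements `table`
#'   (long data.frame), `reports` (named list of `cv_report`s), and `meta`.
#' @export
benchmark_table <- function(specs, strategies, data, plan, ...) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (is.character(strategies)) {
    strategies <- lapply(strategies, imbalance_strategy)
  }
  if (inherits(strategies, "imbalance_strategy")) {
    strategies <- list(strategies)
  }
  reports <- list()
  for (spec in specs) {
    for (strat in strategies) {
      key <- sprintf("%s | %s", spec$label, strat$kind)
      reports[[key]] <- tryCatch(
        cross_validate(spec, strat, data, plan, ...),
        error = function(e) {
          warning(sprintf("benchmark cell '%s' failed: %s", key,
                          conditionMessage(e)))
          NULL
        })
    }
  }
  ok <- !vapply(reports, is.null, logical(1))
  metric_names <- c("PR", "RE", "ACC", "F1", "MCC", "AUC", "AUPRC")
  rows <- list()
  for (metric in metric_names) {
    live <- reports[ok]
    means <- vapply(live, function(r) r$mean[[metric]], numeric(1))
    best <- which.max(means)
    vals_best <- live[[best]]$values[, metric]
    for (i in seq_along(live)) {
      p <- if (i == best) NA_real_ else
        welch_p(live[[i]]$values[, metric], vals_best)
      rows[[length(rows) + 1L]] <- data.frame(
        model = live[[i]]$label, strategy = live[[i]]$strategy,
        metric = metric, mean = means[i], sd = live[[i]]$sd[[metric]],
        p_value = p, stars = if (i == best) "" else star_code(p),
        best = i == best, stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), reports = reports,
                 meta = list(plan = unclass(plan),
                             n = length(data$y),
                             failed_cells = names(reports)[!ok])),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  tab <- x$table
  cells <- unique(tab[, c("model", "strategy")])
  cat(sprintf("<benchmark_table> %d models x strategies, n = %d\n",
              nrow(cells), x$meta$n))
  wide <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- tab[tab$model == cells$model[i] & tab$strategy == cells$strategy[i], ]
    vals <- sprintf("%.4f (%.4f)%s", sub$mean, sub$sd, sub$stars)
    stats::setNames(as.list(vals), metric_labels[sub$metric])
  })
  df <- cbind(cells, do.call(rbind, lapply(wide, as.data.frame)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Emits `metrics.csv` (the long table), `raw_values.json` (repeat-level
#' metric values per cell), and returns the paths.
#'
#' @param bt A [benchmark_table()] result.
#' @param dir Output directory (created if absent).
#' @export
write_benchmark <- function(bt, dir) {
  stopifnot(inherits(bt, "benchmark_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "metrics.csv")
  utils::write.csv(bt$table, csv, row.names = FALSE)
  raw <- lapply(bt$reports, function(r) {
    if (is.null(r)) return(NULL)
    list(strategy = r$strategy,
         values = as.data.frame(r$values))
  })
  js <- file.path(dir, "raw_values.json")
  jsonlite::write_json(raw, js, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(c(metrics = csv, raw = js))
}
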