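# Conventional machine-learning baselines operating on the concatenated
# 47-feature vector: a polynomial SVM, a random forest, and a
# constant-majority dummy. These delegate to the established e1071 and
# randomForest implementations with the benchmark's fixed settings.

#' Fit a baseline classifier
#'
#' \describe{
#'   \item{`svm_poly3_C10`}{[e1071::svm()] with a polynomial kernel of
#'     degree 3 and penalty constant C = 10, probability outputs enabled.}
#'   \item{`rf_100`}{[randomForest::randomForest()] with 100 trees,
#'     considering all 47 input features at each split (`mtry = ncol`).}
#'   \item{`majority`}{Predicts the training prevalence of the positive
#'     class as a constant score — the reference dummy whose accuracy
#'     equals the prevalence and whose MCC is 0.}
#' }
#' The two modalities are concatenated into a single input; feature scaling
#' is the caller's responsibility (the CV harness z-scores per fold).
#'
#' @param kind `"svm_poly3_C10"`, `"rf_100"`, or `"majority"`.
#' @param data A fully imputed [bimodal_dataset()] (or list with x1, x2, y).
#' @param seed RNG seed (both libraries draw random numbers).
#' @param class_weights Optional `c(w_pos, w_neg)` passed to the library's
#'   class-weight argument for the cost-sensitive strategy.
#' @return A fitted model of class `"baseline_model"` exposing
#'   [predict_proba()].
#' @export
fit_baseline <- function(kind = c("svm_poly3_C10", "rf_100", "majority"),
                         data, seed = 1L, class_weights = NULL) {
  kind <- match.arg(kind)
  d <- as_xy(data)
  x <- cbind(d$x1, d$x2)
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  yf <- factor(d$y, levels = c("0", "1"))
  if (length(unique(d$y)) < 2L && kind != "majority") {
    opcnn_stop("baseline training data must contain both classes",
               "data_error")
  }
  cw <- NULL
  if (!is.null(class_weights)) {
    cw <- c("0" = unname(class_weights[2]), "1" = unname(class_weights[1]))
  }
  fitted <- with_seed(seed, switch(kind,
    svm_poly3_C10 = e1071::svm(x = x, y = yf, kernel = "polynomial",
                               degree = 3, cost = 10, probability = TRUE,
                               scale = FALSE, class.weights = cw),
    rf_100 = randomForest::randomForest(x = x, y = yf, ntree = 100,
                                        mtry = ncol(x), classwt = cw),
    majority = list(prevalence = mean(d$y))
  ))
  structure(list(kind = kind, fit = fitted, n_features = ncol(x)),
            class = "baseline_model")
}

#' @rdname predict_proba
#' @export
predict_proba.baseline_model <- function(model, data, ...) {
  x1 <- if (inherits(data, "bimodal_dataset")) data$x1 else as.matrix(data$x1)
  x2 <- if (inherits(data, "bimodal_dataset")) data$x2 else as.matrix(data$x2)
  x <- cbind(x1, x2)
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  if (ncol(x) != model$n_features) {
    opcnn_stop("prediction data has wrong feature count", "dimension_error")
  }
  switch(model$kind,
    svm_poly3_C10 = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    rf_100 = unname(stats::predict(model$fit, x, type = "prob")[, "1"]),
    majority = rep(model$fit$prevalence, nrow(x)))
}
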