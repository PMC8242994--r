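# Class-imbalance strategies: cost-sensitive class weights for the weighted
# binary cross-entropy, SMOTE oversampling, and their hybrid.

#' Cost-sensitive class weights
#'
#' The weights `w_pos = n / (2 n+)` and `w_neg = n / (2 n-)` equalise the
#' total loss mass contributed by each class: `w_pos * n+ = w_neg * n- =
#' n / 2`. With the 757:71 drug table they evaluate to (0.5469, 5.8310).
#'
#' @param n Training-set size (`n = n_pos + n_neg`).
#' @param n_pos,n_neg Class sizes, both >= 1.
#' @return Named numeric vector `c(w_pos, w_neg)`.
#' @export
class_weights <- function(n, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) {
    opcnn_stop("class_weights requires at least one sample per class",
               "balance_error")
  }
  if (n != n_pos + n_neg) {
    opcnn_stop("n must equal n_pos + n_neg", "data_error")
  }
  c(w_pos = n / (2 * n_pos), w_neg = n / (2 * n_neg))
}

#' SMOTE: synthetic minority oversampling
#'
#' Creates synthetic minority samples by interpolating between a uniformly
#' chosen minority row `x` and one of its `k` nearest minority neighbours
#' `x_nn` (Euclidean distance in the feature space supplied — the harness
#' passes the z-scored, concatenated 47-dimensional space):
#' `x_syn = x + lambda (x_nn - x)` with `lambda ~ Uniform(0, 1)`.
#' Deterministic given `seed`.
#'
#' @param minority Numeric matrix of minority rows (m x p, m >= 2).
#' @param n_synthetic Number of synthetic rows to create (>= 0).
#' @param k Neighbour count, `1 <= k <= m - 1` (default 5, the canonical
#'   choice).
#' @param seed RNG seed.
#' @return Matrix of `n_synthetic` synthetic rows (0-row matrix if
#'   `n_synthetic = 0`).
#' @export
smote <- function(minority, n_synthetic, k = 5L, seed = 1L) {
  minority <- as.matrix(minority)
  m <- nrow(minority)
  if (m < 2L) {
    opcnn_stop("SMOTE requires at least 2 minority rows", "data_error")
  }
  k <- as.integer(k)
  if (k < 1L) opcnn_stop("k must be >= 1", "config_error")
  if (k >= m) {
    opcnn_stop(sprintf("k = %d >= minority size %d; use k = %d", k, m, m - 1L),
               "config_error")
  }
  n_synthetic <- as.integer(n_synthetic)
  if (n_synthetic < 0L) opcnn_stop("n_synthetic must be >= 0", "config_error")
  if (n_synthetic == 0L) {
    return(matrix(numeric(0), 0L, ncol(minority),
                  dimnames = list(NULL, colnames(minority))))
  }
  dmat <- as.matrix(stats::dist(minority))
  diag(dmat) <- Inf
  ord <- apply(dmat, 1L, function(row) order(row)[seq_len(k)])
  knn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  with_seed(seed, {
    base <- sample.int(m, n_synthetic, replace = TRUE)
    pick <- sample.int(k, n_synthetic, replace = TRUE)
    nb <- knn[cbind(base, pick)]
    lam <- stats::runif(n_synthetic)
    out <- minority[base, , drop = FALSE] +
      lam * (minority[nb, , drop = FALSE] - minority[base, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
}

#' Imbalance strategy descriptor
#'
#' @param kind `"base"` (no correction), `"cw"` (cost-sensitive class
#'   weights), or `"smote_cw"` (SMOTE oversampling followed by re-derived
#'   class weights — the hybrid).
#' @param smote_k SMOTE neighbour count.
#' @param smote_target_ratio Post-oversampling minority/majority ratio in
#'   (0, 1]; 1 balances the classes fully.
#' @param seed RNG seed for SMOTE draws.
#' @return A list of class `"imbalance_strategy"`.
#' @export
imbalance_strategy <- function(kind = c("base", "cw", "smote_cw"),
                               smote_k = 5L, smote_target_ratio = 1,
                               seed = 1L) {
  kind <- match.arg(kind)
  if (smote_k < 1L) opcnn_stop("smote_k must be >= 1", "config_error")
  if (smote_target_ratio <= 0 || smote_target_ratio > 1) {
    opcnn_stop("smote_target_ratio must be in (0, 1]", "config_error")
  }
  structure(list(kind = kind, smote_k = as.integer(smote_k),
                 smote_target_ratio = smote_target_ratio,
                 seed = as.integer(seed)),
            class = "imbalance_strategy")
}

#' Apply an imbalance strategy to a training set
#'
#' \itemize{
#'   \item `base`: data unchanged, weights (1, 1).
#'   \item `cw`: data unchanged, [class_weights()] of the training counts.
#'   \item `smote_cw`: the minority class is oversampled by [smote()] (both
#'     modalities interpolated jointly in the concatenated feature space,
#'     then split back) until `minority/majority = smote_target_ratio`, and
#'     class weights are re-derived on the augmented counts (weights (1, 1)
#'     at target ratio 1 when the counts divide evenly).
#' }
#' Synthetic rows are flagged in `$synthetic` and get `smote_*` ids.
#' Majority rows are never altered. Call this strictly inside a training
#' fold, after imputation and scaling have been fit on the real rows.
#'
#' @param train A fully imputed [bimodal_dataset()] containing both classes.
#' @param strategy An [imbalance_strategy()].
#' @return List with `data` (the possibly augmented training set) and
#'   `weights` (`c(w_pos, w_neg)`).
#' @export
apply_strategy <- function(train, strategy) {
  stopifnot(inherits(train, "bimodal_dataset"),
            inherits(strategy, "imbalance_strategy"))
  cb <- class_balance(train)
  if (strategy$kind == "base") {
    return(list(data = train, weights = c(w_pos = 1, w_neg = 1)))
  }
  if (strategy$kind == "cw") {
    return(list(data = train,
                weights = class_weights(cb$n, cb$n_pos, cb$n_neg)))
  }
  # smote_cw
  minority_label <- if (cb$n_pos <= cb$n_neg) 1L else 0L
  n_min <- min(cb$n_pos, cb$n_neg)
  n_maj <- max(cb$n_pos, cb$n_neg)
  n_syn <- max(0L, round(strategy$smote_target_ratio * n_maj) - n_min)
  out <- train
  if (n_syn > 0L) {
    idx_min <- which(train$y == minority_label)
    xcat <- cbind(train$x1[idx_min, , drop = FALSE],
                  train$x2[idx_min, , drop = FALSE])
    k <- min(strategy$smote_k, n_min - 1L)
    if (k < 1L) {
      opcnn_stop("SMOTE needs at least 2 minority rows in the training fold",
                 "data_error")
    }
    syn <- smote(xcat, n_syn, k = k, seed = strategy$seed)
    p1 <- ncol(train$x1)
    out <- bimodal_dataset(
      rbind(train$x1, syn[, seq_len(p1), drop = FALSE]),
      rbind(train$x2, syn[, -seq_len(p1), drop = FALSE]),
      c(train$y, rep(minority_label, n_syn)),
      c(train$ids, sprintf("smote_%05d", seq_len(n_syn))),
      provenance = train$provenance,
      synthetic = c(train$synthetic, rep(TRUE, n_syn))
    )
  }
  cb2 <- class_balance(out)
  list(data = out, weights = class_weights(cb2$n, cb2$n_pos, cb2$n_neg))
}
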