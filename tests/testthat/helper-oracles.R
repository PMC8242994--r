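# Independent oracles used to pin the package's numerical operations.
# These deliberately use the most literal (loop-based) formulations.

# outer product of augmented vectors by explicit double loop
oracle_aug_outer <- function(f1, f2) {
  a1 <- c(f1, 1)
  a2 <- c(f2, 1)
  m <- matrix(0, length(a1), length(a2))
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      m[i, j] <- a1[i] * a2[j]
    }
  }
  m
}

# circ(v) %*% c as the column expansion sum_j c_j * a_j
oracle_circ_matvec <- function(v, cc) {
  a <- circulant(v)
  out <- numeric(length(v))
  for (j in seq_along(cc)) out <- out + cc[j] * a[, j]
  out
}

# threshold metrics straight from the defining ratios, with exact integer
# numerators (counts are integers, so products below 2^53 are exact)
oracle_metrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  den <- prod(c(tp + fn, tp + fp, tn + fp, tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(PR = pr, RE = re, ACC = (tp + tn) / n, F1 = f1, MCC = mcc)
}

# AUC by enumerating every positive-negative pair
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# AUPRC by looping over every unique threshold
oracle_prauc <- function(scores, y) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(y == 1 & sel)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# is point p inside (or on) the convex hull of 2-D rows of X
oracle_in_hull_2d <- function(p, X) {
  h <- grDevices::chull(X)
  hull <- X[h, , drop = FALSE]
  m <- nrow(hull)
  crosses <- vapply(seq_len(m), function(i) {
    a <- hull[i, ]
    b <- hull[(i %% m) + 1, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, numeric(1))
  # inside (or on the boundary) iff all edge cross-products share a sign
  all(crosses >= -1e-9) || all(crosses <= 1e-9)
}
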