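# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths: brute-force pair counting, threshold-sweep ROC
# construction, and a paired bootstrap.

# AUC by explicit enumeration of all (positive, negative) pairs, ties 0.5.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC curve built by threshold sweep.
auc_trapezoid <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(ths, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr  <- vapply(ths, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# Paired-bootstrap variance of the AUC difference (subjects resampled with
# replacement, keeping the two scores of each subject together).
boot_var_auc_diff <- function(scores_a, scores_b, labels, B = 2000) {
  n <- length(labels)
  diffs <- numeric(B)
  b <- 0L
  while (b < B) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- labels[idx]
    if (all(yb == 1) || all(yb == 0)) next
    b <- b + 1L
    diffs[b] <- auc_mann_whitney(scores_a[idx], yb) -
                auc_mann_whitney(scores_b[idx], yb)
  }
  stats::var(diffs)
}

# Random paired-score dataset with correlated informative scores.
random_paired_scores <- function(n = 100, delta = 0.8) {
  y <- rbinom(n, 1, 0.5)
  if (all(y == y[1])) y[1] <- 1 - y[1]
  a <- rnorm(n) + delta * y
  b <- 0.6 * a + rnorm(n, sd = 0.8) + 0.3 * y
  list(a = a, b = b, y = y)
}

# Shared Monte-Carlo tolerance: three binomial SEs on each side.
mc_tol <- function(r_hat, r_ref, reps = 2000) {
  3 * sqrt(r_hat * (1 - r_hat) / reps) + 3 * sqrt(r_ref * (1 - r_ref) / reps)
}
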