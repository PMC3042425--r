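#' Mann-Whitney estimate of the area under the ROC curve
#'
#' The empirical probability that a randomly chosen positive subject's
#' score exceeds a randomly chosen negative's, with ties credited 0.5.
#' Computed via midranks, which is algebraically identical to pair counting:
#' AUC = (sum of positive midranks - n1(n1+1)/2) / (n1 n0).
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 outcome vector of the same length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc_mann_whitney <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must be binary 0/1", call. = FALSE)
  if (all(labels == 1) || all(labels == 0))
    stop("degenerate data: only one outcome class present", call. = FALSE)
  invisible(TRUE)
}

# Placement values of one score vector: for each positive, the tie-adjusted
# fraction of negatives it outscores (v10), and for each negative, the
# fraction of positives scoring below it is used symmetrically (v01 is the
# tie-adjusted fraction of positives the negative is outscored by).
# Midrank identities avoid the O(n1*n0) pairwise comparison.
placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Structural-components variance of a single AUC estimate
#'
#' DeLong's variance estimator for one Mann-Whitney AUC:
#' var(AUC) = var(v10)/n1 + var(v01)/n0, where v10 and v01 are the
#' placement values of positives and negatives.
#'
#' @inheritParams auc_mann_whitney
#' @return Non-negative variance estimate.
#' @export
delong_auc_variance <- function(scores, labels) {
  check_scores_labels(scores, labels)
  p <- placements(scores, labels)
  var_or_zero(p$v10) / length(p$v10) + var_or_zero(p$v01) / length(p$v01)
}

# sample (co)variance, with the one-observation case read as zero so that
# single-member outcome classes yield a defined (degenerate) variance
var_or_zero <- function(x) if (length(x) < 2) 0 else stats::var(x)
cov_or_zero <- function(m) {
  if (nrow(m) < 2) matrix(0, ncol(m), ncol(m)) else stats::cov(m)
}

#' DeLong paired test of two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, using the structural-components (placement value) covariance
#' estimator.  For each score the placement values of positives (against
#' all negatives) and of negatives (against all positives) are formed; the
#' covariance of the paired AUC estimates is S10/n1 + S01/n0, where S10 and
#' S01 are the 2x2 sample covariance matrices of the positive and negative
#' placements.  The statistic z = (AUC_a - AUC_b)/sqrt(var_diff) is
#' referred to the standard normal, two-sided, with no continuity
#' correction.
#'
#' When the estimated variance of the difference is numerically zero
#' (below 1e-12, e.g. identical score vectors), the p-value is set to 1 by
#' convention and the result is flagged `degenerate`.
#'
#' @param scores_a,scores_b Paired score vectors on the same subjects.
#' @param labels Binary 0/1 outcome vector.
#' @return Object of class `"auc_comparison"`: list with `auc_a`, `auc_b`,
#'   `var_diff`, `z_stat`, `p_value`, `degenerate`.
#' @examples
#' set.seed(7)
#' y <- rep(0:1, each = 50)
#' a <- rnorm(100) + 0.8 * y
#' b <- a + rnorm(100, sd = 0.5)
#' delong_paired_test(a, b, y)
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("`scores_a` and `scores_b` must have equal length", call. = FALSE)
  check_scores_labels(scores_a, labels)
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- cov_or_zero(cbind(pa$v10, pb$v10))
  s01 <- cov_or_zero(cbind(pa$v01, pb$v01))
  sigma <- s10 / n1 + s01 / n0
  var_diff <- max(sigma[1, 1] + sigma[2, 2] - 2 * sigma[1, 2], 0)
  degenerate <- var_diff < 1e-12
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z_stat = z, p_value = p, degenerate = degenerate),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("DeLong paired test of correlated AUCs\n")
  cat(sprintf("  AUC(a) = %.4f, AUC(b) = %.4f, difference = %+.4f\n",
              x$auc_a, x$auc_b, x$auc_a - x$auc_b))
  cat(sprintf("  var(diff) = %.3e, z = %.4f, two-sided p = %.4g\n",
              x$var_diff, x$z_stat, x$p_value))
  if (x$degenerate)
    cat("  note: degenerate variance; p = 1 by convention\n")
  invisible(x)
}

#' Compare two score columns of a CSV file by the DeLong test
#'
#' Convenience utility for standalone use: reads a CSV with columns
#' `label`, `score_a`, `score_b` (additional columns ignored), runs
#' [delong_paired_test()], and optionally writes the result as JSON.
#'
#' @param path CSV file path.
#' @param json_out Optional path for a JSON copy of the result.
#' @return The `"auc_comparison"` object, invisibly after printing.
#' @export
compare_auc_file <- function(path, json_out = NULL) {
  d <- utils::read.csv(path)
  need <- c("label", "score_a", "score_b")
  if (!all(need %in% names(d)))
    stop("CSV must contain columns label, score_a, score_b", call. = FALSE)
  res <- delong_paired_test(d$score_a, d$score_b, d$label)
  print(res)
  if (!is.null(json_out)) {
    jsonlite::write_json(
      list(auc_a = res$auc_a, auc_b = res$auc_b, var_diff = res$var_diff,
           z = res$z_stat, p_value = res$p_value,
           degenerate = res$degenerate),
      json_out, auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
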