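#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper around IRLS (via [stats::glm.fit()] with a binomial link,
#' epsilon 1e-10, at most 100 iterations) returning the pieces the nested
#' comparison needs: coefficients, the Bernoulli log-likelihood at the
#' optimum, the model-based covariance matrix (inverse observed
#' information), fitted probabilities and a convergence flag.  The fit is
#' flagged non-converged when IRLS fails to converge or when any
#' coefficient exceeds 15 in absolute value, the practical signature of
#' (quasi-)complete separation with unit-scale predictors.
#'
#' @param design Numeric design matrix, n x p, including the intercept
#'   column.
#' @param y Binary 0/1 outcome vector with both classes present.
#' @return List with components `coefficients`, `loglik`, `vcov`,
#'   `fitted`, `converged`.
#' @export
fit_logistic <- function(design, y) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(y) != n) stop("length of `y` must match nrow(design)", call. = FALSE)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (all(y == y[1]))
    stop("degenerate data: only one outcome class present", call. = FALSE)

  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # Bernoulli log-likelihood; clamp keeps 0*log(0) cases finite.
  eps <- .Machine$double.eps
  ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  # summary.glm's covariance: inverse of X'WX from the final IRLS QR,
  # mapped back from pivoted to original column order.
  vc <- tryCatch({
    vcp <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    out <- matrix(NA_real_, p, p)
    piv <- fit$qr$pivot
    out[piv, piv] <- vcp
    out
  }, error = function(e) matrix(NA_real_, p, p))
  converged <- isTRUE(fit$converged) && all(is.finite(beta)) &&
    max(abs(beta)) <= 15 && all(is.finite(vc))
  list(coefficients = unname(beta), loglik = ll, vcov = vc,
       fitted = unname(mu), converged = converged)
}

#' Likelihood-ratio p-value for one added parameter
#'
#' The deviance statistic G = 2(l1 - l0) is referred to a chi-square
#' distribution with 1 degree of freedom.  Small negative G (solver noise)
#' is clipped to zero; negative G beyond `tol` signals the models were not
#' nested or a fit failed.
#'
#' @param loglik_restricted,loglik_expanded Maximised log-likelihoods of the
#'   nested pair.
#' @param tol Tolerance for likelihood dominance violations.
#' @return Upper-tail chi-square(1) probability.
#' @export
lrt_pvalue <- function(loglik_restricted, loglik_expanded, tol = 1e-8) {
  g <- 2 * (loglik_expanded - loglik_restricted)
  if (g < -tol)
    stop("expanded model has lower likelihood than restricted model",
         call. = FALSE)
  stats::pchisq(max(g, 0), df = 1, lower.tail = FALSE)
}

#' Wald p-value for a single coefficient
#'
#' Two-sided standard-normal tail probability of z = estimate / SE, with
#' the model-based (observed-information) standard error.
#'
#' @param beta2_hat Coefficient estimate.
#' @param se_beta2 Its standard error; must be positive.
#' @return Two-sided p-value.
#' @export
wald_pvalue <- function(beta2_hat, se_beta2) {
  if (!is.finite(se_beta2) || se_beta2 <= 0)
    stop("standard error must be positive and finite", call. = FALSE)
  2 * stats::pnorm(-abs(beta2_hat / se_beta2))
}

#' Fit the restricted and expanded nested logistic models
#'
#' Fits logit(y) = b0 + b1 X (restricted) and logit(y) = b0 + b1 X + b2 X*
#' (expanded) by maximum likelihood, computes each subject's in-sample
#' linear predictor under both models, and the likelihood-ratio and Wald
#' p-values for H: b2 = 0.  The linear predictors deliberately reuse the
#' estimation sample (no cross-validation): they are the patient-specific
#' risk scores whose ROC comparison the package studies.
#'
#' @param dataset A `marker_dataset`, or any list with binary `y` and
#'   numeric `x`, `x_star` of equal length.
#' @return Object of class `"nested_fit"`: list with `beta_restricted`
#'   (length 2), `beta_expanded` (length 3), `loglik_restricted`,
#'   `loglik_expanded`, `se_beta2`, `p_lrt`, `p_wald`, `z_restricted`,
#'   `z_expanded` (length-n linear predictors) and `converged`.
#' @examples
#' d <- generate_dataset(sim_config(200, 0.5, mu = 0.5, mu_star = 0.5))
#' f <- fit_nested_models(d)
#' c(f$p_lrt, f$p_wald)
#' @export
fit_nested_models <- function(dataset) {
  y <- dataset$y; x <- dataset$x; x_star <- dataset$x_star
  n <- length(y)
  stopifnot(length(x) == n, length(x_star) == n)
  f0 <- fit_logistic(cbind(1, x), y)
  f1 <- fit_logistic(cbind(1, x, x_star), y)
  converged <- f0$converged && f1$converged
  se2 <- sqrt(f1$vcov[3, 3])
  p_lrt <- p_wald <- NA_real_
  if (converged) {
    p_lrt <- lrt_pvalue(f0$loglik, f1$loglik)
    p_wald <- wald_pvalue(f1$coefficients[3], se2)
  }
  structure(list(
    beta_restricted = f0$coefficients,
    beta_expanded = f1$coefficients,
    loglik_restricted = f0$loglik,
    loglik_expanded = f1$loglik,
    se_beta2 = se2,
    p_lrt = p_lrt,
    p_wald = p_wald,
    z_restricted = drop(cbind(1, x) %*% f0$coefficients),
    z_expanded = drop(cbind(1, x, x_star) %*% f1$coefficients),
    converged = converged
  ), class = "nested_fit")
}

#' @export
print.nested_fit <- function(x, ...) {
  cat("Nested logistic fits for incremental marker value\n")
  cat(sprintf("  restricted: b0 = %.4f, b1 = %.4f (logLik %.3f)\n",
              x$beta_restricted[1], x$beta_restricted[2], x$loglik_restricted))
  cat(sprintf("  expanded:   b0 = %.4f, b1 = %.4f, b2 = %.4f (logLik %.3f)\n",
              x$beta_expanded[1], x$beta_expanded[2], x$beta_expanded[3],
              x$loglik_expanded))
  cat(sprintf("  H: b2 = 0   LRT p = %.4g, Wald p = %.4g\n", x$p_lrt, x$p_wald))
  if (!x$converged) cat("  WARNING: fit flagged non-converged\n")
  invisible(x)
}

#' In-sample linear predictors from a nested fit
#'
#' Recomputes z = b0 + b1 X (restricted) and z = b0 + b1 X + b2 X*
#' (expanded) for arbitrary marker vectors under the fit's estimated
#' coefficients.
#'
#' @param fit A `"nested_fit"`.
#' @param x,x_star Marker vectors.
#' @return List with `z_restricted` and `z_expanded`.
#' @export
linear_predictors <- function(fit, x, x_star) {
  stopifnot(inherits(fit, "nested_fit"), length(x) == length(x_star))
  list(
    z_restricted = drop(cbind(1, x) %*% fit$beta_restricted),
    z_expanded = drop(cbind(1, x, x_star) %*% fit$beta_expanded)
  )
}
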