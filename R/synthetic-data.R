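#' Generate binary outcomes
#'
#' Draws each subject's outcome independently as 1 with probability
#' `prevalence`, via a uniform draw compared against the prevalence.
#' Uses the current RNG state; callers wanting reproducibility seed first
#' (or use [generate_dataset()], which manages substreams).
#'
#' @param n Number of subjects.
#' @param prevalence Outcome probability \eqn{\pi}, strictly in (0,1).
#' @return Integer vector of 0/1 of length `n`.
#' @export
generate_outcomes <- function(n, prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  as.integer(stats::runif(n) < prevalence)
}

#' Generate independent marker pairs conditional on outcome
#'
#' In the diseased class (y = 1) the established marker X is N(mu, 1) and
#' the new marker X* is N(mu_star, 1), independent of X; in the healthy
#' class both are independent standard normals.
#'
#' @param y Binary outcome vector.
#' @param mu,mu_star Mean shifts of X and X* in the diseased class.
#' @return List with components `x` and `x_star`, each of length `length(y)`.
#' @export
generate_markers_independent <- function(y, mu, mu_star) {
  n <- length(y)
  x <- stats::rnorm(n) + mu * y
  x_star <- stats::rnorm(n) + mu_star * y
  list(x = x, x_star = x_star)
}

#' Generate correlated marker pairs conditional on outcome
#'
#' X is drawn as in the independent scheme.  X* is then drawn conditionally
#' on X with standard deviation sqrt(1 - rho^2) and conditional mean
#' `mu_star + rho * X` in the diseased class and `rho * X` in the healthy
#' class, so that within each class X* has unit unconditional variance and
#' correlation `rho` with X.
#'
#' Note that with this recipe the diseased-class mean of X* is
#' `mu_star + rho * mu`, not `mu_star`, whenever both `mu` and `rho` are
#' non-zero.  Setting `centered = TRUE` uses the conditional mean
#' `mu_star + rho * (X - mu * y)` instead, which restores E[X* | y = 1] =
#' `mu_star` at the same correlation; the default follows the literal
#' conditional recipe.
#'
#' @inheritParams generate_markers_independent
#' @param rho Within-class correlation of the two markers, |rho| < 1.
#' @param centered Use the mean-centered conditional draw (see Details).
#' @return List with components `x` and `x_star`.
#' @export
generate_markers_dependent <- function(y, mu, mu_star, rho, centered = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("`rho` must lie strictly between -1 and 1", call. = FALSE)
  n <- length(y)
  x <- stats::rnorm(n) + mu * y
  cond_mean <- if (centered) mu_star * y + rho * (x - mu * y)
               else          mu_star * y + rho * x
  x_star <- cond_mean + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = x, x_star = x_star)
}

#' Generate one replicate dataset
#'
#' Seeds a dedicated substream derived from the configuration (master seed,
#' cell parameters, replicate index), draws outcomes and markers, and
#' returns them as a `marker_dataset`.  Degenerate draws in which every
#' subject falls in one outcome class are discarded and redrawn from the
#' next substream; the number of discarded attempts is recorded in the
#' `"discarded"` attribute.  The correlated scheme is used whenever
#' `rho != 0`.
#'
#' @param config A [sim_config()].
#' @param centered Passed to [generate_markers_dependent()].
#' @return A `marker_dataset`: list with integer vector `y` and numeric
#'   vectors `x`, `x_star`, all of length `config$n`.
#' @examples
#' d <- generate_dataset(sim_config(100, 0.5, mu = 0.3, mu_star = 0.2))
#' table(d$y)
#' @export
generate_dataset <- function(config, centered = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  attempt <- 0L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  repeat {
    set.seed(derive_seed(config, attempt))
    y <- generate_outcomes(config$n, config$prevalence)
    if (any(y == 1L) && any(y == 0L)) break
    attempt <- attempt + 1L
    if (attempt > 1000L)
      stop("could not draw a dataset with both outcome classes", call. = FALSE)
  }
  m <- if (config$rho == 0)
    generate_markers_independent(y, config$mu, config$mu_star)
  else
    generate_markers_dependent(y, config$mu, config$mu_star, config$rho,
                               centered = centered)
  structure(list(y = y, x = m$x, x_star = m$x_star),
            class = "marker_dataset", discarded = attempt)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("Marker dataset: n = %d subjects, %d diseased (prevalence %.3f)\n",
              length(x$y), sum(x$y), mean(x$y)))
  invisible(x)
}

#' @export
as.data.frame.marker_dataset <- function(x, ...) {
  data.frame(y = x$y, x = x$x, x_star = x$x_star)
}

#' Write a replicate dataset to CSV
#'
#' Plain CSV with header `y,x,x_star`, one subject per line; for debugging
#' and interoperability.
#'
#' @param dataset A `marker_dataset`.
#' @param path Output file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' True logistic coefficients of the restricted model
#'
#' Under the generation scheme, Bayes' rule gives the population regression
#' of the outcome on the established marker alone as
#' \deqn{\mathrm{logit}\, P(Y=1 \mid X=x) = \beta_0 + \beta_1 x,}
#' with slope \eqn{\beta_1 = \mu} and intercept
#' \eqn{\beta_0 = -\mu^2/2 + \log\{\pi/(1-\pi)\}}: the log density ratio of
#' N(mu,1) to N(0,1) is \eqn{\mu x - \mu^2/2}, to which the prior log odds
#' are added.
#'
#' @param mu Diseased-class mean shift of X.
#' @param prevalence Outcome prevalence \eqn{\pi}.
#' @return Named numeric vector `c(beta0, beta1)`.
#' @examples
#' true_coefficients(0.3, 0.5)  # beta0 = -0.045, beta1 = 0.3
#' @export
true_coefficients <- function(mu, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  c(beta0 = -0.5 * mu^2 + log(prevalence / (1 - prevalence)),
    beta1 = mu)
}
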