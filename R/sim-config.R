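#' Simulation configuration for one grid cell
#'
#' Bundles the parameters that define one cell of the Monte-Carlo grid:
#' sample size, outcome prevalence, the mean shifts of the established and
#' new markers in the diseased class, the marker correlation, and seeding
#' information.  Two configurations with identical fields always produce
#' bit-identical datasets (see [generate_dataset()]).
#'
#' @param n Subjects per replicate (integer, at least 10).
#' @param prevalence Marginal probability \eqn{\pi} of the outcome, in (0,1).
#' @param mu Mean shift of the established marker X in the diseased class.
#' @param mu_star Mean shift of the new marker X* in the diseased class.
#' @param rho Correlation between X and X* within outcome class, in (-1,1).
#' @param seed Non-negative integer master seed.
#' @param replicate_index Non-negative integer identifying the replicate;
#'   together with the other fields it selects an independent random
#'   substream.
#'
#' @return An object of class `"sim_config"` (a named list of the fields).
#' @examples
#' sim_config(n = 500, prevalence = 0.5, mu = 0, mu_star = 0.3)
#' @export
sim_config <- function(n, prevalence, mu = 0, mu_star = 0, rho = 0,
                       seed = 1L, replicate_index = 0L) {
  stopifnot(
    is.numeric(n), length(n) == 1L, n >= 10, n == round(n),
    is.numeric(prevalence), length(prevalence) == 1L,
    is.numeric(mu), length(mu) == 1L, is.finite(mu),
    is.numeric(mu_star), length(mu_star) == 1L, is.finite(mu_star),
    is.numeric(rho), length(rho) == 1L,
    is.numeric(seed), length(seed) == 1L, seed >= 0, seed == round(seed),
    is.numeric(replicate_index), length(replicate_index) == 1L,
    replicate_index >= 0, replicate_index == round(replicate_index)
  )
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  if (abs(rho) >= 1)
    stop("`rho` must lie strictly between -1 and 1", call. = FALSE)
  structure(
    list(n = as.integer(n), prevalence = prevalence, mu = mu,
         mu_star = mu_star, rho = rho, seed = as.double(seed),
         replicate_index = as.integer(replicate_index)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation cell: n = %d, prevalence = %g, mu = %g, mu* = %g, rho = %g\n",
    x$n, x$prevalence, x$mu, x$mu_star, x$rho))
  cat(sprintf("  seed = %.0f, replicate = %d\n", x$seed, x$replicate_index))
  invisible(x)
}

# Deterministic integer mixer: folds a vector of integers into a single seed
# in [0, 2^31 - 2].  A small LCG step per input keeps every product below
# 2^53 so the arithmetic is exact in doubles.  Not a cryptographic splitter;
# it only needs to decorrelate Mersenne-Twister initialisations across
# (cell, replicate, attempt) coordinates.
mix_seed <- function(parts) {
  m <- 2147483647  # 2^31 - 1
  x <- 11
  for (p in parts) {
    x <- (x * 69069 + (p %% m) + 1) %% m
    x <- (x * 1664525) %% m   # 1664525 * m < 2^52
  }
  x
}

# Substream seed for one replicate attempt of one cell.  Cell parameters are
# encoded at fixed precision so that numerically equal configs share streams.
derive_seed <- function(config, attempt = 0L) {
  mix_seed(c(
    config$seed,
    config$n,
    round(config$prevalence * 1e6),
    round(config$mu * 1e4) + 5e4,       # offset keeps parts non-negative
    round(config$mu_star * 1e4) + 5e4,
    round(config$rho * 1e4) + 5e4,
    config$replicate_index,
    attempt
  ))
}
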