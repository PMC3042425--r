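test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(5, 0.5), "n")
  expect_error(sim_config(100, 0), "prevalence")
  expect_error(sim_config(100, 1), "prevalence")
  expect_error(sim_config(100, 0.5, rho = 1), "rho")
  expect_error(generate_outcomes(10, 1.2), "prevalence")
  expect_error(generate_markers_dependent(c(0, 1), 0, 0, rho = 1), "rho")
})

test_that("outcome prevalence concentrates at pi", {
  set.seed(101)
  y <- generate_outcomes(500, 0.5)
  expect_true(all(y %in% c(0L, 1L)))
  expect_lt(abs(mean(y) - 0.5), 0.07)          # 3 binomial SE at n=500
  y2 <- generate_outcomes(10000, 0.2)
  expect_lt(abs(mean(y2) - 0.2), 0.012)        # 3*sqrt(.2*.8/1e4)
  y3 <- generate_outcomes(200, 1 - 1e-12)
  expect_true(all(y3 == 1L))
})

test_that("independent markers have the stated class-conditional moments", {
  set.seed(202)
  n <- 1e5
  y <- generate_outcomes(n, 0.5)
  m <- generate_markers_independent(y, mu = 0.3, mu_star = 0.2)
  n1 <- sum(y); n0 <- n - n1
  expect_lt(abs(mean(m$x[y == 1]) - mean(m$x[y == 0]) - 0.3),
            3 * sqrt(2 / min(n1, n0)))
  expect_lt(abs(mean(m$x_star[y == 1]) - 0.2), 3 / sqrt(n1))
  # unit variance in each class
  for (cls in 0:1) {
    expect_lt(abs(var(m$x[y == cls]) - 1), 3 * sqrt(2 / sum(y == cls)))
    expect_lt(abs(var(m$x_star[y == cls]) - 1), 3 * sqrt(2 / sum(y == cls)))
  }
  # null markers are mutually independent of everything
  m0 <- generate_markers_independent(y, mu = 0, mu_star = 0)
  expect_lt(abs(cor(m0$x, m0$x_star)), 3 / sqrt(n))
  expect_lt(abs(cor(m0$x, y)), 3 / sqrt(n))
})

test_that("with a null new marker the expanded coefficient is null", {
  set.seed(203)
  n <- 1e5
  y <- generate_outcomes(n, 0.5)
  m <- generate_markers_independent(y, mu = 0.3, mu_star = 0)
  f <- fit_logistic(cbind(1, m$x, m$x_star), y)
  expect_lt(abs(f$coefficients[3]), 0.03)
})

test_that("dependent recipe gives correlation rho and literal conditional mean", {
  set.seed(303)
  n <- 1e5
  y <- generate_outcomes(n, 0.5)
  m <- generate_markers_dependent(y, mu = 0, mu_star = 0, rho = 0.5)
  for (cls in 0:1) {
    expect_lt(abs(cor(m$x[y == cls], m$x_star[y == cls]) - 0.5),
              3 * (1 - 0.5^2) / sqrt(sum(y == cls)))
    expect_lt(abs(var(m$x_star[y == cls]) - 1), 3 * sqrt(2 / sum(y == cls)))
  }
  # literal recipe: E[X* | y=1] = mu_star + rho*mu, not mu_star
  m2 <- generate_markers_dependent(y, mu = 0.3, mu_star = 0, rho = 0.5)
  expect_lt(abs(mean(m2$x_star[y == 1]) - 0.15), 0.02)
  # the centered variant restores E[X* | y=1] = mu_star
  m3 <- generate_markers_dependent(y, mu = 0.3, mu_star = 0, rho = 0.5,
                                   centered = TRUE)
  expect_lt(abs(mean(m3$x_star[y == 1])), 0.02)
})

test_that("rho = 0 reduces the dependent recipe to the independent one", {
  y <- rep(c(0L, 1L), 50)
  set.seed(7); a <- generate_markers_independent(y, 0.2, 0.4)
  set.seed(7); b <- generate_markers_dependent(y, 0.2, 0.4, rho = 0)
  expect_equal(a, b)
})

test_that("true coefficients follow Bayes' rule, minus sign included", {
  expect_equal(unname(true_coefficients(0, 0.5)), c(0, 0))
  tc <- true_coefficients(0.3, 0.5)
  expect_equal(unname(tc["beta1"]), 0.3)
  expect_equal(unname(tc["beta0"]), -0.045)
  tc2 <- true_coefficients(0.2, 0.2)
  expect_equal(unname(tc2["beta0"]), -0.02 + log(0.25))
})

test_that("large-n logistic fit recovers the true restricted coefficients", {
  cfg <- sim_config(1e6, 0.5, mu = 0.3, mu_star = 0, seed = 11)
  d <- generate_dataset(cfg)
  f <- fit_logistic(cbind(1, d$x), d$y)
  se <- sqrt(diag(f$vcov))
  truth <- true_coefficients(0.3, 0.5)
  expect_lt(abs(f$coefficients[1] - truth["beta0"]), 3 * se[1])
  expect_lt(abs(f$coefficients[2] - truth["beta1"]), 3 * se[2])
  # the intercept is clearly negative at this n: the printed-plus-sign
  # alternative (+0.045) is excluded by many standard errors
  expect_lt(f$coefficients[1] + 0.045 - 3 * se[1], 0)
  expect_lt(abs(f$coefficients[1] - (-0.045)), 6 * se[1])
})

test_that("datasets are bit-reproducible and leave the global RNG untouched", {
  cfg <- sim_config(500, 0.5, mu = 0.1, mu_star = 0.2, rho = 0.3, seed = 99,
                    replicate_index = 7)
  set.seed(1); before <- runif(3)
  d1 <- generate_dataset(cfg)
  set.seed(1); runif(3)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  # different replicate index gives a different draw
  cfg2 <- sim_config(500, 0.5, mu = 0.1, mu_star = 0.2, rho = 0.3, seed = 99,
                     replicate_index = 8)
  expect_false(identical(generate_dataset(cfg2)$x, d1$x))
  # generation must not perturb the caller's RNG stream
  set.seed(1); runif(3); invisible(generate_dataset(cfg))
  expect_identical(runif(3), { set.seed(1); runif(6)[4:6] })
})

test_that("degenerate single-class draws are redrawn and counted", {
  # at n=10 and prevalence 0.01 most substreams start all-negative
  cfg <- sim_config(10, 0.01, seed = 5)
  d <- generate_dataset(cfg)
  expect_true(any(d$y == 1L) && any(d$y == 0L))
  expect_gte(attr(d, "discarded"), 0L)
  hits <- vapply(1:30, function(i) {
    attr(generate_dataset(sim_config(10, 0.01, seed = 5,
                                     replicate_index = i)), "discarded")
  }, integer(1))
  expect_gt(sum(hits), 0L)   # redraws do happen in this regime
})

test_that("CSV export round-trips a dataset", {
  d <- generate_dataset(sim_config(50, 0.5, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  back <- read.csv(path)
  expect_equal(back$y, d$y)
  expect_equal(back$x, d$x)
  expect_equal(back$x_star, d$x_star)
})
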