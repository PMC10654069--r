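# A tiny exact-likelihood setup used throughout: Monod data with known
# truth, plus the closed-form Gaussian log-likelihood.

make_monod_data <- function(n = 20, sigma = 0.05, seed = 5,
                            mu_max = 1, K_S = 0.5) {
  generate_dataset(generator_spec(
    "monod", list(mu_max = mu_max, K_S = K_S),
    concentration_grid = list(min = 0.02, max = 4, n = n, spacing = "log"),
    noise_sigma = sigma, seed = seed))
}

monod_predictor <- function(conc, par, d) {
  monod_growth(conc, par[["mu_max"]], par[["K_S"]])
}

test_that("log-likelihood matches the closed form and a direct summation", {
  d <- make_monod_data(sigma = 0)
  truth <- c(mu_max = 1, K_S = 0.5)
  n <- nrow(d$observations)
  sigma <- 0.05
  # perfect fit
  expect_equal(log_likelihood(truth, d, monod_predictor, sigma),
               -n * log(sigma * sqrt(2 * pi)))
  # one residual of exactly sigma costs 0.5
  d2 <- d
  d2$observations$growth_rate[3] <- d2$observations$growth_rate[3] + sigma
  expect_equal(log_likelihood(truth, d2, monod_predictor, sigma),
               -n * log(sigma * sqrt(2 * pi)) - 0.5)
  # arbitrary case against an independent summation
  d3 <- make_monod_data(sigma = 0.08, seed = 42)
  par <- c(mu_max = 1.3, K_S = 0.8)
  pred <- 1.3 * d3$observations$concentration /
    (0.8 + d3$observations$concentration)
  by_hand <- sum(-0.5 * ((d3$observations$growth_rate - pred) / 0.1)^2 -
                   log(0.1 * sqrt(2 * pi)))
  expect_equal(log_likelihood(par, d3, monod_predictor, 0.1), by_hand)
  # infeasible models reject through -Inf
  bad_predictor <- function(conc, par, d) stop("nope")
  expect_identical(log_likelihood(par, d3, bad_predictor, 0.1), -Inf)
})

test_that("chains are reproducible and respect degenerate proposals", {
  d <- make_monod_data()
  cfg <- mcmc_config(400, 100, seed = 9,
                     initial_values = c(mu_max = 0.8, K_S = 0.4))
  r1 <- metropolis_hastings(cfg, d, monod_predictor)
  r2 <- metropolis_hastings(cfg, d, monod_predictor)
  expect_identical(r1$samples, r2$samples)
  expect_equal(nrow(r1$samples), 300)
  # zero step sizes: the chain never leaves the start
  cfg0 <- mcmc_config(200, 50, seed = 9,
                      step_sizes = c(mu_max = 0, K_S = 0),
                      initial_values = c(mu_max = 0.8, K_S = 0.4))
  r0 <- suppressWarnings(metropolis_hastings(cfg0, d, monod_predictor))
  expect_true(all(r0$samples[, "mu_max"] == 0.8))
  expect_true(all(r0$samples[, "K_S"] == 0.4))
})

test_that("a flat likelihood explores the prior with near-total acceptance", {
  d <- make_monod_data()
  cfg <- mcmc_config(2000, 200, seed = 2, noise_sigma = 1e6,
                     step_sizes = c(mu_max = 0.05, K_S = 0.05),
                     initial_values = c(mu_max = 2.5, K_S = 25))
  r <- suppressWarnings(
    metropolis_hastings(cfg, d, monod_predictor,
                        upper_bounds = c(mu_max = 5, K_S = 50)))
  expect_gt(r$acceptance_rate, 0.95)
})

test_that("stationary frequencies match a two-level posterior", {
  # a step-function predictor makes the posterior piecewise flat on the
  # prior interval: mass ratio of the two plateaus is known analytically
  d <- growth_dataset(c(1, 2, 3), c(0.2, 0.2, 0.2), "two-level", 100)
  step_pred <- function(conc, par, d) {
    rep(if (par[["theta"]] < 0.5) 0.2 else 0.25, length(conc))
  }
  sigma <- 0.05
  ll_lo <- sum(dnorm(rep(0.2, 3), 0.2, sigma, log = TRUE))
  ll_hi <- sum(dnorm(rep(0.2, 3), 0.25, sigma, log = TRUE))
  # prior uniform on (0, 1): regions have equal width
  p_lo <- exp(ll_lo) / (exp(ll_lo) + exp(ll_hi))
  cfg <- mcmc_config(40000, 2000, seed = 31, noise_sigma = sigma,
                     step_sizes = c(theta = 0.25),
                     initial_values = c(theta = 0.4))
  r <- suppressWarnings(
    metropolis_hastings(cfg, d, step_pred, upper_bounds = c(theta = 1)))
  emp_lo <- mean(r$samples[, "theta"] < 0.5)
  expect_equal(emp_lo, p_lo, tolerance = 0.05)
})

test_that("the sampler recovers Monod parameters from synthetic data", {
  d <- make_monod_data(n = 20, sigma = 0.05, seed = 7)
  cfg <- mcmc_config(4000, 1000, seed = 7,
                     initial_values = c(mu_max = 0.7, K_S = 0.3),
                     step_sizes = c(mu_max = 0.04, K_S = 0.04))
  r <- metropolis_hastings(cfg, d, monod_predictor,
                           upper_bounds = c(mu_max = 5, K_S = 50))
  expect_lt(abs(r$point_estimate[["mu_max"]] - 1) / 1, 0.1)
  expect_lt(abs(r$point_estimate[["K_S"]] - 0.5) / 0.5, 0.25)
  # cross-check the posterior mode against a dense grid-search likelihood
  mg <- seq(0.8, 1.2, length.out = 60)
  kg <- seq(0.25, 0.9, length.out = 60)
  ll <- outer(mg, kg, Vectorize(function(m, k) {
    log_likelihood(c(mu_max = m, K_S = k), d, monod_predictor, 0.05)
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(r$map[["mu_max"]] - mg[best[1]]), 0.05)
  expect_lt(abs(r$map[["K_S"]] - kg[best[2]]), 0.08)
})

test_that("diagnostics flag pathological chains instead of failing silently", {
  d <- make_monod_data()
  # gigantic steps: almost everything rejected
  cfg <- mcmc_config(500, 100, seed = 3,
                     step_sizes = c(mu_max = 500, K_S = 500),
                     initial_values = c(mu_max = 1, K_S = 0.5))
  expect_warning(
    metropolis_hastings(cfg, d, monod_predictor,
                        upper_bounds = c(mu_max = 5, K_S = 50)),
    "acceptance rate|rejected")
})

test_that("config validation catches inconsistent settings", {
  expect_error(mcmc_config(100, 100), "burn_in")
  expect_error(mcmc_config(noise_sigma = 0), "positive")
  expect_error(mcmc_config(step_sizes = c(a = -1)), "non-negative")
  d <- make_monod_data()
  expect_error(
    metropolis_hastings(mcmc_config(100, 10), d, monod_predictor),
    "initial_values")
})
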