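#' Sampler configuration
#'
#' Settings for the Metropolis-Hastings random walk used in calibration.
#' Proposals are independent Gaussians per parameter with the given step
#' sizes; parameters carry independent uniform priors on `(0, upper)`, so
#' non-positive or out-of-bound proposals are rejected through the prior and
#' the chain explores a pure-likelihood surface inside the box.
#'
#' @param n_iterations total chain length.
#' @param burn_in samples discarded from the front (< `n_iterations`).
#' @param step_sizes named numeric vector of proposal s.d. per parameter;
#'   `NULL` defaults to 5% of the initial values.
#' @param seed integer RNG seed for the chain.
#' @param initial_values named numeric vector of starting values, or the
#'   string `"grid"` to initialize from a coarse log-posterior grid scan
#'   over the prior box.
#' @param noise_sigma observation noise s.d. of the Gaussian likelihood,
#'   d^-1.
#' @param upper_bounds named numeric vector of prior upper bounds; `NULL`
#'   uses the model defaults.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 20000L, burn_in = 5000L,
                        step_sizes = NULL, seed = 1L,
                        initial_values = NULL, noise_sigma = 0.05,
                        upper_bounds = NULL) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  if (burn_in >= n_iterations) {
    stop("burn_in must be smaller than n_iterations", call. = FALSE)
  }
  if (!is.null(step_sizes) && any(step_sizes < 0)) {
    stop("step_sizes must be non-negative", call. = FALSE)
  }
  if (noise_sigma <= 0) stop("noise_sigma must be positive", call. = FALSE)
  structure(list(n_iterations = n_iterations, burn_in = burn_in,
                 step_sizes = step_sizes, seed = as.integer(seed),
                 initial_values = initial_values,
                 noise_sigma = noise_sigma, upper_bounds = upper_bounds),
            class = "mcmc_config")
}

#' Gaussian log-likelihood of a growth predictor
#'
#' Independent Gaussian residuals between observed and predicted growth
#' rates with fixed noise scale `sigma`. Predictors that signal model
#' infeasibility (class `cfm_infeasible`) or return non-finite values yield
#' `-Inf`, so such proposals are rejected.
#'
#' @param par named numeric parameter vector.
#' @param data a [growth_dataset()].
#' @param predictor `function(concentration, par, data)` returning predicted
#'   growth rates.
#' @param sigma observation noise s.d., d^-1 (> 0).
#' @return log density (scalar; `-Inf` on infeasibility).
#' @export
log_likelihood <- function(par, data, predictor, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  obs <- data$observations
  pred <- tryCatch(predictor(obs$concentration, par, data),
                   cfm_infeasible = function(e) NULL,
                   error = function(e) NULL)
  if (is.null(pred) || length(pred) != nrow(obs) || any(!is.finite(pred))) {
    return(-Inf)
  }
  sum(stats::dnorm(obs$growth_rate, mean = pred, sd = sigma, log = TRUE))
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Generic engine behind [fit_monod()] and [fit_cfm()]: symmetric Gaussian
#' proposals on all parameters jointly, acceptance probability
#' `min(1, exp(delta log-posterior))`, uniform `(0, upper)` priors.
#' Bit-reproducible for a given seed; the session RNG state is restored on
#' exit. A chain that accepts (almost) nothing or (almost) everything, or
#' whose split halves disagree, triggers a diagnostics warning rather than
#' silent success.
#'
#' @param config an [mcmc_config()]; `initial_values` and `step_sizes` must
#'   be resolvable (a named init vector, or `"grid"` plus bounds).
#' @param data a [growth_dataset()].
#' @param predictor `function(concentration, par, data)` -> predicted growth
#'   rates.
#' @param upper_bounds named numeric prior upper bounds (overridden by
#'   `config$upper_bounds`).
#' @return An object of class `mcmc_result`: list with `samples` (post
#'   burn-in matrix), `full_chain`, `acceptance_rate`, `point_estimate`
#'   (posterior means), `map` (best log-posterior draw), `log_post` trace.
#' @export
metropolis_hastings <- function(config, data, predictor,
                                upper_bounds = NULL) {
  stopifnot(inherits(config, "mcmc_config"), inherits(data, "growth_data"))
  if (!is.null(config$upper_bounds)) upper_bounds <- config$upper_bounds
  init <- config$initial_values
  if (is.null(init)) stop("initial_values must be supplied", call. = FALSE)
  if (identical(init, "grid")) {
    if (is.null(upper_bounds)) {
      stop("grid initialization needs upper bounds", call. = FALSE)
    }
    init <- grid_initializer(data, predictor, upper_bounds,
                             config$noise_sigma)
  }
  par_names <- names(init)
  if (is.null(par_names)) stop("initial_values must be named", call. = FALSE)
  if (is.null(upper_bounds)) {
    upper_bounds <- stats::setNames(rep(Inf, length(init)), par_names)
  }
  upper_bounds <- upper_bounds[par_names]
  steps <- config$step_sizes
  if (is.null(steps)) steps <- abs(init) * 0.05
  steps <- steps[par_names]

  log_post <- function(par) {
    if (any(par <= 0) || any(par >= upper_bounds)) return(-Inf)
    log_likelihood(par, data, predictor, config$noise_sigma)
  }

  n <- config$n_iterations
  k <- length(init)
  chain <- matrix(NA_real_, nrow = n, ncol = k,
                  dimnames = list(NULL, par_names))
  lp_trace <- numeric(n)
  cur <- init
  lp <- log_post(cur)
  if (!is.finite(lp)) {
    stop("model not evaluable at the initial values", call. = FALSE)
  }
  n_acc <- 0L
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      prop <- cur + stats::rnorm(k, sd = steps)
      lp_prop <- log_post(prop)
      u <- stats::runif(1)  # drawn unconditionally: keeps the RNG stream
      if (is.finite(lp_prop) && log(u) < (lp_prop - lp)) {
        cur <- prop
        lp <- lp_prop
        n_acc <- n_acc + 1L
      }
      chain[i, ] <- cur
      lp_trace[i] <- lp
    }
  })
  acc <- n_acc / n
  keep <- chain[(config$burn_in + 1L):n, , drop = FALSE]
  lp_keep <- lp_trace[(config$burn_in + 1L):n]
  diagnose_chain(keep, acc)
  best <- which.max(lp_keep)
  structure(list(
    samples = keep,
    full_chain = chain,
    log_post = lp_keep,
    acceptance_rate = acc,
    point_estimate = colMeans(keep),
    map = keep[best, ],
    config = config
  ), class = "mcmc_result")
}

# Acceptance-rate bounds and a split-chain comparison; warn, never fail.
diagnose_chain <- function(samples, acceptance_rate) {
  if (acceptance_rate <= 0) {
    warning("all proposals were rejected: chain never moved",
            call. = FALSE)
  } else if (acceptance_rate < 0.1 || acceptance_rate > 0.6) {
    warning(sprintf(
      "acceptance rate %.2f outside the 0.10-0.60 efficiency band; %s",
      acceptance_rate,
      if (acceptance_rate < 0.1) "consider smaller steps"
      else "consider larger steps"), call. = FALSE)
  }
  half <- nrow(samples) %/% 2L
  if (half >= 50L) {
    m1 <- colMeans(samples[seq_len(half), , drop = FALSE])
    m2 <- colMeans(samples[(half + 1L):nrow(samples), , drop = FALSE])
    sd_all <- apply(samples, 2, stats::sd)
    drift <- abs(m1 - m2) / pmax(sd_all, .Machine$double.eps)
    if (any(is.finite(drift) & drift > 1.5)) {
      warning("split-chain means differ by > 1.5 posterior s.d.: ",
              "chain may not have converged", call. = FALSE)
    }
  }
  invisible(NULL)
}

# Coarse grid scan of the log posterior over the prior box (log-spaced),
# used as an automatic initializer when no manual estimate is supplied.
grid_initializer <- function(data, predictor, upper_bounds, sigma,
                             n_per_dim = 12L) {
  par_names <- names(upper_bounds)
  axes <- lapply(upper_bounds, function(u) {
    exp(seq(log(u * 1e-3), log(u * 0.95), length.out = n_per_dim))
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- par_names
  lp <- apply(grid, 1L, function(g) {
    log_likelihood(stats::setNames(g, par_names), data, predictor, sigma)
  })
  if (all(!is.finite(lp))) {
    stop("grid initializer: model infeasible everywhere in the prior box",
         call. = FALSE)
  }
  stats::setNames(grid[which.max(lp), ], par_names)
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf("Metropolis-Hastings chain: %d kept samples, acceptance %.2f\n",
              nrow(x$samples), x$acceptance_rate))
  est <- rbind(mean = x$point_estimate, MAP = x$map)
  print(signif(est, 5))
  invisible(x)
}
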