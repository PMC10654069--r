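#' Fit a growth model to a dataset
#'
#' Front door of the calibration machinery: fits either the Monod reference
#' model (`mu_max`, `K_S`) or the allocation model (phosphate affinity `A_P`
#' and machinery-to-chlorophyll ratio `A_Pho`, all other cell parameters
#' held at the supplied profile) to one growth-vs-concentration dataset by
#' random-walk Metropolis-Hastings. For the allocation model the dataset's
#' own irradiance is used, mirroring how each culture experiment sets its
#' light level.
#'
#' @param data a [growth_dataset()] (or path to a single-dataset CSV).
#' @param model `"monod"` or `"cfm"`.
#' @param params a [cell_params()] profile (allocation model only).
#' @param config an [mcmc_config()]. When `initial_values` is `NULL` a
#'   coarse grid scan over the prior box supplies the start.
#' @return An object of class `growth_fit` with components `model`,
#'   `estimate` (posterior means), `map`, `samples`, `acceptance_rate`,
#'   `rmse` (of the posterior-mean curve), `data`, `params`, `config`.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot` and `simulate`.
#' @seealso [fit_monod()], [fit_cfm()]
#' @export
#' @examples
#' d <- generate_dataset(generator_spec("monod",
#'   list(mu_max = 1, K_S = 0.5), seed = 3))
#' f <- fit_growth(d, "monod", config = mcmc_config(2000, 500, seed = 3))
#' coef(f)
fit_growth <- function(data, model = c("monod", "cfm"),
                       params = default_cell_params(),
                       config = mcmc_config()) {
  model <- match.arg(model)
  if (is.character(data)) {
    ds <- read_growth_csv(data)
    if (length(ds) != 1L) {
      stop("CSV contains ", length(ds),
           " datasets; fit_growth() takes exactly one", call. = FALSE)
    }
    data <- ds[[1L]]
  }
  stopifnot(inherits(data, "growth_data"))
  if (model == "monod") {
    predictor <- function(conc, par, d) {
      monod_growth(conc, par[["mu_max"]], par[["K_S"]])
    }
    bounds <- c(mu_max = 5, K_S = 50)
  } else {
    predictor <- function(conc, par, d) {
      p <- params
      p$A_P <- par[["A_P"]]
      p$A_Pho <- par[["A_Pho"]]
      cfm_predict_mu(conc, p, d$irradiance, nutrient = d$nutrient)
    }
    bounds <- c(A_P = 1, A_Pho = 20)
  }
  if (is.null(config$initial_values)) config$initial_values <- "grid"
  res <- metropolis_hastings(config, data, predictor,
                             upper_bounds = bounds)
  est <- res$point_estimate
  pred <- predictor(data$observations$concentration, est, data)
  rmse <- sqrt(mean((data$observations$growth_rate - pred)^2))
  structure(list(
    model = model, estimate = est, map = res$map,
    samples = res$samples, log_post = res$log_post,
    acceptance_rate = res$acceptance_rate, rmse = rmse,
    data = data, params = if (model == "cfm") params else NULL,
    config = config, predictor = predictor
  ), class = "growth_fit")
}

#' Fit the Monod reference model
#'
#' Specialization of [fit_growth()] for Monod kinetics; returns estimates of
#' the maximum growth rate and half-saturation constant for the dataset.
#'
#' @inheritParams fit_growth
#' @return a `growth_fit` object.
#' @export
fit_monod <- function(data, config = mcmc_config()) {
  fit_growth(data, model = "monod", config = config)
}

#' Fit the allocation model
#'
#' Specialization of [fit_growth()] that calibrates the phosphate affinity
#' `A_P` and the photosynthetic-machinery ratio `A_Pho`, with every other
#' cell parameter fixed at `base_params`.
#'
#' @inheritParams fit_growth
#' @param base_params the fixed [cell_params()] profile.
#' @return a `growth_fit` object.
#' @export
fit_cfm <- function(data, base_params = default_cell_params(),
                    config = mcmc_config()) {
  fit_growth(data, model = "cfm", params = base_params, config = config)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s fit to %s (%s limitation, n = %d)\n",
              if (x$model == "monod") "Monod" else "Allocation model",
              x$data$organism, x$data$nutrient,
              nrow(x$data$observations)))
  cat("Posterior means:\n")
  print(signif(x$estimate, 5))
  cat(sprintf("Acceptance rate %.2f, RMSE %.4g d^-1\n",
              x$acceptance_rate, x$rmse))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$estimate

#' @export
summary.growth_fit <- function(object, ...) {
  qs <- t(apply(object$samples, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- list(model = object$model, organism = object$data$organism,
              estimate = object$estimate, map = object$map,
              quantiles = qs, acceptance_rate = object$acceptance_rate,
              rmse = object$rmse,
              n_samples = nrow(object$samples))
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("%s fit to %s\n",
              if (x$model == "monod") "Monod" else "Allocation model",
              x$organism))
  cat(sprintf("%d posterior samples, acceptance %.2f, RMSE %.4g\n",
              x$n_samples, x$acceptance_rate, x$rmse))
  cat("Posterior mean / MAP:\n")
  print(signif(rbind(mean = x$estimate, MAP = x$map), 5))
  cat("Posterior quantiles:\n")
  print(signif(x$quantiles, 5))
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$data$observations$concentration
  } else if (is.data.frame(newdata)) {
    newdata <- newdata$concentration
  }
  object$predictor(newdata, object$estimate, object$data)
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) {
  object$data$observations$growth_rate - fitted(object)
}

#' @export
plot.growth_fit <- function(x, n_grid = 200, ...) {
  obs <- x$data$observations
  grid <- seq(min(obs$concentration), max(obs$concentration),
              length.out = n_grid)
  plot(obs$concentration, obs$growth_rate,
       xlab = sprintf("%s concentration (uM)",
                      if (x$data$nutrient == "P") "Phosphate" else "Nitrate"),
       ylab = expression(mu ~ (d^-1)),
       main = sprintf("%s: %s fit", x$data$organism,
                      if (x$model == "monod") "Monod" else "allocation model"),
       pch = 19, ...)
  graphics::lines(grid, x$predictor(grid, x$estimate, x$data), lwd = 2)
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws new noisy datasets on the fitted dataset's concentration grid with
#' the fitted (posterior-mean) curve as truth and the configured observation
#' noise, truncated at zero like the generator module.
#'
#' @param object a `growth_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [growth_dataset()] objects.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = 1L, ...) {
  conc <- object$data$observations$concentration
  mu <- predict(object)
  sigma <- object$config$noise_sigma
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      growth_dataset(conc, pmax(0, mu + stats::rnorm(length(mu),
                                                     sd = sigma)),
                     organism = sprintf("%s-sim%02d",
                                        object$data$organism, i),
                     irradiance = object$data$irradiance,
                     nutrient = object$data$nutrient)
    })
  })
}

#' Write a fit report
#'
#' Serializes the point estimates, acceptance rate and RMSE as JSON and the
#' posterior samples as CSV alongside.
#'
#' @param fit a `growth_fit`.
#' @param path JSON output path; chains go to `<path>_chain.csv`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    model = fit$model,
    organism = fit$data$organism,
    nutrient = fit$data$nutrient,
    irradiance = fit$data$irradiance,
    point_estimate = as.list(fit$estimate),
    map = as.list(fit$map),
    acceptance_rate = fit$acceptance_rate,
    rmse = fit$rmse,
    n_samples = nrow(fit$samples)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  chain_path <- sub("\\.json$", "", path)
  write_pipeline_table(as.data.frame(fit$samples),
                       paste0(chain_path, "_chain.csv"))
  invisible(path)
}
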