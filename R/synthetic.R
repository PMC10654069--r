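#' Specification for a synthetic growth dataset
#'
#' Describes how to simulate one growth-vs-concentration dataset with the
#' statistical structure the calibration assumes: a clean curve from either
#' the Monod model or the allocation model, sampled on a concentration grid
#' (log-spaced by default, mirroring how culture experiments concentrate
#' points at low concentration), with additive Gaussian observation noise on
#' the growth rate truncated at zero. The `cfm_with_inhibition` generator
#' additionally multiplies the clean curve by an exponentially declining
#' factor above a threshold concentration, emulating the high-phosphate
#' growth inhibition seen in some organisms that neither model captures —
#' a negative control only.
#'
#' @param generator one of `"monod"`, `"cfm"`, `"cfm_with_inhibition"`.
#' @param true_params for `"monod"`: `list(mu_max=, K_S=)`; for the cfm
#'   generators: a [cell_params()] object.
#' @param concentration_grid numeric vector of concentrations (uM), or a list
#'   `list(min=, max=, n=, spacing=)` with spacing `"log"` (default) or
#'   `"linear"`.
#' @param noise_sigma observation noise s.d. on growth rate, d^-1 (>= 0).
#' @param seed integer RNG seed.
#' @param organism organism label for the simulated dataset.
#' @param irradiance irradiance of the simulated culture (cfm generators).
#' @param nutrient `"P"` or `"N"`.
#' @param inhibition_threshold concentration (uM) above which inhibition
#'   sets in (`cfm_with_inhibition` only).
#' @param inhibition_rate exponential decline rate per uM above the
#'   threshold.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(generator = c("monod", "cfm",
                                         "cfm_with_inhibition"),
                           true_params,
                           concentration_grid = list(min = 0.02, max = 4,
                                                     n = 12,
                                                     spacing = "log"),
                           noise_sigma = 0.05, seed = 1L,
                           organism = "synthetic", irradiance = 200,
                           nutrient = c("P", "N"),
                           inhibition_threshold = 2,
                           inhibition_rate = 0.2) {
  generator <- match.arg(generator)
  nutrient <- match.arg(nutrient)
  grid <- .expand_grid_spec(concentration_grid)
  if (length(grid) < 3L) stop("concentration grid needs n >= 3", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (generator == "monod") {
    stopifnot(is.list(true_params),
              all(c("mu_max", "K_S") %in% names(true_params)))
    if (true_params$mu_max <= 0 || true_params$K_S <= 0) {
      stop("Monod parameters must be positive", call. = FALSE)
    }
  } else {
    true_params <- validate_cell_params(true_params)
  }
  structure(list(generator = generator, true_params = true_params,
                 concentration_grid = grid, noise_sigma = noise_sigma,
                 seed = as.integer(seed), organism = organism,
                 irradiance = irradiance, nutrient = nutrient,
                 inhibition_threshold = inhibition_threshold,
                 inhibition_rate = inhibition_rate),
            class = "generator_spec")
}

.expand_grid_spec <- function(g) {
  if (is.numeric(g)) return(sort(as.numeric(g)))
  stopifnot(is.list(g), all(c("min", "max", "n") %in% names(g)))
  spacing <- if (is.null(g$spacing)) "log" else g$spacing
  if (spacing == "log") {
    if (g$min <= 0) stop("log spacing requires min > 0", call. = FALSE)
    exp(seq(log(g$min), log(g$max), length.out = g$n))
  } else {
    seq(g$min, g$max, length.out = g$n)
  }
}

# Clean (noise-free) curve of a generator on its grid.
clean_curve <- function(spec) {
  s <- spec$concentration_grid
  mu <- switch(spec$generator,
    monod = monod_growth(s, spec$true_params$mu_max, spec$true_params$K_S),
    cfm = cfm_predict_mu(s, spec$true_params, spec$irradiance,
                         nutrient = spec$nutrient),
    cfm_with_inhibition = {
      base <- cfm_predict_mu(s, spec$true_params, spec$irradiance,
                             nutrient = spec$nutrient)
      fac <- ifelse(s > spec$inhibition_threshold,
                    exp(-spec$inhibition_rate *
                          (s - spec$inhibition_threshold)), 1)
      base * fac
    })
  mu
}

#' Simulate a growth dataset
#'
#' Evaluates the generator described by `spec` on its concentration grid and
#' adds iid Gaussian noise truncated at zero (growth rates are
#' non-negative). Deterministic given the spec's seed; the RNG state of the
#' session is left untouched.
#'
#' @param spec a [generator_spec()].
#' @return A [growth_dataset()] with the spec attached as attribute
#'   `"generator_spec"` and the clean curve as attribute `"clean_mu"`.
#' @export
#' @examples
#' sp <- generator_spec("monod", list(mu_max = 1, K_S = 0.5), seed = 7)
#' d <- generate_dataset(sp)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  mu <- clean_curve(spec)
  noisy <- with_seed(spec$seed, {
    pmax(0, mu + stats::rnorm(length(mu), sd = spec$noise_sigma))
  })
  d <- growth_dataset(spec$concentration_grid, noisy,
                      organism = spec$organism,
                      irradiance = spec$irradiance,
                      nutrient = spec$nutrient)
  attr(d, "generator_spec") <- spec
  attr(d, "clean_mu") <- mu
  d
}

#' Reproducible multi-organism fixture suite
#'
#' Draws `n_organisms` allocation-model parameterizations spanning a
#' plausible range of phosphate affinities (0.01-0.1 per uM),
#' machinery-to-chlorophyll ratios (2-4.5) and irradiances (50-400), sizes
#' each concentration grid around the organism's own crossover concentration
#' (so both the nutrient-limited rise and the plateau are sampled), and
#' simulates one noisy dataset per organism. Generation validates that every
#' fixture admits a feasible model evaluation.
#'
#' @param n_organisms number of datasets (>= 1).
#' @param seed integer RNG seed controlling both the parameter draws and the
#'   observation noise.
#' @param n_points observations per dataset.
#' @param noise_sigma observation noise s.d., d^-1.
#' @return list of [growth_dataset()] objects, each with its
#'   `generator_spec` attached.
#' @export
fixture_suite <- function(n_organisms, seed = 1L, n_points = 12L,
                          noise_sigma = 0.05) {
  stopifnot(n_organisms >= 1)
  draws <- with_seed(seed, {
    data.frame(
      A_P = stats::runif(n_organisms, 0.01, 0.1),
      A_Pho = stats::runif(n_organisms, 2, 4.5),
      irradiance = stats::runif(n_organisms, 50, 400),
      sub_seed = sample.int(1e6, n_organisms)
    )
  })
  lapply(seq_len(n_organisms), function(i) {
    p <- cell_params(A_P = draws$A_P[i], A_Pho = draws$A_Pho[i])
    irr <- draws$irradiance[i]
    cross <- crossover_concentration(p, irr)
    spec <- generator_spec(
      "cfm", p,
      concentration_grid = list(min = cross / 50, max = 3 * cross,
                                n = n_points, spacing = "log"),
      noise_sigma = noise_sigma, seed = draws$sub_seed[i],
      organism = sprintf("synthetic-%02d", i), irradiance = irr)
    generate_dataset(spec)
  })
}

#' Write a simulated dataset with provenance
#'
#' Writes the dataset in the calibration CSV dialect and its generator spec
#' as a YAML sidecar (`<path>.yaml`) so simulated data remain traceable.
#'
#' @param dataset a [growth_dataset()] created by [generate_dataset()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(dataset, path) {
  write_growth_csv(dataset, path)
  spec <- attr(dataset, "generator_spec")
  if (!is.null(spec)) {
    s <- unclass(spec)
    if (inherits(s$true_params, "cell_params")) {
      s$true_params <- unclass(s$true_params)
    }
    s$concentration_grid <- as.numeric(s$concentration_grid)
    yaml::write_yaml(s, paste0(path, ".yaml"))
  }
  invisible(path)
}

# Evaluate code with a temporary RNG seed, restoring session RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
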