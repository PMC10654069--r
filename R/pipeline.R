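#' Crossover concentration between nutrient and carbon limitation
#'
#' The phosphate (or nitrate) concentration at which the nutrient-limited
#' branch reaches the carbon-limited plateau, located by bisection on the
#' difference between the two branch solutions to 1e-6 uM.
#'
#' @param params a [cell_params()] object.
#' @param irradiance photon flux, umol photons m^-2 s^-1.
#' @param nutrient `"P"` (default) or `"N"`.
#' @param tol bisection tolerance, uM.
#' @return concentration, uM.
#' @export
#' @examples
#' crossover_concentration(default_cell_params(), 200)
crossover_concentration <- function(params, irradiance = 200,
                                    nutrient = "P", tol = 1e-6) {
  env0 <- if (nutrient == "P") cfm_env(0, irradiance)
          else cfm_env(0, irradiance, nitrate = 0)
  mu_c <- solve_c_limited(env0, params)
  branch <- function(s) {
    env <- if (nutrient == "P") cfm_env(s, irradiance)
           else cfm_env(0, irradiance, nitrate = s)
    solve_p_limited(env, params, nutrient = nutrient)
  }
  hi <- 1
  while (branch(hi) < mu_c && hi < 1e6) hi <- hi * 2
  if (branch(hi) < mu_c) {
    stop("carbon limitation not reached below 1e6 uM", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (branch(mid) < mu_c) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Monod versus allocation-model comparison
#'
#' Fits both models to every dataset and tabulates their point estimates,
#' fit quality and dense predicted curves — the tabular form of a
#' side-by-side growth-curve comparison.
#'
#' @param data a CSV path or a list of [growth_dataset()] objects.
#' @param params a [cell_params()] profile for the allocation-model fits.
#' @param config an [mcmc_config()]; each dataset gets a seed offset so
#'   chains are independent yet reproducible.
#' @param n_grid points in each dense predicted curve.
#' @param out_dir optional directory; when given, writes `comparison.json`,
#'   `comparison_summary.csv` and `comparison_curves.csv`.
#' @return list with `summary` (one row per organism: estimates and RMSEs),
#'   `curves` (long data.frame of dense predictions), `fits` (the
#'   `growth_fit` objects) and a `provenance` attribute.
#' @export
run_comparison <- function(data, params = default_cell_params(),
                           config = mcmc_config(), n_grid = 100,
                           out_dir = NULL) {
  datasets <- if (is.character(data)) read_growth_csv(data) else data
  if (!length(datasets)) stop("no datasets to compare", call. = FALSE)
  fits <- vector("list", length(datasets))
  sum_rows <- list()
  curve_rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    fm <- fit_monod(d, config = cfg_i)
    fc <- fit_cfm(d, base_params = params, config = cfg_i)
    fits[[i]] <- list(monod = fm, cfm = fc)
    grid <- seq(min(d$observations$concentration),
                max(d$observations$concentration), length.out = n_grid)
    curve_rows[[i]] <- data.frame(
      organism = d$organism,
      concentration = rep(grid, 2),
      mu = c(fm$predictor(grid, fm$estimate, d),
             fc$predictor(grid, fc$estimate, d)),
      model = rep(c("monod", "cfm"), each = n_grid),
      stringsAsFactors = FALSE)
    sum_rows[[i]] <- data.frame(
      organism = d$organism, nutrient = d$nutrient,
      irradiance = d$irradiance, n_obs = nrow(d$observations),
      monod_mu_max = fm$estimate[["mu_max"]],
      monod_K_S = fm$estimate[["K_S"]],
      monod_rmse = fm$rmse,
      cfm_A_P = fc$estimate[["A_P"]],
      cfm_A_Pho = fc$estimate[["A_Pho"]],
      cfm_rmse = fc$rmse,
      stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, sum_rows),
              curves = do.call(rbind, curve_rows),
              fits = fits)
  attr(out, "provenance") <- pipeline_provenance(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      c(attr(out, "provenance"),
        list(organisms = out$summary$organism,
             summary = out$summary)),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    write_pipeline_table(out$summary,
                         file.path(out_dir, "comparison_summary.csv"))
    write_pipeline_table(out$curves,
                         file.path(out_dir, "comparison_curves.csv"))
  }
  out
}

#' Allocation profile along a phosphate gradient
#'
#' Runs the allocation model over a phosphate grid and reports, per
#' concentration, the realized growth rate, every carbon quota, and the
#' partition of total cellular phosphorus into the three reported pools:
#' RNA, photosynthetic (thylakoid phospholipid) and other (DNA plus residual
#' P). Pool fractions sum to one on every row.
#'
#' @param params a [cell_params()] object.
#' @param phosphate_grid concentrations, uM.
#' @param irradiance photon flux, umol photons m^-2 s^-1.
#' @param out_dir optional output directory (`allocation_profile.csv`).
#' @return data.frame, one row per concentration.
#' @export
run_allocation_profile <- function(params = default_cell_params(),
                                   phosphate_grid =
                                     exp(seq(log(0.005), log(5),
                                             length.out = 60)),
                                   irradiance = 200, out_dir = NULL) {
  rows <- lapply(phosphate_grid, function(s) {
    g <- growth_rate(cfm_env(s, irradiance), params)
    st <- g$state
    p_other <- st$Q_P_DNA + st$Q_P_Oth
    data.frame(
      phosphate = s, mu = g$mu, limitation = st$limitation_flag,
      Q_C_Pro = st$Q_C_Pro, Q_C_RNA = st$Q_C_RNA, Q_C_DNA = st$Q_C_DNA,
      Q_C_Chl = st$Q_C_Chl, Q_C_PlipThy = st$Q_C_PlipThy,
      Q_C_Csto = st$Q_C_Csto, Q_C_Other = st$Q_C_Other,
      Q_P_total = st$Q_P_total,
      frac_P_RNA = st$Q_P_RNA / st$Q_P_total,
      frac_P_photo = st$Q_P_Thy / st$Q_P_total,
      frac_P_other = p_other / st$Q_P_total,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- pipeline_provenance(NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_table(out, file.path(out_dir, "allocation_profile.csv"))
  }
  out
}

#' Growth curves across light intensities
#'
#' For each irradiance: the full growth curve over the phosphate grid, the
#' carbon-limited plateau and the crossover concentration. Both the plateau
#' and the crossover are non-decreasing in irradiance — brighter light
#' raises the attainable growth rate and with it the phosphorus needed to
#' reach it.
#'
#' @param params a [cell_params()] object.
#' @param irradiances photon fluxes, umol photons m^-2 s^-1 (> 0).
#' @param phosphate_grid concentrations, uM.
#' @param out_dir optional output directory (`light_sweep_curves.csv`,
#'   `light_sweep_summary.csv`).
#' @return list with `curves` (long data.frame) and `summary` (per
#'   irradiance: plateau, crossover).
#' @export
run_light_sweep <- function(params = default_cell_params(),
                            irradiances = c(50, 100, 200, 400),
                            phosphate_grid = exp(seq(log(0.005), log(5),
                                                     length.out = 40)),
                            out_dir = NULL) {
  if (any(irradiances <= 0)) {
    stop("irradiances must be positive", call. = FALSE)
  }
  curves <- list()
  summ <- list()
  for (i in seq_along(irradiances)) {
    irr <- irradiances[i]
    cc <- growth_curve(phosphate_grid, params, irradiance = irr)
    cc$irradiance <- irr
    curves[[i]] <- cc
    summ[[i]] <- data.frame(
      irradiance = irr,
      plateau_mu = solve_c_limited(cfm_env(0, irr), params),
      crossover_uM = crossover_concentration(params, irr))
  }
  out <- list(curves = do.call(rbind, curves),
              summary = do.call(rbind, summ))
  attr(out, "provenance") <- pipeline_provenance(NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_table(out$curves,
                         file.path(out_dir, "light_sweep_curves.csv"))
    write_pipeline_table(out$summary,
                         file.path(out_dir, "light_sweep_summary.csv"))
  }
  out
}

#' Nitrogen-phosphorus contrast
#'
#' Puts the P-limited and N-limited growth curves on a shared axis by
#' dividing nitrate concentrations by 15 (a typical N:P ratio of organic
#' matter) — a presentation transform applied here only, never inside the
#' solvers — and tabulates the intracellular P:C and N:C quotas against
#' growth rate. Both curves share the identical carbon-limited plateau.
#'
#' @param params a [cell_params()] object.
#' @param phosphate_grid phosphate concentrations, uM.
#' @param nitrate_grid nitrate concentrations, uM; default `15 *
#'   phosphate_grid` so the normalized axes coincide.
#' @param irradiance photon flux.
#' @param np_ratio the normalizing N:P ratio (default 15).
#' @param out_dir optional output directory (`np_growth_curves.csv`,
#'   `np_quota_curves.csv`).
#' @return list with `growth` (nutrient, concentration, normalized
#'   concentration, mu) and `quotas` (mu, Q_P, Q_N along the respective
#'   limitation branches) plus `plateau_mu`.
#' @export
run_np_comparison <- function(params = default_cell_params(),
                              phosphate_grid = exp(seq(log(0.005), log(5),
                                                       length.out = 40)),
                              nitrate_grid = NULL, irradiance = 200,
                              np_ratio = 15, out_dir = NULL) {
  if (is.null(nitrate_grid)) nitrate_grid <- np_ratio * phosphate_grid
  p_curve <- growth_curve(phosphate_grid, params, irradiance, "P")
  n_curve <- growth_curve(nitrate_grid, params, irradiance, "N")
  growth <- rbind(
    data.frame(nutrient = "P", concentration = p_curve$concentration,
               concentration_normalized = p_curve$concentration,
               mu = p_curve$mu, limitation = p_curve$limitation,
               stringsAsFactors = FALSE),
    data.frame(nutrient = "N", concentration = n_curve$concentration,
               concentration_normalized = n_curve$concentration / np_ratio,
               mu = n_curve$mu, limitation = n_curve$limitation,
               stringsAsFactors = FALSE))
  mu_c <- solve_c_limited(cfm_env(0, irradiance), params)
  mu_grid <- seq(0, mu_c, length.out = 50)
  quotas <- do.call(rbind, lapply(mu_grid, function(m) {
    st <- carbon_quotas(m, cfm_env(0, irradiance), params)
    data.frame(mu = m,
               Q_P = as.numeric(phosphorus_quota(st, params)),
               Q_N = as.numeric(nitrogen_quota(st, params)))
  }))
  out <- list(growth = growth, quotas = quotas, plateau_mu = mu_c)
  attr(out, "provenance") <- pipeline_provenance(NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_table(growth, file.path(out_dir, "np_growth_curves.csv"))
    write_pipeline_table(quotas, file.path(out_dir, "np_quota_curves.csv"))
  }
  out
}

#' Lossless CSV table output
#'
#' Writes numeric columns with 17 significant digits so that tables
#' round-trip bit-identically through [read_pipeline_table()].
#'
#' @param df a data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pipeline_table <- function(df, path) {
  fmt <- df
  for (cn in names(fmt)) {
    if (is.double(fmt[[cn]])) fmt[[cn]] <- sprintf("%.17g", fmt[[cn]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_table
#' @export
read_pipeline_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in names(df)) {
    if (is.character(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (!anyNA(v)) df[[cn]] <- v
    }
  }
  df
}

# Machine-readable provenance header attached to every runner result.
pipeline_provenance <- function(config) {
  cfg_hash <- if (is.null(config)) NA_character_ else {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(unclass(config), tf)
    unname(tools::md5sum(tf))
  }
  list(package = "cfmphyto",
       version = as.character(utils::packageVersion("cfmphyto")),
       seed = if (is.null(config)) NA_integer_ else config$seed,
       config_md5 = cfg_hash)
}
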