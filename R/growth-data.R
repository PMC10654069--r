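#' Growth-rate versus concentration dataset
#'
#' The calibration target: paired observations of extracellular nutrient
#' concentration (uM) and specific growth rate (d^-1) for one organism at
#' one culture irradiance.
#'
#' @param concentration numeric vector of concentrations, uM (>= 0).
#' @param growth_rate numeric vector of growth rates, d^-1 (>= 0).
#' @param organism organism label.
#' @param irradiance culture irradiance, umol photons m^-2 s^-1.
#' @param nutrient `"P"` or `"N"`.
#' @return An object of class `growth_data`: list with `organism`,
#'   `nutrient`, `irradiance` and a data.frame `observations`.
#' @export
#' @examples
#' growth_dataset(c(0.1, 0.5, 2), c(0.2, 0.7, 1.1), "example", 200)
growth_dataset <- function(concentration, growth_rate, organism = "unknown",
                           irradiance = 200, nutrient = c("P", "N")) {
  nutrient <- match.arg(nutrient)
  concentration <- as.numeric(concentration)
  growth_rate <- as.numeric(growth_rate)
  if (length(concentration) != length(growth_rate)) {
    stop("concentration and growth_rate must have equal length", call. = FALSE)
  }
  if (length(concentration) < 3L) {
    stop("a growth dataset needs at least 3 observations", call. = FALSE)
  }
  if (anyNA(concentration) || anyNA(growth_rate) ||
      any(concentration < 0) || any(growth_rate < 0)) {
    stop("concentrations and growth rates must be non-negative and finite",
         call. = FALSE)
  }
  if (is.na(irradiance) || irradiance < 0) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  structure(list(
    organism = as.character(organism),
    nutrient = nutrient,
    irradiance = as.numeric(irradiance),
    observations = data.frame(concentration = concentration,
                              growth_rate = growth_rate)
  ), class = "growth_data")
}

#' @export
print.growth_data <- function(x, ...) {
  cat(sprintf("Growth dataset: %s (%s limitation), I = %g, n = %d\n",
              x$organism, x$nutrient, x$irradiance, nrow(x$observations)))
  print(utils::head(x$observations, 6))
  if (nrow(x$observations) > 6) cat("  ...\n")
  invisible(x)
}

#' Read / write growth datasets as CSV
#'
#' The CSV dialect has columns `organism`, `nutrient`, `concentration_uM`,
#' `growth_rate_per_day`, `irradiance`; one dataset per (organism, nutrient)
#' group. Malformed files raise a schema error naming the offending rows.
#'
#' @param path CSV file path.
#' @param datasets a `growth_data` object or list of them (for writing).
#' @return `read_growth_csv()` returns a list of `growth_data`;
#'   `write_growth_csv()` returns `path` invisibly.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organism", "nutrient", "concentration_uM",
            "growth_rate_per_day", "irradiance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("growth CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("growth CSV contains no observations", call. = FALSE)
  num <- c("concentration_uM", "growth_rate_per_day", "irradiance")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("growth CSV column '%s' has invalid values at row(s) %s",
                   cn, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    df[[cn]] <- v
  }
  keys <- split(df, list(df$organism, df$nutrient), drop = TRUE)
  out <- lapply(keys, function(d) {
    irr <- unique(d$irradiance)
    if (length(irr) != 1L) {
      stop(sprintf("dataset %s/%s mixes irradiances %s: one per dataset",
                   d$organism[1], d$nutrient[1],
                   paste(irr, collapse = ", ")), call. = FALSE)
    }
    growth_dataset(d$concentration_uM, d$growth_rate_per_day,
                   organism = d$organism[1], irradiance = irr,
                   nutrient = d$nutrient[1])
  })
  unname(out)
}

#' @rdname read_growth_csv
#' @export
write_growth_csv <- function(datasets, path) {
  if (inherits(datasets, "growth_data")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    data.frame(organism = d$organism, nutrient = d$nutrient,
               concentration_uM = d$observations$concentration,
               growth_rate_per_day = d$observations$growth_rate,
               irradiance = d$irradiance, stringsAsFactors = FALSE)
  })
  write_pipeline_table(do.call(rbind, rows), path)
}
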