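#' Physiological parameters of the cell flux model
#'
#' Constructs and validates the full parameter set of the coarse-grained
#' allocation model. All quotas are expressed per unit cellular carbon
#' (mol mol C^-1), rates in d^-1 and concentrations in uM, so that the
#' phosphate uptake law `V_P = A_P * [PO4]` is dimensionally closed with
#' `A_P` in (mol P (mol C)^-1 d^-1) per uM.
#'
#' Fields left `NULL` fall back to the packaged `default` profile
#' (see [default_cell_params()]), which is stored as an annotated YAML file
#' under `inst/params/default.yaml`.
#'
#' @param ... named numeric overrides of individual parameters; unknown names
#'   are an error.
#' @param base parameter list to start from, default the packaged profile.
#'
#' @return An object of class `cell_params`: a named list with components
#' \describe{
#'   \item{A_P}{phosphate affinity, (mol P (mol C)^-1 d^-1) uM^-1}
#'   \item{A_Pho}{photosynthetic machinery to chlorophyll quota ratio (dimensionless)}
#'   \item{P_max}{maximum carbon fixation rate per chlorophyll carbon, d^-1}
#'   \item{O_I}{irradiance saturation constant, (umol photons m^-2 s^-1)^-1}
#'   \item{E}{biosynthesis respiration/excretion overhead (dimensionless)}
#'   \item{A_Bio}{biosynthetic protein per unit growth rate, d}
#'   \item{A_RNA}{RNA synthesis coefficient linking RNA quota to mu x protein quota, d}
#'   \item{A_Plip}{thylakoid phospholipid per unit chlorophyll (dimensionless)}
#'   \item{Q_C_Pro_other, Q_C_DNA, Q_C_RNA_min, Q_C_other}{constant carbon quotas, mol C (mol C)^-1}
#'   \item{Y_RNA, Y_DNA, Y_Plip}{P:C stoichiometric ratios, mol P (mol C)^-1}
#'   \item{Q_P_other}{constant residual phosphorus quota, mol P (mol C)^-1}
#'   \item{Y_Pro_N, Y_RNA_N, Y_DNA_N, Y_Chl_N}{N:C stoichiometric ratios (nitrogen variant)}
#'   \item{A_N}{nitrate affinity, (mol N (mol C)^-1 d^-1) uM^-1}
#' }
#' @export
#' @examples
#' p <- cell_params(A_P = 0.05)
#' p$A_P
cell_params <- function(..., base = default_cell_params()) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L])) {
    over <- over[[1L]]
  }
  known <- .cfm_param_names
  if (length(over)) {
    bad <- setdiff(names(over), known)
    if (length(bad)) {
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    base[names(over)] <- lapply(over, as.numeric)
  }
  validate_cell_params(base)
}

.cfm_param_names <- c(
  "A_P", "A_Pho", "P_max", "O_I", "E", "A_Bio", "A_RNA", "A_Plip",
  "Q_C_Pro_other", "Q_C_DNA", "Q_C_RNA_min", "Q_C_other",
  "Y_RNA", "Y_DNA", "Y_Plip", "Q_P_other",
  "Y_Pro_N", "Y_RNA_N", "Y_DNA_N", "Y_Chl_N", "A_N"
)

validate_cell_params <- function(p) {
  miss <- setdiff(.cfm_param_names, names(p))
  if (length(miss)) {
    stop("missing cell parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p <- p[.cfm_param_names]
  vals <- unlist(p, use.names = TRUE)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("cell parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("cell parameters must be non-negative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  qc_const <- p$Q_C_Pro_other + p$Q_C_DNA + p$Q_C_RNA_min + p$Q_C_other
  if (qc_const >= 1) {
    stop("constant carbon quotas sum to ", signif(qc_const, 4),
         " >= 1: no carbon remains for growth machinery", call. = FALSE)
  }
  structure(p, class = "cell_params")
}

#' Packaged default parameter profile
#'
#' Reads the versioned `default` profile shipped with the package. The profile
#' pairs stoichiometric ratios fixed by molecular composition (one P per ~9.5
#' C in a ribonucleotide gives `Y_RNA` ~ 0.105; amino-acid composition gives a
#' protein N:C near 0.27) with allocation coefficients of the magnitude
#' reported for the cell flux model family; at the profile's reference
#' irradiance of 200 umol photons m^-2 s^-1 the carbon-limited saturated
#' growth rate is 1.16 d^-1.
#'
#' @return A `cell_params` object.
#' @seealso [read_cell_params()] to load a profile from a YAML or JSON file.
#' @export
default_cell_params <- function() {
  path <- system.file("params", "default.yaml", package = "cfmphyto",
                      mustWork = TRUE)
  read_cell_params(path)
}

#' Read / write a parameter profile
#'
#' Parameter profiles are flat YAML (or JSON) maps with one entry per
#' [cell_params()] field; units are annotated as comments in the shipped
#' default file. Extra keys starting with `"."` (e.g. provenance notes)
#' are ignored.
#'
#' @param path file to read or write.
#' @param params a `cell_params` object (for writing).
#' @return `read_cell_params()` returns a validated `cell_params` object;
#'   `write_cell_params()` returns `path` invisibly.
#' @export
read_cell_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw[!startsWith(names(raw), ".")]
  validate_cell_params(lapply(raw, as.numeric))
}

#' @rdname read_cell_params
#' @export
write_cell_params <- function(params, path) {
  params <- validate_cell_params(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(unclass(params), path)
  }
  invisible(path)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell flux model parameters\n")
  v <- unlist(x)
  out <- data.frame(value = signif(v, 6))
  print(out)
  invisible(x)
}

#' Extracellular environment
#'
#' Bundles the conditions a model run responds to: phosphate (uM), optional
#' nitrate (uM, used only by the nitrogen-limitation variant) and irradiance
#' (umol photons m^-2 s^-1).
#'
#' @param phosphate phosphate concentration, uM (>= 0).
#' @param irradiance photon flux, umol photons m^-2 s^-1 (>= 0).
#' @param nitrate nitrate concentration, uM (>= 0), or `NA` when unused.
#' @return An object of class `cfm_env`.
#' @export
#' @examples
#' cfm_env(phosphate = 0.5, irradiance = 200)
cfm_env <- function(phosphate, irradiance = 200, nitrate = NA_real_) {
  phosphate <- as.numeric(phosphate)
  irradiance <- as.numeric(irradiance)
  nitrate <- as.numeric(nitrate)
  stopifnot(length(phosphate) == 1L, length(irradiance) == 1L,
            length(nitrate) == 1L)
  if (is.na(phosphate) || phosphate < 0) {
    stop("phosphate must be a non-negative concentration (uM)", call. = FALSE)
  }
  if (is.na(irradiance) || irradiance < 0) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  if (!is.na(nitrate) && nitrate < 0) {
    stop("nitrate must be non-negative when supplied", call. = FALSE)
  }
  structure(list(phosphate = phosphate, irradiance = irradiance,
                 nitrate = nitrate),
            class = "cfm_env")
}

#' @export
print.cfm_env <- function(x, ...) {
  cat(sprintf("Environment: PO4 = %g uM, I = %g umol photons m-2 s-1",
              x$phosphate, x$irradiance))
  if (!is.na(x$nitrate)) cat(sprintf(", NO3 = %g uM", x$nitrate))
  cat("\n")
  invisible(x)
}
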