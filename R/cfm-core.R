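#' Light-saturating photosynthesis rate
#'
#' Carbon fixation per unit chlorophyll carbon as a saturating function of
#' irradiance, `P_max * (1 - exp(-O_I * I))`. Strictly increasing in `I` and
#' bounded above by `P_max`.
#'
#' @param irradiance photon flux, umol photons m^-2 s^-1 (>= 0); vectorized.
#' @param params a [cell_params()] object.
#' @return carbon fixation rate per chlorophyll carbon, d^-1.
#' @export
#' @examples
#' p <- default_cell_params()
#' photosynthesis_rate(200, p)
photosynthesis_rate <- function(irradiance, params) {
  if (any(is.na(irradiance)) || any(irradiance < 0)) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  params$P_max * (1 - exp(-params$O_I * irradiance))
}

# Condition signalling that a requested growth rate cannot be supported:
# negative carbon storage (carbon over-committed) or no admissible root.
cfm_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("cfm_infeasible", "error")))
}

# mu-polynomial structure of the carbon quotas:
#   Q_C_Chl      = k_chl * mu,                k_chl = (1+E)/P_I
#   Q_C_PlipThy  = A_Plip * k_chl * mu
#   Q_C_Pro      = p1 * mu + p0,              p1 = A_Pho*k_chl + A_Bio
#   Q_C_RNA      = Q_C_RNA_min + A_RNA * mu * Q_C_Pro   (quadratic in mu)
# Returns the shared coefficient bundle used by quotas and polynomials.
.quota_coefs <- function(irradiance, params) {
  p_i <- photosynthesis_rate(irradiance, params)
  k_chl <- if (p_i > 0) (1 + params$E) / p_i else Inf
  list(
    p_i = p_i,
    k_chl = k_chl,
    p1 = params$A_Pho * k_chl + params$A_Bio,
    p0 = params$Q_C_Pro_other
  )
}

#' Carbon allocation at a prescribed growth rate
#'
#' Evaluates the carbon side of the allocation model at growth rate `mu`:
#' chlorophyll scales with `mu` through the light-saturating photosynthesis
#' rate, protein is linear in `mu` (photosynthetic + biosynthetic + constant),
#' RNA is quadratic in `mu` (proportional to `mu` times the protein quota on
#' top of a constant floor), DNA and "other" carbon are constant, and carbon
#' storage takes up the residual so the quotas always sum to one.
#'
#' @param mu specific growth rate, d^-1 (>= 0).
#' @param env a [cfm_env()] object (only `irradiance` is used).
#' @param params a [cell_params()] object.
#' @return An object of class `cfm_allocation` with the carbon quotas filled
#'   in and the phosphorus quotas `NA` (see [phosphorus_quota()]).
#'   Signals a condition of class `cfm_infeasible` if the residual carbon
#'   storage would be negative, i.e. `mu` is not attainable under carbon
#'   availability.
#' @export
#' @examples
#' p <- default_cell_params()
#' a <- carbon_quotas(0.5, cfm_env(1, 200), p)
#' a$Q_C_Csto
carbon_quotas <- function(mu, env, params) {
  stopifnot(length(mu) == 1L)
  if (is.na(mu) || mu < 0) stop("mu must be non-negative", call. = FALSE)
  qc <- .quota_coefs(env$irradiance, params)
  if (mu > 0 && !is.finite(qc$k_chl)) {
    cfm_infeasible("no photosynthesis at zero light: positive growth infeasible")
  }
  q_chl <- if (mu == 0) 0 else qc$k_chl * mu
  q_plip <- params$A_Plip * q_chl
  q_pro <- qc$p1 * mu + qc$p0
  if (mu == 0) q_pro <- qc$p0
  q_rna <- params$Q_C_RNA_min + params$A_RNA * mu * q_pro
  used <- q_pro + q_rna + params$Q_C_DNA + q_chl + q_plip + params$Q_C_other
  q_csto <- 1 - used
  if (q_csto < -1e-12) {
    cfm_infeasible(sprintf(
      "growth rate %.6g d^-1 infeasible: carbon storage would be %.3g",
      mu, q_csto))
  }
  structure(list(
    mu = mu,
    Q_C_Pro = q_pro, Q_C_RNA = q_rna, Q_C_DNA = params$Q_C_DNA,
    Q_C_Chl = q_chl, Q_C_PlipThy = q_plip,
    Q_C_Csto = max(q_csto, 0), Q_C_Other = params$Q_C_other,
    Q_P_Thy = NA_real_, Q_P_RNA = NA_real_, Q_P_DNA = NA_real_,
    Q_P_Oth = NA_real_, Q_P_Sto = NA_real_, Q_P_total = NA_real_,
    limitation_flag = NA_character_
  ), class = "cfm_allocation")
}

#' Phosphorus quota of an allocation state
#'
#' Converts the carbon quotas to phosphorus through fixed stoichiometric
#' ratios: RNA and DNA carry `Y_RNA`/`Y_DNA` mol P per mol C, the thylakoid
#' phospholipid carries `Y_Plip`, a constant residual pool `Q_P_other` covers
#' metabolites, and phosphorus storage is zero (no luxury uptake in this
#' model). The total inherits RNA's quadratic dependence on growth rate.
#'
#' @param state a `cfm_allocation` from [carbon_quotas()].
#' @param params a [cell_params()] object.
#' @return Total phosphorus quota, mol P (mol C)^-1, with the component
#'   breakdown attached as attribute `"components"`.
#' @export
phosphorus_quota <- function(state, params) {
  comp <- list(
    Q_P_Thy = params$Y_Plip * state$Q_C_PlipThy,
    Q_P_RNA = params$Y_RNA * state$Q_C_RNA,
    Q_P_DNA = params$Y_DNA * state$Q_C_DNA,
    Q_P_Oth = params$Q_P_other,
    Q_P_Sto = 0
  )
  total <- comp$Q_P_Thy + comp$Q_P_RNA + comp$Q_P_DNA + comp$Q_P_Oth +
    comp$Q_P_Sto
  attr(total, "components") <- comp
  total
}

# Nitrogen quota (comparison variant): protein, RNA, DNA and chlorophyll
# converted through N:C ratios. No storage, no residual pool.
nitrogen_quota <- function(state, params) {
  comp <- list(
    Q_N_Pro = params$Y_Pro_N * state$Q_C_Pro,
    Q_N_RNA = params$Y_RNA_N * state$Q_C_RNA,
    Q_N_DNA = params$Y_DNA_N * state$Q_C_DNA,
    Q_N_Chl = params$Y_Chl_N * state$Q_C_Chl
  )
  total <- comp$Q_N_Pro + comp$Q_N_RNA + comp$Q_N_DNA + comp$Q_N_Chl
  attr(total, "components") <- comp
  total
}

#' Diffusion-limited phosphate uptake
#'
#' Uptake is linear in the extracellular concentration, `V_P = A_P * [PO4]`,
#' as expected when transport is diffusion limited.
#'
#' @param env a [cfm_env()] object.
#' @param params a [cell_params()] object.
#' @return uptake rate, mol P (mol C)^-1 d^-1.
#' @export
uptake_rate <- function(env, params) {
  params$A_P * env$phosphate
}

#' Polynomial coefficients of the steady-state growth conditions
#'
#' Collects powers of the growth rate in the two closure conditions of the
#' model. Carbon limitation: the carbon quotas with zero storage must sum to
#' one, a quadratic `a_C mu^2 + b_C mu + c_C = 0`. Nutrient limitation: at
#' steady state uptake balances dilution by growth, `A_P [PO4] = mu Q_P(mu)`,
#' a cubic `a_P mu^3 + b_P mu^2 + c_P mu + d_P = 0` (the extra power comes
#' from multiplying the quadratic quota by `mu`). The same expansion with N:C
#' ratios gives the nitrogen variant.
#'
#' @param env a [cfm_env()] object.
#' @param params a [cell_params()] object.
#' @param nutrient `"P"` (default) or `"N"` for the nitrogen variant.
#' @return An object of class `cfm_poly`: list with `c_quad = c(a_C, b_C,
#'   c_C)` and `nut_cubic = c(a, b, c, d)` in decreasing powers of `mu`,
#'   plus the nutrient label.
#' @export
#' @examples
#' assemble_coefficients(cfm_env(1, 200), default_cell_params())
assemble_coefficients <- function(env, params, nutrient = c("P", "N")) {
  nutrient <- match.arg(nutrient)
  qc <- .quota_coefs(env$irradiance, params)
  if (!is.finite(qc$k_chl) || qc$p_i <= 0) {
    stop("photosynthesis rate must be positive to assemble coefficients",
         call. = FALSE)
  }
  # carbon conservation with zero storage:
  # 1 = (p1 mu + p0) + (Q_RNA_min + A_RNA mu (p1 mu + p0))
  #     + Q_DNA + (1 + A_Plip) k_chl mu + Q_other
  a_c <- params$A_RNA * qc$p1
  b_c <- qc$p1 + (1 + params$A_Plip) * qc$k_chl + params$A_RNA * qc$p0
  c_c <- qc$p0 + params$Q_C_RNA_min + params$Q_C_DNA + params$Q_C_other - 1
  if (a_c == 0 && b_c == 0) {
    stop("degenerate parameters: carbon balance has no mu dependence",
         call. = FALSE)
  }

  if (nutrient == "P") {
    # Q_P(mu) = qa mu^2 + qb mu + q0
    qa <- params$Y_RNA * params$A_RNA * qc$p1
    qb <- params$Y_RNA * params$A_RNA * qc$p0 +
      params$Y_Plip * params$A_Plip * qc$k_chl
    q0 <- params$Y_RNA * params$Q_C_RNA_min +
      params$Y_DNA * params$Q_C_DNA + params$Q_P_other
    supply <- params$A_P * env$phosphate
  } else {
    if (is.na(env$nitrate)) {
      stop("nitrate concentration required for the nitrogen variant",
           call. = FALSE)
    }
    qa <- params$Y_RNA_N * params$A_RNA * qc$p1
    qb <- params$Y_Pro_N * qc$p1 + params$Y_RNA_N * params$A_RNA * qc$p0 +
      params$Y_Chl_N * qc$k_chl
    q0 <- params$Y_Pro_N * qc$p0 + params$Y_RNA_N * params$Q_C_RNA_min +
      params$Y_DNA_N * params$Q_C_DNA
    supply <- params$A_N * env$nitrate
  }
  if (qa == 0 && qb == 0 && q0 == 0) {
    stop("degenerate parameters: nutrient balance has no mu dependence",
         call. = FALSE)
  }
  structure(list(
    c_quad = c(a_C = a_c, b_C = b_c, c_C = c_c),
    nut_cubic = c(a = qa, b = qb, c = q0, d = -supply),
    nutrient = nutrient
  ), class = "cfm_poly")
}

#' @export
print.cfm_poly <- function(x, ...) {
  cat("Steady-state polynomial coefficients (decreasing powers of mu)\n")
  cat("  C-limited quadratic:", paste(signif(x$c_quad, 6), collapse = ", "),
      "\n")
  cat(sprintf("  %s-limited cubic:   %s\n", x$nutrient,
              paste(signif(x$nut_cubic, 6), collapse = ", ")))
  invisible(x)
}

# Evaluate a polynomial given coefficients in decreasing powers.
.polyval <- function(coefs, x) {
  out <- 0
  for (cf in coefs) out <- out * x + cf
  out
}

# Smallest non-negative real root of a polynomial (decreasing powers),
# polished by Newton and validated against the residual; guarded bisection
# on [0, hi] as fallback. `resid` is the scalar residual function whose sign
# change brackets the physical root (resid(0) >= 0 on the relevant branch).
.smallest_root <- function(coefs, resid, hi_cap = 1e3, tol = 1e-12) {
  while (length(coefs) > 1L && coefs[1] == 0) coefs <- coefs[-1L]
  roots <- tryCatch(polyroot(rev(coefs)), error = function(e) complex(0))
  scale <- max(abs(coefs), 1)
  re <- Re(roots)[abs(Im(roots)) < 1e-7 * pmax(abs(roots), 1)]
  re <- sort(re[re > -1e-10])
  root <- NA_real_
  for (r in pmax(re, 0)) {
    r2 <- .newton_polish(coefs, r)
    if (r2 >= -1e-12 && abs(resid(max(r2, 0))) < 1e-8 * scale) {
      root <- max(r2, 0)
      break
    }
  }
  if (is.na(root)) {
    root <- .bisect_root(resid, hi_cap)
  }
  if (is.na(root)) return(NA_real_)
  root
}

.newton_polish <- function(coefs, x, iters = 6L) {
  dcoefs <- coefs[-length(coefs)] * rev(seq_len(length(coefs) - 1L))
  for (i in seq_len(iters)) {
    f <- .polyval(coefs, x)
    d <- .polyval(dcoefs, x)
    if (!is.finite(d) || d == 0) break
    step <- f / d
    x <- x - step
    if (abs(step) < 1e-15 * max(abs(x), 1)) break
  }
  x
}

# Bisection for the smallest root of resid (resid(0) >= 0, decreasing through
# the root). Returns NA if no sign change up to hi_cap.
.bisect_root <- function(resid, hi_cap = 1e3, tol = 1e-12) {
  f0 <- resid(0)
  if (f0 < 0) return(NA_real_)
  if (f0 == 0) return(0)
  hi <- 1
  while (resid(hi) > 0 && hi < hi_cap) hi <- hi * 2
  if (resid(hi) > 0) return(NA_real_)
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (fm > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Carbon-limited (saturated) growth rate
#'
#' Solves the carbon-conservation quadratic for the growth rate at which the
#' carbon quotas sum to one with zero storage. This is the plateau of the
#' growth curve: the fastest growth the cell can sustain regardless of
#' nutrient supply.
#'
#' @inheritParams assemble_coefficients
#' @return growth rate, d^-1.
#' @export
#' @examples
#' solve_c_limited(cfm_env(1, 200), default_cell_params())
solve_c_limited <- function(env, params) {
  poly <- assemble_coefficients(env, params)
  co <- poly$c_quad
  resid <- function(mu) -.polyval(co, mu)  # 1 - sum(Q_C) without storage
  if (co[["c_C"]] >= 0) {
    cfm_infeasible("constant carbon quotas leave no room for growth machinery")
  }
  root <- .smallest_root(co, resid)
  if (is.na(root) || root < 0) {
    cfm_infeasible("no feasible carbon-limited growth rate")
  }
  # all quotas are non-negative for mu >= 0 by construction; verify residual
  st <- carbon_quotas(root, env, params)
  if (abs(st$Q_C_Csto) > 1e-9) {
    cfm_infeasible("carbon-limited root failed residual validation")
  }
  unname(root)
}

#' Phosphorus-limited growth rate
#'
#' Solves the steady-state nutrient balance `A_P [PO4] = mu Q_P(mu)` — a
#' cubic in `mu` — for the smallest non-negative real root, the steady state
#' continuously connected to `mu = 0` at zero phosphate. The root is polished
#' against the residual and falls back to guarded bisection; because all
#' coefficients of `mu Q_P(mu)` are non-negative the balance has exactly one
#' non-negative solution.
#'
#' @inheritParams assemble_coefficients
#' @param nutrient `"P"` (default) or `"N"`; [solve_n_limited()] is the
#'   nitrogen wrapper.
#' @return growth rate, d^-1 (unconstrained by carbon; see [growth_rate()]
#'   for the realized rate).
#' @export
#' @examples
#' solve_p_limited(cfm_env(0.2, 200), default_cell_params())
solve_p_limited <- function(env, params, nutrient = "P") {
  poly <- assemble_coefficients(env, params, nutrient = nutrient)
  co <- poly$nut_cubic
  supply <- -co[["d"]]
  resid <- function(mu) supply - mu * .polyval(co[1:3], mu)
  if (supply == 0) {
    if (co[["c"]] > 0 || co[["b"]] > 0 || co[["a"]] > 0) return(0)
    cfm_infeasible("nutrient balance degenerate at zero supply")
  }
  root <- .smallest_root(co, resid)
  if (is.na(root) || root < 0) {
    cfm_infeasible("no non-negative steady-state growth rate")
  }
  unname(root)
}

#' @rdname solve_p_limited
#' @export
solve_n_limited <- function(env, params) {
  solve_p_limited(env, params, nutrient = "N")
}

#' Realized growth rate and allocation
#'
#' The realized growth rate is the minimum of the nutrient-limited and
#' carbon-limited branch solutions; whichever branch binds sets the
#' limitation flag. The returned allocation is evaluated at the realized
#' rate: carbon storage is the non-negative residual of the carbon budget
#' (exactly zero when carbon limits) and phosphorus storage is always zero
#' (no luxury uptake).
#'
#' @inheritParams assemble_coefficients
#' @param nutrient `"P"` (default) or `"N"` for the nitrogen variant.
#' @return A list with `mu` (d^-1) and `state` (a `cfm_allocation` carrying
#'   all carbon and phosphorus quotas plus `limitation_flag`).
#' @export
#' @examples
#' g <- growth_rate(cfm_env(0.3, 200), default_cell_params())
#' g$mu
#' g$state$limitation_flag
growth_rate <- function(env, params, nutrient = "P") {
  mu_c <- solve_c_limited(env, params)
  mu_n <- solve_p_limited(env, params, nutrient = nutrient)
  if (mu_c <= mu_n) {
    mu <- mu_c
    flag <- "C-limited"
  } else {
    mu <- mu_n
    flag <- if (nutrient == "P") "P-limited" else "N-limited"
  }
  state <- carbon_quotas(mu, env, params)
  if (flag == "C-limited") state$Q_C_Csto <- 0
  qp <- phosphorus_quota(state, params)
  comp <- attr(qp, "components")
  state[names(comp)] <- comp
  state$Q_P_total <- as.numeric(qp)
  state$limitation_flag <- flag
  list(mu = mu, state = state)
}

#' @export
print.cfm_allocation <- function(x, ...) {
  cat(sprintf("Allocation state at mu = %.4g d^-1 (%s)\n", x$mu,
              ifelse(is.na(x$limitation_flag), "branch unset",
                     x$limitation_flag)))
  qc <- unlist(x[c("Q_C_Pro", "Q_C_RNA", "Q_C_DNA", "Q_C_Chl",
                   "Q_C_PlipThy", "Q_C_Csto", "Q_C_Other")])
  cat("  C quotas (mol C / mol C):\n")
  print(signif(qc, 4))
  if (!is.na(x$Q_P_total)) {
    qp <- unlist(x[c("Q_P_Thy", "Q_P_RNA", "Q_P_DNA", "Q_P_Oth", "Q_P_Sto")])
    cat(sprintf("  P quotas (mol P / mol C), total %.4g:\n", x$Q_P_total))
    print(signif(qp, 4))
  }
  invisible(x)
}

#' Growth curve over a phosphate (or nitrate) gradient
#'
#' Convenience sweep of [growth_rate()] over a concentration grid at fixed
#' irradiance.
#'
#' @param concentration numeric vector of concentrations, uM.
#' @param params a [cell_params()] object.
#' @param irradiance photon flux, umol photons m^-2 s^-1.
#' @param nutrient `"P"` (default) or `"N"`.
#' @return data.frame with columns `concentration`, `mu`, `limitation`.
#' @export
growth_curve <- function(concentration, params, irradiance = 200,
                         nutrient = "P") {
  rows <- lapply(concentration, function(s) {
    env <- if (nutrient == "P") cfm_env(s, irradiance)
           else cfm_env(0, irradiance, nitrate = s)
    g <- growth_rate(env, params, nutrient = nutrient)
    data.frame(concentration = s, mu = g$mu,
               limitation = g$state$limitation_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Fast predictor used by calibration: assemble coefficients once, then solve
# the cubic per concentration and cap at the carbon-limited plateau.
cfm_predict_mu <- function(concentration, params, irradiance,
                           nutrient = "P") {
  env0 <- if (nutrient == "P") cfm_env(0, irradiance)
          else cfm_env(0, irradiance, nitrate = 0)
  poly <- assemble_coefficients(env0, params, nutrient = nutrient)
  cq <- poly$c_quad
  if (cq[["c_C"]] >= 0) cfm_infeasible("no carbon-limited root")
  mu_c <- .smallest_root(cq, function(mu) -.polyval(cq, mu))
  if (is.na(mu_c) || mu_c < 0) cfm_infeasible("no carbon-limited root")
  aff <- if (nutrient == "P") params$A_P else params$A_N
  abc <- poly$nut_cubic[1:3]
  a <- abc[[1]]; b <- abc[[2]]; cc <- abc[[3]]
  v <- aff * concentration
  # g(mu) = mu * Q(mu) is convex increasing on [0, Inf) (all coefficients
  # >= 0), so Newton from above converges monotonically to the unique
  # non-negative root of g(mu) = supply; the realized rate is capped at the
  # carbon-limited plateau, so iteration stays on [0, mu_c].
  x <- rep(mu_c, length(v))
  for (it in 1:60) {
    g <- ((a * x + b) * x + cc) * x - v
    dg <- (3 * a * x + 2 * b) * x + cc
    step <- ifelse(dg > 0, g / dg, 0)
    x_new <- pmin(pmax(x - step, 0), mu_c)
    if (max(abs(x_new - x)) < 1e-13) {
      x <- x_new
      break
    }
    x <- x_new
  }
  resid <- abs(((a * x + b) * x + cc) * x - v)
  at_cap <- abs(x - mu_c) < 1e-10
  ok <- at_cap | resid < 1e-9 * pmax(v, 1)
  if (!all(ok)) {
    # fall back to the guarded general solver for the few that missed
    for (j in which(!ok)) {
      co <- c(abc, d = -v[j])
      r <- .smallest_root(co, function(mu) v[j] - mu * .polyval(abc, mu))
      if (is.na(r)) cfm_infeasible("no nutrient-limited root")
      x[j] <- min(r, mu_c)
    }
  }
  x
}
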