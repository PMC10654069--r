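# Independent oracles: quota sums written out term by term from the model
# definitions (no calls into the package's solver/coefficient code), plus a
# plain bisection root finder.

# Sum of carbon quotas at mu, storage excluded.
oracle_qc_sum <- function(mu, irradiance, p) {
  p_i <- p$P_max * (1 - exp(-p$O_I * irradiance))
  q_chl <- (1 + p$E) * mu / p_i
  q_plip <- p$A_Plip * q_chl
  q_pro <- p$A_Pho * q_chl + p$A_Bio * mu + p$Q_C_Pro_other
  q_rna <- p$Q_C_RNA_min + p$A_RNA * mu * q_pro
  q_pro + q_rna + p$Q_C_DNA + q_chl + q_plip + p$Q_C_other
}

# Phosphorus demand mu * Q_P(mu), term by term.
oracle_muQp <- function(mu, irradiance, p) {
  p_i <- p$P_max * (1 - exp(-p$O_I * irradiance))
  q_chl <- (1 + p$E) * mu / p_i
  q_pro <- p$A_Pho * q_chl + p$A_Bio * mu + p$Q_C_Pro_other
  q_rna <- p$Q_C_RNA_min + p$A_RNA * mu * q_pro
  qp <- p$Y_RNA * q_rna + p$Y_DNA * p$Q_C_DNA +
    p$Y_Plip * p$A_Plip * q_chl + p$Q_P_other
  mu * qp
}

# Bisection for f(mu) = 0 with f(lo) >= 0 >= f(hi), to absolute tol on mu.
oracle_bisect <- function(f, lo = 0, hi = 50, tol = 1e-12) {
  flo <- f(lo)
  if (flo < 0) stop("oracle_bisect: f(lo) < 0")
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Bisection solution of the carbon-limited growth rate.
oracle_mu_c <- function(irradiance, p) {
  oracle_bisect(function(mu) 1 - oracle_qc_sum(mu, irradiance, p))
}

# Bisection solution of the nutrient-limited growth rate.
oracle_mu_p <- function(phosphate, irradiance, p) {
  oracle_bisect(function(mu) p$A_P * phosphate -
                  oracle_muQp(mu, irradiance, p))
}

# Random valid parameter set spanning a wide physiological range; constant
# carbon quotas always sum to < 0.73 so every draw is feasible.
random_params <- function() {
  cell_params(
    A_P = 10^stats::runif(1, -2, -0.5),
    A_Pho = stats::runif(1, 1.5, 5),
    P_max = stats::runif(1, 150, 400),
    O_I = stats::runif(1, 0.004, 0.015),
    E = stats::runif(1, 0.3, 0.9),
    A_Bio = stats::runif(1, 0.15, 0.4),
    A_RNA = stats::runif(1, 0.08, 0.3),
    A_Plip = stats::runif(1, 0.05, 0.25),
    Q_C_Pro_other = stats::runif(1, 0.15, 0.3),
    Q_C_DNA = stats::runif(1, 0.005, 0.02),
    Q_C_RNA_min = stats::runif(1, 0.002, 0.01),
    Q_C_other = stats::runif(1, 0.2, 0.4),
    Y_RNA = stats::runif(1, 0.08, 0.12),
    Y_DNA = stats::runif(1, 0.08, 0.12),
    Y_Plip = stats::runif(1, 0.015, 0.035),
    Q_P_other = stats::runif(1, 2e-4, 2e-3)
  )
}

random_irradiance <- function() stats::runif(1, 30, 500)
random_phosphate <- function() 10^stats::runif(1, -2, 0.7)

# Carbon-quota sum of an allocation state (all components incl. storage).
state_qc_sum <- function(st) {
  st$Q_C_Pro + st$Q_C_RNA + st$Q_C_DNA + st$Q_C_Chl + st$Q_C_PlipThy +
    st$Q_C_Csto + st$Q_C_Other
}
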