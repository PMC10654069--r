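test_that("photosynthesis saturates with irradiance", {
  p <- default_cell_params()
  expect_identical(photosynthesis_rate(0, p), 0)
  expect_equal(photosynthesis_rate(1e9, p), p$P_max)
  expect_equal(photosynthesis_rate(1 / p$O_I, p),
               p$P_max * (1 - exp(-1)))
  ii <- seq(0, 600, by = 25)
  rates <- photosynthesis_rate(ii, p)
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates <= p$P_max))
  expect_error(photosynthesis_rate(-1, p), "non-negative")
})

test_that("carbon quotas follow the allocation forms and sum to one", {
  p <- default_cell_params()
  env <- cfm_env(1, 200)
  # zero-growth baseline
  st0 <- carbon_quotas(0, env, p)
  expect_identical(st0$Q_C_Chl, 0)
  expect_identical(st0$Q_C_Pro, p$Q_C_Pro_other)
  expect_identical(st0$Q_C_RNA, p$Q_C_RNA_min)
  expect_equal(st0$Q_C_Csto,
               1 - (p$Q_C_Pro_other + p$Q_C_RNA_min + p$Q_C_DNA +
                      p$Q_C_other))
  # components always sum to exactly 1 (storage is the residual)
  for (mu in c(0, 0.2, 0.7, 1.1)) {
    st <- carbon_quotas(mu, env, p)
    expect_equal(state_qc_sum(st), 1, tolerance = 1e-12)
    expect_true(all(unlist(st[c("Q_C_Pro", "Q_C_RNA", "Q_C_DNA", "Q_C_Chl",
                                "Q_C_PlipThy", "Q_C_Csto",
                                "Q_C_Other")]) >= 0))
  }
  # at the carbon-limited root the storage residual vanishes
  mu_c <- solve_c_limited(env, p)
  expect_lt(abs(carbon_quotas(mu_c, env, p)$Q_C_Csto), 1e-9)
  # over-committed carbon raises a typed infeasibility, not a clamp
  expect_error(carbon_quotas(5, env, p), class = "cfm_infeasible")
  expect_error(carbon_quotas(0.5, cfm_env(1, 0), p),
               class = "cfm_infeasible")
})

test_that("phosphorus quota matches a term-by-term hand computation", {
  p <- default_cell_params()
  env <- cfm_env(1, 200)
  st <- carbon_quotas(0.5, env, p)
  # independent spreadsheet-style evaluation at mu = 0.5
  p_i <- p$P_max * (1 - exp(-p$O_I * 200))
  q_chl <- (1 + p$E) * 0.5 / p_i
  q_pro <- p$A_Pho * q_chl + p$A_Bio * 0.5 + p$Q_C_Pro_other
  q_rna <- p$Q_C_RNA_min + p$A_RNA * 0.5 * q_pro
  by_hand <- p$Y_RNA * q_rna + p$Y_DNA * p$Q_C_DNA +
    p$Y_Plip * p$A_Plip * q_chl + p$Q_P_other
  expect_equal(as.numeric(phosphorus_quota(st, p)), by_hand,
               tolerance = 1e-12)
  # zero-growth baseline: no thylakoid P
  st0 <- carbon_quotas(0, env, p)
  expect_equal(as.numeric(phosphorus_quota(st0, p)),
               p$Y_RNA * p$Q_C_RNA_min + p$Y_DNA * p$Q_C_DNA + p$Q_P_other)
  # degenerate stoichiometry collapses to the residual pool
  pz <- cell_params(Y_RNA = 0, Y_DNA = 0, Y_Plip = 0, Q_P_other = 0.003)
  for (mu in c(0, 0.4, 1)) {
    expect_equal(as.numeric(phosphorus_quota(carbon_quotas(mu, env, pz), pz)),
                 0.003)
  }
  # component sum equals the reported total
  comp <- attr(phosphorus_quota(st, p), "components")
  expect_equal(sum(unlist(comp)), as.numeric(phosphorus_quota(st, p)),
               tolerance = 1e-14)
  expect_identical(comp$Q_P_Sto, 0)
})

test_that("uptake is linear in phosphate with slope A_P", {
  p <- cell_params(A_P = 0.01)
  expect_identical(uptake_rate(cfm_env(0, 200), p), 0)
  expect_equal(uptake_rate(cfm_env(2, 200), p), 0.02)
  expect_equal(uptake_rate(cfm_env(4, 200), p),
               2 * uptake_rate(cfm_env(2, 200), p))
})

test_that("polynomial coefficients are consistent with the quota operations", {
  p <- default_cell_params()
  env <- cfm_env(0.8, 200)
  poly <- assemble_coefficients(env, p)
  # the only mu-free term of the steady state is -A_P [PO4]
  expect_equal(unname(poly$nut_cubic[["d"]]), -p$A_P * 0.8)
  # residual identity: cubic(mu) == mu Q_P(mu) - V_P for arbitrary mu
  for (mu in c(0, 0.3, 0.9, 1.4)) {
    qp <- tryCatch(
      as.numeric(phosphorus_quota(carbon_quotas(mu, env, p), p)),
      cfm_infeasible = function(e) NULL)
    if (is.null(qp)) {
      # above the carbon-limited root the quota path refuses; use the oracle
      lhs <- oracle_muQp(mu, 200, p) - uptake_rate(env, p)
    } else {
      lhs <- mu * qp - uptake_rate(env, p)
    }
    co <- poly$nut_cubic
    rhs <- ((co[["a"]] * mu + co[["b"]]) * mu + co[["c"]]) * mu + co[["d"]]
    expect_equal(rhs, lhs, tolerance = 1e-10)
  }
  # quadratic residual identity: quad(mu) == sum(Q_C)(mu) - 1, storage excluded
  for (mu in c(0, 0.5, 1.16)) {
    cq <- poly$c_quad
    rhs <- (cq[["a_C"]] * mu + cq[["b_C"]]) * mu + cq[["c_C"]]
    expect_equal(rhs, oracle_qc_sum(mu, 200, p) - 1, tolerance = 1e-10)
  }
  # no quadratic RNA term -> the carbon balance degenerates to linear
  plin <- cell_params(A_RNA = 0)
  expect_identical(assemble_coefficients(env, plin)$c_quad[["a_C"]], 0)
})

test_that("branch solvers agree with the bisection oracle", {
  set.seed(401)
  for (i in 1:100) {
    p <- random_params()
    irr <- random_irradiance()
    s <- random_phosphate()
    env <- cfm_env(s, irr)
    expect_equal(solve_c_limited(env, p), oracle_mu_c(irr, p),
                 tolerance = 1e-8)
    expect_equal(solve_p_limited(env, p), oracle_mu_p(s, irr, p),
                 tolerance = 1e-8)
  }
})

test_that("degenerate linear carbon balance is solved exactly", {
  # A_RNA = 0 removes the quadratic term; root from the linear closed form
  p <- cell_params(A_RNA = 0)
  env <- cfm_env(1, 200)
  co <- assemble_coefficients(env, p)$c_quad
  expect_identical(co[["a_C"]], 0)
  expect_equal(solve_c_limited(env, p), -co[["c_C"]] / co[["b_C"]],
               tolerance = 1e-12)
})

test_that("zero phosphate means zero growth", {
  p <- default_cell_params()
  expect_identical(solve_p_limited(cfm_env(0, 200), p), 0)
  expect_identical(growth_rate(cfm_env(0, 200), p)$mu, 0)
})

test_that("the realized growth curve is two-phase", {
  p <- default_cell_params()
  grid <- exp(seq(log(0.005), log(8), length.out = 60))
  curve <- growth_curve(grid, p, irradiance = 200)
  mu_c <- solve_c_limited(cfm_env(0, 200), p)
  expect_true(all(diff(curve$mu) >= -1e-12))
  plateau <- curve$limitation == "C-limited"
  expect_true(any(plateau) && any(!plateau))
  # flag is monotone: P-limited strictly below the crossover, C-limited above
  expect_true(all(diff(as.integer(plateau)) >= 0))
  expect_true(all(abs(curve$mu[plateau] - mu_c) < 1e-12))
  rise <- curve$mu[!plateau]
  expect_true(all(diff(rise) > 0))
  # saturation: large phosphate gives the carbon-limited rate
  g <- growth_rate(cfm_env(1e6, 200), p)
  expect_equal(g$mu, mu_c)
  expect_identical(g$state$limitation_flag, "C-limited")
  expect_identical(g$state$Q_C_Csto, 0)
})

test_that("realized allocation respects storage rules and P bookkeeping", {
  set.seed(402)
  for (i in 1:25) {
    p <- random_params()
    irr <- random_irradiance()
    s <- random_phosphate()
    env <- cfm_env(s, irr)
    g <- growth_rate(env, p)
    st <- g$state
    expect_equal(state_qc_sum(st), 1, tolerance = 1e-10)
    expect_equal(st$Q_P_Thy + st$Q_P_RNA + st$Q_P_DNA + st$Q_P_Oth +
                   st$Q_P_Sto, st$Q_P_total, tolerance = 1e-10)
    expect_identical(st$Q_P_Sto, 0)
    if (st$limitation_flag == "C-limited") {
      expect_identical(st$Q_C_Csto, 0)
    } else {
      expect_gte(st$Q_C_Csto, 0)
      # steady state holds at the realized rate: uptake balances dilution
      expect_equal(g$mu * st$Q_P_total, uptake_rate(env, p),
                   tolerance = 1e-9)
    }
  }
})

test_that("growth rate is monotone in phosphate and irradiance", {
  p <- default_cell_params()
  ss <- exp(seq(log(0.01), log(5), length.out = 25))
  mus <- vapply(ss, function(s) growth_rate(cfm_env(s, 150), p)$mu,
                numeric(1))
  expect_true(all(diff(mus) >= -1e-12))
  ii <- seq(30, 500, length.out = 20)
  mus_i <- vapply(ii, function(irr) growth_rate(cfm_env(0.3, irr), p)$mu,
                  numeric(1))
  expect_true(all(diff(mus_i) >= -1e-12))
})

test_that("initial slope of the growth curve equals A_P / Q_P(0)", {
  set.seed(403)
  for (i in 1:10) {
    p <- random_params()
    irr <- random_irradiance()
    qp0 <- as.numeric(phosphorus_quota(carbon_quotas(0, cfm_env(0, irr), p),
                                       p))
    h <- 1e-7
    slope_num <- solve_p_limited(cfm_env(h, irr), p) / h
    expect_equal(slope_num, p$A_P / qp0, tolerance = 1e-4)
  }
})

test_that("RNA fraction of cellular P rises with growth rate", {
  set.seed(404)
  for (i in 1:20) {
    p <- cell_params(A_P = 10^runif(1, -2, -0.5),
                     A_Pho = runif(1, 2, 4.5))
    irr <- runif(1, 50, 400)
    env <- cfm_env(0, irr)
    mu_c <- solve_c_limited(env, p)
    mus <- seq(0, mu_c, length.out = 30)
    frac <- vapply(mus, function(m) {
      st <- carbon_quotas(m, env, p)
      qp <- phosphorus_quota(st, p)
      attr(qp, "components")$Q_P_RNA / as.numeric(qp)
    }, numeric(1))
    expect_true(all(diff(frac) >= -1e-12))
  }
})

test_that("nitrogen variant shares the carbon plateau and solves correctly", {
  p <- default_cell_params()
  expect_identical(solve_n_limited(cfm_env(0, 200, nitrate = 0), p), 0)
  # protein-only N demand makes the balance quadratic: closed-form check
  pq <- cell_params(Y_RNA_N = 0, Y_DNA_N = 0, Y_Chl_N = 0)
  env <- cfm_env(0, 200, nitrate = 4)
  qc <- cfmphyto:::.quota_coefs(200, pq)
  # A_N [NO3] = mu * Y_Pro_N * (p1 mu + p0)
  aa <- pq$Y_Pro_N * qc$p1
  bb <- pq$Y_Pro_N * qc$p0
  supply <- pq$A_N * 4
  closed <- (-bb + sqrt(bb^2 + 4 * aa * supply)) / (2 * aa)
  expect_equal(solve_n_limited(env, pq), closed, tolerance = 1e-10)
  # the plateau is nutrient-agnostic
  g_n <- growth_rate(cfm_env(0, 200, nitrate = 1e6), p, nutrient = "N")
  g_p <- growth_rate(cfm_env(1e6, 200), p)
  expect_equal(g_n$mu, g_p$mu)
  expect_identical(g_n$state$limitation_flag, "C-limited")
})

test_that("invalid inputs are rejected", {
  p <- default_cell_params()
  expect_error(cfm_env(-1, 200), "phosphate")
  expect_error(cfm_env(1, -5), "irradiance")
  expect_error(carbon_quotas(-0.1, cfm_env(1, 200), p), "non-negative")
  expect_error(cell_params(Q_C_other = 0.9), "sum")
  expect_error(cell_params(A_P = -1), "non-negative")
  expect_error(cell_params(bogus = 1), "unknown")
  expect_error(solve_n_limited(cfm_env(1, 200), p), "nitrate")
})
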