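fig4_env <- function(ca) list(I_a = 1000, D_v = 0.02, C_a = ca,
                              Gamma_star = 40)

test_that("electron transport light response", {
  expect_equal(electron_transport(0, 200), 0)
  expect_equal(electron_transport(1e9, 200), 200, tolerance = 1e-5)
  # at alpha_q * I = J_max the hyperbola gives J_max / 2
  expect_equal(electron_transport(200 / 0.3, 200), 100)
  j <- electron_transport(seq(0, 3000, by = 10), 300)
  expect_true(all(diff(j) >= 0) && all(diff(diff(j)) <= 1e-12))  # concave
})

test_that("temperature response anchors at 25 degC and peaks at t_opt", {
  expect_equal(jmax_at_temperature(250, 25), 250)
  expect_lt(jmax_at_temperature(250, 10), jmax_at_temperature(250, 25))
  tt <- seq(-9, 59, by = 0.01)
  jt <- jmax_at_temperature(100, tt, t_opt = 31)
  expect_equal(tt[which.max(jt)], 31, tolerance = 0.011)
  expect_true(all(jt > 0))
  expect_error(jmax_at_temperature(100, 70), "domain")
})

test_that("assimilation quadratic agrees with a root-bracketing oracle", {
  env <- list(C_a = 380, Gamma_star = 40)
  r0 <- assimilation(0, env, 100)
  expect_equal(r0$A_g, 0)
  expect_equal(r0$C_i, 40)            # no-flux equilibrium at Gamma*
  rb <- assimilation(1e5, env, 100)
  expect_equal(rb$C_i, 380, tolerance = 1e-2)
  expect_equal(rb$A_g, (100 / 4) * (380 - 40) / (380 + 2 * 40),
               tolerance = 1e-3)
  r <- assimilation(0.2, env, 100)
  o <- oracle_assim(0.2, 380, 40, 100)
  expect_equal(r$C_i, o$C_i, tolerance = 1e-8)
  expect_equal(r$A_g, o$A_g, tolerance = 1e-8)
  expect_true(r$C_i >= 40 && r$C_i <= 380)
})

test_that("transpiration is the linear diffusion law", {
  expect_equal(transpiration(0.3, 0), 0)
  expect_equal(transpiration(0.2, 0.01), 2 * transpiration(0.1, 0.01))
  expect_equal(transpiration(0.1, 0.02), 3.2e-3)
})

test_that("lambda from suction follows the water-use function", {
  expect_equal(lambda_from_suction(120, 1, c(0.7, 5, 5), 1), 120 * 0.7)
  expect_equal(lambda_from_suction(77, 0, c(2, 3), 2), 77)
  expect_equal(lambda_from_suction(100, -0.5, c(0.5, 1, 2), 3),
               100 * 3.5^(-0.5))
  expect_equal(lambda_from_suction(100, -0.5, c(0, 0), 2, lambda_max = 9e3),
               9e3)                   # degenerate zero-suction cap
  # alternative operator grouping, switchable
  expect_equal(lambda_from_suction(10, -1, c(1, 2), 2, per_layer = TRUE),
               10 * (1 + 1 / 2))
})

test_that("stomata shut when water is too costly and open with lambda", {
  env <- fig4_env(380)
  j <- electron_transport(1000, 250)
  lam_min <- 1.6 * env$D_v / ((env$C_a - env$Gamma_star) * 1e-6)
  r <- optimal_gs(env, j, lam_min * 0.9)
  expect_equal(r$g_s, 0)
  et <- vapply(seq(lam_min * 1.05, 5000, length.out = 40),
               function(l) optimal_gs(env, j, l)$E_t, numeric(1))
  expect_true(all(diff(et) >= -1e-15))
})

test_that("optimal_gs matches the brute-force oracle and holds the slope", {
  set.seed(5)
  for (i in 1:30) {
    env <- list(I_a = runif(1, 100, 2000), D_v = runif(1, 0.005, 0.04),
                C_a = runif(1, 280, 600), Gamma_star = 40)
    j <- electron_transport(env$I_a, runif(1, 80, 600))
    lam <- runif(1, 150, 4000)
    r <- optimal_gs(env, j, lam)
    o <- oracle_gs_grid(env, j, lam)
    expect_lte(abs(r$g_s - o$g_s), o$grid_step)
    if (r$g_s > 1e-6 && !r$limited) {
      expect_equal(oracle_slope(r$g_s, env, j), lam, tolerance = 1e-3)
      expect_equal(r$lambda_used, lam, tolerance = 1e-3)
    }
  }
})

test_that("supply cap binds transpiration and flags the result", {
  env <- fig4_env(380)
  j <- electron_transport(1000, 400)
  free <- optimal_gs(env, j, 2000)
  cap <- free$E_t / 2
  r <- optimal_gs(env, j, 2000, supply_cap = cap)
  expect_true(r$limited)
  expect_equal(r$E_t, cap, tolerance = 1e-12)
  expect_lt(r$g_s, free$g_s)
})

test_that("intrinsic water-use efficiency rises with CO2 at fixed conductance", {
  j <- 150
  iwue <- vapply(seq(300, 700, by = 50), function(ca)
    assimilation(0.15, list(C_a = ca, Gamma_star = 40), j)$A_g / 0.15,
    numeric(1))
  expect_true(all(diff(iwue) > 0))
})

test_that("transpiration response to CO2 reverses between high and low lambda", {
  # high marginal cost, high capacity: eCO2 lowers transpiration
  j485 <- function(ca) electron_transport(1000, 485)
  et_hi <- vapply(c(317, 380), function(ca)
    optimal_gs(fig4_env(ca), j485(ca), 3000)$E_t, numeric(1))
  expect_lt(et_hi[2], et_hi[1])
  # low marginal cost, low capacity: eCO2 raises transpiration
  j250 <- function(ca) electron_transport(1000, 250)
  et_lo <- vapply(c(317, 380), function(ca)
    optimal_gs(fig4_env(ca), j250(ca), 200)$E_t, numeric(1))
  expect_gt(et_lo[2], et_lo[1])
})

test_that("canopy fluxes scale with cover and reject overlap", {
  env <- c(fig4_env(380), T_a = 25)
  per <- big_leaf("perennial", 0.22, 250)
  sea <- big_leaf("seasonal", 0.42, 200)
  out <- canopy_fluxes(per, sea, env, 400, 300)
  sea0 <- big_leaf("seasonal", 0, 200)
  out0 <- canopy_fluxes(per, sea0, env, 400, 300)
  expect_equal(out0$E_t_s, 0)
  expect_equal(out0$A_g_s, 0)
  per2 <- big_leaf("perennial", 0.44, 250)
  out2 <- canopy_fluxes(per2, sea0, env, 400, 300)
  expect_equal(out2$E_t_p, 2 * out0$E_t_p, tolerance = 1e-12)
  expect_equal(out2$A_g_p, 2 * out0$A_g_p, tolerance = 1e-12)
  expect_error(canopy_fluxes(big_leaf("perennial", 0.7, 250),
                             big_leaf("seasonal", 0.5, 200), env, 400, 300),
               "overlap")
})
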