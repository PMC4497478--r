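test_that("relative sensitivity reproduces the printed arithmetic", {
  # an enrichment experiment at 580 ppm against a 380 ppm ambient is a
  # relative CO2 change of 580/380 - 1 = 0.5 at the printed precision
  expect_equal(580 / 380 - 1, 0.5, tolerance = 0.06)
  expect_equal(round(580 / 380 - 1, 1), 0.5)
  expect_equal(relative_sensitivity(100, 150, 380, 580),
               0.5 / (580 / 380 - 1))
  # sensitivity 0.7 under a 20 % CO2 increase implies a 14 % response
  expect_equal(relative_sensitivity(1, 1.14, 380, 456), 0.7)
  expect_equal(relative_sensitivity(5, 5, 317, 380), 0)
  expect_true(is.na(relative_sensitivity(0, 2, 317, 380)))
  expect_error(relative_sensitivity(1, 2, 317, 317), "undefined")
})

test_that("scenario validation enforces the mode contract", {
  site <- synthetic_site("water_limited")
  expect_error(scenario_spec(site, 380, "medium"), "frozen_params")
  expect_error(scenario_spec(site, -1, "long"), "positive")
  sc <- scenario_spec(site, 350, "long", n_years = 1, rng_seed = 2)
  f1 <- scenario_forcing(sc)
  f2 <- scenario_forcing(sc)
  expect_identical(f1, f2)
})

mk_const_sim <- function(lam = c(1, 2, 100)) {
  # hand-built logs: one year, constant fluxes, known lambda series
  nh <- 365 * 24
  hourly <- data.frame(
    t = seq_len(nh), I_a = rep(c(rep(0, 6), rep(1e-3, 12), rep(0, 6)), 365),
    T_a = 25, D_v = 0.01, rain = 1200 / nh,
    infiltration = 1200 / nh, runoff = 0, drainage = 500 / nh,
    E_s = 200 / nh, E_t_p = 300 / nh, E_t_s = 100 / nh,
    g_s_p = 0.2, g_s_s = 0.1, C_i_p = 250, C_i_s = 260,
    A_g_p = rep(c(rep(0, 6), rep(10, 12), rep(0, 6)), 365),
    A_g_s = rep(c(rep(0, 6), rep(5, 12), rep(0, 6)), 365),
    lambda_p = rep(lam, length.out = 365 * 24),
    lambda_s = 500, supply_p = 1, supply_s = 1,
    Theta_1 = 0.25, Av_Theta = 0.4, storage = 1000)
  hourly$lambda_p <- rep(rep(lam, length.out = 365), each = 24)
  # make storage consistent with the constant budget (helps the audit)
  dstep <- with(hourly[1, ], rain - runoff - drainage - E_s - E_t_p - E_t_s)
  hourly$storage <- 1000 + cumsum(rep(dstep, nh))
  daily <- data.frame(day = 1:365, J_max25_p = 200, J_max25_s = 150,
                      M_A_p = 0.3, M_A_s = 0.4, y_r_p = 1.5,
                      RAI_p = 0.5, RAI_s = 0.3, A_g_total = 0.4,
                      R_foliage = 0.05, R_roots = 0.03, R_wood = 0.02,
                      NCP_day = 0.3,
                      lambda_p = rep(lam, length.out = 365), lambda_s = 500)
  list(hourly = hourly, daily = daily, ncp = sum(daily$NCP_day),
       totals = list(), c_a = 380)
}

test_that("summaries of constant logs return the constants, with median lambdas", {
  sim <- mk_const_sim()
  s <- summarize_run(sim, last_n_years = 1)
  expect_equal(s$P, 1200, tolerance = 1e-9)
  expect_equal(s$Q, 500, tolerance = 1e-9)
  expect_equal(s$E_T, 600, tolerance = 1e-9)
  expect_equal(s$E_t_p, 300, tolerance = 1e-9)
  expect_equal(s$G_s_p, 200)          # 0.2 mol -> mmol
  expect_equal(s$M_A_s, 0.4)
  expect_equal(s$Theta_1, 0.25)
  expect_equal(s$J_max25_p, 200)
  # medians, not means: (1, 2, 100) -> 2
  expect_equal(s$lambda_p_median, 2)
  expect_equal(s$iWUE_p, 10 / 0.2)
  # water balance identity reported and satisfied
  expect_lt(abs(s$balance_residual), 1e-6 * s$P)
  expect_error(summarize_run(sim, last_n_years = 3), "window")
})

test_that("summary window errors and component accounting are coherent", {
  sim <- mk_const_sim()
  s <- summarize_run(sim, 1)
  expect_equal(s$E_T, s$E_t_p + s$E_t_s + s$E_s, tolerance = 1e-9)
  # WUE = total assimilation / total transpiration by construction
  ag_p_year <- 10 * 1e-6 * 3600 * 0.3 * 12 * 365   # daylight hours only
  expect_equal(s$WUE_p, ag_p_year / (300 / 0.018) * 1000, tolerance = 1e-6)
})

test_that("medium-term runs freeze the six constants and reproduce identity scenarios", {
  site <- synthetic_site("water_limited")
  p <- long_term_params(0.25, 1.5, 600, -0.6, 700, -0.4)
  scm <- scenario_spec(site, 380, "medium", frozen_params = p,
                       n_years = 1, rng_seed = 13)
  run <- run_medium_term(scm, last_n_years = 1)
  d <- run$sim$daily
  expect_true(all(d$M_A_p == p$m_a_p))
  expect_true(all(d$y_r_p == p$y_r_p))
  # identity scenario: rerunning the same frozen scenario is bit-identical
  run2 <- run_medium_term(scm, last_n_years = 1)
  expect_identical(run$sim$daily, run2$sim$daily)
  expect_equal(run$summary, run2$summary)
  # cover constraint holds in every daily row
  expect_true(all(d$M_A_p + d$M_A_s <= 1 + 1e-12))
})

test_that("degenerate forcing with no rain starves the vegetation", {
  site <- synthetic_site("water_limited")
  site$climate$wet_day_prob <- 0
  p <- long_term_params(0.3, 1.5, 500, -0.5, 500, -0.5)
  scm <- scenario_spec(site, 380, "medium", frozen_params = p,
                       n_years = 1, rng_seed = 3)
  run <- run_medium_term(scm, last_n_years = 1)
  # initial stored moisture allows a little early transpiration at most
  expect_lt(run$summary$E_t_p + run$summary$E_t_s, 60)
  expect_lt(run$ncp, 0)   # all-cost economy once the column dries
})

test_that("experiment tables report baseline values and percent deviations", {
  s0 <- summarize_run(mk_const_sim(), 1)
  s1 <- s0; s1$WUE_p <- s0$WUE_p * 1.2; s1$Q <- s0$Q * 0.9
  ex <- list(long = list("317" = list(summary = s0),
                         "380" = list(summary = s1)),
             medium = list("317" = list(summary = s0),
                           "380" = list(summary = s0)))
  tab <- experiment_table(ex)
  expect_equal(tab$value_317[tab$variable == "P"], s0$P)
  expect_equal(tab$long_380_pct[tab$variable == "WUE_p"], 20)
  expect_equal(tab$long_380_pct[tab$variable == "Q"], -10)
  expect_equal(tab$medium_380_pct[tab$variable == "WUE_p"], 0)
})
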