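mk_state <- function(j_p = 100, j_s = 80, ma_s = 0.3, sar_p = rep(0.5, 3),
                     sar_s = c(0.5, 0.5, 0), ma_p = 0.2)
  daily_state(j_p, j_s, ma_s, sar_p, sar_s, m_a_p = ma_p)

test_that("daily costs are linear with a hand-computed oracle", {
  cp <- cost_params(foliage_cost_coeff = 0.1,
                    photosynthetic_capacity_cost_coeff = 1e-3,
                    root_cost_coeff = 0.2, wood_cost_coeff = 0.05,
                    wood_depth_coeff = 0.4, capacity_cost_exponent = 1)
  zero <- mk_state(1e-12, 1e-12, 0, rep(0, 3), rep(0, 3), ma_p = 0)
  cz <- daily_costs(zero, 1.5, cp)
  expect_equal(cz$R_foliage, 0, tolerance = 1e-12)
  expect_equal(cz$R_roots, 0)
  expect_equal(cz$R_wood, 0)

  st <- mk_state()
  cc <- daily_costs(st, 1.5, cp)
  # hand arithmetic: foliage 0.1*(0.2+0.3) + 1e-3*(100*0.2 + 80*0.3)
  expect_equal(cc$R_foliage, 0.1 * 0.5 + 1e-3 * (20 + 24))
  expect_equal(cc$R_roots, 0.2 * 0.5 * (1.5 + 1.0))
  expect_equal(cc$R_wood, 0.05 * 0.2 * (1 + 0.4 * 1.5))

  st2 <- mk_state(ma_s = 0.6)
  cc2 <- daily_costs(st2, 1.5, cp)
  # doubling seasonal cover doubles its share of the foliage cost
  expect_equal(cc2$R_foliage - 0.1 * 0.2 - 1e-3 * 20,
               2 * (cc$R_foliage - 0.1 * 0.2 - 1e-3 * 20))
})

test_that("NCP accounting is additive and exact", {
  fl <- data.frame(day = 1:3, A_g_total = c(0.5, 0.8, 0.2))
  cl <- data.frame(day = 1:3, R_foliage = c(0.1, 0.1, 0.1),
                   R_roots = c(0.05, 0.05, 0.05), R_wood = rep(0.02, 3))
  expect_equal(ncp_total(fl, cl), (0.5 + 0.8 + 0.2) - 3 * 0.17)
  expect_equal(ncp_total(fl[1:2, ], cl[1:2, ]) + ncp_total(fl[3, ], cl[3, ]),
               ncp_total(fl, cl))
  z <- data.frame(day = 1, A_g_total = 0)
  zc <- data.frame(day = 1, R_foliage = 0, R_roots = 0, R_wood = 0)
  expect_equal(ncp_total(z, zc), 0)
  expect_error(ncp_total(fl, cl[c(2, 1, 3), ]), "misaligned")
})

test_that("marginal probes recover gradient signs on an analytic surface", {
  # synthetic NCP surface, quadratic in each variable
  surf <- function(st) {
    -(st$j_max25_p - 120)^2 / 100 - (st$j_max25_s - 60)^2 / 100 -
      (st$m_a_s - 0.4)^2 - sum((st$s_ar_p - 0.8)^2) -
      sum((st$s_ar_s - 0.2)^2)
  }
  st <- mk_state()
  g <- marginal_ncp(st, surf, probe = 0.01)
  expect_gt(g$j_max25_p, 0)   # 100 < 120: uphill
  expect_lt(g$j_max25_s, 0)   # 80 > 60: downhill
  expect_gt(g$m_a_s, 0)
  expect_true(all(g$s_ar_p > 0))
  expect_true(all(g$s_ar_s[1:2] < 0))
  g0 <- marginal_ncp(st, surf, probe = 0)
  expect_true(all(unlist(g0) == 0))
})

test_that("a lightless day makes photosynthetic capacity a pure cost", {
  cp <- cost_params()
  dark <- function(st) -sum(unlist(daily_costs(st, 1.5, cp)))
  g <- marginal_ncp(mk_state(), dark, probe = 0.05)
  expect_lt(g$j_max25_p, 0)
  expect_lt(g$j_max25_s, 0)
})

test_that("daily adjustment is a clipped fixed-point iteration", {
  st <- mk_state()
  same <- daily_adjust(st, marginal_ncp(st, function(s) 0, probe = 0.05))
  expect_equal(unclass(same), unclass(st))
  # cover constraint: proposed growth beyond 1 - M_A,p is clipped
  st2 <- mk_state(ma_s = 0.69, ma_p = 0.3)
  gain <- list(j_max25_p = 0, j_max25_s = 0, m_a_s = 1,
               s_ar_p = rep(0, 3), s_ar_s = rep(0, 3))
  adj <- daily_adjust(st2, gain, step = 0.1)
  expect_equal(adj$m_a_s, 0.7)
  expect_lte(adj$m_a_s + adj$m_a_p, 1)
})

test_that("hill climbing converges to the marginal-cost-equals-benefit point", {
  # 1-D economy in j_max25_p: concave benefit, linear cost
  benefit <- function(j) 2 * j / (j + 150)
  cost <- function(j) 0.004 * j
  surf <- function(st) benefit(st$j_max25_p) - cost(st$j_max25_p)
  jj <- seq(5, 2000, by = 0.5)
  j_opt <- jj[which.max(benefit(jj) - cost(jj))]  # exhaustive scan oracle
  st <- mk_state(j_p = 20)
  step <- 0.05
  for (i in 1:400)
    st <- daily_adjust(st, marginal_ncp(st, surf, probe = 0.01), step = step)
  expect_lt(abs(st$j_max25_p - j_opt) / j_opt, 2 * step)
  # constraints preserved throughout any adjustment sequence
  expect_true(st$m_a_s + st$m_a_p <= 1)
  expect_true(all(unlist(st[c("j_max25_p", "j_max25_s", "m_a_s")]) >= 0))
})
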