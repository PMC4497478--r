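soils <- list(sandy_loam = soil_preset("sandy_loam"),
              loam = soil_preset("loam"),
              sandy_clay_loam = soil_preset("sandy_clay_loam"))

test_that("retention curve limits and closed form", {
  sl <- soils$sandy_loam
  expect_equal(vg_saturation(0, sl), 1)
  th0 <- sl$theta_r + vg_saturation(0, sl) * (sl$theta_s - sl$theta_r)
  expect_equal(th0, 0.41)  # saturated water content, sandy loam
  # residual limit
  se_dry <- vg_saturation(1e6, sl)
  expect_lt(sl$theta_r + se_dry * (sl$theta_s - sl$theta_r),
            sl$theta_r + 1e-4)
  # closed-form value at h = 1 m
  expect_equal(vg_saturation(1, sl),
               (1 + 7.5^1.89)^(-(1 - 1 / 1.89)), tolerance = 1e-14)
  expect_error(vg_saturation(-0.1, sl), "domain")
})

test_that("conductivity curve limits, monotonicity and closed form", {
  for (s in soils) {
    expect_equal(vg_conductivity(1, s), s$k_sat)
    expect_equal(vg_conductivity(0, s), 0)
    kk <- vg_conductivity(seq(0, 1, length.out = 200), s)
    expect_true(all(diff(kk) >= 0))
  }
  scl <- soils$sandy_clay_loam
  expect_equal(vg_conductivity(0.5, scl),
               oracle_vg_k(0.5, 1.48, 3.639e-6), tolerance = 1e-14)
  expect_error(vg_conductivity(1.2, soils$loam), "domain")
})

test_that("retention and conductivity match the independent closed form on random pairs", {
  set.seed(77)
  for (i in 1:100) {
    s <- soils[[sample(3, 1)]]
    h <- runif(1, 0, 50)
    se <- vg_saturation(h, s)
    expect_equal(se, oracle_vg_se(h, s$theta_r, s$theta_s, s$alpha_vg,
                                  s$n_vg), tolerance = 1e-12)
    expect_equal(vg_conductivity(se, s), oracle_vg_k(se, s$n_vg, s$k_sat),
                 tolerance = 1e-12)
  }
})

test_that("suction inversion is the exact inverse of the retention curve", {
  s <- soils$loam
  h <- c(0, 10^seq(-3, 3, length.out = 50))
  expect_equal(vg_suction(vg_saturation(h, s), s), h, tolerance = 1e-8)
})

test_that("hydrostatic equilibrium column is a fixed point of the step", {
  s <- soils$sandy_loam
  g <- catchment_geometry(3, 1, 2)
  st <- soil_state(s, g, water_table = g$z_channel)
  out <- step_soil_water(st, s, g, rain_mm_h = 0, dt_h = 1)
  expect_equal(out$state$theta, st$theta, tolerance = 1e-7)
  expect_equal(out$drainage, 0)       # water table at channel elevation
  expect_equal(out$runoff, 0)
})

test_that("rain on a saturated column leaves as runoff with storage unchanged", {
  s <- soils$sandy_loam
  g <- catchment_geometry(2, 0.5, 2)
  st <- soil_state(s, g, theta = rep(s$theta_s, g$n_layers))
  ctl <- vom_control(c_drain = 0)     # isolate the saturation excess
  out <- step_soil_water(st, s, g, rain_mm_h = 50, dt_h = 1, control = ctl)
  expect_equal(out$runoff, 50, tolerance = 1e-9)
  expect_equal(soil_storage_mm(out$state, g), soil_storage_mm(st, g),
               tolerance = 1e-9)
})

test_that("mass balance closes over a pulse on a dry column", {
  s <- soils$sandy_loam
  g <- catchment_geometry(2, 0.5, 2)
  dry <- soil_state(s, g,
                    theta = rep(s$theta_r + 0.02 * (s$theta_s - s$theta_r),
                                g$n_layers))
  st <- dry
  stor0 <- soil_storage_mm(st, g)
  inflow <- 0; outflow <- 0
  for (hh in 1:6) {
    rain <- if (hh == 1) 10 else 0    # 10 mm pulse, then redistribution
    out <- step_soil_water(st, s, g, rain_mm_h = rain,
                           uptake_p_mm_h = rep(0.05, g$n_layers),
                           e_s_mm_h = 0.1, dt_h = 1)
    inflow <- inflow + out$infiltration
    outflow <- outflow + out$runoff + out$drainage + out$soil_evap +
      sum(out$uptake_p) + sum(out$uptake_s) - out$shortfall
    st <- out$state
  }
  dstor <- soil_storage_mm(st, g) - stor0
  expect_lt(abs(dstor - (inflow - outflow)),
            1e-9 * max(soil_storage_mm(st, g), 1))
  expect_true(all(st$theta >= s$theta_r & st$theta <= s$theta_s))
})

test_that("drainage flux is zero at the channel and strictly increasing above it", {
  s <- soils$sandy_loam
  g <- catchment_geometry(3, 1, 2)
  mk <- function(zw) structure(list(z_w = zw), class = "soil_state")
  expect_equal(drainage_flux(mk(g$z_channel), g, s), 0)
  expect_equal(drainage_flux(mk(0.2), g, s), 0)
  q <- vapply(seq(1.1, 3, by = 0.1),
              function(z) drainage_flux(mk(z), g, s), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_equal(max(q), drainage_flux(mk(g$z_surface), g, s))
})

test_that("soil evaporation responds to shading, moisture and radiation", {
  s <- soils$sandy_loam
  g <- catchment_geometry(2, 0.5, 2)
  forcing <- list(I_g = 600)
  wet <- soil_state(s, g, theta = rep(s$theta_s - 0.01, g$n_layers))
  expect_equal(soil_evaporation(wet, forcing, 1, s), 0)     # fully shaded
  dry <- soil_state(s, g, theta = rep(s$theta_r + 1e-9, g$n_layers))
  expect_lt(soil_evaporation(dry, forcing, 0, s), 1e-6)     # residual topsoil
  expect_equal(soil_evaporation(wet, list(I_g = 0), 0, s), 0)
  ths <- seq(0.1, 0.4, by = 0.05)
  es <- vapply(ths, function(t0) {
    st <- soil_state(s, g, theta = rep(t0, g$n_layers))
    soil_evaporation(st, forcing, 0.3, s)
  }, numeric(1))
  expect_true(all(diff(es) > 0))      # monotone in surface saturation
})

test_that("hourly stepping is stable under every preset soil", {
  for (s in soils) {
    g <- catchment_geometry(2, 0.5, 2)
    # half-wet over dry: strong gradients
    th <- c(rep(s$theta_s - 1e-3, 2), rep(s$theta_r + 0.01, 2))
    st <- soil_state(s, g, theta = th)
    ctl <- vom_control(c_drain = 0)
    stor <- soil_storage_mm(st, g)
    for (hh in 1:48) {
      out <- step_soil_water(st, s, g, control = ctl)
      st <- out$state
      stor <- c(stor, soil_storage_mm(st, g))
      expect_true(all(st$theta >= s$theta_r - 1e-12 &
                        st$theta <= s$theta_s + 1e-12))
    }
    # redistribution with no sinks or drainage: storage conserved, no blowup
    expect_equal(max(abs(diff(stor))), 0, tolerance = 1e-8)
    expect_true(st$z_w >= 0 && st$z_w <= g$z_surface)
  }
})
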