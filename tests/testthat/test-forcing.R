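test_that("synthetic daily generator honours degenerate and deterministic cases", {
  spec0 <- climate_spec(wet_day_prob = 0, rng_seed = 4)
  d0 <- generate_synthetic_daily(spec0, 2)
  expect_equal(nrow(d0), 2 * 365)
  expect_true(all(d0$rain_mm == 0))

  spec <- climate_spec(rng_seed = 9)
  expect_identical(generate_synthetic_daily(spec, 2),
                   generate_synthetic_daily(spec, 2))
  spec2 <- climate_spec(rng_seed = 10)
  expect_false(identical(generate_synthetic_daily(spec, 2)$rain_mm,
                         generate_synthetic_daily(spec2, 2)$rain_mm))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_synthetic_daily(spec, 1))
  expect_identical(runif(1), before)
})

test_that("long-run annual rainfall converges to the specified mean", {
  spec <- climate_spec(mean_annual_rain_mm = 1000, wet_day_prob = 0.25,
                       rng_seed = 2)
  d <- generate_synthetic_daily(spec, 200)
  annual <- tapply(d$rain_mm, rep(seq_len(200), each = 365), sum)
  expect_lt(abs(mean(annual) - 1000) / 1000, 0.05)
})

test_that("daily weather invariants hold across seeds", {
  for (seed in 1:5) {
    d <- generate_synthetic_daily(climate_spec(rng_seed = seed), 2)
    expect_true(all(d$rain_mm >= 0))
    expect_true(all(d$I_g_daily >= 0))
    expect_true(all(d$T_max >= d$T_min))
    expect_true(all(d$e_a >= 0))
  }
})

test_that("spec validation rejects bad configurations", {
  expect_error(climate_spec(mean_annual_rain_mm = -5), "configuration")
  expect_error(climate_spec(wet_day_prob = 1.4), "configuration")
  expect_error(generate_synthetic_daily(climate_spec(), 0), "configuration")
})

test_that("PPFD conversion applies the fixed coefficient", {
  expect_identical(ppfd_from_irradiance(0), 0)
  expect_equal(ppfd_from_irradiance(1000), 4.57e-3)
  a <- runif(10, 0, 1200); b <- runif(10, 0, 1200)
  expect_equal(ppfd_from_irradiance(a + b),
               ppfd_from_irradiance(a) + ppfd_from_irradiance(b))
  expect_error(ppfd_from_irradiance(-1), "domain")
})

test_that("hourly disaggregation conserves mass and energy and spans the temperature range", {
  day <- data.frame(doy = 40, rain_mm = 24, I_g_daily = 20,
                    T_max = 33, T_min = 21, e_a = 1.5)
  h <- disaggregate_to_hourly(day, latitude_deg = -20, c_a = 380)
  expect_equal(nrow(h), 24)
  expect_true(all(h$rain == 1))                      # even spread over 24 h
  expect_equal(sum(h$rain), day$rain_mm)
  expect_equal(sum(h$I_g * 3600) / 1e6, day$I_g_daily, tolerance = 1e-9)
  expect_equal(max(h$T_a), day$T_max)
  expect_equal(min(h$T_a), day$T_min)
  expect_true(all(h$D_v >= 0))
  expect_equal(h$I_a, 4.57e-6 * h$I_g)
  # night: hours well before dawn and after dusk carry no light
  expect_true(all(h$I_a[c(1:5, 21:24)] == 0))
})

test_that("vectorised disaggregation agrees with the single-day operation", {
  d <- generate_synthetic_daily(climate_spec(rng_seed = 6), 1)
  h_all <- make_hourly_forcing(d, -20, 350)
  for (k in c(1, 100, 300)) {
    h1 <- disaggregate_to_hourly(d[k, ], -20, 350)
    hk <- h_all[h_all$day == k, ]
    expect_equal(hk$I_g, h1$I_g, tolerance = 1e-12)
    expect_equal(hk$T_a, h1$T_a, tolerance = 1e-12)
    expect_equal(hk$D_v, h1$D_v, tolerance = 1e-12)
  }
  # mass/energy conservation across every day
  ig_daily <- colSums(matrix(h_all$I_g, 24)) * 3600 / 1e6
  expect_equal(ig_daily, d$I_g_daily, tolerance = 1e-9)
  rain_daily <- colSums(matrix(h_all$rain, 24))
  expect_equal(rain_daily, d$rain_mm, tolerance = 1e-12)
})

test_that("weather files round-trip and report gaps", {
  d <- generate_synthetic_daily(climate_spec(rng_seed = 8), 1)
  f <- tempfile(fileext = ".csv")
  write_daily_weather(d, f)
  r <- read_daily_weather(f)
  expect_equal(r$rain_mm, d$rain_mm, tolerance = 1e-10)
  expect_equal(r$T_max, d$T_max, tolerance = 1e-10)
  expect_length(attr(r, "gaps"), 0)

  d2 <- d[-10, ]  # drop one day
  write_daily_weather(d2, f)
  expect_message(r2 <- read_daily_weather(f), "missing day")
  expect_equal(attr(r2, "gaps"), d$date[10])

  writeLines("", f)
  expect_error(read_daily_weather(f), "format error")
  writeLines("date,rain_mm\n2000-01-01,5", f)
  expect_error(read_daily_weather(f), "missing columns")
})
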