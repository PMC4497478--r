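## Elevated-CO2 experiment protocol: long-term adaptation runs (all six
## community parameters re-optimized by SCE at each CO2 level) vs
## medium-term runs (the six constants frozen at the baseline-CO2 optimum,
## only the daily/hourly properties adapting), summary tables over the last
## simulation years and relative CO2 sensitivities.

#' Synthetic site presets for desk-scale experiments
#'
#' Two contrasting synthetic sites: `"water_limited"` (strongly seasonal,
#' 500 mm rainfall under high evaporative demand) and `"energy_limited"`
#' (2500 mm, humid). Both use a shallow (3 m) sandy-loam column so the full
#' experiment protocol runs at desk scale.
#'
#' @param type site type.
#' @return list with `climate` ([climate_spec()]), `soil`, `geometry`.
#' @export
synthetic_site <- function(type = c("water_limited", "energy_limited")) {
  type <- match.arg(type)
  # the column drains freely to bedrock: no permanent groundwater subsidy,
  # so vegetation lives off seasonally stored soil water as at dry savanna
  # sites where the water table sits far below the root zone
  geometry <- catchment_geometry(3, 0, 2)
  if (type == "water_limited") {
    # strongly seasonal dry savanna: annual potential evaporation well above
    # the 500 mm rainfall, concentrated in a single wet season
    list(climate = climate_spec(mean_annual_rain_mm = 500,
                                wet_season_center = 15,
                                rain_seasonality = 0.9,
                                wet_day_prob = 0.15,
                                latitude_deg = -20,
                                temperature_mean = 27,
                                temperature_amplitude = 4,
                                relative_humidity_mean = 0.45),
         soil = soil_preset("sandy_loam"), geometry = geometry,
         name = type)
  } else {
    list(climate = climate_spec(mean_annual_rain_mm = 2500,
                                wet_season_center = 15,
                                rain_seasonality = 0.6,
                                wet_day_prob = 0.45,
                                latitude_deg = -16,
                                temperature_mean = 24,
                                temperature_amplitude = 3,
                                relative_humidity_mean = 0.8),
         soil = soil_preset("sandy_loam"), geometry = geometry,
         name = type)
  }
}

#' Scenario specification
#'
#' @param site a [synthetic_site()] (or compatible list with `climate`,
#'   `soil`, `geometry`).
#' @param c_a atmospheric CO2 mole fraction (ppm).
#' @param mode `"long"` (all properties optimized at this CO2) or
#'   `"medium"` (six constants frozen; requires `frozen_params`).
#' @param frozen_params a [long_term_params()], required for medium-term
#'   scenarios.
#' @param n_years forcing years.
#' @param rng_seed seed for forcing generation and optimization.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(site, c_a, mode = c("long", "medium"),
                          frozen_params = NULL, n_years = 6, rng_seed = 1L) {
  mode <- match.arg(mode)
  if (c_a <= 0) stop("configuration error: c_a must be positive")
  if (mode == "medium" && is.null(frozen_params))
    stop("configuration error: medium-term mode requires frozen_params")
  structure(list(site = site, c_a = c_a, mode = mode,
                 frozen_params = frozen_params, n_years = n_years,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_spec")
}

#' Build hourly forcing for a scenario
#'
#' The forcing depends only on the site, years and seed - never on CO2 or
#' mode - so scenarios sharing a seed share meteorology bit for bit.
#'
#' @param scenario a [scenario_spec()].
#' @return hourly forcing data.frame.
#' @export
scenario_forcing <- function(scenario) {
  spec <- scenario$site$climate
  spec$rng_seed <- scenario$rng_seed
  daily <- generate_synthetic_daily(spec, scenario$n_years)
  make_hourly_forcing(daily, spec$latitude_deg, c_a = scenario$c_a)
}

# default SCE search box for the six long-term parameters
long_term_bounds <- function(geom) {
  # exponents restricted to the strictly conservative branch (lambda
  # decreasing as the root zone dries); near-zero or positive exponents
  # give pathological drought-insensitive strategies that a finite search
  # budget exploits. Factors below ~100 keep stomata shut even in wet soil
  # (lambda under the minimum attainable slope), i.e. dead communities.
  list(lower = c(m_a_p = 0.02, y_r_p = 0.5, c_lambda_f_p = 100,
                 c_lambda_e_p = -1.2, c_lambda_f_s = 100,
                 c_lambda_e_s = -1.2),
       upper = c(m_a_p = 0.95, y_r_p = min(2.5, geom$z_surface),
                 c_lambda_f_p = 3000, c_lambda_e_p = -0.05,
                 c_lambda_f_s = 3000, c_lambda_e_s = -0.05))
}

as_long_term <- function(x) {
  long_term_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' NCP objective for a scenario
#'
#' Returns the closure evaluated by the optimizer: six raw parameters (with
#' the rooting depth snapped to the 0.5 m grid) to total simulated NCP.
#'
#' @param scenario a [scenario_spec()].
#' @param forcing optional precomputed forcing (rebuilt if missing).
#' @param costs,control cost coefficients and numerical control.
#' @return function `numeric(6) -> NCP`.
#' @export
scenario_objective <- function(scenario, forcing = NULL,
                               costs = cost_params(),
                               control = vom_control()) {
  if (is.null(forcing)) forcing <- scenario_forcing(scenario)
  site <- scenario$site
  function(x) {
    p <- as_long_term(x)
    simulate_vom(forcing, scenario$c_a, site$soil, site$geometry, p,
                 costs = costs, control = control,
                 keep_logs = FALSE)$ncp
  }
}

#' Long-term adaptation run
#'
#' SCE maximization of NCP over the six community parameters at the
#' scenario's CO2 level, followed by a logged simulation with the incumbent
#' and a summary over the last years.
#'
#' @param scenario a [scenario_spec()] with `mode = "long"`.
#' @param sce an [sce_config()]; its `transform` is overridden by the
#'   rooting-depth grid snap.
#' @param costs,control cost coefficients and numerical control.
#' @param last_n_years summary window (years).
#' @param seed_params optional [long_term_params()] injected into the
#'   initial SCE population (used by the experiment protocol to guarantee
#'   long-term dominance over the medium-term scenario).
#' @return list with `params` (the incumbent as [long_term_params()]),
#'   `ncp`, `summary`, `sim` (logged simulation) and `sce` (optimizer
#'   output).
#' @export
run_long_term <- function(scenario, sce = sce_config(max_evaluations = 250),
                          costs = cost_params(), control = vom_control(),
                          last_n_years = 2, seed_params = NULL) {
  stopifnot(scenario$mode == "long")
  forcing <- scenario_forcing(scenario)
  obj <- scenario_objective(scenario, forcing, costs, control)
  b <- long_term_bounds(scenario$site$geometry)
  sce$transform <- function(x) { x[2] <- round(x[2] * 2) / 2; x }
  # a neutral mid-range starting point is always injected; when an incumbent
  # from a previous optimization is supplied it is injected as well, which
  # guarantees the long-term >= medium-term NCP dominance by construction
  neutral <- c(0.3, 1.5, 500, -0.5, 500, -0.5)
  init <- rbind(neutral,
                if (!is.null(seed_params))
                  unlist(seed_params[c("m_a_p", "y_r_p", "c_lambda_f_p",
                                       "c_lambda_e_p", "c_lambda_f_s",
                                       "c_lambda_e_s")]))
  opt <- sce_maximize(obj, b$lower, b$upper, config = sce, init = init)
  best <- as_long_term(sce$transform(opt$best_par))
  sim <- simulate_vom(forcing, scenario$c_a, scenario$site$soil,
                      scenario$site$geometry, best, costs = costs,
                      control = control, keep_logs = TRUE)
  list(params = best, ncp = sim$ncp,
       summary = summarize_run(sim, last_n_years = last_n_years),
       sim = sim, sce = opt)
}

#' Medium-term response run
#'
#' Re-runs a scenario at a new CO2 level with the six community constants
#' frozen at the supplied values; only the daily and hourly vegetation
#' properties adapt.
#'
#' @param scenario a [scenario_spec()] with `mode = "medium"` and
#'   `frozen_params` set.
#' @param costs,control cost coefficients and numerical control.
#' @param last_n_years summary window (years).
#' @return list with `params` (the frozen constants), `ncp`, `summary` and
#'   `sim`.
#' @export
run_medium_term <- function(scenario, costs = cost_params(),
                            control = vom_control(), last_n_years = 2) {
  stopifnot(scenario$mode == "medium")
  if (is.null(scenario$frozen_params))
    stop("configuration error: medium-term mode requires frozen_params")
  forcing <- scenario_forcing(scenario)
  sim <- simulate_vom(forcing, scenario$c_a, scenario$site$soil,
                      scenario$site$geometry, scenario$frozen_params,
                      costs = costs, control = control, keep_logs = TRUE)
  list(params = scenario$frozen_params, ncp = sim$ncp,
       summary = summarize_run(sim, last_n_years = last_n_years), sim = sim)
}

#' Summary table over the last years of a simulation
#'
#' Annual water fluxes, big-leaf conductances, covers, assimilation,
#' water-use efficiencies, capacities, marginal water cost medians, root
#' area indices and soil saturation statistics over the final
#' `last_n_years` of a logged simulation. Marginal water costs are
#' summarized as medians, everything else as means. The water-balance
#' identity `P = Q + E_T + dStorage` is reported explicitly.
#'
#' @param sim a logged result of [simulate_vom()].
#' @param last_n_years length of the averaging window (years).
#' @return one-row data.frame (class `summary_table`).
#' @export
summarize_run <- function(sim, last_n_years = 5) {
  if (is.null(sim$hourly))
    stop("simulation was run without logs; re-run with keep_logs = TRUE")
  h <- sim$hourly; d <- sim$daily
  n_years_total <- nrow(h) / (24 * 365)
  if (last_n_years > n_years_total + 1e-9)
    stop("summary window longer than the simulation")
  hw <- h[h$t > nrow(h) - last_n_years * 365 * 24, ]
  dw <- d[d$day > nrow(d) - last_n_years * 365, ]
  yr <- last_n_years
  mol_per_mm <- 1 / 0.018  # mol H2O per mm of water depth (per m2)

  day_p <- hw$I_a > 0 & hw$g_s_p > 1e-8
  day_s <- hw$I_a > 0 & hw$g_s_s > 1e-8
  et_p <- sum(hw$E_t_p); et_s <- sum(hw$E_t_s)
  # daily ground-area assimilation per component (mol d-1): per-leaf flux
  # times the day's cover, accumulated from the hourly log
  ma_p <- dw$M_A_p[1]
  ag_p_h <- hw$A_g_p * 1e-6 * 3600 * ma_p
  ma_s_h <- rep(dw$M_A_s, each = 24)[seq_len(nrow(hw))]
  ag_s_h <- hw$A_g_s * 1e-6 * 3600 * ma_s_h
  q_total <- sum(hw$drainage) + sum(hw$runoff)
  p_total <- sum(hw$rain)
  e_t <- et_p + et_s + sum(hw$E_s)
  # storage is logged after each step; reconstruct the pre-step storage of
  # the first window hour from that hour's budget (dS = P - runoff - Q -
  # E_s - E_t for the hour) so the window balance closes exactly
  stor_first_pre <- hw$storage[1] - (hw$rain[1] - hw$runoff[1] -
    hw$drainage[1] - hw$E_s[1] - hw$E_t_p[1] - hw$E_t_s[1])
  dstor <- hw$storage[nrow(hw)] - stor_first_pre

  out <- data.frame(
    P = p_total / yr,
    Q = q_total / yr,
    E_T = e_t / yr,
    E_t_p = et_p / yr,
    E_t_s = et_s / yr,
    E_s = sum(hw$E_s) / yr,
    G_s_p = if (any(day_p)) mean(hw$g_s_p[day_p]) * 1000 else 0,
    G_s_s = if (any(day_s)) mean(hw$g_s_s[day_s]) * 1000 else 0,
    M_A_p = ma_p,
    M_A_s = mean(dw$M_A_s),
    A_g_p = mean(tapply(ag_p_h, rep(seq_len(nrow(hw) / 24), each = 24),
                        sum)) * 1000,
    A_g_s = mean(tapply(ag_s_h, rep(seq_len(nrow(hw) / 24), each = 24),
                        sum)) * 1000,
    WUE_p = if (et_p > 0) sum(ag_p_h) / (et_p * mol_per_mm) * 1000 else NA,
    WUE_s = if (et_s > 0) sum(ag_s_h) / (et_s * mol_per_mm) * 1000 else NA,
    iWUE_p = if (any(day_p)) mean(hw$A_g_p[day_p] / hw$g_s_p[day_p]) else NA,
    iWUE_s = if (any(day_s)) mean(hw$A_g_s[day_s] / hw$g_s_s[day_s]) else NA,
    J_max25_p = mean(dw$J_max25_p),
    J_max25_s = mean(dw$J_max25_s),
    lambda_p_median = median(dw$lambda_p),
    lambda_s_median = median(dw$lambda_s),
    RAI_p = mean(dw$RAI_p),
    RAI_s = mean(dw$RAI_s),
    Theta_1 = mean(hw$Theta_1),
    Av_Theta = mean(hw$Av_Theta),
    dStorage = dstor / yr,
    balance_residual = (p_total - q_total - e_t - dstor) / yr)
  class(out) <- c("summary_table", class(out))
  out
}

#' Relative CO2 sensitivity
#'
#' Relative change of a variable per relative change in CO2:
#' `(v_new/v_ref - 1) / (C_a_new/C_a_ref - 1)`. A sensitivity of 0.7 under
#' a 20 % CO2 increase means a 14 % response.
#'
#' @param v_ref,v_new variable at the reference and new CO2 level.
#' @param c_a_ref,c_a_new the two CO2 levels (ppm).
#' @return dimensionless sensitivity; `NA` when the reference value is 0.
#' @export
relative_sensitivity <- function(v_ref, v_new, c_a_ref, c_a_new) {
  if (c_a_ref == 0 || c_a_new == c_a_ref)
    stop("undefined: need c_a_ref != 0 and c_a_new != c_a_ref")
  ifelse(v_ref == 0, NA_real_,
         (v_new / v_ref - 1) / (c_a_new / c_a_ref - 1))
}

#' Full elevated-CO2 experiment on one site
#'
#' Runs the protocol: long-term adaptation at each CO2 level (the SCE
#' population at elevated CO2 is seeded with the baseline incumbent so
#' long-term NCP dominates the medium-term NCP by construction), plus
#' medium-term runs at the elevated levels with the baseline constants
#' frozen.
#'
#' @param site a [synthetic_site()].
#' @param ca_levels CO2 levels (ppm); the first is the baseline.
#' @param n_years forcing years per run.
#' @param sce an [sce_config()].
#' @param costs,control cost coefficients and numerical control.
#' @param last_n_years summary window.
#' @param rng_seed seed shared by all runs (identical forcing).
#' @return list with `long` and `medium` (named by CO2 level), the
#'   `baseline_params`, and `sensitivities` (long + medium, computed with
#'   [relative_sensitivity()] between the first and last CO2 level).
#' @export
run_co2_experiment <- function(site, ca_levels = c(317, 350, 380),
                               n_years = 6,
                               sce = sce_config(max_evaluations = 250),
                               costs = cost_params(),
                               control = vom_control(),
                               last_n_years = 2, rng_seed = 1L) {
  stopifnot(length(ca_levels) >= 2)
  base_ca <- ca_levels[1]
  long <- list(); medium <- list()
  sc0 <- scenario_spec(site, base_ca, "long", n_years = n_years,
                       rng_seed = rng_seed)
  long[[as.character(base_ca)]] <-
    run_long_term(sc0, sce = sce, costs = costs, control = control,
                  last_n_years = last_n_years)
  frozen <- long[[as.character(base_ca)]]$params
  medium[[as.character(base_ca)]] <- long[[as.character(base_ca)]]
  for (ca in ca_levels[-1]) {
    scl <- scenario_spec(site, ca, "long", n_years = n_years,
                         rng_seed = rng_seed)
    long[[as.character(ca)]] <-
      run_long_term(scl, sce = sce, costs = costs, control = control,
                    last_n_years = last_n_years, seed_params = frozen)
    scm <- scenario_spec(site, ca, "medium", frozen_params = frozen,
                         n_years = n_years, rng_seed = rng_seed)
    medium[[as.character(ca)]] <-
      run_medium_term(scm, costs = costs, control = control,
                      last_n_years = last_n_years)
  }
  ca_hi <- ca_levels[length(ca_levels)]
  sens <- function(runs) {
    force(runs)
    s0 <- runs[[as.character(base_ca)]]$summary
    s1 <- runs[[as.character(ca_hi)]]$summary
    vars <- names(s0)[!names(s0) %in% c("dStorage", "balance_residual")]
    setNames(vapply(vars, function(v)
      relative_sensitivity(s0[[v]], s1[[v]], base_ca, ca_hi), numeric(1)),
      vars)
  }
  list(long = long, medium = medium, baseline_params = frozen,
       sensitivities = list(long = sens(long), medium = sens(medium)))
}

#' Experiment report table
#'
#' Formats an experiment result in the conventional layout: absolute values
#' at the baseline CO2 level, percent deviations from the baseline at every
#' higher level, separately for the medium-term and long-term modes.
#'
#' @param ex result of [run_co2_experiment()].
#' @return data.frame with one row per summary variable.
#' @export
experiment_table <- function(ex) {
  cas <- names(ex$long)
  base <- cas[1]
  s0 <- ex$long[[base]]$summary
  vars <- names(s0)[!names(s0) %in% c("dStorage", "balance_residual")]
  out <- data.frame(variable = vars,
                    baseline = unlist(s0[1, vars], use.names = FALSE))
  for (ca in cas[-1]) {
    for (mode in c("medium", "long")) {
      s1 <- ex[[mode]][[ca]]$summary
      dev <- 100 * (unlist(s1[1, vars], use.names = FALSE) / out$baseline - 1)
      out[[paste0(mode, "_", ca, "_pct")]] <- round(dev, 1)
    }
  }
  names(out)[2] <- paste0("value_", base)
  out
}
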