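## Simulation driver: wraps the compiled hourly engine. One call runs the
## coupled soil-water / canopy / daily-dynamics model over an hourly forcing
## table for fixed long-term parameters.

#' Numerical and physiological control parameters
#'
#' Collects every tunable coefficient of the simulator in one place, with
#' units and defaults. None of these are fitted to any site in this package.
#'
#' @param alpha_q quantum yield of electron transport (mol e- per mol
#'   quanta).
#' @param gamma_star CO2 compensation point without dark respiration (ppm);
#'   held temperature-independent by default for testability.
#' @param t_opt,sigma_t optimum and width (degC) of the electron-transport
#'   temperature response.
#' @param g_max upper bound on stomatal conductance (mol m-2 s-1).
#' @param psi_min minimum root-collar total head (m; ~ -1.5 MPa).
#' @param c_soil soil-to-root geometry factor of the radial pathway (-).
#' @param r_root radial root resistance per unit root area (m head per
#'   (m s-1) flux).
#' @param c_es soil evaporation efficiency (fraction of the radiative
#'   potential).
#' @param c_drain drainage closure coefficient (-).
#' @param lambda_max cap on the marginal water cost (mol mol-1).
#' @param adjust_step daily multiplicative hill-climbing step (relative).
#' @param probe_step relative finite-difference probe for marginal NCP.
#' @param j_floor,j_cap,ma_floor,sar_floor,sar_cap clipping bounds of the
#'   dynamic vegetation variables.
#' @param dtheta_max sub-step limiter: max water-content change per substep
#'   as a fraction of `theta_s - theta_r`.
#' @param substep_max maximum substeps per hour.
#' @return object of class `vom_control`.
#' @export
vom_control <- function(alpha_q = 0.3, gamma_star = 40, t_opt = 30,
                        sigma_t = 12, g_max = 10, psi_min = -150,
                        c_soil = 0.01, r_root = 1e7, c_es = 0.35,
                        c_drain = 1, lambda_max = 1e5,
                        adjust_step = 0.1, probe_step = 0.05,
                        j_floor = 5, j_cap = 2000, ma_floor = 0.01,
                        sar_floor = 0.01, sar_cap = 50,
                        dtheta_max = 0.1, substep_max = 5000L) {
  structure(as.list(environment()), class = "vom_control")
}

#' Long-term vegetation parameters
#'
#' The six community-scale constants optimized by SCE: perennial cover,
#' perennial rooting depth and the two water-use functions.
#'
#' @param m_a_p perennial big-leaf cover in `[0, 1]`.
#' @param y_r_p perennial maximum rooting depth (m, snapped to the 0.5 m
#'   layer grid).
#' @param c_lambda_f_p,c_lambda_e_p,c_lambda_f_s,c_lambda_e_s water-use
#'   function factors/exponents (perennial, seasonal).
#' @return object of class `long_term_params`.
#' @export
long_term_params <- function(m_a_p, y_r_p, c_lambda_f_p, c_lambda_e_p,
                             c_lambda_f_s, c_lambda_e_s) {
  if (m_a_p < 0 || m_a_p > 1) stop("m_a_p must lie in [0, 1]")
  if (y_r_p < 0.5) stop("y_r_p must be at least one layer (0.5 m)")
  y_r_p <- round(y_r_p * 2) / 2
  structure(list(m_a_p = m_a_p, y_r_p = y_r_p,
                 c_lambda_f_p = c_lambda_f_p, c_lambda_e_p = c_lambda_e_p,
                 c_lambda_f_s = c_lambda_f_s, c_lambda_e_s = c_lambda_e_s),
            class = "long_term_params")
}

hourly_log_names <- c("t", "I_a", "T_a", "D_v", "rain", "infiltration",
                      "runoff", "drainage", "E_s", "E_t_p", "E_t_s",
                      "g_s_p", "g_s_s", "C_i_p", "C_i_s", "A_g_p", "A_g_s",
                      "lambda_p", "lambda_s", "supply_p", "supply_s",
                      "Theta_1", "Av_Theta", "storage")
daily_log_names <- c("day", "J_max25_p", "J_max25_s", "M_A_p", "M_A_s",
                     "y_r_p", "RAI_p", "RAI_s", "A_g_total", "R_foliage",
                     "R_roots", "R_wood", "NCP_day", "lambda_p", "lambda_s")

#' Run the coupled simulation
#'
#' Advances the multi-layer soil water balance and two-big-leaf canopy hour
#' by hour; at each midnight the marginal water costs are recomputed from
#' the root-zone suction profile and the dynamic vegetation properties take
#' one hill-climbing step on yesterday's marginal NCP (soil trajectory
#' frozen during the probes).
#'
#' @param forcing hourly forcing data.frame from [make_hourly_forcing()]
#'   (columns `I_a`, `I_g`, `T_a`, `D_v`, `rain`); length a multiple of 24.
#' @param c_a atmospheric CO2 mole fraction (ppm).
#' @param soil,geom soil parameters and catchment geometry.
#' @param params a [long_term_params()].
#' @param costs a [cost_params()].
#' @param control a [vom_control()].
#' @param init list of initial values: `theta` (per-layer, defaults to
#'   hydrostatic equilibrium with the water table at the channel),
#'   `jmax25_p`, `jmax25_s`, `ma_s`, `sar`.
#' @param keep_logs keep full hourly/daily logs (set `FALSE` inside
#'   optimization loops).
#' @return list with `totals` (water/carbon budget), `daily` and `hourly`
#'   data.frames, `theta_final` and `ncp` (mol C m-2 ground).
#' @export
simulate_vom <- function(forcing, c_a, soil, geom, params,
                         costs = cost_params(), control = vom_control(),
                         init = list(), keep_logs = TRUE) {
  stopifnot(nrow(forcing) %% 24 == 0)
  if (params$y_r_p > geom$z_surface)
    stop("rooting depth exceeds soil depth")
  defaults <- list(
    theta = soil_state(soil, geom)$theta,
    jmax25_p = 150, jmax25_s = 150, ma_s = 0.2, sar = 0.3)
  init <- utils::modifyList(defaults, init)
  fm <- as.matrix(forcing[, c("I_a", "I_g", "T_a", "D_v", "rain")])
  res <- simulate_vom_cpp(fm, c_a,
                          c(soil$theta_r, soil$theta_s, soil$alpha_vg,
                            soil$n_vg, soil$k_sat),
                          c(geom$z_surface, geom$z_channel, geom$gamma0_deg,
                            geom$layer_thickness, geom$catchment_length_m),
                          c(params$m_a_p, params$y_r_p, params$c_lambda_f_p,
                            params$c_lambda_e_p, params$c_lambda_f_s,
                            params$c_lambda_e_s),
                          c(costs$foliage_cost_coeff,
                            costs$photosynthetic_capacity_cost_coeff,
                            costs$root_cost_coeff, costs$wood_cost_coeff,
                            costs$wood_depth_coeff,
                            costs$capacity_cost_exponent),
                          unclass(control), init, keep_logs)
  daily <- as.data.frame(res$daily)
  names(daily) <- daily_log_names
  out <- list(totals = res$totals, daily = daily,
              theta_final = res$theta_final, ncp = res$ncp,
              c_a = c_a, params = params)
  if (keep_logs) {
    hourly <- as.data.frame(res$hourly)
    names(hourly) <- hourly_log_names
    out$hourly <- hourly
  }
  out
}
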