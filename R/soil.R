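## Soil hydraulics and the multi-layer water balance of a rectangular soil
## block over impermeable bedrock. Retention/conductivity follow van
## Genuchten (1980) / Mualem; lateral drainage is a Dupuit-Forchheimer
## closure on the water table height above the channel.

#' Soil hydraulic parameter set
#'
#' @param theta_r residual volumetric water content.
#' @param theta_s saturated volumetric water content.
#' @param alpha_vg inverse of air-entry suction (m-1).
#' @param n_vg pore-size distribution measure (> 1).
#' @param k_sat saturated hydraulic conductivity (m s-1).
#' @return object of class `soil_params`.
#' @export
soil_params <- function(theta_r, theta_s, alpha_vg, n_vg, k_sat) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("invalid soil: need 0 <= theta_r < theta_s <= 1")
  if (n_vg <= 1) stop("invalid soil: n_vg must exceed 1")
  if (alpha_vg <= 0 || k_sat <= 0)
    stop("invalid soil: alpha_vg and k_sat must be positive")
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha_vg = alpha_vg,
                 n_vg = n_vg, m_vg = 1 - 1 / n_vg, k_sat = k_sat),
            class = "soil_params")
}

#' Named soil texture presets
#'
#' Van Genuchten parameter sets for the three textures used by the site
#' presets (sandy loam, loam, sandy clay loam).
#'
#' @param name one of `"sandy_loam"`, `"loam"`, `"sandy_clay_loam"`.
#' @return a [soil_params()] object.
#' @export
soil_preset <- function(name = c("sandy_loam", "loam", "sandy_clay_loam")) {
  name <- match.arg(name)
  switch(name,
    sandy_loam      = soil_params(0.065, 0.41, 7.5, 1.89, 1.228e-5),
    loam            = soil_params(0.078, 0.43, 3.6, 1.56, 2.889e-6),
    sandy_clay_loam = soil_params(0.100, 0.39, 5.9, 1.48, 3.639e-6))
}

#' Catchment geometry of the rectangular soil block
#'
#' @param z_surface soil surface elevation above bedrock (m); must be a
#'   multiple of `layer_thickness`.
#' @param z_channel drainage channel elevation above bedrock (m).
#' @param gamma0_deg slope angle near the drainage channel (degrees).
#' @param layer_thickness soil layer thickness (m), default 0.5.
#' @param catchment_length_m effective lateral drainage length scale (m).
#' @return object of class `catchment_geometry` with an `n_layers` field.
#' @export
catchment_geometry <- function(z_surface, z_channel, gamma0_deg,
                               layer_thickness = 0.5,
                               catchment_length_m = 100) {
  if (!(z_surface > z_channel && z_channel >= 0))
    stop("invalid geometry: need z_surface > z_channel >= 0")
  if (!(gamma0_deg > 0 && gamma0_deg < 90))
    stop("invalid geometry: slope angle out of (0, 90)")
  n <- z_surface / layer_thickness
  if (abs(n - round(n)) > 1e-9)
    stop("invalid geometry: z_surface must be a multiple of layer_thickness")
  structure(list(z_surface = z_surface, z_channel = z_channel,
                 gamma0_deg = gamma0_deg, layer_thickness = layer_thickness,
                 catchment_length_m = catchment_length_m,
                 n_layers = as.integer(round(n))),
            class = "catchment_geometry")
}

#' Site presets (catchment structure + soil texture)
#'
#' Four named site parameterisations spanning a water-limited to
#' energy-limited gradient: `"VIR"` and `"HS"` (sandy loam, 15 m column),
#' `"TUM"` (loam, 30 m) and `"CT"` (sandy clay loam, 15 m).
#'
#' @param name site code.
#' @return list with elements `soil` and `geometry`.
#' @export
site_preset <- function(name = c("VIR", "HS", "TUM", "CT")) {
  name <- match.arg(name)
  switch(name,
    VIR = list(soil = soil_preset("sandy_loam"),
               geometry = catchment_geometry(15, 5, 2)),
    HS  = list(soil = soil_preset("sandy_loam"),
               geometry = catchment_geometry(15, 10, 2)),
    TUM = list(soil = soil_preset("loam"),
               geometry = catchment_geometry(30, 5, 11.5)),
    CT  = list(soil = soil_preset("sandy_clay_loam"),
               geometry = catchment_geometry(15, 5, 2)))
}

#' Effective saturation from matric suction head (van Genuchten retention)
#'
#' `Theta = (1 + (alpha h)^n)^(-m)` with `m = 1 - 1/n`.
#'
#' @param h matric suction head (m, >= 0); vectorised.
#' @param soil a [soil_params()] object.
#' @return effective saturation in `(0, 1]`.
#' @export
vg_saturation <- function(h, soil) {
  if (any(h < 0)) stop("domain error: suction head must be non-negative")
  (1 + (soil$alpha_vg * h)^soil$n_vg)^(-soil$m_vg)
}

#' Matric suction head from effective saturation (closed-form inverse)
#'
#' @param se effective saturation in `(0, 1]`.
#' @param soil a [soil_params()] object.
#' @return suction head (m), capped at 1e4 m for numerical safety.
#' @export
vg_suction <- function(se, soil) {
  se <- pmin(pmax(se, 1e-9), 1)
  h <- ifelse(se >= 1, 0,
              (se^(-1 / soil$m_vg) - 1)^(1 / soil$n_vg) / soil$alpha_vg)
  pmin(h, 1e4)
}

#' Unsaturated hydraulic conductivity (Mualem)
#'
#' `K = K_sat Theta^0.5 (1 - (1 - Theta^(1/m))^m)^2`.
#'
#' @param se effective saturation in `[0, 1]`; vectorised.
#' @param soil a [soil_params()] object.
#' @return conductivity (m s-1) in `[0, K_sat]`.
#' @export
vg_conductivity <- function(se, soil) {
  if (any(se < 0 | se > 1))
    stop("domain error: effective saturation must lie in [0, 1]")
  t <- 1 - (1 - se^(1 / soil$m_vg))^soil$m_vg
  soil$k_sat * sqrt(se) * t^2
}

# contiguous saturated thickness above bedrock (m)
water_table_elevation <- function(theta, soil, geom) {
  se <- (theta - soil$theta_r) / (soil$theta_s - soil$theta_r)
  nsat <- 0L
  for (i in rev(seq_along(theta))) {
    if (se[i] >= 0.9999) nsat <- nsat + 1L else break
  }
  nsat * geom$layer_thickness
}

#' Soil column state
#'
#' Constructs a consistent soil column state (per-layer water content and
#' suction head plus water-table elevation). By default the column is in
#' hydrostatic equilibrium with a water table at `water_table` metres above
#' bedrock.
#'
#' @param soil a [soil_params()] object.
#' @param geom a [catchment_geometry()] object.
#' @param water_table initial water-table elevation above bedrock (m);
#'   defaults to the channel elevation.
#' @param theta optional explicit per-layer water content vector (top first);
#'   overrides `water_table`.
#' @return object of class `soil_state` with fields `theta`, `h`, `z_w`.
#' @export
soil_state <- function(soil, geom, water_table = geom$z_channel, theta = NULL) {
  n <- geom$n_layers
  dz <- geom$layer_thickness
  if (is.null(theta)) {
    zc <- geom$z_surface - (seq_len(n) - 0.5) * dz
    h_eq <- pmax(0, zc - water_table)
    se <- vg_saturation(h_eq, soil)
    theta <- soil$theta_r + se * (soil$theta_s - soil$theta_r)
  } else {
    if (length(theta) != n) stop("theta must have one value per layer")
    if (any(theta < soil$theta_r - 1e-12 | theta > soil$theta_s + 1e-12))
      stop("theta outside [theta_r, theta_s]")
    theta <- pmin(pmax(theta, soil$theta_r), soil$theta_s)
  }
  se <- pmin(pmax((theta - soil$theta_r) / (soil$theta_s - soil$theta_r),
                  1e-9), 1)
  structure(list(theta = theta, h = vg_suction(se, soil),
                 z_w = water_table_elevation(theta, soil, geom)),
            class = "soil_state")
}

#' Total column storage (mm)
#'
#' @param state a [soil_state()].
#' @param geom the matching [catchment_geometry()].
#' @export
soil_storage_mm <- function(state, geom) {
  sum(state$theta) * geom$layer_thickness * 1000
}

#' Advance the soil water balance by one step
#'
#' Explicit, adaptively sub-stepped Darcy fluxes between 0.5 m layers
#' (arithmetic-mean conductivity, total-head gradient), infiltration-excess
#' and saturation-excess runoff, Dupuit lateral drainage and prescribed
#' sinks (root uptake per layer, soil evaporation). Sinks are capped so no
#' layer is driven below residual water content; any shortfall is reported,
#' never negative storage.
#'
#' @param state a [soil_state()].
#' @param soil,geom soil parameters and geometry.
#' @param rain_mm_h rainfall arrival rate (mm per hour).
#' @param uptake_p_mm_h,uptake_s_mm_h per-layer root extraction demand
#'   (mm per hour) for the perennial and seasonal components; default zero.
#' @param e_s_mm_h soil evaporation demand from the top layer (mm per hour).
#' @param dt_h step length (hours).
#' @param control list of numerical coefficients, see [vom_control()];
#'   entries `c_drain`, `dtheta_max`, `substep_max` are used here.
#' @return list with the new `state`, realized fluxes in mm (`infiltration`,
#'   `runoff`, `drainage`, `soil_evap`, `uptake_p`, `uptake_s` per layer),
#'   `shortfall` (mm of unmet sink demand) and `substeps`.
#' @export
step_soil_water <- function(state, soil, geom, rain_mm_h = 0,
                            uptake_p_mm_h = NULL, uptake_s_mm_h = NULL,
                            e_s_mm_h = 0, dt_h = 1, control = vom_control()) {
  n <- geom$n_layers
  if (is.null(uptake_p_mm_h)) uptake_p_mm_h <- numeric(n)
  if (is.null(uptake_s_mm_h)) uptake_s_mm_h <- numeric(n)
  stopifnot(dt_h > 0, length(uptake_p_mm_h) == n, length(uptake_s_mm_h) == n)
  if (rain_mm_h < 0 || e_s_mm_h < 0 || any(uptake_p_mm_h < 0) ||
      any(uptake_s_mm_h < 0))
    stop("sinks and rain must be non-negative")
  res <- soil_step_cpp(state$theta,
                       c(soil$theta_r, soil$theta_s, soil$alpha_vg,
                         soil$n_vg, soil$k_sat),
                       c(geom$z_surface, geom$z_channel, geom$gamma0_deg,
                         geom$layer_thickness, geom$catchment_length_m),
                       rain_mm_h, uptake_p_mm_h, uptake_s_mm_h, e_s_mm_h,
                       dt_h, control$c_drain, control$dtheta_max,
                       control$substep_max)
  new_state <- soil_state(soil, geom, theta = res$theta)
  list(state = new_state,
       infiltration = res$infiltration_mm,
       runoff = res$runoff_mm,
       drainage = res$drainage_mm,
       soil_evap = res$soil_evap_mm,
       uptake_p = res$uptake_p_mm,
       uptake_s = res$uptake_s_mm,
       shortfall = res$shortfall_mm,
       substeps = res$substeps)
}

#' Lateral drainage flux from the saturated zone
#'
#' Dupuit-Forchheimer outflow per unit catchment area, proportional to the
#' saturated conductivity, the sine of the channel-side slope angle and the
#' water-table height above the channel, scaled by the catchment length.
#'
#' @param state a [soil_state()] (only `z_w` is used).
#' @param geom a [catchment_geometry()].
#' @param soil a [soil_params()].
#' @param control numerical coefficients ([vom_control()]; `c_drain`).
#' @return drainage (mm per hour per unit catchment area).
#' @export
drainage_flux <- function(state, geom, soil, control = vom_control()) {
  head <- max(0, state$z_w - geom$z_channel)
  control$c_drain * soil$k_sat * sin(geom$gamma0_deg * pi / 180) * head /
    geom$catchment_length_m * 3.6e6
}

#' Soil evaporation
#'
#' Radiation-driven potential rate scaled by the unshaded ground fraction and
#' the top-layer effective saturation:
#' `E_s = (1 - FPC) * Theta_1 * c_es * I_g / lambda_E`.
#'
#' @param state a [soil_state()].
#' @param forcing one hourly forcing record (needs `I_g` in W m-2, or `I_a`
#'   from which irradiance is recovered).
#' @param total_fpc combined big-leaf cover in `[0, 1]`.
#' @param soil a [soil_params()].
#' @param control numerical coefficients (`c_es`).
#' @return soil evaporation (mm per hour).
#' @export
soil_evaporation <- function(state, forcing, total_fpc, soil,
                             control = vom_control()) {
  if (total_fpc < 0 || total_fpc > 1) stop("total_fpc must lie in [0, 1]")
  ig <- if (!is.null(forcing$I_g)) forcing$I_g else forcing$I_a / 4.57e-6
  se1 <- (state$theta[1] - soil$theta_r) / (soil$theta_s - soil$theta_r)
  (1 - total_fpc) * se1 * control$c_es * ig / 2.45e9 * 3.6e6
}
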