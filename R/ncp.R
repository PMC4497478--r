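## Net Carbon Profit accounting and day-by-day dynamic optimization of the
## fast vegetation properties (photosynthetic capacities, seasonal cover,
## per-layer fine-root surface areas) by single-step hill climbing on
## finite-difference marginal NCP.

#' Carbon cost coefficients
#'
#' Maintenance/turnover respiration coefficients. Defaults are
#' order-of-magnitude values chosen for a functioning carbon economy; they
#' are configuration, not measurements, and every test in this package is
#' invariant- or oracle-based rather than dependent on their specific values.
#'
#' @param foliage_cost_coeff respiration+turnover per unit big-leaf cover
#'   (mol C m-2 ground d-1 per unit M_A).
#' @param photosynthetic_capacity_cost_coeff respiration per unit
#'   `J_max25 ^ capacity_cost_exponent` per unit cover (mol C m-2 d-1 per
#'   (umol m-2 s-1)^exponent).
#' @param capacity_cost_exponent exponent of the capacity cost in
#'   `J_max25`. The default 2 makes the marginal cost of photosynthetic
#'   capacity increase with capacity, which keeps the day-to-day capacity
#'   optimum weakly sensitive to CO2 (a few percent per 20 % CO2, as
#'   observed for canopy-scale acclimation); 1 recovers a cost linear in
#'   `J_max25`.
#' @param root_cost_coeff respiration+turnover per unit fine-root surface
#'   area (mol C m-2 root d-1).
#' @param wood_cost_coeff cost per unit perennial cover (mol C m-2 d-1).
#' @param wood_depth_coeff relative increase of the wood cost per metre of
#'   perennial rooting depth (m-1).
#' @return object of class `cost_params`.
#' @export
cost_params <- function(foliage_cost_coeff = 0.06,
                        photosynthetic_capacity_cost_coeff = 6e-7,
                        root_cost_coeff = 0.06,
                        wood_cost_coeff = 0.04,
                        wood_depth_coeff = 0.2,
                        capacity_cost_exponent = 2) {
  x <- list(foliage_cost_coeff = foliage_cost_coeff,
            photosynthetic_capacity_cost_coeff = photosynthetic_capacity_cost_coeff,
            root_cost_coeff = root_cost_coeff,
            wood_cost_coeff = wood_cost_coeff,
            wood_depth_coeff = wood_depth_coeff,
            capacity_cost_exponent = capacity_cost_exponent)
  if (any(unlist(x) < 0)) stop("cost coefficients must be non-negative")
  structure(x, class = "cost_params")
}

#' Day-varying vegetation state
#'
#' @param j_max25_p,j_max25_s electron transport capacities at 25 degC
#'   (umol m-2 s-1).
#' @param m_a_s seasonal big-leaf cover.
#' @param s_ar_p,s_ar_s per-layer fine-root surface areas (m2 m-3).
#' @param m_a_p perennial cover (constant; kept here for the cover
#'   constraint).
#' @return object of class `daily_state`.
#' @export
daily_state <- function(j_max25_p, j_max25_s, m_a_s, s_ar_p, s_ar_s,
                        m_a_p = 0) {
  if (m_a_s + m_a_p > 1 + 1e-12)
    stop("invariant error: M_A,s + M_A,p must not exceed 1")
  if (any(c(j_max25_p, j_max25_s, m_a_s, s_ar_p, s_ar_s) < 0))
    stop("daily state entries must be non-negative")
  structure(list(j_max25_p = j_max25_p, j_max25_s = j_max25_s,
                 m_a_s = m_a_s, s_ar_p = s_ar_p, s_ar_s = s_ar_s,
                 m_a_p = m_a_p),
            class = "daily_state")
}

#' Daily maintenance and turnover costs
#'
#' Foliage cost is linear in cover and in capacity-weighted cover; root cost
#' is linear in total fine-root area; wood cost is linear in perennial cover
#' with a rooting-depth surcharge.
#'
#' @param state a [daily_state()].
#' @param y_r_p perennial maximum rooting depth (m).
#' @param costs a [cost_params()].
#' @param layer_thickness soil layer thickness (m).
#' @return list with `R_foliage`, `R_roots`, `R_wood` (mol C m-2 ground d-1).
#' @export
daily_costs <- function(state, y_r_p, costs, layer_thickness = 0.5) {
  g <- costs$capacity_cost_exponent
  r_fol <- costs$foliage_cost_coeff * (state$m_a_p + state$m_a_s) +
    costs$photosynthetic_capacity_cost_coeff *
      (state$j_max25_p^g * state$m_a_p + state$j_max25_s^g * state$m_a_s)
  r_roots <- costs$root_cost_coeff * layer_thickness *
    (sum(state$s_ar_p) + sum(state$s_ar_s))
  r_wood <- costs$wood_cost_coeff * state$m_a_p *
    (1 + costs$wood_depth_coeff * y_r_p)
  list(R_foliage = r_fol, R_roots = r_roots, R_wood = r_wood)
}

#' Net Carbon Profit over a simulation
#'
#' `NCP = sum over days of (A_g_total - R_total)`; additive over any
#' partition of days.
#'
#' @param flux_log data.frame with columns `day` and `A_g_total`
#'   (mol C m-2 ground d-1).
#' @param cost_log data.frame with columns `day`, `R_foliage`, `R_roots`,
#'   `R_wood`.
#' @return total NCP (mol C m-2 ground).
#' @export
ncp_total <- function(flux_log, cost_log) {
  if (nrow(flux_log) != nrow(cost_log) ||
      any(flux_log$day != cost_log$day))
    stop("flux and cost logs are misaligned")
  sum(flux_log$A_g_total -
        (cost_log$R_foliage + cost_log$R_roots + cost_log$R_wood))
}

#' Finite-difference marginal NCP sensitivities
#'
#' Probes each dynamic variable with a relative step and evaluates the NCP
#' the previous day would have produced, via a caller-supplied replay
#' function (typically yesterday's environment with the soil trajectory
#' frozen).
#'
#' @param state a [daily_state()].
#' @param replay function `daily_state -> NCP` for the reference day.
#' @param probe relative probe step (0 gives all-zero sensitivities).
#' @return list of sensitivities: `j_max25_p`, `j_max25_s`, `m_a_s`,
#'   `s_ar_p` (vector), `s_ar_s` (vector); each is the NCP difference for
#'   its probe.
#' @export
marginal_ncp <- function(state, replay, probe = 0.05) {
  zero <- list(j_max25_p = 0, j_max25_s = 0, m_a_s = 0,
               s_ar_p = numeric(length(state$s_ar_p)),
               s_ar_s = numeric(length(state$s_ar_s)))
  if (probe == 0) return(zero)
  base <- replay(state)
  tweak <- function(field, i = NULL) {
    st <- unclass(state)
    if (is.null(i)) st[[field]] <- st[[field]] * (1 + probe)
    else st[[field]][i] <- st[[field]][i] * (1 + probe)
    if (field == "m_a_s")
      st$m_a_s <- min(st$m_a_s, max(0, 1 - st$m_a_p))
    replay(structure(st, class = "daily_state")) - base
  }
  out <- zero
  out$j_max25_p <- tweak("j_max25_p")
  out$j_max25_s <- tweak("j_max25_s")
  out$m_a_s <- tweak("m_a_s")
  for (i in seq_along(state$s_ar_p)) out$s_ar_p[i] <- tweak("s_ar_p", i)
  for (i in seq_along(state$s_ar_s)) out$s_ar_s[i] <- tweak("s_ar_s", i)
  out
}

#' One day of hill climbing on the dynamic vegetation properties
#'
#' Each variable takes one bounded multiplicative step in the direction of
#' positive marginal NCP; the seasonal cover is clipped to
#' `[floor, 1 - M_A,p]` and root areas to their configured band.
#'
#' @param state a [daily_state()].
#' @param gains sensitivities as returned by [marginal_ncp()].
#' @param step relative step size per day.
#' @param j_bounds,ma_floor,sar_bounds clipping bounds.
#' @return the adjusted [daily_state()].
#' @export
daily_adjust <- function(state, gains, step = 0.02,
                         j_bounds = c(5, 2000), ma_floor = 0.01,
                         sar_bounds = c(0.01, 50)) {
  mv <- function(x, g, lo, hi) {
    if (g == 0) return(x)             # zero gain: exact fixed point
    x <- if (g > 0) x * (1 + step) else x * (1 - step)
    min(max(x, lo), hi)
  }
  st <- unclass(state)
  st$j_max25_p <- mv(st$j_max25_p, gains$j_max25_p, j_bounds[1], j_bounds[2])
  st$j_max25_s <- mv(st$j_max25_s, gains$j_max25_s, j_bounds[1], j_bounds[2])
  ma_cap <- max(0, 1 - st$m_a_p)
  st$m_a_s <- mv(st$m_a_s, gains$m_a_s, min(ma_floor, ma_cap), ma_cap)
  for (i in seq_along(st$s_ar_p))
    st$s_ar_p[i] <- mv(st$s_ar_p[i], gains$s_ar_p[i],
                       sar_bounds[1], sar_bounds[2])
  for (i in seq_along(st$s_ar_s))
    st$s_ar_s[i] <- mv(st$s_ar_s[i], gains$s_ar_s[i],
                       sar_bounds[1], sar_bounds[2])
  structure(st, class = "daily_state")
}
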