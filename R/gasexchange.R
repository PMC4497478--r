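## Two-big-leaf canopy gas exchange, electron-transport limited, with
## Cowan-Farquhar optimal stomatal control: stomata hold the marginal water
## cost dEt/dAg at a prescribed lambda through the day. lambda itself is a
## daily function of root-zone matric suction.

#' Big-leaf configuration
#'
#' @param component `"perennial"` or `"seasonal"`.
#' @param m_a fractional ground cover of the big leaf in `[0, 1]`.
#' @param j_max25 electron transport capacity at 25 degC
#'   (umol m-2 s-1 per leaf area).
#' @param c_lambda_f,c_lambda_e factor and exponent of the water-use function
#'   relating lambda to root-zone suction.
#' @return object of class `big_leaf`.
#' @export
big_leaf <- function(component = c("perennial", "seasonal"), m_a, j_max25,
                     c_lambda_f = 500, c_lambda_e = -0.5) {
  component <- match.arg(component)
  if (m_a < 0 || m_a > 1) stop("fractional cover must lie in [0, 1]")
  if (j_max25 <= 0) stop("j_max25 must be positive")
  structure(list(component = component, m_a = m_a, j_max25 = j_max25,
                 c_lambda_f = c_lambda_f, c_lambda_e = c_lambda_e),
            class = "big_leaf")
}

#' Electron transport rate (light response)
#'
#' Rectangular hyperbola with quantum yield `alpha_q`:
#' `J = alpha_q I J_max / (alpha_q I + J_max)`; saturates at `J_max` and
#' equals `J_max / 2` where `alpha_q I = J_max`.
#'
#' @param i_a PPFD (umol quanta m-2 s-1); vectorised.
#' @param j_max_t electron transport capacity at leaf temperature
#'   (umol m-2 s-1).
#' @param alpha_q quantum yield (mol electrons per mol quanta).
#' @return J (umol electrons m-2 s-1).
#' @export
electron_transport <- function(i_a, j_max_t, alpha_q = 0.3) {
  stopifnot(all(i_a >= 0), j_max_t > 0)
  alpha_q * i_a * j_max_t / (alpha_q * i_a + j_max_t)
}

#' Temperature response of electron transport capacity
#'
#' Gaussian response anchored so that the capacity at 25 degC equals
#' `j_max25` exactly, with a single maximum at `t_opt`.
#'
#' @param j_max25 capacity at 25 degC (umol m-2 s-1).
#' @param t_a air temperature (degC) in (-10, 60).
#' @param t_opt optimum temperature (degC).
#' @param sigma_t response width (degC).
#' @return capacity at `t_a` (umol m-2 s-1).
#' @export
jmax_at_temperature <- function(j_max25, t_a, t_opt = 30, sigma_t = 12) {
  if (any(t_a <= -10 | t_a >= 60))
    stop("domain error: temperature outside (-10, 60) degC")
  d <- (t_a - t_opt)^2 - (25 - t_opt)^2
  j_max25 * exp(-d / (2 * sigma_t^2))
}

#' Assimilation and leaf-internal CO2 at prescribed stomatal conductance
#'
#' Couples the diffusion law `A_g = g_s (C_a - C_i)` with the
#' electron-transport-limited demand `A_g = (J/4)(C_i - Gamma*)/(C_i + 2
#' Gamma*)` and returns the root of the resulting quadratic with
#' `Gamma* <= C_i <= C_a`.
#'
#' @param g_s stomatal conductance to CO2 (mol m-2 s-1 per leaf area).
#' @param env list with `C_a` and `Gamma_star` (ppm).
#' @param j electron transport rate (umol m-2 s-1).
#' @return list with `A_g` (umol m-2 s-1) and `C_i` (ppm).
#' @export
assimilation <- function(g_s, env, j) {
  if (g_s < 0) stop("g_s must be non-negative")
  ca <- env$C_a; gam <- env$Gamma_star
  a4 <- j / 4
  if (g_s == 0) return(list(A_g = 0, C_i = gam))
  if (a4 <= 0) return(list(A_g = 0, C_i = ca))
  b2 <- -(g_s * ca - 2 * gam * g_s - a4)
  c2 <- -(2 * gam * g_s * ca + a4 * gam)
  ci <- (-b2 + sqrt(max(b2^2 - 4 * g_s * c2, 0))) / (2 * g_s)
  ci <- min(max(ci, gam), ca)
  list(A_g = g_s * (ca - ci), C_i = ci)
}

#' Transpiration at prescribed stomatal conductance
#'
#' `E_t = 1.6 g_s D_v` with 1.6 the H2O:CO2 diffusivity ratio.
#'
#' @param g_s stomatal conductance to CO2 (mol m-2 s-1 per leaf area).
#' @param d_v vapour mole fraction deficit (mol mol-1).
#' @return transpiration (mol H2O m-2 s-1 per leaf area).
#' @export
transpiration <- function(g_s, d_v) {
  stopifnot(all(g_s >= 0), all(d_v >= 0))
  1.6 * g_s * d_v
}

#' Marginal water cost lambda from root-zone suction
#'
#' `lambda = c_f * (sum of suction heads over the rooted layers)^(c_e)`.
#' A zero suction sum with a negative exponent is capped at `lambda_max`.
#'
#' @param c_f,c_e factor and exponent of the water-use function.
#' @param h_layers per-layer matric suction heads (m, >= 0), top first.
#' @param i_r index of the deepest rooted layer.
#' @param lambda_max cap applied to degenerate/huge values.
#' @param per_layer if `TRUE`, use the alternative reading
#'   `c_f * sum(h_i^(c_e))` (exponent inside the sum).
#' @return lambda (mol H2O per mol CO2).
#' @export
lambda_from_suction <- function(c_f, c_e, h_layers, i_r,
                                lambda_max = 1e5, per_layer = FALSE) {
  if (any(h_layers < 0)) stop("suction heads must be non-negative")
  if (i_r < 1 || i_r > length(h_layers)) stop("i_r out of range")
  h <- h_layers[seq_len(i_r)]
  lam <- if (per_layer) {
    if (any(h == 0) && c_e < 0) lambda_max else c_f * sum(h^c_e)
  } else {
    s <- sum(h)
    if (s <= 0 && c_e < 0) lambda_max else c_f * s^c_e
  }
  min(max(lam, 0), lambda_max)
}

#' Optimal stomatal conductance at constant marginal water cost
#'
#' Finds `g_s` such that the slope `dE_t/dA_g` at the operating point equals
#' `lambda` (the Cowan condition; equivalently `g_s` maximises
#' `A_g - E_t/lambda`). For the electron-transport-limited assimilation
#' model the condition reduces to a quadratic in the leaf-internal CO2 mole
#' fraction, which is solved in closed form. Boundary returns: `g_s = 0`
#' when no positive conductance attains the slope (water too costly), and a
#' supply-capped `g_s` (flagged) when optimal transpiration would exceed
#' `supply_cap`.
#'
#' @param env list with `I_a` (PPFD, umol m-2 s-1), `D_v` (mol mol-1),
#'   `C_a` and `Gamma_star` (ppm); `T_a` optional (used only by callers that
#'   apply the temperature response beforehand).
#' @param j electron transport rate (umol m-2 s-1).
#' @param lambda marginal water cost (mol H2O per mol CO2), > 0.
#' @param supply_cap maximum transpiration rate (mol H2O m-2 s-1 per leaf
#'   area); `Inf` for unlimited.
#' @param g_max upper bound on stomatal conductance (mol m-2 s-1).
#' @return list with `g_s`, `C_i` (ppm), `A_g` (umol m-2 s-1), `E_t`
#'   (mol m-2 s-1), `lambda_used` (the slope at the operating point) and
#'   `limited` (TRUE when the supply cap bound the solution).
#' @export
optimal_gs <- function(env, j, lambda, supply_cap = Inf, g_max = 10) {
  if (lambda <= 0) stop("lambda must be positive")
  ca <- env$C_a * 1e-6; gam <- env$Gamma_star * 1e-6
  dv <- env$D_v
  a4 <- j / 4 * 1e-6
  zero <- list(g_s = 0, C_i = env$Gamma_star, A_g = 0, E_t = 0,
               lambda_used = NA_real_, limited = FALSE)
  if (a4 <= 0 || ca <= gam) return(zero)
  if (supply_cap <= 0) { zero$limited <- TRUE; return(zero) }
  if (dv <= 0) {
    gs <- g_max
  } else {
    lambda_min <- 1.6 * dv / (ca - gam)
    if (lambda <= lambda_min * (1 + 1e-12)) return(zero)
    k <- 3 * gam * lambda / (1.6 * dv)
    qa <- 1 - k
    qb <- 2 * (k * ca - gam)
    qc <- 3 * gam * ca - 2 * gam^2 - k * ca^2
    if (abs(qa) < 1e-14) {
      ci <- -qc / qb
    } else {
      disc <- qb^2 - 4 * qa * qc
      if (disc < 0) return(zero)
      roots <- (-qb + c(1, -1) * sqrt(disc)) / (2 * qa)
      roots <- roots[roots > gam & roots < ca]
      if (!length(roots)) return(zero)
      ci <- max(roots)
    }
    gs <- a4 * (ci - gam) / ((ci + 2 * gam) * (ca - ci))
  }
  limited <- FALSE
  gs <- min(gs, g_max)
  if (dv > 0 && is.finite(supply_cap)) {
    gs_cap <- supply_cap / (1.6 * dv)
    if (gs > gs_cap) { gs <- gs_cap; limited <- TRUE }
  }
  if (gs <= 0) { zero$limited <- limited; return(zero) }
  ax <- assimilation(gs, list(C_a = env$C_a, Gamma_star = env$Gamma_star), j)
  # report the realized slope dEt/dAg at the operating point (numerical)
  dg <- gs * 1e-5
  a_hi <- assimilation(gs + dg, list(C_a = env$C_a,
                                     Gamma_star = env$Gamma_star), j)$A_g
  a_lo <- assimilation(gs - dg, list(C_a = env$C_a,
                                     Gamma_star = env$Gamma_star), j)$A_g
  lam_used <- if (a_hi > a_lo)
    (1.6 * dv * 2 * dg) / ((a_hi - a_lo) * 1e-6) else NA_real_
  list(g_s = gs, C_i = ax$C_i, A_g = ax$A_g, E_t = 1.6 * gs * dv,
       lambda_used = lam_used, limited = limited)
}

#' Hourly canopy fluxes of the two big leaves
#'
#' Scales per-leaf fluxes of each big leaf to ground area by its fractional
#' cover. The two opaque big leaves may not overlap: `M_A,s + M_A,p <= 1`.
#'
#' @param perennial,seasonal [big_leaf()] configurations.
#' @param env environment as in [optimal_gs()] plus `T_a` (degC).
#' @param lambda_p,lambda_s marginal water costs for the two leaves.
#' @param supply_cap_p,supply_cap_s transpiration caps (mol m-2 s-1 per leaf
#'   area).
#' @param alpha_q,t_opt,sigma_t,g_max physiological constants, see
#'   [electron_transport()], [jmax_at_temperature()], [optimal_gs()].
#' @return one-row data.frame of ground-area fluxes (`E_t_p`, `E_t_s` mol
#'   m-2 s-1, `A_g_p`, `A_g_s` umol m-2 s-1) and per-leaf conductances
#'   (`G_s_p`, `G_s_s` mol m-2 s-1).
#' @export
canopy_fluxes <- function(perennial, seasonal, env, lambda_p, lambda_s,
                          supply_cap_p = Inf, supply_cap_s = Inf,
                          alpha_q = 0.3, t_opt = 30, sigma_t = 12,
                          g_max = 10) {
  if (perennial$m_a + seasonal$m_a > 1 + 1e-12)
    stop("invariant error: big-leaf covers overlap (M_A,s + M_A,p > 1)")
  one <- function(leaf, lambda, cap) {
    jt <- jmax_at_temperature(leaf$j_max25, env$T_a, t_opt, sigma_t)
    j <- electron_transport(env$I_a, jt, alpha_q)
    if (leaf$m_a <= 0)
      return(list(g_s = 0, A_g = 0, E_t = 0))
    optimal_gs(env, j, lambda, supply_cap = cap, g_max = g_max)
  }
  p <- one(perennial, lambda_p, supply_cap_p)
  s <- one(seasonal, lambda_s, supply_cap_s)
  data.frame(E_t_p = p$E_t * perennial$m_a, E_t_s = s$E_t * seasonal$m_a,
             A_g_p = p$A_g * perennial$m_a, A_g_s = s$A_g * seasonal$m_a,
             G_s_p = p$g_s, G_s_s = s$g_s)
}
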