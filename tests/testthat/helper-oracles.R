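# Independent oracles used across the suite. These deliberately do not call
# the package implementations they check.

# van Genuchten retention / Mualem conductivity, written out directly
oracle_vg_se <- function(h, thr, ths, alpha, n) {
  m <- 1 - 1 / n
  (1 + (alpha * h)^n)^(-m)
}
oracle_vg_k <- function(se, n, ksat) {
  m <- 1 - 1 / n
  ksat * se^0.5 * (1 - (1 - se^(1 / m))^m)^2
}

# electron-transport-limited assimilation at prescribed gs, solved by root
# bracketing on the supply/demand balance in ci (independent of the
# package's closed-form quadratic)
oracle_assim <- function(gs, ca, gam, j) {
  if (gs <= 0 || j <= 0) return(list(A_g = 0, C_i = if (gs <= 0) gam else ca))
  f <- function(ci) gs * (ca - ci) - (j / 4) * (ci - gam) / (ci + 2 * gam)
  ci <- uniroot(f, c(gam, ca), tol = 1e-12)$root
  list(A_g = gs * (ca - ci), C_i = ci)
}

# brute-force Cowan optimum: maximize Ag - Et/lambda on a gs grid.
# Vectorised quadratic solve, written independently of the package.
oracle_gs_grid <- function(env, j, lambda, g_max = 10, n_grid = 1000) {
  gs <- seq(0, g_max, length.out = n_grid)
  ca <- env$C_a; gam <- env$Gamma_star
  a4 <- j / 4
  b2 <- -(gs * ca - 2 * gam * gs - a4)
  c2 <- -(2 * gam * gs * ca + a4 * gam)
  ci <- ifelse(gs > 0,
               (-b2 + sqrt(pmax(b2^2 - 4 * gs * c2, 0))) / (2 * pmax(gs, 1e-300)),
               gam)
  ci <- pmin(pmax(ci, gam), ca)
  ag <- gs * (ca - ci)               # umol m-2 s-1
  et <- 1.6 * gs * env$D_v           # mol m-2 s-1
  obj <- ag * 1e-6 - et / lambda
  k <- which.max(obj)
  list(g_s = gs[k], objective = obj[k], grid_step = gs[2] - gs[1])
}

# root uptake: solve the collar potential of the resistor network by
# bisection on total supply(psi_r) = demand
oracle_uptake <- function(psi, cond, demand, psi_min) {
  supply <- function(pr) sum(cond * pmax(0, psi - pr))
  if (supply(psi_min) <= demand)
    return(list(uptake = cond * pmax(0, psi - psi_min),
                limited = supply(psi_min) < demand))
  pr <- uniroot(function(p) supply(p) - demand,
                c(psi_min, max(psi)), tol = 1e-14)$root
  list(uptake = cond * pmax(0, psi - pr), limited = FALSE, psi_r = pr)
}

# numerical slope dEt/dAg at a given gs
oracle_slope <- function(gs, env, j, dg = NULL) {
  if (is.null(dg)) dg <- max(gs * 1e-5, 1e-9)
  a_hi <- oracle_assim(gs + dg, env$C_a, env$Gamma_star, j)$A_g
  a_lo <- oracle_assim(gs - dg, env$C_a, env$Gamma_star, j)$A_g
  (1.6 * env$D_v * 2 * dg) / ((a_hi - a_lo) * 1e-6)
}

# small standard simulation fixture shared by several files
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      site <- synthetic_site("water_limited")
      sc <- scenario_spec(site, 380, "long", n_years = 1, rng_seed = 21)
      forc <- scenario_forcing(sc)
      p <- long_term_params(0.3, 1.5, 500, -0.5, 800, -0.5)
      cache <<- list(site = site, forcing = forc, params = p,
                     sim = simulate_vom(forc, 380, site$soil, site$geometry,
                                        p, keep_logs = TRUE))
    }
    cache
  }
})
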