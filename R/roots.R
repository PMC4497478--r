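## Vertical root profiles and water extraction through a soil-to-root
## resistance network. The plant is treated as a steady-state conduit: water
## extracted in an hour equals transpiration delivered in that hour, with a
## single root-collar potential solved per step.

#' Root profile for one vegetation component
#'
#' @param s_ar fine-root surface area per soil volume (m2 m-3), one value per
#'   soil layer (top first). Entries below `max_depth` are forced to zero.
#' @param max_depth maximum rooting depth (m); seasonal vegetation is fixed
#'   at 1 m by convention.
#' @param layer_thickness soil layer thickness (m).
#' @return object of class `root_profile` with `s_ar`, `max_depth` and the
#'   index `i_r` of the deepest rooted layer.
#' @export
root_profile <- function(s_ar, max_depth, layer_thickness = 0.5) {
  if (any(s_ar < 0)) stop("root surface areas must be non-negative")
  if (max_depth < layer_thickness)
    stop("max_depth must be at least one layer")
  i_r <- min(length(s_ar), as.integer(round(max_depth / layer_thickness)))
  if (i_r < length(s_ar)) s_ar[(i_r + 1):length(s_ar)] <- 0
  structure(list(s_ar = s_ar, max_depth = max_depth,
                 layer_thickness = layer_thickness, i_r = i_r),
            class = "root_profile")
}

# layer conductances (m s-1 per m head, per unit ground area):
# root area per ground area in the layer times the series conductance of the
# soil-to-root path (soil term c_soil * K) and the radial root path (1/r_root)
root_layer_conductance <- function(state, profile, soil,
                                   control = vom_control()) {
  se <- pmin(pmax((state$theta - soil$theta_r) /
                    (soil$theta_s - soil$theta_r), 1e-9), 1)
  k <- vg_conductivity(se, soil)
  u <- 1 / (control$r_root + 1 / (control$c_soil * k + 1e-300))
  profile$s_ar * profile$layer_thickness * u
}

# water potential driving uptake: matric potential only (m); elevation
# differences within a root zone are negligible against psi_min
layer_water_potential <- function(state) -state$h

#' Root water uptake through the resistance network
#'
#' Solves for the root-collar potential such that the sum of per-layer
#' extractions (each proportional to layer conductance times the potential
#' difference, floored at zero - no reverse flow) meets the demand. If even
#' the minimum collar potential cannot meet demand, extraction is capped and
#' the `limited` flag is set; the gas-exchange layer uses that flag to close
#' stomata.
#'
#' @param state a [soil_state()].
#' @param profile a [root_profile()].
#' @param demand_mm_h transpiration demand (mm per hour per ground area).
#' @param soil,geom soil parameters and catchment geometry.
#' @param control numerical coefficients (`psi_min`, `c_soil`, `r_root`).
#' @return list with `uptake` (mm per hour per layer), `total`, `limited`
#'   and the solved collar potential `psi_root` (m).
#' @export
root_water_uptake <- function(state, profile, demand_mm_h, soil, geom,
                              control = vom_control()) {
  if (demand_mm_h < 0) stop("demand must be non-negative")
  cond <- root_layer_conductance(state, profile, soil, control)
  psi <- layer_water_potential(state)
  demand_ms <- demand_mm_h / 3.6e6
  n <- length(psi)
  active <- cond > 0 & psi > control$psi_min
  smax <- sum(cond[active] * (psi[active] - control$psi_min))
  if (demand_ms <= 0) {
    return(list(uptake = numeric(n), total = 0, limited = FALSE,
                psi_root = control$psi_min))
  }
  if (smax <= demand_ms) {
    upt <- ifelse(active, cond * pmax(0, psi - control$psi_min), 0)
    return(list(uptake = upt * 3.6e6, total = smax * 3.6e6,
                limited = smax < demand_ms, psi_root = control$psi_min))
  }
  ord <- order(psi, decreasing = TRUE)
  ord <- ord[active[ord]]
  csum <- 0; cpsi <- 0; psi_r <- control$psi_min
  for (j in seq_along(ord)) {
    i <- ord[j]
    csum <- csum + cond[i]; cpsi <- cpsi + cond[i] * psi[i]
    nxt <- if (j < length(ord)) psi[ord[j + 1]] else control$psi_min
    cand <- (cpsi - demand_ms) / csum
    if (cand >= nxt - 1e-15) { psi_r <- cand; break }
  }
  upt <- ifelse(cond > 0, cond * pmax(0, psi - psi_r), 0)
  list(uptake = upt * 3.6e6, total = sum(upt) * 3.6e6, limited = FALSE,
       psi_root = psi_r)
}

#' Maximum water supply rate of a root system
#'
#' Extraction with the root-collar potential at its configured minimum:
#' the supply cap the stomatal-closure logic enforces.
#'
#' @inheritParams root_water_uptake
#' @return supply (mm per hour per ground area).
#' @export
max_supply <- function(state, profile, soil, geom, control = vom_control()) {
  cond <- root_layer_conductance(state, profile, soil, control)
  psi <- layer_water_potential(state)
  sum(cond * pmax(0, psi - control$psi_min)) * 3.6e6
}

#' Root area index
#'
#' Fine-root surface area per unit ground area:
#' `RAI = sum_i S_Ar_i * layer_thickness`.
#'
#' @param profile a [root_profile()].
#' @return RAI (m2 m-2).
#' @export
root_area_index <- function(profile) {
  sum(profile$s_ar) * profile$layer_thickness
}
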