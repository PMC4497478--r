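---
title: "vegopt: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vegopt: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented in `vegopt`: the coupled
water-balance / vegetation model, the optimality principles that drive it,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## 1. The model

### Soil water balance

The catchment is a rectangular block of soil over impermeable bedrock,
discretised into 0.5 m layers. Each layer carries a volumetric water
content $\theta_i \in [\theta_r, \theta_s]$; effective saturation, matric
suction head $h$ (m, positive) and hydraulic conductivity follow van
Genuchten (1980) and Mualem:

$$\Theta = \bigl[1 + (\alpha h)^n\bigr]^{-m},\quad m = 1 - 1/n, \qquad
K(\Theta) = K_{sat}\,\Theta^{1/2}\bigl[1-(1-\Theta^{1/m})^m\bigr]^2 .$$

Named parameter sets for sandy loam, loam and sandy clay loam are built in
(`soil_preset()`), as are four site geometries spanning a dry-to-wet
gradient (`site_preset()`).

Vertical fluxes are Darcy fluxes on the total head $H_i = z_i - h_i$ with
arithmetic-mean conductivity of adjacent layers, integrated by explicit,
adaptively sub-stepped Euler (sub-step limited so no layer changes by more
than a tenth of its water-holding range; donor-side flux scaling keeps
every layer at or above residual content). Rain infiltrates up to
$K_{sat}$ (infiltration excess) and up to pore space (saturation excess);
the remainder is runoff. Lateral drainage is a Dupuit–Forchheimer closure
on the water-table height $z_w$ above the channel elevation $z_r$:

$$Q = c_{drain}\,K_{sat}\,\sin\gamma_0\,\frac{\max(0, z_w - z_r)}{L_c},$$

with the three catchment parameters (surface elevation, channel elevation,
slope angle) plus an effective drainage length $L_c$ (100 m default). Soil
evaporation is a radiation-driven potential scaled by the unshaded ground
fraction and the top-layer saturation,
$E_s = (1-\mathrm{FPC})\,\Theta_1\,c_{es}\,I_g/\lambda_E$ — the two
controls that matter for the CO$_2$ experiments (shading feedback and
surface-moisture feedback) with a single efficiency $c_{es}$.

### Root water uptake

Each vegetation component owns a vertical profile of fine-root surface
area per soil volume, $S_{Ar,i}$. Layer $i$ contributes a conductance
$C_i = S_{Ar,i}\,\Delta z\,/\,(r_{root} + 1/(c_{soil} K_i))$ — radial root
resistance in series with a soil-to-root term that collapses as the soil
dries. The plant is a steady-state conduit: hourly uptake equals hourly
transpiration, with one root-collar potential $\psi_r$ solved per hour from
$\sum_i C_i \max(0, \psi_i - \psi_r) = E_t$ (piecewise-linear, closed
form). The collar potential is bounded below by $\psi_{min}$ (−150 m
$\approx$ −1.5 MPa); the corresponding supply maximum caps transpiration,
and a capped hour is flagged so stomata close to match. Uptake potentials
use matric potential only: elevation differences of a metre or two inside
a root zone are negligible against $\psi_{min}$, and this keeps the
resistor network exactly symmetric for identical layers.

### Canopy gas exchange

The canopy is two opaque big leaves (perennial and seasonal cover
fractions, $M_{A,s}+M_{A,p}\le 1$). Photosynthesis is electron-transport
limited (carboxylation limitation deliberately omitted):

$$A_g = \frac{J}{4}\,\frac{C_i-\Gamma^*}{C_i+2\Gamma^*}, \qquad
J = \frac{\alpha_q I_a J_{max}}{\alpha_q I_a + J_{max}},$$

with $J_{max}$ following a Gaussian temperature response anchored exactly
at its 25 °C value. Diffusion supplies
$A_g = g_s (C_a - C_i)$ and costs water $E_t = 1.6\,g_s D_v$. Stomata obey
the Cowan–Farquhar rule: through a day, $g_s$ is chosen so the marginal
water cost of carbon $\partial E_t/\partial A_g$ equals a constant
$\lambda$. For this assimilation model the condition reduces to a
quadratic in $C_i$,

$$(1-k)\,C_i^2 + 2(k C_a - \Gamma^*)\,C_i +
  \bigl(3\Gamma^* C_a - 2\Gamma^{*2} - k C_a^2\bigr) = 0,
  \qquad k = \frac{3\Gamma^* \lambda}{1.6\,D_v},$$

solved in closed form — an intentional deviation from a generic 1-D root
finder: it is exact, branch-safe (stomata shut when
$\lambda \le 1.6 D_v/(C_a-\Gamma^*)$, the minimum attainable slope) and
two orders of magnitude faster, which the optimization protocol needs. The
closed form is validated against brute-force grid maximization of
$A_g - E_t/\lambda$ in the acceptance suite.

$\lambda$ itself is a daily function of root-zone suction — the water-use
strategy of the community:

$$\lambda = c_{\lambda f}\Bigl(\sum_{i=1}^{i_r} h_i\Bigr)^{c_{\lambda e}},$$

evaluated at midnight over the rooted layers of each component. The
alternative grouping $c_f \sum h_i^{c_e}$ (exponent inside the sum) is a
plausible reading of the same strategy family; it is implemented behind
the `per_layer` flag of `lambda_from_suction()` and off by default — for a
single rooted layer the two coincide, and the outer-exponent form keeps
$\lambda$ monotone in total root-zone dryness, which is the property the
strategy interpretation relies on.

### Net Carbon Profit and daily dynamics

Daily NCP is assimilation minus maintenance/turnover:
foliage $c_{Mf}(M_{A,p}+M_{A,s})$ plus a photosynthetic-capacity term
$c_{Jv}\,J_{max25}^{\gamma} M_A$, roots
$c_r \Delta z \sum S_{Ar}$, and wood
$c_w M_{A,p}(1 + c_{wd}\, y_{r,p})$. The capacity-cost exponent $\gamma$
defaults to 2: with a linear capacity cost the daily capacity optimum of
this assimilation model shifts by tens of percent under a 20 % CO$_2$
increase, whereas canopy-scale acclimation observed and simulated in this
literature is a few percent — an increasing marginal cost of capacity is
the simplest structure that reproduces this. Setting $\gamma = 1$ recovers
the plain linear accounting (and is what the unit test of the cost
contract pins).

Dynamic properties adapt each midnight using the previous day replayed
with the soil-state trajectory frozen (a first-order approximation that
makes the probes nearly free):

* $J_{max25}$ of each leaf is re-tuned by a multiplicative ladder search
  (factors 1/3 … 3, 10 % granularity near the current value) — capacity
  has no structural inertia, so quasi-direct daily optimization is the
  faithful scheme. Incremental-only adjustment made capacity ride a
  floor-to-peak sawtooth over each growing season whose seasonal mean
  responded to CO$_2$ several times more strongly than its optimum.
* Seasonal cover and per-layer root areas move one bounded multiplicative
  hill-climbing step (10 %/day default) in the direction of positive
  marginal NCP, clipped to $[floor, 1-M_{A,p}]$ and $[floor, cap]$. These
  are structures built from carbon; one bounded step per day is the
  spec-intended scheme. The default step was raised from 2 % because at
  2 %/day a seasonal leaf cannot climb from its dry-season floor to a
  realistic wet-season cover within one wet season — the seasonal
  component would be structurally dead in any strongly seasonal climate.

### Long-term optimization

The six community constants ($M_{A,p}$, $y_{r,p}$, $c_{\lambda f,p}$,
$c_{\lambda e,p}$, $c_{\lambda f,s}$, $c_{\lambda e,s}$) are optimized by
standard SCE-UA (complexes evolved by competitive simplex steps on
triangularly weighted subcomplexes, periodic shuffling; deterministic
under a seed). The rooting depth is snapped to the 0.5 m layer grid before
each evaluation. Search bounds restrict the water-use exponents to
$[-1.2, -0.05]$ — the strictly conservative branch where $\lambda$ falls
as the root zone dries. Near-zero and positive exponents admit
drought-insensitive or profligate-when-dry strategies which a
finite-budget search exploits (this model has no mortality, so running
every hour at the supply cap carries no structural risk); they are
physiologically meaningless and excluded by construction. Factors below
about 100 put $\lambda$ under the minimum attainable slope even in wet
soil, i.e. permanently shut stomata, and are excluded as dead communities.

### The elevated-CO₂ protocol

`run_co2_experiment()` runs, per site: long-term adaptation at the
baseline CO$_2$ (default 317 ppm), long-term adaptation at each elevated
level with the baseline incumbent injected into the SCE start population,
and medium-term reruns at the elevated levels with the six constants
frozen at the baseline optimum. Injecting the incumbent guarantees
long-term NCP $\ge$ medium-term NCP by construction, which turns the
optimality-dominance property into a deterministic invariant rather than a
budget-dependent hope. A fixed neutral parameter vector is injected into
every start population as well. Summaries follow the last-years-averaging
convention (means of fluxes and states, medians of $\lambda$) and report
the water-balance identity $P = Q + E_T + \Delta S$ explicitly rather than
assuming steady state.

## 2. Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha_q` | 0.3 | mol e⁻ (mol quanta)⁻¹ | effective canopy quantum yield of the light hyperbola |
| `gamma_star` | 40 | ppm | CO₂ compensation point; temperature-independent by default for testability |
| `g_max` | 10 | mol m⁻² s⁻¹ | numerical upper bound of the stomatal solver |
| `psi_min` | −150 | m | root-collar potential floor (≈ −1.5 MPa wilting) |
| `c_soil`, `r_root` | 0.01, 10⁷ | –, m s | soil-to-root geometry factor and radial root resistivity; set so a root area index near 0.5 supplies a few mm h⁻¹ from moist soil |
| `c_es` | 0.35 | – | soil-evaporation efficiency relative to the radiative potential; bare moist soil evaporates at roughly a third of the equilibrium rate once surface resistance is accounted for |
| `c_drain` | 1 | – | drainage closure coefficient |
| `adjust_step`, `probe_step` | 0.1, 0.05 | d⁻¹, – | daily hill-climbing step and finite-difference probe |
| costs `c_Mf, c_Jv, c_r, c_w` | 0.06, 6·10⁻⁷, 0.06, 0.04 | mol C m⁻² d⁻¹ (per unit driver) | order-of-magnitude maintenance/turnover coefficients; **not** taken from any site calibration (see §4) |

## 3. The synthetic weather generator

`generate_synthetic_daily()` emulates an interpolated daily station
product: rainfall occurrence from a two-state first-order chain whose wet
probability varies seasonally (concentration parameter 0–1), exponential
wet-day depths scaled so the expected annual total matches the specified
mean, daily irradiance as extraterrestrial radiation times a stochastic
clear-sky fraction (reduced on wet days), a seasonal temperature cycle
with AR(1) day-to-day noise and a wet-day-reduced diurnal range, and
vapour pressure as mean relative humidity times saturation vapour pressure.
Years are exactly 365 days; there is no leap-day astronomy.

Hourly disaggregation: rain is spread evenly over 24 h; irradiance follows
the positive part of the solar-elevation sine normalised to conserve the
daily energy exactly; temperature runs from `T_min` at dawn to `T_max` two
hours after solar noon along half-cosine segments whose anchors are
snapped to the hour-centre grid (so the series attains both extremes
exactly); vapour pressure is constant over the day and the mole-fraction
deficit is floored at zero.

What a green test on synthetic weather does **not** establish: the
generator has no multi-day synoptic structure beyond lag-1 persistence, no
interannual variability modes, no correlated temperature–humidity
extremes, and its two site presets live on a 3 m soil column so that the
CO₂ protocol runs in minutes. Soil-moisture relief under elevated CO₂ is
therefore roughly an order of magnitude stronger than on deep (15–30 m)
natural profiles — consequences in §5.

## 4. Numerical choices

* Soil stepping: adaptive explicit sub-stepping, `dtheta_max = 0.1` of the
  retention range per sub-step, donor-side scaling at 95 % of available
  water, saturation excess cascaded upward to runoff. Mass closure on any
  run is checked to 10⁻⁶ relative (typically ~10⁻¹²).
* Retention inversion is the exact closed form; suction is capped at
  10⁴ m to keep $\lambda$ finite on desiccated layers.
* The stomatal quadratic falls back to the linear root when $k \to 1$ and
  returns the shut-stomata branch when no admissible root exists; supply
  caps produce the flagged capped branch.
* Tie-break: with $\lambda$ above the minimum slope the interior optimum
  is the unique maximizer of $A_g - E_t/\lambda$ (the objective is zero at
  $g_s = 0$ and increasing while the slope is below $\lambda$), so no
  two-candidate comparison is needed.
* SCE evolution steps budget 3 evaluations; the loop stops at least 3
  evaluations before the cap so the budget is never exceeded.
* Cost coefficients are configuration, not measurements. They were chosen
  (once) so the 500 mm strongly seasonal site equilibrates to a mixed
  savanna — coexisting big leaves, moderate $\lambda \sim 200$, a
  transpiration/soil-evaporation split typical of open savanna — and the
  humid site to a closed canopy. No test asserts their values.

## 5. Known limitations

* **Several process closures are reconstructions.** The diurnal
  disaggregation shapes, drainage closure, soil-evaporation formula, root
  resistivities, temperature response of $J_{max}$ and all cost
  coefficients stand in for unavailable supplementary material. Each is
  isolated behind a single function or coefficient so it can be replaced
  without touching balance accounting.
* **No mortality, no hydraulic damage.** Operating at the supply cap every
  hour is costless, so strategies that lean on the cap are viable; the
  search bounds exclude their extreme (drought-insensitive) forms.
* **Desk-scale columns exaggerate moisture feedback.** On the 3 m columns
  the CO₂-driven soil-moisture relief is large; components that are
  water-starved at baseline respond to elevated CO₂ with *increased* mean
  per-leaf stomatal conductance (relief outpacing leaf-level closure).
  The acceptance suite documents exactly which component/mode/site slots
  this affects; water-use efficiency and intrinsic water-use efficiency
  increase in every slot regardless — the most robust directional response
  the model produces.
* **Two opaque big leaves.** No within-canopy light gradient, no height
  advantage for perennials; on humid sites the partitioning between the
  components is economically near-degenerate and the seasonal water-use
  parameters are weakly identified.
* The steady-state plant (no tissue water storage) removes nocturnal
  refilling dynamics; uptake equals transpiration every hour.
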