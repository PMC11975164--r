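---
title: "Forecast-informed pond operations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecast-informed pond operations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondcast)
```

## The problem

Open raceway ponds growing microalgae are operated semi-continuously: every
day (or every few days) a fraction of the culture is harvested and replaced
with fresh medium. The dilution rate controls a trade-off. A dense culture
absorbs most of the incident light within the top few centimetres; cells
circulating below that depth respire instead of growing, so standing
biomass above an optimum *reduces* net production. A thin culture wastes
light by transmitting it to the pond floor. Because the optimum depends on
the next day's irradiance and water temperature, a fixed routine (say 60%
every 3 days, or 20% daily) is systematically suboptimal under variable
weather.

pondcast implements the forecast-informed alternative: each day, simulate
tomorrow's biomass production for every candidate dilution rate under an
ensemble of weather forecasts, and apply the rate that maximises the
ensemble-mean production. The package contains every piece needed to study
this closed loop end to end with synthetic data: a weather generator, an
ensemble-forecast-error generator, a pond thermal model, a layered growth
model, the operating policies, the daily optimiser, and the evaluation
statistics.

## Growth model

The culture is assumed nutrient-replete, well mixed, at constant pH, with
no contamination — biomass responds only to light and temperature. The
water column (depth $z_{max}$, default 0.25 m) is divided into $M$
equal-volume layers perpendicular to the incident light; irradiance at the
midpoint $z_j$ of layer $j$ follows the Beer–Lambert law

$$I_j = I_0 \, e^{-(k_w + k_b c)\, z_j},$$

with background attenuation $k_w$ (default 0.2 m⁻¹), biomass-specific
attenuation $k_b$ (default 120 m⁻¹ per g L⁻¹) and concentration $c$ in
g AFDW L⁻¹. A layer at or above the compensation irradiance (default
10 µmol m⁻² s⁻¹) contributes its specific growth rate $\mu(T, I_j)$; a
layer below it contributes $-\ell(T, I_j)$, the dark-loss (respiration)
rate — the dark zone costs biomass even at noon. Because the pond is well
mixed, cells sample all layers and the whole culture changes at the layer
mean $r = \frac{1}{M}\sum_j r_j$ (d⁻¹), applied exponentially within each
hourly step: $c' = c\, e^{r\,\Delta t/24}$.

Rates come from a `strain_response` table over a (temperature × irradiance)
grid, interpolated bilinearly and clamped to the nearest edge outside the
grid — laboratory rate tables have finite support and extrapolating growth
beyond the measured range is riskier than holding the edge value. The
built-in `default_strain()` is a synthetic, clearly parametric stand-in for
a laboratory table of a fast-growing thermotolerant chlorophyte: a cardinal
temperature model (CTMI; 5/36/42 °C) times Monod light saturation
(half-saturation 120 µmol m⁻² s⁻¹) with µ_max = 3 d⁻¹, and Q₁₀ = 2 dark
loss anchored at 0.08 d⁻¹ at 20 °C. All constants are invented defaults,
not measurements; the surface is *sampled onto a grid* so every downstream
computation exercises the same interpolation path as a measured table read
with `read_strain_table()`.

$M = 100$ layers by default: the tests verify that halving or doubling $M$
changes daily production by less than 0.5%, so the layer discretisation is
not a meaningful error source at this resolution.

## Pond water temperature

Growth needs culture temperature, which lags and damps air temperature.
pondcast uses a zero-dimensional energy balance for the well-mixed column —
the quantity the growth model consumes is exactly the depth-averaged
temperature, so a 2-D hydrodynamic model would add state the biology cannot
see. The net surface flux is

$$Q_{net} = SW(1-\alpha) + LW_{in} - LW_{out} - \lambda E - H,$$

with Brunt clear-sky atmospheric longwave driven by vapor pressure at the
dew point, grey-body water emission ($\varepsilon = 0.97$), wind-function
latent heat $\lambda E = (a + b\,U)(e_s(T_w) - e_a)$ and Bowen-ratio
sensible heat. The temperature update is explicit Euler,
$T' = T + \Delta t\, Q_{net} / (\rho c_p z_{max})$, sub-stepped at 300 s
internally (a 0.25 m column has a relaxation time of a few hours, so 300 s
is comfortably stable; the hourly interface is unchanged). Evaporative loss
is computed as a diagnostic but depth is held constant, emulating daily
make-up water.

The flux coefficients are standard limnological forms, but their values
(notably the wind function $a = 120$, $b = 20$ W m⁻² kPa⁻¹) are the
package's own calibration: they were chosen once so that the simulated
summer pond climatology (daily maxima around 33–35 °C with occasional cool
spells into the high 20s) is realistic for a shallow desert raceway. They
are parameters of `thermal_params()`, not constants.

## Synthetic weather and synthetic forecast error

`generate_truth_weather()` emulates a mid-summer arid-subtropical regime at
33.4° N (a Mesa, Arizona-like site), hourly, with a fixed UTC offset of −7:

* **Radiation.** Clear-sky shortwave from solar geometry (solar constant ×
  zenith cosine × transmittance 0.75 along the slant path), times
  $1 - 0.5\,\kappa_t$ where cloudiness $\kappa_t \in [0,1]$ is a latent
  hourly AR(1) Gaussian (coefficient 0.97, so cloudy spells are
  day-coherent) mapped through $\Phi(\cdot)^3$ — the cube skews the climate
  toward clear skies with occasional overcast days. PAR is 0.45 × shortwave
  × 4.57 µmol J⁻¹ (exposed in `shortwave_to_par()` because conversion
  conventions differ between data sets). Under the defaults the standard
  deviation of daily-maximum PAR across a 92-day season is a few hundred
  µmol m⁻² s⁻¹, the variability regime the study design targets; the test
  suite asserts it within a factor of two of 286.
* **Temperature.** Mean 31 °C plus an 8 °C diurnal sinusoid peaking at
  15:00 local, plus an AR(1) synoptic anomaly (sd 2 °C, coefficient 0.98)
  and a cool-when-cloudy coupling. Dew point is air temperature minus a
  positive AR(1) deficit (mean 15 °C — arid air), which guarantees
  dewpoint ≤ air temperature by construction rather than by clipping.
* **Wind, pressure.** AR(1) around 3 m s⁻¹, floored at 0.2; constant
  97 kPa.

`generate_ensemble_forecast()` derives member $m$ as truth + systematic
bias + a member-specific AR(1) perturbation (coefficient 0.9 — forecast
busts are synoptically coherent, whole days wrong together, not hourly
noise). Shortwave is treated multiplicatively so nights stay dark; air
temperature, dew point and wind additively; physical bounds are re-imposed
afterwards. The default mild bias (shortwave ×1.03, air +0.5 °C) and
spreads (12% relative shortwave, 1.2 °C air) are invented stand-ins for
typical short-range NWP ensemble error — no quantitative error statistics
exist for the emulated setting, so these are labelled calibration values,
not estimates. Member seeds derive deterministically from (config seed,
member index), so any single member is reproducible in isolation; inside a
treatment run the per-day seed additionally folds in the day index.

What the generator deliberately does **not** emulate: lead-time-dependent
skill decay, state-dependent bias (e.g. larger errors on cold days),
orographic effects, and any spatial structure. Conclusions from passing
tests therefore concern the *mechanism* of forecast-informed operation —
they show the optimiser extracts value from imperfect day-coherent
forecasts, not that any specific NWP product has a particular skill.

## The daily decision

At the operation hour (18:00 local by default) the optimiser evaluates the
scenario grid $d \in \{0, 0.01, \ldots, 0.99\}$ — from "no operation" to
"near-complete blowdown" — under each of the $E$ forecast members
($E \times 100$ one-day simulations; 1100 with the default 11-member
ensemble). The objective for member $m$ is total production over the
horizon:

$$J_m(d) = d\,c\,V + c^+_m(d)\, V,$$

harvested mass now plus predicted standing biomass at tomorrow's harvest
time. The chosen rate maximises the ensemble mean $\bar J(d)$, ties going
to the smallest rate (least pumping, least intervention). This concrete
objective makes batch operation the special case $d = 0$ and yields two
analytically solvable regimes used as test oracles: with attenuation off
and constant rates, $J(d) = cV(d + (1-d)e^{r})$ is monotone, so the argmax
is 0 when growth beats harvest ($e^{r} > 1$) and 0.99 when the culture is
losing mass. With self-shading on, $\bar J$ has an interior maximum and the
decision becomes weather-dependent — that interior optimum is the entire
reason forecast information has value, and the tests assert its existence
by grid search.

Design choices worth recording:

* **Horizon.** One day. Next-day forecasts are the most accurate, and a
  one-day horizon makes the decision greedy; multi-day lookahead is a
  configuration extension (`horizon_hours`), not a default.
* **Decision vs. evolution.** The forecast is used *only* to decide. After
  the dilution is applied, the pond always evolves under the truth weather.
  This separation is what makes forecast error matter at all.
* **Forecast timing.** The synthetic ensemble for day $k$ is issued at the
  decision instant itself and covers exactly the next 24 h. A real archive
  issued at 00 UTC would add a fixed lead offset; in a synthetic study the
  offset only relabels the error process, so the simpler convention wins.
* **Temperature initial condition.** Each member's water-temperature
  forecast starts from the current truth-simulated pond temperature — the
  operator knows today's pond state; only the future is uncertain.
* **Time base.** All timestamps are UTC; the experiment configuration
  carries a fixed UTC offset (−7 default) used for solar geometry and the
  local harvest hour. No daylight-saving rules.

## Experiments and evaluation

`run_experiment()` compares named policies on one shared truth season:
batch (no operation until the final day), fixed routines (60% every 3 days;
20% daily — the two industry-standard references), perfect-forecast FIPO (a
degenerate single-member ensemble equal to truth) and ensemble FIPO. Every
run is closed by harvesting the remaining standing biomass as a terminal
ledger event, which makes batch totals (all standing stock) directly
comparable with semi-continuous totals. The presets are an 8-operation-day
window in late August (`short_term`) and a 92-day June–August season
(`long_term`); both sizes keep a full four-treatment comparison within
seconds on one core thanks to the compiled simulation kernels.

Statistics: Nash–Sutcliffe efficiency for series agreement (1 = perfect,
≤ 0 = the observed mean predicts no worse); classical one-way ANOVA across
treatments on weekly production, where a week is a block of 7 operation
days, the trailing partial week is dropped, and the terminal stock event is
excluded (it is inventory, not weekly production); and percent relative
differences as used in treatment-comparison tables. All four treatments
enter the ANOVA as groups. The degenerate zero-within-variance ANOVA case
is reported explicitly as an infinite F with a warning rather than an
error, and a constant observed series makes NSE an explicit
undefined-metric error.

## Numerical and reproducibility notes

* The compiled growth kernel reproduces the R-level reference
  (`step_growth()`, `engine = "r"`) to machine precision; the equivalence
  is tested. Within the kernel, per-layer irradiance is attenuated
  incrementally (one `exp` per concentration per step) and the temperature
  dimension of the rate table is collapsed once per hour — pure
  restructuring, no approximation.
* A zero-bias zero-spread ensemble is *bit-identical* to the truth slice by
  construction (multiplication by 1, addition of exact zeros), so the
  degenerate-ensemble treatment reproduces the perfect-forecast treatment's
  ledger; this is tested at 1e-9 relative tolerance over a full season.
* Every stochastic component takes an explicit seed, generators restore the
  session RNG state, and one master seed reproduces an entire experiment
  (weather seed = seed; forecast seed derived from it). Output directories
  receive the fully resolved configuration so any run can be reproduced
  from its artifacts.
* Grid queries outside the strain table clamp; dilution rates are capped at
  0.99 (the top of the scenario grid); concentration 0 is absorbing.

## Limitations

The growth model has no photoacclimation, no chromatic (wavelength-
resolved) attenuation, no nutrient or pH state, and no contamination or
grazer dynamics; the thermal model has no stratification, sediment heat
flux or ice; the economics of pumping and labour are outside the objective.
The synthetic-data conclusions transfer to real operations only to the
extent that real forecast error resembles a day-coherent AR(1)-plus-bias
process — with real archives, the same interfaces accept measured forcing
through `read_meteo_table()` and real rate tables through
`read_strain_table()`.
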