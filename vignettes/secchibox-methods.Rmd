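---
title: "Methods: a box model of lake transparency under reclaimed-water replenishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a box model of lake transparency under reclaimed-water replenishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secchibox)
```

## The problem

Water-scarce cities increasingly top up ornamental urban lakes with reclaimed
water (RW, treated wastewater effluent) instead of scarce surface water (SW,
typically river water). The two sources pull transparency — the water-quality
attribute the public actually sees — in opposite directions: RW carries far
less suspended sediment than river water (about 10 vs 45–60 mg/L) but far
more nitrogen and phosphorus (about 15 vs 2 mg/L of dissolved inorganic N),
so it clears the water column while fertilizing algal growth that clouds it
again. `secchibox` quantifies that trade-off for a small, shallow,
continuously flushed landscape lake and solves the operational question: for
each month, what is the least total inflow, and at which RW volume fraction,
that keeps the Secchi depth above a management target (default 70 cm)?

## Transparency model

Secchi depth follows the classical contrast-transmittance relation

$$SD = \frac{\gamma}{c + K_d},$$

with $\gamma = 8.9$ m the coupling constant of the human contrast threshold,
$c = a + b$ the beam attenuation, and $K_d$ the downwelling diffuse
attenuation. Total absorption and scattering are linear in the optically
active constituents — chlorophyll-a (CHL, µg/L), inorganic suspended solids
(ISS, mg/L) and detritus carbon (DC, mg/L):

$$a = a_w + a_\phi\,[CHL] + a_{p-\phi}\,[ISS] + a^*_{p-\phi}\,[DC],$$

and likewise for $b$. Because 1 µg/L = 1 mg/m³ and 1 mg/L = 1 g/m³, the
m²/mg and m²/g specific coefficients apply with no unit conversion. $K_d$
uses Kirk's relation; we adopt the bracket grouping

$$K_d = \frac{a}{\mu_0}\sqrt{1 + (0.425\,\mu_0 - 0.19)\,\frac{b}{a}},$$

i.e. the entire expression (not only the square root) is divided by $\mu_0$,
which is the form with the correct limits: at $b = 0$, $K_d = a/\mu_0$, and
$K_d \ge a$ whenever $\mu_0 \le 1$. The radicand is non-negative for
$\mu_0 \ge 0.19/0.425 \approx 0.447$; smaller average cosines are rejected.
Everything is treated as one broadband (PAR-averaged) channel; no wavelength
is resolved, and CDOM absorption is deliberately excluded (it is weak
relative to suspended matter in this setting).

The bundled coefficient set (`optical_coefficients()`) carries the calibrated
values $\gamma = 8.9$, $a_w = 0.050$, $a_\phi = 0.020$, $a_{ISS} = 0.08$,
$a_{DC} = 0.24$, $b_w = 0.0019$, $b_{ISS} = 0.025$. Three coefficients are
not part of that calibrated set and are package choices, config-exposed and
flagged when defaulted: $\mu_0 = 0.856$ (a conventional clear-sky average
cosine), $b_\phi = 0.12$ m²/mg (a moderate phytoplankton-specific
scattering), and $b_{DC} = 0.5\,b_{ISS}$. See *Limitations* for evidence
that $b_\phi$ may be generous.

## Ecosystem box model

The lake (storage 200,000 m³, area 10 ha, mean depth 2 m) is treated as one
completely stirred tank at fixed water level: outflow equals replenishment
inflow plus storm runoff. For each constituent $X$,

$$\frac{dX}{dt} = \frac{Q_{in} X_{in} + Q_r X_r - Q_{out} X}{V}
  + \text{sources} - \text{sinks}.$$

State variables are phytoplankton carbon (PC), detritus carbon, ISS,
ammonium, nitrate and inorganic phosphorus; chlorophyll-a is tied to PC by a
fixed ratio. The kinetics use six calibrated constants — maximum growth
`mypc` = 2.8/d at 20 °C, death `deac` = 0.10/d, growth temperature theta
`tetg` = 1.14, half-saturations `kn` = 0.05 mg N/L and `kp` = 0.009 mg P/L,
and detritus mineralization `kmdm` = 0.040/d — plus closure constants the
box reduction needs. The closures are documented package choices, not values
from any calibrated template: fixed stoichiometry near Redfield
(`n_to_c` = 0.18, `p_to_c` = 0.024 g/g C), `chl_to_c` = 25 µg Chl-a per mg C,
light half-saturation `i_k` = 80 W/m², settling velocities 0.05 (ISS) and
0.1 (DC) m/d, and no temperature dependence of mineralization by default
(the printed calibration reports a theta for growth only; an optional
`tet_miner` is exposed).

Growth is multiplicative Monod:
$\mu = \texttt{mypc}\cdot\theta^{T-20}\cdot f_I\cdot
\min\!\big(\tfrac{DIN}{k_n+DIN},\tfrac{IP}{k_p+IP}\big)$, with the light
response averaged analytically over the water column under the *current*
diffuse attenuation, so algal self-shading and sediment shading feed back on
growth:

$$f_I = \frac{1}{K_d H}\,
  \ln\!\frac{i_k + I_0}{i_k + I_0 e^{-K_d H}}.$$

Nitrogen uptake prefers ammonium through a smooth switch
$f_{pref} = \frac{NH_4}{NH_4 + k_{pref}}$ with $k_{pref} = 0.01$ mg N/L;
the remainder is drawn from nitrate, so total N is conserved exactly while
small $k_{pref}$ approximates strict ammonium-first drawdown (a hard switch
would be non-smooth and conserve nothing extra). Death routes PC to detritus;
mineralization returns detritus N and P to the dissolved pools. In the
closed, settling-free configuration the construction conserves total N and P
identically, which the test suite verifies to 0.1% over 30 days.

### Numerics

Explicit Euler at a 30-minute step (the step at which the governing processes
are slow: the fastest routine rates are about 0.4–2/d, giving per-step
changes well under 5%), with non-negativity clipping at the zero boundary and
outputs at a 90-minute cadence. Euler preserves linear invariants, so mass
conservation is exact up to clipping. Two guards:

* a stability check errors out (advising a smaller step) when any *bulk*
  component — concentration above 1 mg/L — changes by more than 50% in one
  step. The floor matters: near the zero boundary, drawdown and refill are
  legitimately fast relative to the stock (nutrient exhaustion during a
  bloom, a storm-runoff pulse into a near-empty pool, a tracer filling from
  zero), and there clipping plus the saturating Monod feedback are the
  appropriate treatment, not an error;
* trajectories are verified against an adaptive stiff integrator (lsoda) on
  a 10-day run (max deviation < 1%) and against a halved step on a 30-day
  run (< 1%), and stabilized scenario means at 1800 s vs 450 s agree within
  2%.

The integration loop is compiled (Rcpp); `lake_derivatives()` is the
readable reference implementation, and the test suite holds the two to
1e-10 agreement.

## Synthetic forcing and sources

No measured meteorology ships with the package; `synth_forcing()` generates
it for a temperate continental site in northwest China (34.3° N):

* water temperature: sinusoidal climatology $16 \pm 12$ °C peaking at day
  207 (≈ 4 °C in late January, ≈ 28 °C in late July), plus an AR(1) daily
  anomaly (sd 0.8 °C), clipped to [0, 35] °C;
* irradiance: clear-sky solar geometry (declination, hour angle, latitude)
  with atmospheric transmission 0.70, times a Beta-distributed daily
  cloudiness factor of mean 0.72 — July daily means ≈ 190 W/m², January
  ≈ 80 W/m², realistic for the region; zero at night;
* rainfall: a seeded marked point process (Poisson event counts, gamma
  depths, events spread over 0.5–12 h) rescaled so each month exactly meets
  its configured normal (defaults 6–99 mm, summer-peaking).

All generators are pure functions of (config, seed). Scenario runs use the
deterministic climatological variant (monthly mean temperature, mid-month
diurnal irradiance at mean cloudiness, rainfall spread uniformly), so
scenario results are exactly reproducible with no seed at all.

External nutrient sources follow the documented boundary data: monthly influent
concentrations and dry-deposition masses are built in
(`monthly_influent()`, `deposition_flux()`; deposition is constant within
each month), and storm runoff from 0.067 km² of impervious pavement uses a
runoff coefficient of 0.9 with fixed concentrations (2.5/4/0.64 mg/L of
NH₄⁺-N/NO₃⁻-N/IP). The influent table prints only total suspended solids;
the inorganic fraction defaults to 0.75, the ratio of the surface-water
endmember (45/60), and is config-exposed.

## Scenarios and optimization

`blend_sources()` mixes the SW endmember (1.65/0.35/0.2 mg/L nutrients,
60 mg/L SS of which 45 inorganic) and RW endmember (5/10/0.5 mg/L, 10 mg/L
SS, taken fully inorganic after treatment) volume-linearly; the organic SS
remainder becomes inflow detritus carbon at 0.5 g C/g. `run_scenario()`
integrates a (month, RW fraction, flow) cell under the month's climatology
until the means of SD and chlorophyll over two consecutive 7-day windows
drift by less than 1% (checked every 28 days, capped at 365 days, flagged
if unmet), then reports the final-week means. `min_flow_for_target()` scans
the designed flow range [0.05, 0.77] m³/s on a 0.03 grid and refines the
bracketing interval by bisection to 0.005 m³/s; the exhaustive coarse scan
makes the answer robust to the non-monotone SD(Q) curves this model can
produce (monotonicity is still checked and reported). `optimize_month()`
minimizes that flow over the RW-fraction grid (step 0.05), breaking ties
toward the higher reclaimed fraction; `annual_plan()` assembles the monthly
schedule and compares its volume against SW-only and RW-only baselines, with
savings computed over the months attainable in both plans whenever some
month cannot reach the target at any allowed flow.

Problem sizes used throughout the shipped tests and the acceptance script:
365-day historical runs at 30-minute steps for calibration experiments,
28-day chunks (up to 365 days) per scenario cell, a 21 × 25 (fraction ×
flow) optimization grid per month, and 10 seeded replicates in the
parameter-recovery experiment.

## Calibration and skill

`rmse()` and `nse()` implement the usual skill metrics (the test suite pins
the 3-point hand examples: RMSE $\sqrt{1/3}$, NSE 0.5). `calibrate()`
replaces a manual "adjust until it fits" workflow with a reproducible one:
Nelder-Mead in log-parameter space, from the supplied start plus
Latin-hypercube multistarts, minimizing the sum over observed variables of
RMSE normalized by the observed mean (so µg/L and mg/L variables weigh
comparably); the returned fit never scores worse than its start. Because no
real monitoring series ships with the package, `synth_observations()`
simulates a year under the historical influent at a constant 0.1 m³/s
intake (the reported long-term average is below 0.1), samples mid-month, and
adds multiplicative Gaussian noise (default CV 10%), keeping the noise-free
truth alongside.

The recovery experiment — 10 seeds, 10% noise, free set (`mypc`, `deac`,
`chl_to_c`) — calibrates on the full 12-month year and recovers medians
within 15% of truth (measured: ≈ 7%, 2%, 4%). Restricting calibration to
January–July leaves a genuine ridge (growth, death and the Chl:C ratio can
partially trade off), which is why the chronological split is used for
out-of-sample skill — calibrate on January–July, validate on
August–December, with median held-out NSE around 0.9 for both SD and Chl-a,
comfortably above the usual 0.7 reliability threshold — rather than for
recovery.

## Design choices where the design was open

* **One box, not a hydrodynamic mesh.** The target quantities are lake-mean
  monthly SD and Chl-a in a shallow (≤ 2 m), continuously flushed lake; a
  completely mixed reactor is the transparent reduction. The consequences of
  losing spatial transport are real and documented below.
* **Minimum-of-Monod colimitation, fixed stoichiometry, fixed Chl:C.** The
  simplest closures with the right limits; each is config-exposed.
* **Smooth ammonium preference** instead of a hard NH₄-first switch, for
  exact N conservation and a continuous right-hand side.
* **Stabilization criterion** operationalized as < 1% drift of consecutive
  weekly means, since "after stabilization" is otherwise undefined.
* **Scenario determinism over realism in forcing**: scenario cells use the
  deterministic climatology so that the optimizer's objective is
  well-defined; the stochastic generator exists for calibration experiments
  and robustness checks.

## What the synthetic data do and do not establish

The generators emulate seasonal temperature and light, plausible storm
timing, the printed influent and deposition schedule, and monthly sampling
with multiplicative noise. They do not emulate spatial heterogeneity between
sampling points, autocorrelated sensor error, extreme weather, sediment
resuspension events, or macrophyte/zooplankton dynamics. Passing the
recovery and skill tests therefore shows the *pipeline* is correct and the
parameters are identifiable under the model's own assumptions — not that the
box model is an adequate description of any particular real lake.

## Known limitations

* **Concentration-type nutrient boundary in a CSTR.** Because the
  replenishment water itself carries the nutrients, nutrient load scales
  with inflow. At the stabilized state the phytoplankton balance forces
  $\mu = Q/V + \texttt{deac}$, and the phosphorus budget then makes the
  stabilized bloom *grow* with flow over the lower flow range before
  light-capping flattens it. Flushing therefore cannot suppress warm-season
  blooms in this reduction: with the default kinetics, realized July growth
  (~1.1/d) always exceeds the largest available dilution (0.43/d at
  0.77 m³/s). Three-dimensional transport (short-circuiting of the intake
  plume toward the outlet), vertical light structure, algal settling and
  grazing — all outside this model's scope — are what make strong flushing
  effective in practice; expect this package to be pessimistic about
  warm-season transparency and about the water-saving benefit of blending,
  and treat warm-month "unattainable" verdicts as a property of the box
  reduction, not of the lake.
* **$b_\phi$ is uncertain and likely generous.** The bundled calibrated
  coefficients omit phytoplankton-specific and detritus-specific scattering;
  back-solving the transparency relation against co-occurring bloom SD/Chl-a
  values suggests an effective $b_\phi$ nearer 0.01–0.06 m²/mg than the 0.12
  default. Supplying `optical_coefficients(b_phi = ...)` changes SD levels
  during blooms materially; all scenario conclusions should be read with
  that sensitivity in mind.
* **No dissolved oxygen, sediment diagenesis, resuspension, macrophytes or
  grazers**; ISS is biologically and chemically inert; CDOM is excluded.
* **Monthly climatological scenarios** ignore within-month weather
  variability; stabilized means are conditional on a stationary month.
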