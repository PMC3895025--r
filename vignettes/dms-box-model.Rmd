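---
title: "A zero-dimensional box model of the coastal DMS(P) cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A zero-dimensional box model of the coastal DMS(P) cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsbox)
```

## The model

`dmsbox` simulates the sulfur cycle of a shallow, permanently mixed coastal
water column (the default configuration is a 17-m box of the kind found in
the eutrophied southern North Sea) with three state-variable groups, all in
mmolS m⁻³:

* **DMSPp**, particulate dimethylsulfoniopropionate, tracked separately for
  three phytoplankton functional types (FT) — diatoms (DA), nanoflagellates
  (NF) and *Phaeocystis* colonies (OP);
* **DMSPd**, dissolved DMSP;
* **DMS**, dimethylsulfide.

The sulfur module is *slaved to a carbon forcing*: the phytoplankton carbon
fluxes (growth µₙ, lysis, grazing, sedimentation, all mgC m⁻³ h⁻¹) and the
bacterial state (biomass BC, substrate SBC, kinetic constants) are inputs,
not prognostic variables. Each FT carries a fixed S:C quota SCₙ, so

$$\frac{d\,\mathrm{DMSPp}_n}{dt} =
  SC_n\,(\mu_n - \mathrm{lysis}_n - \mathrm{grazing}_n - \mathrm{sed}_n).$$

Because the right-hand side is the carbon balance times a constant, DMSPpₙ is
exactly SCₙ·Bₙ whenever it starts at quota equilibrium — the
*quota-equivalence oracle* the tests exploit.

Released sulfur is routed through ten named fluxes: a fraction
`y_DMS_n` (default 10 %) of the lysis release is cleaved directly to DMS by
phytoplankton DMSP-lyase (f1), the rest enters DMSPd (f2); grazed DMSPp
enters DMSPd (f3) except an optional fraction `graz_to_DMS` (reference 0,
variant 0.3) that is cleaved during digestion (f3b); sedimentation exports
DMSPp (f4). Bacteria consume DMSPd in proportion to their carbon uptake and
the DMSPd:substrate ratio,

$$\mathrm{uptake} = Ratio^{BC}_{S,\mathrm{DMSPd}}\;
  \frac{b_{mx}\,BC\,SBC}{SBC + k_{sbc}}\;\frac{\mathrm{DMSPd}}{SBC},$$

assimilate what their growth requires
(Sneed = y_BC·uptake_C/12·SC_BC, f5), demethylate most of the remainder to
MeSH/sulfate (f6) and cleave the fraction `lyase_Bact` (default 10 %) to DMS
(f7). When the DMSPd uptake cannot cover Sneed, the bacterial lyase is shut
off entirely and the shortfall is drawn from DMS on top of the base DMS
consumption (f8). DMS is also photooxidized to DMSO with a depth-averaged
first-order rate K0·(1−e^(−k_D H))/(k_D H) (f10) and emitted to the
atmosphere as k_DMS·DMS/H (f9), with
k_DMS = k600·(Sc_DMS/600)^(−1/2) and Sc_DMS the Saltzman cubic in
temperature.

Integration is an explicit Euler scheme (reference step 15 min). All fluxes
are evaluated on the beginning-of-step state; if a step would overdraw a
pool, all sinks of that pool are rescaled proportionally within the step and
the *post-limiting* fluxes are written to the ledger, so the per-step sulfur
balance closes to machine precision by construction. Step-halving (15 min →
7.5 min) changes annual budget entries by well under 1 %.

## Parameters that matter

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `SC_DA` | diatom S:C quota | mmolS mgC⁻¹ | 0.000072 |
| `SC_NF`, `SC_OP` | flagellate / *Phaeocystis* quota | mmolS mgC⁻¹ | 0.00092 |
| `SC_BC` | bacterial S:C quota | molS:molC | 0.01 |
| `y_DMS_n` | phytoplankton lyase yield on lysis | – | 0.1 |
| `lyase_Bact` | bacterial cleavage of non-assimilated DMSPd | – | 0.1 |
| `K0` | surface photooxidation rate | h⁻¹ | 0.09 |
| `ratio_S_DMSPd`, `ratio_S_DMS` | community fraction using DMSPd / DMS | – | 1 |
| `graz_to_DMS` | grazed DMSPp routed to DMS | – | 0 |

The phytoplankton quota column of the source parameter table is labelled
molS:mgC; we store it as mmolS per mgC, the only reading consistent with
the parenthesized molar ratios (0.00092 mmolS:mgC × 12 mgC mmolC⁻¹ =
0.011 molS:molC). All sensitivity tests specified in molS:molC are
converted by /12 on construction.

## The synthetic forcing generator

The original study drives the sulfur module with a full ecological model;
this package replaces that forcing with a desk-scale generator
(`generate_forcing()`) so the sulfur kinetics are testable stand-alone. A
user CSV path (`read_forcing()`) preserves fidelity for anyone with real
ecosystem-model output.

What the generator emulates:

* the seasonal succession — spring diatoms (peak day 75), a short intense
  *Phaeocystis* bloom (peak day 115, 1600 mgC m⁻³, ≈25 mg Chl a m⁻³ total
  at C:Chl = 64), nanoflagellates, summer diatoms;
* exact discrete carbon closure: biomass is baseline plus Gaussian pulses,
  and growth/loss fluxes are derived so µ − losses equals ΔB/Δt at every
  step (residual < 10⁻⁹);
* a loss-rate ramp from 10 % to 90 % of each pulse's intrinsic rate (1/σ)
  across the descending limb, so lysis peaks after the biomass peak and the
  DMSPd maximum lags the DMSPp maximum by several days;
* structural zeros: *Phaeocystis* colonies are not grazed, nanoflagellates
  do not sediment;
* bacterial biomass as a lagged smoothed response (EMA, τ = 60 h) to the
  substrate-release flux. We drive the response with exudation
  (0.01 h⁻¹ × total biomass) *plus* lysis rather than lysis alone: a
  lysis-only driver keeps bacteria — and with them the removal rates of
  both dissolved pools — rising through the entire bloom decay, which
  pushes the DMS maximum after the DMSPd maximum and contradicts the
  observed structure of bacterial maxima sitting at the decline of each
  bloom. With the exudation term the bacterial maximum trails the biomass
  peak by a few days and then relaxes, and the DMS maximum falls between
  the DMSPp and DMSPd maxima, as observed;
* wind as an AR(1) daily series around a seasonal mean (spring Apr–May mean
  3.3 m s⁻¹, sd ≈ 1.7, winter means above 5 m s⁻¹), truncated at zero and
  interpolated hourly; fewer than 6 % of hourly values exceed 8 m s⁻¹;
* seasonal sinusoids for temperature (11 ± 6 °C) and daily-mean irradiance
  (120 ± 95 W m⁻²) with an optional diel cycle; constant k_D = 0.5 m⁻¹.

What it does **not** emulate: nutrient limitation and variable stoichiometry,
the spring/summer difference in diatom physiology, substrate-pool dynamics
(SBC is constant, so bacterial carbon uptake varies only through BC),
advective exchange between boxes, and observational error. A green test on
this generator therefore establishes that the *sulfur kinetics* behave as
specified under a realistic seasonal structure — not that the package
reproduces any particular year of field data. For the same reason the
absolute values of the published sensitivity table (reference annual mean
DMS 0.9 µmolS m⁻³, emission 0.19 mmolS m⁻² y⁻¹) are *not* asserted
anywhere; only the orderings and directions of the 21 perturbations are,
and those all hold on the synthetic scenario.

Bacterial scenario constants (BC baseline 30 mgC m⁻³, gain 2 h, SBC
15 mgC m⁻³, bmx 0.05 h⁻¹, k_sbc 25 mgC m⁻³, y_BC 0.3) were chosen once so
that the annual budget reproduces the qualitative structure of the source
budget — DMSPd fate dominated by demethylation with cleavage < 10 %,
DMS removed overwhelmingly by bacteria with photooxidation second and
emission a few percent, emission ≪ 1 % of DMSPp production — and are not
revisited.

## Numerical choices

* **Flux limiter.** Proportional rescaling of all sinks of a pool when an
  Euler step would overdraw it. At the 15-min reference step the limiter is
  inactive in the default scenario (pools stay at quota equilibrium or
  relax smoothly); it matters for coarse experimentation steps and bloom
  collapse.
* **Caps.** DMSPd and DMS uptake are additionally capped at pool/dt before
  the limiter, matching the kinetics contracts.
* **S-deficit top-up.** The DMS drawn to cover an unmet bacterial S need is
  capped by the available DMS; any remainder is recorded in the ledger as
  `S_unmet`, a diagnostic rather than an error (low-quota scenarios
  legitimately cover only part of the bacterial S demand).
* **Photooxidation** uses depth attenuation only, with UV-A attenuation
  taken equal to PAR attenuation; a diel-irradiance scaling switch exists
  (`photolysis_diel`) and is off by default.
* **Schmidt exponent** −1/2 (wavy surface), configurable in `k_dms()`.
* **Gas-transfer curves.** The Nightingale quadratic is used as published
  (0.222 u² + 0.333 u, cm h⁻¹). The DMS-specific eddy-covariance curve is a
  cubic *fitted in this package* (see `gas_coefficients()`): its source
  publication presents it only graphically, so we constructed a stand-in
  that tracks 0.92× Nightingale below 8 m s⁻¹ and falls to 0.50× by
  15 m s⁻¹, clamped at its highest fitted wind speed. It reproduces every
  behavior stated for the original — near-coincidence at low wind, strong
  divergence above 8 m s⁻¹, an annual mean 5–15 % (nominally ~9 %) below
  Nightingale under the default wind climate — but it is a synthetic fit,
  not a transcription.
* **Time convention.** Regular grid in hours since Jan 1, 365-day year
  (configurable), leap years ignored. The final forcing row repeats the
  penultimate fluxes and is never integrated.

## Empirical algorithms

Five published chlorophyll-based DMS predictors are implemented for
comparison (`dms_anderson()`, `dms_simo_dachs()`, `dms_lana()`,
`dms_belviso()`, `dms_aumont()`), together with the community-structure
index Fp (diatom share of total Chl a). Transcription notes:

* the Simó & Dachs high-ratio intercept is 0.6, taken from the original
  publication (the table we reproduce truncates it);
* the quadratic coefficient of the Belviso DMS:DMSP polynomial is +16.00;
  the reproduced table renders the sign ambiguously, but a negative sign
  would make the ratio ≤ −30 at Fp = 1 (structurally negative DMS), while
  +16 matches the companion Aumont fit on the same data;
* the Belviso branch threshold variable (printed as "Chla′") is read as
  total Chl a;
* the Aumont ratio is discontinuous at Fp = 0.6; both branch values are
  exposed (`aumont_ratio(..., side=)`).

Both Fp-based fits blow up at eutrophic chlorophyll (hundreds to thousands
of nM DMS at 25 mg Chl m⁻³). This is a documented property of the
algorithms and is reproduced, not clamped; outputs carry an `extrapolated`
flag beyond the fitted range (total Chl > 4 mg m⁻³).

`compare_with_simulation()` evaluates the algorithms on daily means of the
forcing and pairs them with simulator output. Nitrate is not part of the
forcing schema; the Anderson Q term uses a seasonal drawdown series derived
from cumulative production (30 → 1 mmol m⁻³) unless the caller supplies
one. The comparison reproduces the qualitative finding that
chlorophyll-driven predictors generate DMS during diatom blooms where the
mechanistic model, driven by the quota contrast between diatoms and
*Phaeocystis*, concentrates DMS in the *Phaeocystis* period.

## Design decisions that were genuinely open

* **Per-FT DMSPp states.** The bulk DMSPp equation is linear, so tracking
  three per-FT pools whose sum is the bulk pool changes nothing numerically
  while enabling the quota-equivalence oracle and per-FT production shares.
* **DMSPd/DMS uptake forms.** The uptake equations are reconstructed as
  carbon-uptake-proportional with pool:SBC stoichiometry, which is the only
  form consistent with the describing prose; coefficients are not otherwise
  constrained.
* **Budget share denominators.** Gross DMS production (f1 + f3b + f7) is
  the denominator for DMS-sink shares; the annual storage change is
  reported but excluded (a seasonal cycle returns close to its winter
  state, so the difference is far below rounding).
* **Wind test 18** ("constant annual-mean wind") is implemented as a
  constant 3.9 m s⁻¹ series.
* **File formats.** Configuration is JSON and trajectories/ledgers are CSV
  (lossless, 17-significant-digit doubles); no YAML or NetCDF library is
  part of the supported dependency set, and plain-text outputs keep runs
  diffable.

## Known limitations

* The generator's carbon fluxes are kinematically consistent but not
  mechanistic: losses are partitioned by fixed fractions, and the loss-rate
  ramp is a shape assumption, so the annual lysis:grazing split of the
  DMSPd source (~85/15 here) is steeper than the ~68/32 of the source
  budget, which had grazed spring/summer diatom blooms of comparable
  magnitude to the *Phaeocystis* bloom.
* Absolute pool sizes are scenario-dependent: the default run peaks near
  1.5 mmolS m⁻³ DMSPp (quota × biomass), tens of µmolS m⁻³ DMSPd and a few
  µmolS m⁻³ DMS — the right relative structure, smaller dissolved-pool
  amplitudes than the 1989 hindcast this model family was built for.
* One bacterial community; no separate DMS- vs DMSP-consumer guilds, no
  Archaea, no DMSO tracking, no phytoplankton DMSPd uptake, no variable
  (light-dependent) quotas.

## A worked run

```{r example, eval = FALSE}
f <- generate_forcing(default_bloom_specs(), environment_spec(),
                      dt = 0.25, seed = 1)
sim <- run_simulation(f, sulfur_params())
b <- integrate_budget(sim)
b$shares$dms_sinks        # bacterial uptake / photooxidation / emission, %
run_experiment(forcing = f)   # reference + the 21 sensitivity tests
```
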