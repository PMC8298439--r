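---
title: "Methods: from whole-cell PAL kinetics to plasma Phe lowering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from whole-cell PAL kinetics to plasma Phe lowering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(phesim)
```

phesim is a quantitative systems pharmacology toolkit for orally dosed,
phenylalanine-ammonia-lyase (PAL) expressing synthetic biotics in
phenylketonuria (PKU). The engineered organism consumes phenylalanine (Phe)
in the gut lumen, converting it to trans-cinnamic acid (TCA), which the host
absorbs, converts hepatically to hippurate (HA), and excretes in urine.
Because the consumed Phe never reaches the plasma, the oral dose lowers
blood Phe — the toxic species in PKU.

The package chains four models:

1. **Whole-cell PAL kinetics** — the rate at which a cell suspension
   consumes Phe, with pH and product (TCA) inhibition
   (`pal_flux()`, `simulate_invitro_batch()`, and the fitters
   `fit_michaelis_menten()`, `fit_ph_linear()`, `fit_tca_exponential()`).
2. **Gastrointestinal transit** — a two-compartment stomach/small-intestine
   model that places a dose and a meal in the gut and predicts urinary HA
   (`simulate_gi_dose()`).
3. **Plasma Phe metabolism** — an extended one-compartment blood model with
   discrete meals, PAH substrate activation, transaminase and renal
   elimination (`simulate_blood()`, `fasting_phe()`).
4. **Dose–response coupling** — the GI model's per-meal Phe consumption is
   fed into the blood model as a dietary removal, giving percent lowering as
   a function of dose in CFU (`predict_lowering()`, `dose_response_curve()`).

All public functions accept and return tibbles or small parameter objects,
and the fit/simulation objects support `tidy()`, `glance()`, and
`autoplot()`.

## 1. Whole-cell PAL kinetics

The volumetric Phe consumption rate of a suspension of $N$ CFU/mL at
Phe concentration $S$ (µmol/mL), pH $p$, and TCA concentration $C$
(µmol/mL ≡ mM) is

$$
v(S, N, p, C) \;=\;
V_{\max}\,\frac{S}{K_m + S}\;\cdot\;\frac{N}{10^9}\;\cdot\;
K_{i,\mathrm{pH}}(p)\;\cdot\;K_{i,\mathrm{TCA}}(C),
$$

with the two inhibition factors

$$
K_{i,\mathrm{pH}}(p) = \mathrm{clamp}\!\left(0.25\,p - 0.7,\; 0,\; 1\right),
\qquad
K_{i,\mathrm{TCA}}(C) = 0.67\,e^{-0.53\,C} + 0.33 .
$$

Activity is therefore zero at or below pH 2.8, full at or above pH 6.8, and
TCA feedback asymptotically reduces activity to a 33 % floor. Default
constants (`pal_params()`):

| parameter | value | units | meaning |
|---|---|---|---|
| `km` | 0.0184 (CI 0.005–0.0442) | µmol/mL | Michaelis constant |
| `vmax` | 0.0162 (CI 0.0154–0.0171) | µmol/min per 10⁹ CFU | maximal whole-cell rate |
| `ki_ph_slope`, `ki_ph_intercept` | 0.25, −0.7 | — | pH activity line |
| `ki_tca_amp`, `ki_tca_rate`, `ki_tca_floor` | 0.67, 0.53, 0.33 | —, mL/µmol, — | TCA feedback |

`simulate_invitro_batch()` integrates $\dot S = -v$, $\dot C = +v$ in a
closed vessel (cells and pH constant), which conserves $S + C$ exactly and
is the generating process for the `ivs_timecourse` fixture flavor.

### Fitting and identifiability

The three fitters use `minpack.lm::nlsLM` (Michaelis–Menten and TCA decay;
multi-start over $K_m$ guesses) and `stats::lm` (pH line), and return a
common `pal_fit` object with asymptotic 95 % confidence intervals.
`pal_params_from_fits()` assembles the three fits back into a `pal_params`
object, carrying the $K_m$/$V_{\max}$ interval endpoints along for
uncertainty propagation.

One identifiability caveat is worth stating plainly. A characterization
design whose lowest substrate concentration (0.3125 µmol/mL) is ~17× $K_m$
contains almost no curvature information about $K_m$: under 15 % assay
noise the point estimate scatters over more than an order of magnitude,
which is consistent with the wide published interval on $K_m$ itself. The
asymptotic CIs own up to this (≈ 95 % joint coverage in Monte-Carlo), and
$K_m$ point estimates become reliable (within a factor of 2 in ≥ 95 % of
replicates) once the design spans the half-saturation region. The test
suite checks both statements separately; the fitter documentation states
the design precondition.

### The synthetic data generator

`simulate_rate_data()` produces `tibble(x, y, replicate)` datasets for the
three assay flavors plus a batch time course, with multiplicative
log-normal noise: $y = y_{\mathrm{true}} \cdot \varepsilon$,
$\log\varepsilon \sim \mathcal N(0, \sigma)$,
$\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$, so the noise respects
positivity and has the requested coefficient of variation. Seeding uses
`withr::with_seed`, so the caller's RNG state is untouched. The true
curve is stored in the `"y_true"` attribute and the generating parameters
in `"truth"`, making exact round-trip tests possible at `noise_cv = 0`.

By default the Michaelis–Menten flavor reports *instantaneous* initial
rates, which round-trip exactly through the fitter. Real endpoint assays
(measure TCA at 60 min, divide by time) are biased low at concentrations
near $K_m$ because substrate depletes during the incubation; passing
`endpoint_min = 60` generates that realistic, biased version from the
batch model instead. The generator is deliberately simple beyond this: no
pipetting serial correlation, no plate effects, and the same CV at every
design point.

## 2. Gastrointestinal transit

The GI model tracks eight states (cells, Phe, TCA in stomach and small
intestine, plus cumulative absorbed Phe and TCA) in *amounts* (CFU, µmol);
volumes enter only when converting to the concentrations that the rate law
needs.

**Gastric emptying** follows a power-exponential curve: the fraction of
stomach contents remaining at $t$ minutes is

$$
f(t) = 2^{-(t/t_{1/2})^{\beta}},
$$

and contents leave the stomach with the corresponding hazard rate

$$
k(t) = -\frac{f'(t)}{f(t)}
     = \frac{\ln 2 \,\beta}{t_{1/2}}\left(\frac{t}{t_{1/2}}\right)^{\beta-1}.
$$

The hazard form is the design decision that makes the per-state ODEs
consistent with the aggregate curve: every species in the stomach
(cells, Phe, TCA) empties with rate $k(t)$, so each individually follows
$f(t)$, and for $\beta > 1$ the hazard starts at 0 (an initial lag) and
grows. The dose vehicle volume (100 mL in the human parameterization)
empties together with the contents, so the stomach liquid volume is
$V_{\mathrm{st}} + V_{\mathrm{vehicle}} f(t)$.

**Gastric pH** falls postprandially as
$p(t) = (p_0 - p_{\min}) e^{-k_{\mathrm{pH}} t} + p_{\min}$, which shuts
PAL activity off in the stomach as acid overcomes the meal's buffering;
small-intestinal pH is constant. Luminal Phe (and TCA) in the small
intestine is absorbed with first-order rate $\lambda$. PAL flux in each
compartment is the kinetic law of Section 1 evaluated at that compartment's
concentrations and pH, scaled to amounts.

Since absorbed TCA is quantitatively converted to HA and excreted, the
model's *predicted urinary HA* equals total Phe consumed by PAL
(µmol; ×179.17/1000 for mg HA). This is the measurable biomarker linking
the model to in vivo data.

Two species parameterizations ship as registries (`gut_params("human")`,
`gut_params("nhp")`):

| parameter | human | NHP | units |
|---|---|---|---|
| `beta`, `t_half` | 1.12, 43 | 1.12, 24.5 | —, min |
| `ph0` → `ph_min` (`k_ph`) | 6.0 → 1.71 (0.02653) | 6.0 → 1.97 (0.004) | —, min⁻¹ |
| `ph_si` | 6.5 | 5.8 | — |
| `vol_st`, `vol_si` | 35, 54 | 17, 13.7 | mL |
| `lam` | 0.1019 | 0.1019 | min⁻¹ |
| `phe_st0`, `phe_si0` | 12108, 30.2 | 1513.41, 7.7 | µmol |
| `dose_vehicle_ml` | 100 | 0 | mL |

`phe_st0` is the stomach Phe of the default meal; passing `meal_phe_g`
rescales it (2 g Phe ↔ 12108 µmol in the human case).

## 3. Plasma Phe metabolism

Plasma Phe $P$ (mmol/L) in a one-compartment model of distribution volume
$V_d \cdot W$ obeys

$$
\frac{dP}{dt} = k_a G \cdot \frac{1}{M V_d W} + v_{\mathrm{npd}}
  - \underbrace{f_{\mathrm{PAH}} V_{\max}^{\mathrm{PAH}}
    \frac{P^2}{P^2 + K_m^{\mathrm{PAH}} P + K_m^{\mathrm{PAH}} K_a^{\mathrm{PAH}}}}_{\text{PAH (substrate activation)}}
  - \underbrace{V_{\max}^{\mathrm{tr}} \frac{P}{K_m^{\mathrm{tr}} + P}}_{\text{transaminase}}
  - \underbrace{P \cdot CL_r \cdot V_d}_{\text{renal}},
$$

where $G$ (mg) is Phe in the gut compartment, absorbed first-order at
$k_a = 0.25\ \mathrm{hr}^{-1}$, $M$ is the Phe molar mass, and
$v_{\mathrm{npd}}$ is a constant net protein-breakdown input. The renal
term is taken literally as written ($P \cdot CL_r \cdot V_d$, with $CL_r$
in (L/kg)/hr), which makes it a small (≈ 1 %) elimination pathway — as
`elimination_attribution()` confirms. Defaults (`blood_params()`): see the
table in `?blood_params`; the scenario input `f_pah` scales PAH activity
(0 = classical PKU, 0.01–0.02 = residual-activity phenotypes, 0.5 is used
as the heterozygote assumption, 1 = healthy).

**Meals** are discrete boluses added to the gut compartment by integrator
events: `meal_schedule()` splits the daily dietary Phe (default
2.5 g/day, the content of a 50 g-protein diet) across meals at 0/4/10 h
each day, and optionally removes a fraction or an absolute amount (mg,
clipped at the meal's content) from each meal before absorption — the hook
by which luminal consumption by the biotic, or a dietary prescription, acts.

**Fasting readout.** Simulations run long enough to reach the daily
periodic steady state (180 days by default for headline numbers; the
24-hour periodicity of the solution is tested directly), and
`fasting_phe()` reads plasma Phe 14 h after the final day's last meal —
a morning fasting draw after a 6 pm dinner. `fasting_equilibrium()`
cross-checks the meal-driven simulation against the meal-free algebraic
steady state (`v_npd` balancing the three elimination terms) by
`stats::uniroot`.

With these defaults the model's fasting predictions are ≈ 1154 µmol/L for
classical PKU, ≈ 837 and ≈ 656 µmol/L at 1 % and 2 % residual PAH
activity, ≈ 96 µmol/L for a heterozygote, and ≈ 65 µmol/L for a healthy
subject.

**Inversion.** `required_consumption_for_lowering()` finds by bisection
the daily luminal Phe consumption (mg/day, split over the meals) that
achieves a target percent lowering of the fasting readout; for a 30 %
lowering in classical PKU this is ≈ 777 mg/day. The companion
`diet_reduction_scan()` expresses the same axis as fractional diet
reduction (20 % / 50 % reductions lower fasting Phe by ≈ 20 % / 44 %).

## 4. Dose–response coupling

`phe_consumed_per_day()` runs the GI model once per administration (dose
taken with each meal; per-meal dietary Phe defaults to the daily total
divided by the administrations) and sums the predicted consumption, capped
at the dietary intake itself. `predict_lowering()` then feeds that
consumption into the blood model as an absolute per-meal removal and
reports percent lowering of the fasting readout. With three
administrations per day for 28 days in classical PKU, 10¹¹ CFU/day-level
dosing gives single-digit percent lowering and 2×10¹² CFU/day ≈ 36 %
lowering.

**Uncertainty bands.** With `with_ci = TRUE`, the pipeline is re-run at
the two corners of the $K_m$/$V_{\max}$ 95 % confidence box that bound
activity: (`km_lo`, `vmax_hi`) gives the high-activity bound (more
consumption, lower Phe) and (`km_hi`, `vmax_lo`) the low-activity bound.
This deliberately propagates *parameter* uncertainty only — corners of a
box rather than a full posterior — and is labeled as such in the outputs
(`lowering_lo`/`lowering_hi` etc.).

## Numerical choices

* All ODEs are integrated with `deSolve::ode` (lsoda), `rtol = 1e-8`,
  `atol = 1e-10` for the GI and blood models and `1e-10`/`1e-12` for the
  stiff-free in vitro batch; integration failures raise a
  `phesim_integration_error` instead of returning partial output.
* Meal boluses use deSolve events (`method = "add"`) at exact event times;
  the $t = 0$ bolus goes directly into the initial state.
* The gastric-emptying hazard at $t = 0$ is $0$ for $\beta > 1$ and
  $\ln 2 / t_{1/2}$ at $\beta = 1$; solvers never evaluate the singular
  $\beta < 1$ case with the shipped parameterizations.
* Root finding (`fasting_equilibrium()`,
  `required_consumption_for_lowering()`) uses `stats::uniroot` on
  verified sign-changing brackets; an unreachable target raises
  `phesim_domain_error`.
* Errors are classed (`phesim_invalid_input`, `phesim_fit_error`,
  `phesim_integration_error`, `phesim_domain_error`) and degenerate but
  recoverable fits warn with class `phesim_degenerate_fit`.
* Correctness is tested against independent fixed-step Euler oracles
  written directly from the rate laws, conservation laws (closed-vessel
  and GI mass balance to 10⁻⁶ relative), closed-form special cases
  (exponential gut decay, half-life of the emptying curve, hazard–curve
  quadrature consistency), and Monte-Carlo parameter recovery.

## Limitations

* The blood model is one-compartment with a constant protein-breakdown
  input; it has no protein-synthesis feedback, no large-neutral-amino-acid
  transport competition, and no inter-individual variability.
* The GI model treats absorption as a single first-order step and assumes
  complete TCA → HA conversion and urinary recovery.
* Confidence bands propagate only the $K_m$/$V_{\max}$ interval corners;
  GI and blood parameters are treated as fixed.
* The power-exponential emptying hazard is singular at $t = 0$ for
  $\beta < 1$; such parameterizations are not supported.
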