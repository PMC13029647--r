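---
title: "Models and methods in cobioleach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cobioleach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobioleach)
```

## The system

cobioleach analyses co-bioleaching experiments in which pyrite flotation
tailings and ground printed circuit board (PCB) dust are leached together by
an acidophilic, iron-oxidising microbial community. The experimental design
it targets is a two-reactor cascade: a first (control) chemostat receives
only tailings and fresh medium; its liquid phase — acid, ferric iron, and
cells — flows continuously into a second (experimental) reactor that also
receives PCB dust. The control reactor is the lixiviant generator and
inoculator; the experimental reactor is where PCB toxicity acts. The package
implements the quantitative models used to interpret such runs: the cascade
cell balance, the material balance for the stepwise PCB feed, growth-rate
estimation from cell counts, leaching stoichiometry and yields, batch-mode
process indicators, and community–exposure correlation, plus a seeded
synthetic-data generator that makes every estimator testable against known
truth.

## The cascade cell balance

With dilution rate $D$ (day$^{-1}$, the reciprocal of the 5-day retention
time, so $D = 0.2$ by default) and specific growth rates $\mu_1$, $\mu_2$
(day$^{-1}$) in the two reactors, the cell concentrations $X_1, X_2$
(in units of $10^7$ cells/mL) obey

$$\frac{dX_1}{d\tau} = X_1(\mu_1 - D), \qquad
  \frac{dX_2}{d\tau} = D X_1 + \mu_2 X_2 - D X_2.$$

At chemostat steady state in reactor 1, $\mu_1 = D$ and $X_1$ is constant —
the defining property of chemostat operation — and the second equation is
linear with constant coefficients:

$$X_2(\tau) = \frac{D X_1}{D - \mu_2} + C e^{(\mu_2 - D)\tau},
  \qquad C = X_{2,0} - \frac{D X_1}{D - \mu_2}.$$

`analytic_X2()` implements this closed form; `simulate_cascade()` integrates
the system numerically (deSolve `lsoda`, rtol $10^{-8}$, atol $10^{-10}$;
the system stiffens when $\mu_2 \ll 0$, and `lsoda` switches methods as
needed). Steady-state mode (reactor 1 held constant) is the default, since
that is the balance the closed form assumes; `steady_state = FALSE`
integrates both equations for transient $X_1$.

The long-run behaviour is classified by `classify_regime()` from the sign of
$\mu_2$ relative to $0$ and $D$: exponential growth ($\mu_2 > D$), a plateau
above $X_1$ ($D > \mu_2 > 0$), convergence to exactly $X_1$ ($\mu_2 = 0$),
and — the diagnostic case — a plateau *below* $X_1$, possible only with net
cell death ($\mu_2 < 0$). A sustained cell deficit in the experimental
reactor, despite continuous inoculation from the control, is therefore
direct evidence of a negative growth rate, i.e. toxicity-driven death.

Numerical choices worth stating:

* $\mu_2 = D$ makes the particular solution singular. The closed form
  refuses it with an instructive error, and the degenerate branch
  $X_2(\tau) = X_{2,0} + D X_1 \tau$ (linear growth, slope $D X_1$) is
  handled by the simulator and by the internal solution used in fitting.
  This avoids a silent division by zero at the boundary.
* Regime boundaries ($\mu_2 = 0$, $\mu_2 = D$) are compared with an absolute
  tolerance of $10^{-12}$: growth rates in this domain are order 0.1–1
  day$^{-1}$, so anything below that tolerance is numerically zero.
* `steady_state_X2()` returns $X_1$ *exactly* when $\mu_2 = 0$ rather than
  computing $D X_1 / D$, so the equality invariant holds to the bit.
* Trajectories are floored at zero (and flagged) as a guard, although with
  $X_1 > 0$ the inflow term keeps $X_2$ positive for any finite $\mu_2$.

## The PCB feed material balance

The in-reactor PCB dust concentration under the stepwise feed programme is
propagated by a constant-volume mixing balance: when $V_{added}$ mL of pulp
at inlet concentration $Y_i$ displaces the same volume of reactor pulp,

$$X_{i+1} = \frac{X_i\,(V_{total} - V_{added}) + Y_i\,V_{added}}{V_{total}}.$$

Each step is a convex combination of $X_i$ and $Y_i$ (so the series is
bounded by its inputs and converges geometrically to a constant feed), and
mass is conserved exactly: $(X_{i+1} - X_i) V_{total} = (Y_i - X_i)
V_{added}$.

`pcb_feed_schedule()` encodes the published continuous-mode programme:
15 steps ending on days 3–34, inlet 5 g/L through day 11, 12.5 g/L for the
steps ending days 14–22, and 37.5 g/L thereafter, with
$V_{added} = 400$ mL of a $V_{total} = 1000$ mL working volume. Two readings
embedded in that schedule deserve explanation, because the source tables do
not state them outright:

* **The 400 mL per-step replacement.** With a 5-day retention time the
  dilution rate is 0.2 day$^{-1}$, and with ~2-day sampling each step
  nominally exchanges 40% of the volume. A fixed 400 mL per step — including
  the three 3-day intervals (days 11→14, 22→25, 31→34) — is the only
  per-step volume that reproduces the published concentration series; strict
  $D\,\Delta t$ accounting over the 3-day gaps does not. The recursion
  therefore models the sampling-step bookkeeping actually used, not an exact
  chemostat clock.
* **Feed-switch timing.** The step *ending* on day 22 still uses the old
  12.5 g/L feed; 37.5 g/L applies from the step ending day 25. This is the
  only timing consistent with the published day-22 value of 11.9 g/L.

Full precision is carried between steps; rounding happens only at reporting.
The reproduction tolerance used in the tests is ±0.06 g/L against the
printed one-decimal values: half an ULP of the printed precision plus the
day-25 case, where the full-precision 22.15 g/L prints as 22.2. A companion
property checks that carrying *rounded* intermediates (one decimal) still
reproduces the series within ±0.1 g/L, so the result does not depend on an
unstated rounding convention.

`limit_concentration()` gives the closed-form limit of the recursion under a
constant feed and the step count to reach it within a tolerance
($n = \lceil \log(\varepsilon/|X_0 - Y|) / \log(1 - f) \rceil$ for replaced
fraction $f$).

## Growth-rate estimation

Rearranging the cascade balance gives the estimators:

$$\hat\mu_1(t) = D + \frac{X_1'(t)}{X_1(t)}, \qquad
  \hat\mu_2(t) = \frac{X_2'(t) - D X_1(t) + D X_2(t)}{X_2(t)}.$$

Derivatives come from finite differences: the three-point nonuniform central
formula at interior points (sampling in these experiments is irregular, with
2–3 day gaps) and two-point one-sided formulas at the ends. The control
series is linearly interpolated onto the experimental sampling times, with
no extrapolation — experimental points outside the control's span are
dropped. Zero counts are floored at half the smallest positive observed
count (with a warning) *only* in the pointwise estimator, where a division
by zero would otherwise occur; the global fit uses raw values.

`fit_mu2_constant()` fits a single $\mu_2$ by least squares between the
closed-form $X_2(\tau)$ and the observed counts, taking $X_1$ as the mean of
the interpolated control series and $X_{2,0}$ as the first experimental
count. The 1-D objective is minimised by `stats::optimize` over
$[-5, 3]$ day$^{-1}$, a bracket generously containing every physically
plausible rate in this system (observed rates are within $\pm 1.1$). The
internal solution handles the $\mu_2 = D$ boundary continuously, so the
objective has no singularity inside the bracket. Uncertainty comes from a
seeded residual bootstrap (default 200 resamples): residuals are resampled
with replacement onto the fitted curve, the fit repeated, and the half-width
reported as 1.96 bootstrap standard deviations. All seeded routines save and
restore the caller's RNG state.

Validation is by parameter recovery at the study conditions: with $D = 0.2$,
12 samples every 3 days, and 10% lognormal count noise, the global fit's
bias over 100 seeded replicates is well below 0.05 day$^{-1}$; the pointwise
estimator on a noise-free trajectory at 0.1-day spacing recovers a
generating $\mu_2 = -1.07$ day$^{-1}$ (the magnitude reported for the toxic
third stage) to better than 0.01 day$^{-1}$ at interior points.

## Leaching stoichiometry and yields

Pyrite biooxidation supplies both lixiviants: sulfuric acid and ferric iron.
The packaged reaction set (`bioleach_reactions()`) covers direct oxidative
pyrite dissolution, microbial ferrous-iron oxidation, ferric pyrite
leaching, base-metal leaching by ferric iron and by acid plus oxygen, and
metallic-nickel dissolution in sulfuric acid. The parser accepts plain-text
equations with trailing charges (`"FeS2 + 14 Fe+3 + 8 H2O -> 15 Fe+2 +
2 SO4-2 + 16 H+1"`); `Me` is a placeholder divalent metal so the generic
equations can be balance-checked symbolically and then instantiated per
metal (`instantiate_metal()`). `check_balance()` reports per-element and
charge residuals; all six packaged reactions balance exactly for Cu, Ni and
Zn. `pyrite_budget()` and `metal_leach_demand()` convert molar throughputs
into acid/iron/oxygen budgets using the balanced coefficient ratios (e.g.
16 H$^+$ and 15 Fe$^{2+}$ produced and 14 Fe$^{3+}$ consumed per mole of
pyrite on the ferric pathway); both are linear in their molar argument.

The control-corrected leach yield of a metal from the PCB dust is

$$Y_m = \frac{m_{LE} - m_{LC}}{X_i\, V_{total}\, \omega} \times 100\%,$$

where $m_{LE}$ and $m_{LC}$ are the metal masses in the liquid phase of the
experimental and control reactors, $X_i$ the in-reactor PCB concentration
(g/L), $V_{total}$ the working volume (L), and $\omega$ the metal's mass
fraction in the dust (`pcb_composition()`; Cu 2.6%, Ni 0.5%). A unit
decision had to be made here: the quantities in the numerator are taken as
*masses* (grams) of metal in the whole liquid phase — concentration times
liquid volume, computed upstream — which is the only reading under which the
formula is dimensionally a fraction. Yields outside $[0, 100]$ are reported
unclipped with an `in_range = FALSE` flag: a negative yield means the
control mobilised more metal than the experiment (control mismatch), and
values above 100% flag sampling or composition error; both are diagnostics
worth surfacing, not values to truncate.

## Batch-mode process indicators

Batch runs are summarised by four landmark times: first crossing of a
reference pH (1.2, falling) and Eh (800 mV, rising), the time of complete
ferrous-iron oxidation, and the lag-phase duration.

* Crossings are located by linear interpolation between the bracketing
  samples — the least-surprising refinement of tables reported at integer
  sampling days — and every metric also offers `snap = TRUE`, which reports
  the first sample time at or past the threshold, for like-for-like
  comparison with integer-day tables.
* "Complete oxidation" is operationalised as *sustained* depletion: the
  first sample below the detection limit with no later sample above it, so a
  transient dip does not count. The default LOD of 0.05 g/L is a practical
  floor for titrimetric iron determination and is configurable, since the
  method's true limit is rarely stated.
* The lag phase has no standard operational definition in these reports, so
  the package defines one and says so: the interpolated time at which the
  cell count first exceeds `k_fold` (default 2) times the initial count and
  is still above it at the next sample. The parameter is exposed so other
  conventions can be applied.

A monotonicity property follows from interpolation and is tested: raising a
falling threshold (pH 1.3 vs 1.2) can only make the crossing earlier or
equal.

## Community–exposure correlation

Genus relative-abundance tables are wide data frames (one row per sample,
metadata plus one percent column per genus) validated on construction:
abundances in $[0, 100]$, per-sample totals not exceeding 100, and totals
within 1 of 100 whenever an `Other` column closes the composition; partial
tables are accepted. `encode_exposure()` joins each sample's day to the
material-balance concentration series (most recent step value), with
control-reactor samples at zero; both a concentration encoding (g/L) and a
presence encoding (0/1) are supported, because published correlations in
this area rarely state which was used. `correlate_genera()` computes one
Pearson correlation per genus against the exposure (via `stats::cor`, with
explicit refusal of the undefined constant-vector case rather than a silent
`NA`). No multiple-testing correction is applied — the analyses this mirrors
apply none — and p-values (two-sided t) are off by default.

Published correlation values for this system (e.g. strong negative
correlations for *Ferroplasma* and *Sulfobacillus*) are treated as
qualitative context, not reproduction targets: the exact sample set and
exposure encoding behind them are not recoverable from the printed partial
abundances. What the package validates instead is directional: communities
generated with a programmed negative responder yield a negative fitted
correlation in essentially all seeded replicates.

## The synthetic-data generator

`generate_continuous_cascade()` and `generate_batch_run()` produce data with
the statistical structure the estimators assume, under one seeded RNG stream
per scenario (fixed seed ⇒ identical bytes; no time-based seeding).

The continuous generator holds the control reactor at chemostat steady state
(counts at `X1_steady`, default 200 × 10⁷ cells/mL, within the observed
100–350 range) and drives the experimental reactor's growth rate through a
piecewise-linear toxicity response to the current PCB concentration:

$$\mu_2(X) = \mu_{base}\max\!\left(0, 1 - \frac{X}{X_{tox}}\right)
           - \delta\,\frac{\max(0, X - X_{tox})}{X_{tox}}.$$

Defaults $\mu_{base} = 0.05$, $X_{tox} = 15$ g/L, $\delta = 0.78$ day$^{-1}$
are the simplest calibration reproducing the qualitative finding the model
exists to test: $\mu_2 \approx 0$ at tolerated loadings (≤ 12 g/L) and
$\mu_2 \approx -1.07$ day$^{-1}$ at the top concentration of 35.5 g/L. This
shape is an artifact choice, not a mechanistic claim. Because the PCB
concentration is piecewise constant between feed events, $X_2$ is propagated
*exactly*, interval by interval, with the closed form — the noise-free
generator output equals the model solution to machine precision (a property
the tests cross-check against independent ODE integration).

Noise models: cell counts get multiplicative lognormal noise (default CV
10%, mean-corrected so the expectation is unbiased); pH and Eh get additive
Gaussian noise (SD 0.03 and 8 mV); iron determinations get *relative*
Gaussian noise (SD 5%) truncated at zero and then censored at the 0.05 g/L
detection limit, mimicking a titrimetric assay — in particular, a depleted
ferrous pool stays at zero instead of being resurrected by additive noise.
Total iron is computed as the sum of the noised species, so the
`fetot = fe2 + fe3` invariant holds exactly in generated data.

The batch generator uses phenomenological shape templates with programmed
landmarks, so recovery can be scored against truth: delayed-logistic counts
(default lag 12 days, rate 1.2 day$^{-1}$, plateau 150 × 10⁷ cells/mL),
exponential pH decline after the lag from 1.7 towards 0.95, a sigmoidal Eh
rise from 630 to 880 mV, and a linear ferrous decline hitting zero at the
programmed depletion day. The final pH of 0.95 sits well below the 1.2
reference so that the reference crossing falls on the steep part of the
decline, where a crossing time is actually identifiable — batch runs of this
system do continue acidifying past the reference. The generator returns the
noise-free landmark times (computed by root-finding on the continuous
shapes) in a `truth` attribute.

Abundance tables are generated with a logistic response per genus (template:
*Leptospirillum* and *Acidithiobacillus* favoured, *Ferroplasma* and
*Sulfobacillus* suppressed by exposure), lognormal sample noise, and an
`Other` remainder closing each sample to exactly 100%.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mechanistic pH/Eh chemistry (no Nernst relation,
no speciation), substrate limitation (growth rates are constant or
exposure-driven, never Monod), solid-phase PCB consumption by leaching (the
material balance treats dust as conserved between feed events), adaptation
dynamics (the toxicity response is static), and the compositional coupling
of real 16S relative abundances. Recovery results certify the estimators
under the stated noise models, not the field validity of those models.

## Problem sizes used in validation

The packaged checks run at these sizes, chosen to exercise the study
conditions at desk scale: 200 random parameter draws for the closed-form
versus ODE comparison (relative tolerance $10^{-5}$ over 0–50 days); 100
seeded replicates for the $\mu_2$ fit-bias study (12 samples, CV 10%) and
for each directional community/stage-3 check; a 30-scenario grid (three
programmed lags × ten seeds) for batch landmark recovery, scored against
one sampling interval; a 0.1-day grid over 30 days for the pointwise
estimator. The full test suite runs in a few seconds.

## Known limitations

* The cascade model assumes equal dilution rates in both reactors and
  steady-state reactor 1; stage transitions in real runs briefly violate
  both, and the constant-$X_1$ assumption is asserted, not demonstrated.
* The dilution recursion's fixed 400 mL per sampling step reproduces the
  published bookkeeping but is not a strict chemostat clock over 3-day
  intervals (see above); users modelling a different rig should supply their
  own schedule.
* `fit_mu2_constant()` estimates a single constant $\mu_2$; over windows
  where toxicity rises, the estimate is an effective average, useful mainly
  for its sign and magnitude.
* The lag-phase and depletion definitions are operational conventions;
  results should be reported together with `k_fold` and the LOD used.
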