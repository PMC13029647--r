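# cobioleach

Quantitative analysis of **co-bioleaching experiments** in which pyrite
flotation tailings and ground printed circuit board (PCB) dust are leached
together by acidophilic, iron-oxidising microorganisms — for
biohydrometallurgy researchers running (or simulating) two-reactor cascade
chemostats and needing the models that interpret them.

In the cascade design, a control chemostat fed only tailings generates the
lixiviants (biogenic ferric iron and sulfuric acid) and continuously
inoculates a second, experimental reactor that also receives PCB dust. The
cell balance of the cascade is

```
dX1/dτ = X1 (μ1 − D)
dX2/dτ = D X1 + μ2 X2 − D X2
```

with dilution rate `D` (day⁻¹) and specific growth rates `μ1`, `μ2`
(day⁻¹). At chemostat steady state `μ1 = D`, `X1` is constant, and the
second reactor has the closed form

```
X2(τ) = D·X1/(D − μ2) + C·e^(μ2 − D)τ
```

whose long-run level sits **below** `X1` only if `μ2 < 0` — so a sustained
cell deficit in the PCB-fed reactor, despite continuous inoculation, is
direct evidence of toxicity-driven cell death. The package implements this
model (closed form, stiff-capable numerical integration, steady states,
regime classification), and around it:

* the **material-balance recursion**
  `X_{i+1} = (X_i·V_remaining + Y_i·V_added)/V_total` for the in-reactor PCB
  concentration under a stepwise feed programme, with the published
  continuous-mode schedule packaged (`pcb_feed_schedule()`);
* **growth-rate estimation** from cell-count series — pointwise via finite
  differences and globally by least-squares fit of the closed form, with a
  seeded residual bootstrap;
* **leaching stoichiometry**: a charged-species equation parser and
  element/charge balance checker for the pyrite and metal-leaching
  chemistry, plus molar acid/iron/oxygen budgets;
* the **control-corrected leach yield**
  `Ym = (m_LE − m_LC)/(Xi·V_total·ω) × 100%`;
* **batch-mode process indicators**: interpolated threshold crossings
  (pH 1.2, Eh 800 mV), sustained ferrous-iron depletion, lag-phase duration;
* **community–exposure correlation** for genus relative-abundance tables,
  with concentration and presence encodings of exposure;
* a **seeded synthetic-data generator** for batch and continuous runs, so
  every estimator is validated by parameter recovery against known truth.

## Worked example

```r
library(cobioleach)

## In-reactor PCB concentration under the stepwise feed programme
ser <- run_schedule(5, pcb_feed_schedule())
tail(ser, 3)
#>    day     conc
#> 14  29 31.97403
#> 15  31 34.18442
#> 16  34 35.51065
```

Starting from 5 g/L, the 400 mL-per-step mixing balance drives the reactor
to 35.5 g/L by day 34 under the 37.5 g/L feed — matching the published
series to one decimal at every sampling day.

```r
## Cascade model at the toxic-stage growth rate
p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
classify_regime(p)
#> [1] "BELOW_X1"
steady_state_X2(p)
#> [1] 31.49606
```

With `μ2 = −1.07` day⁻¹ the experimental reactor settles at ~31 × 10⁷
cells/mL — a 6-fold deficit against the control's 200, sustained only by the
continuous cell inflow.

```r
## Recover the growth rate from a synthetic toxic third stage
b <- generate_continuous_cascade(synthetic_scenario(seed = 1))
w <- which(b$counts_exp$time_days >= 22)
fit <- fit_mu2_constant(b$counts_control,
                        cell_count_series(b$counts_exp$time_days[w],
                                          b$counts_exp$count[w],
                                          "experimental"),
                        D = 0.2, seed = 1)
sprintf("fitted mu2 = %.3f +/- %.3f per day", fit$mu2, fit$half_width)
#> [1] "fitted mu2 = -0.294 +/- 0.201 per day"
```

The fitted rate is negative: over a window where toxicity is still rising,
the constant-`μ2` fit is an effective average, and its sign is the
diagnostic.

```r
## Copper yield: 0.091 g net Cu mobilised from 5 g/L dust at 2.6% Cu in 1 L
leach_yield(m_le = 0.091, m_lc = 0, xi = 5, v_total = 1,
            omega = pcb_composition()[["Cu"]])
#> $yield_pct
#> [1] 70
#>
#> $in_range
#> [1] TRUE

## Genus responses to exposure in the generated community
correlate_genera(abundance_table(as.data.frame(
  b$abundance[b$abundance$reactor == "experimental", ])))
#>               genus          r n defined
#> 1    Leptospirillum  0.9996394 3    TRUE
#> 2 Acidithiobacillus  0.9983900 3    TRUE
#> 3       Ferroplasma -0.9998977 3    TRUE
#> 4     Sulfobacillus -0.9942641 3    TRUE
#> 5             Other  0.9753989 3    TRUE
```

The programmed negative responders (*Ferroplasma*, *Sulfobacillus*) come
out strongly negatively correlated with PCB exposure, the tolerant genera
positively — the directional pattern the analysis is designed to detect.

See `vignettes/cobioleach-methods.Rmd` for the models, their assumptions,
the numerical choices, and what the synthetic generator does and does not
emulate.

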