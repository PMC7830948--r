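# plnopt

Design-of-experiments tooling for nanoparticle formulation optimization.
`plnopt` is aimed at formulation scientists running small response-surface
studies of polymer–lipid hybrid nanoparticles (PLNs): particles with a
poly(lactic-co-glycolic acid) (PLGA) core, a lecithin shell, and a poloxamer
surfactant, whose mean particle size and drug entrapment efficiency (EE%)
must be traded off by choosing the three component amounts.

The package covers the full computational pipeline of such a study:

* **Box–Behnken designs** — the classical 3-factor, 3-level construction
  (12 edge midpoints plus replicated centers; 15 runs with 3 centers), with
  coded ↔ actual factor conversion: `coded = (actual − center)/((high − low)/2)`.
* **Quadratic response-surface fits** — ordinary least squares on coded
  levels of the full second-order polynomial

  *Y = b₀ + b₁x₁ + b₂x₂ + b₃x₃ + b₁₂x₁x₂ + b₁₃x₁x₃ + b₂₃x₂x₃ + b₁₁x₁² +
  b₂₂x₂² + b₃₃x₃²*

  with prediction, checkpoint analysis, and diffable text serialization.
* **Derringer–Suich desirability optimization** — per-goal desirabilities
  d ∈ [0, 1] (minimize / maximize / in-range, with weights and importances),
  combined as the importance-weighted geometric mean
  *D = (∏ dᵢ^rᵢ)^(1/Σrᵢ)*, maximized by seeded multi-start L-BFGS-B over
  the factor cuboid; plus design-space (overlay) feasibility masks.
* **Characterization arithmetic** — encapsulation efficiency
  *EE% = 100·(W_total − W_free)/W_total*; cumulative dissolution release
  with the sampling-replacement correction *Mₙ = CₙV + v·Σᵢ₌₁…ₙ₋₁ Cᵢ*;
  the 10× sink-condition rule; and comparative-Ct (2^−ΔΔCt) relative gene
  expression against a housekeeping reference.
* **Seeded simulators** for every input the pipeline consumes (quadratic
  surfaces with Gaussian noise, first-order dissolution with withdrawal
  bookkeeping, grouped qPCR Ct tables), so everything is testable without
  lab data.

A packaged fixture set (`pln_factors()`, `pln_design()`, `pln_goals()`,
`pln_solutions()`) reproduces a published 15-run PLGA–lecithin 5-fluorouracil
formulation study end to end.

## Worked example

Fit both responses of the packaged study and optimize the formulation:

```r
library(plnopt)

design <- pln_design()                # 15-run Box–Behnken, responses attached
size_model <- fit_quadratic(design, "particle_size")
size_model
#> Quadratic response-surface model for 'particle_size' (coded factors: plga, lecithin, poloxamer)
#>      b0      b1      b2      b3     b12     b13     b23     b11     b22     b33
#> 150.000   7.125  18.625  -4.500   9.000   5.250  -6.750   7.750  14.750  -6.500
#> R2 0.9757 | adj R2 0.9320 | residual SD 5.074 on 5 df

ee_model <- fit_quadratic(design, "ee")
predict_response(size_model, c(plga = 67.5, lecithin = 69.9, poloxamer = 1.5))
#> 141.1566   # nm, at the study's selected optimum settings
predict_response(ee_model, c(plga = 67.5, lecithin = 69.9, poloxamer = 1.5))
#> 75.60291   # % EE at the same settings

sol <- optimize_desirability(list(size_model, ee_model), pln_goals(),
                             n_starts = 64, seed = 1)
sol[1, ]
#>   rank    plga lecithin poloxamer particle_size      ee d_particle_size d_ee desirability
#> 1    1 72.0712  86.7875       1.5       139.091 75.6008        0.998723    1     0.999915
```

The intercept 150.0 is the mean of the three center runs — a property of
Box–Behnken designs worth checking by eye. The optimizer's top solution
(PLGA 72.1 mg, lecithin 86.8 mg, poloxamer 1.5% w/v; predicted 139.1 nm and
75.6% EE) lands on the same settings as the first solution reported by the
original study's DoE software: the importance-5 maximize goal pins EE at its
upper limit while particle size drops to just above its observed minimum.

See the vignette (`vignettes/formulation-optimization.Rmd`) for the model
conventions, the desirability construction, simulator design, and numerical
choices.

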