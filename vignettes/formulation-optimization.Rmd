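---
title: "Optimizing a nanoparticle formulation with Box-Behnken designs and desirability functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a nanoparticle formulation with Box-Behnken designs and desirability functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnopt)
```

## The problem

Hybrid polymer-lipid nanoparticles (PLNs) — a PLGA core stabilized by a
lecithin shell, dispersed with a poloxamer surfactant — are a carrier system
for poorly behaved drugs such as 5-fluorouracil. Two properties decide
whether a formulation is worth taking forward: the mean particle size
(smaller particles disperse and penetrate better) and the entrapment
efficiency, EE% (how much of the dose actually ends up inside the
particles). Both depend nonlinearly and jointly on the amounts of polymer,
lipid and surfactant, so trial-and-error screening is wasteful.

The standard answer in pharmaceutics is response surface methodology (RSM):
run a small, structured experiment over the three factors, fit a quadratic
polynomial to each response, and search the fitted surfaces for the settings
that best trade the responses off against each other. `plnopt` implements
that pipeline end to end, together with the characterization arithmetic that
surrounds it in a formulation study (encapsulation efficiency, dissolution
release with sampling correction, sink-condition checks, and comparative-Ct
gene expression for downstream pharmacology).

## The design: a three-factor Box-Behnken

A Box-Behnken design places each factor at three levels, coded -1/0/+1. For
three factors it consists of the 12 midpoints of the cube's edges — every
(+/-1, +/-1) combination over each factor pair, with the third factor at its
center — plus replicated center points; with 3 center runs that is the
classical 15-run design. It supports a full quadratic model while never
combining two factors at their extremes simultaneously, which matters when
extreme corners are physically awkward to prepare.

Coding uses the half-range: `coded = (actual - center) / ((high - low) / 2)`.
The packaged study's levels are not all perfectly symmetric about their
centers (lecithin runs 66.67 / 133.34 / 200 mg per 100 mL), so the coded low
level of lecithin is -1.00008 rather than exactly -1. We keep the printed
center at coded 0 — the optimizer solutions depend on it — and accept coded
magnitudes up to 1 + 1e-3 as "in design". `bbd_design()` emits edge runs in
factor-pair order then centers; run order is not algorithmically meaningful
for a least-squares fit (a dedicated test confirms permutation invariance),
so the printed run order of the study is preserved only by the fixture
loader `pln_design()`, not by the generator.

```{r design}
facs <- pln_factors()
design <- pln_design()
design[c(1, 11, 13), ]
```

## The model: a full 10-term quadratic per response

Each response is fitted by ordinary least squares on the coded levels:

$$Y = b_0 + b_1 x_1 + b_2 x_2 + b_3 x_3 + b_{12} x_1 x_2 + b_{13} x_1 x_3 +
b_{23} x_2 x_3 + b_{11} x_1^2 + b_{22} x_2^2 + b_{33} x_3^2$$

Always all 10 terms: no stepwise reduction, because dropping terms changes
predictions at off-design settings and the study this package reproduces
reports none. Fitting on coded rather than actual units makes coefficients
comparable across factors and is prediction-invariant. Responses enter as
per-run means; the per-run standard deviations of the packaged study are
carried as `_sd` metadata but do not weight the fit, since replicate-level
data are not available. With 15 runs and 10 terms the residual has 5 degrees
of freedom; the F statistic and p value are exposed as plain diagnostics and
drive no decisions.

```{r fit}
size_model <- fit_quadratic(design, "particle_size")
ee_model <- fit_quadratic(design, "ee")
size_model
```

For a Box-Behnken design the intercept equals the center-run mean (here
exactly 150 nm), a useful hand check. `checkpoint_analysis()` tabulates
observed against predicted at any extra runs to probe the polynomial's
predictive ability.

## The optimization: Derringer-Suich desirability

Each goal maps a predicted response onto [0, 1]. For a minimize goal with
limits (L, U) and weight w, `d = ((U - y)/(U - L))^w` between the limits,
clamped outside; maximize goals mirror it; `in_range` goals are hard box
constraints (d = 1 inside, 0 outside). The overall desirability is the
importance-weighted geometric mean `D = (prod d_i^r_i)^(1/sum r_i)`, so any
fully undesirable goal zeroes D.

Two conventions had to be fixed because the original study delegates them to
its DoE software. First, the functional form itself: we use the standard
one-sided Derringer-Suich construction; all weights in the packaged goal set
are 1, so the curvature exponent never departs from linear in reproduction
runs. Second, whether the importances of factor `in_range` goals (importance
3 each in the packaged set) count in the denominator `sum r_i`: we include
them by default (`include_range_importance = TRUE`), matching common DoE
software. Since those goals contribute d = 1 inside their box, including
them only rescales D monotonically — it cannot reorder solutions — and the
flag makes the choice switchable. Under this convention the study optimum
scores D of about 0.9999; with factor importances excluded it is about
0.9998. The study itself prints both 1 and 0.948 for its optimum's
desirability in different places, an internal inconsistency that cannot be
resolved from the printed tables; we therefore treat the predicted responses,
not D, as the quantities worth reproducing.

The search is multi-start bounded L-BFGS-B from a Latin-hypercube sample of
start points (seeded, so runs are reproducible), over the cuboid formed by
intersecting each factor's range with its `in_range` goal. A quadratic D
surface is smooth but can be multimodal after the desirability transform,
hence the multi-start; 64 starts makes the result seed-stable to better than
1e-3 in D on this problem, and an exhaustive 0.01-coded-resolution grid
search in the test suite confirms the optimum. Local optima closer than 0.02
coded units are merged (the study's software printed three near-duplicate
solutions; a deduplication radius and a tie-break — predicted size ascending
at equal D — are needed for a stable ranked list).

```{r optimize}
sol <- optimize_desirability(list(size_model, ee_model), pln_goals(),
                             n_starts = 64, seed = 1)
sol[1, ]
```

The top solution sits at the EE upper limit (importance 5 pins it there)
with a predicted size just above the observed minimum — the same region as
all three solutions reported by the original software. `design_space()`
evaluates the fitted surfaces on a regular grid and masks where all
constraints hold, the classical overlay plot's gray region, reporting the
feasible volume fraction; grids are evaluated in chunks so fine resolutions
stay memory-bounded.

## Characterization arithmetic

`ee_percent(w_total, w_free)` is the mass-balance definition
`100 (W_total - W_free) / W_total`, with `w_free > w_total` rejected as an
assay/blank problem.

`cumulative_release()` corrects dissolution data for sampling with medium
replacement. Withdrawing an aliquot of volume v at each time removes drug
from the vessel, so the raw concentration reading underestimates cumulative
release; the standard additive correction is
`M_n = C_n V + v * sum_{i<n} C_i`. The correction convention is not stated
in the study this package reproduces — only that samples were withdrawn and
replaced — so the additive form, the standard in dissolution practice, is
adopted and documented here. Non-monotone cumulative curves are flagged with
a warning but reported as computed (clipping would hide data problems);
values above 110% of dose raise an error, since that signals a unit mistake
rather than noise.

`sink_condition()` implements the usual 10x rule: dissolution is
solubility-unlimited when the vessel volume is at least 10 times
`dose / saturation_solubility`.

`fold_change_ddct()` is the comparative-Ct method: per sample
`dCt = Ct_target - Ct_reference`, calibrated by the arithmetic mean dCt of
the control group (the study does not say whether a mean or a single
calibrator sample was used; the mean is the common choice and is documented
here), then `fold = 2^-ddCt`. Group summaries are mean and SD of per-sample
folds, matching the usual mean +/- SD presentation. Amplification-efficiency
correction (Pfaffl) is out of scope.

## The simulators, and what passing tests show

Three seeded generators emulate the statistical structure each analysis
assumes, so the pipeline is testable with no external data:

* `simulate_design_responses()` evaluates a known 10-coefficient quadratic
  on the generated design and adds i.i.d. Gaussian noise per response — the
  simplest structure consistent with mean +/- SD reporting of replicate
  means. Noiseless surfaces must be recovered to 1e-8; with noise sd sigma,
  the Monte-Carlo SD of each linear coefficient is sigma/sqrt(8) (each
  linear column of the 3-factor design has sum of squares 8 and is
  orthogonal to the rest), checked at 500 replicates within 15%.
* `simulate_release()` integrates first-order release
  `M(t) = dose * plateau * (1 - exp(-kt))` with explicit bookkeeping of each
  withdrawn aliquot, and exposes the true released-mass trajectory; the
  replacement correction must recover it to 1e-9 when measurement noise is
  zero. First-order kinetics is purely a test signal — the package fits no
  release model. Measurement noise is multiplicative (constant CV), the
  usual behavior of spectrophotometric assays.
* `simulate_ct()` draws grouped target/reference Ct values with Gaussian
  cycle noise; a group's log2 shift of s must be recovered as a fold change
  of 2^s up to Monte-Carlo error (a 2-fold shift at n = 50 over 200
  replicates is recovered within 5%; the small upward bias of averaging
  lognormal folds is well inside that band).

What these simulations do not emulate: real DLS size distributions (only
run-mean sizes), batch effects or drifts across runs, non-Gaussian assay
error, qPCR efficiency differences between target and reference, or any of
the in-vivo endpoints. Passing tests therefore demonstrate correctness of
the arithmetic and the optimizer on data with the assumed structure, not
robustness to real-world artifacts.

Test problem sizes (500-replicate coefficient recovery, 200-replicate Ct
recovery at n = 50, 0.01-coded grid confirmation of the optimum) were chosen
so the whole suite runs in well under a minute while keeping Monte-Carlo
error far below the asserted tolerances.

## Numerical choices and degenerate inputs

* OLS is solved by `lm()` (QR); an explicit normal-equations solve serves as
  an independent oracle in the tests, with agreement to 1e-8 required.
* Rank-deficient designs (fewer than 10 informative runs, duplicate-only
  points) raise errors rather than returning NA coefficients.
* Predictions at settings with any coded magnitude above 2 are computed but
  flagged as extrapolation (attribute plus warning).
* Desirability bases are clamped to [0, 1] before the weight exponent is
  applied, so fractional weights never see a negative base.
* `overall_desirability()` works in log space and short-circuits at any
  d = 0, avoiding underflow with large importances.
* The optimizer merges local optima within 0.02 coded units and ranks by D
  descending, tie-breaking by the first minimize-goal prediction ascending.
* Model records serialize at 17 significant digits, so text round-trips
  preserve predictions to machine precision.

## Known limitations

Only the 3-factor Box-Behnken construction is implemented; other design
families (central composite, D-optimal) and blocking/randomization are out
of scope, as are weighted or mixed-model fits, two-sided "target-is-best"
desirability, release-kinetics model fitting, and statistical testing across
expression groups. The packaged study's own printed inconsistencies — a
"138 nm" minimum size in the text against 139 nm in the design table, and
the two conflicting desirability values — are shipped as printed and noted,
not resolved. One further wrinkle: the printed design-table responses are
rounded to 3-4 significant figures and the reported solution settings to 3,
which is why reproduction tolerances of +/-0.5 nm (size) and +/-0.25% (EE)
are used for the predicted optima rather than exact equality.
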