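---
title: "Models and methods for selective berry foraging from bear telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for selective berry foraging from bear telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Brown bears in managed boreal forests depend on ripe berries — chiefly
bilberry (*Vaccinium myrtillus*) and lingonberry (*V. vitis-idaea*) — to
build fat reserves during autumn hyperphagia before hibernation. Berry
occurrence, abundance and sugar content vary strongly with forestry-driven
habitat (clearcut, young forest, mature forest, bog), terrain, and date
within the short ripening season, and bears may or may not place their
foraging where berries are better than the landscape average.

`bearberry` implements the complete analysis chain for a
*used-versus-available* study of this question:

1.  classify berry-foraging bouts from 30-minute GPS fixes;
2.  place 1-m² sample plots at used positions (with the field protocol's
    digit-based offset and relocation rules) and at random available
    positions;
3.  model berry counts with species-specific **hurdle mixed models** — a
    binomial (logit) occurrence part and a zero-truncated negative binomial
    (log) abundance part — plus a seasonal-shift count model and Gaussian
    sugar-content models;
4.  reduce full models by likelihood-ratio backward selection, compare
    factor levels with single-step adjusted contrasts, and draw
    population-level prediction curves.

Because telemetry and plot inventories of this kind are rarely shared, the
package ships a **synthetic study generator** with fully recorded ground
truth, so that every stage — classifier, likelihoods, selection procedure,
pipeline plumbing — is testable end to end.

## Trajectory classification

Collars record a fix every 30 min (48/day). Berry foraging appears as runs
of *consistently slow, meandering* movement, operationalised as maximal
runs of at least 3 consecutive fixes in which **every step** (Euclidean
distance between successive fixes) lies in [25, 300] m. Failed fixes
invalidate the step before and after them and therefore terminate runs;
they are kept as rows so gaps are explicit. Segments with any fix within
200 m (inclusive) of a known attractant site (slaughter dumps, oat fields)
are discarded whole.

Two readings of the 25–300 m rule are possible — per step, or on the
run's total path length. The slow-movement rationale describes each
30-minute interval, so the per-step rule is the default; the alternative is
available via `find_foraging_segments(rule = "total")`.

Plots are sampled once per segment, at the **second** fix (1-based), to
limit spatial autocorrelation between samples; segments of ≥ 7 fixes
(> 3.5 h) are additionally sampled at the **second-to-last** fix.

## The plot protocol

From a sampled GPS position the field crew walks 0–9 m — the last digit of
the truncated integer Y coordinate — in a cardinal direction taken from the
last digit of the X coordinate. The digit-to-direction bijection is not
itself important (any fixed assignment is statistically equivalent); the
default maps digit mod 4 = 0,1,2,3 to N,E,S,W and is configurable. If a
selected plot shows obvious foraging signs (stripped twigs, fallen
berries), it is reflected through the GPS position to the opposite side at
the same distance — an involution, so applying it twice restores the
original plot.

Available plots are drawn uniformly over the landscape. Rows in habitat
"other" and rows with incomplete covariates are excluded before modelling,
and each random plot is assigned to one of the monitored bears uniformly at
random so a bear-level random intercept can be shared across the design.

## Statistical models

All models are special cases of one likelihood: a GLMM with a single
random intercept \(b_g \sim N(0, \sigma^2)\),

\[
  y_{ij} \mid b_j \;\sim\; f(y \mid \eta_{ij}),\qquad
  \eta_{ij} = x_{ij}'\beta + b_j,
\]

with \(f\) one of

* binomial with logit link (berry occurrence; sugar selection of plots),
* negative binomial with log link, variance \(\mu + \mu^2/\theta\)
  (seasonal-shift counts),
* **zero-truncated** negative binomial with log link (abundance among
  occupied plots), with
  \(P(k) = \mathrm{NB}(k;\mu,\theta)\,/\,(1 - (\theta/(\theta+\mu))^\theta)\)
  for \(k \ge 1\),
* Gaussian with identity link (sugar content, %Brix).

The hurdle model is the pair (binomial occurrence on all rows,
zero-truncated abundance on the positive rows); its likelihood factorises,
so the two parts are estimated independently and the total log-likelihood
is their sum.

### Estimation

The marginal likelihood integrates the random intercept per group by
**adaptive Gauss–Hermite quadrature**: for each group the integrand's mode
is found by a Newton iteration and the quadrature nodes are centred and
scaled there. One node is exactly the Laplace approximation; the default
10 nodes leave quadrature error far below any tolerance used here
(10 vs 20 nodes move the log-likelihood by < 1e-4 on the bundled test
problems). Dispersion (\(\theta\), or the residual SD) and \(\sigma\) are
estimated jointly on the log scale; fixed-effect columns are standardised
internally for conditioning and mapped back exactly. The score is
evaluated as the posterior-weighted derivative at the quadrature nodes,
and standard errors come from the inverse observed information
(central-differenced analytic gradient). The quadrature kernel is
compiled (C++); a pure-R reference implementation of the same likelihood
is retained (`backend = "R"`) and the two agree to near machine precision,
which the test suite asserts.

Convergence is reported honestly: a fit flags non-convergence, a
non-positive-definite information matrix, and (for the binomial family)
likely complete separation.

### Model reduction and inference

Full models contain plot type, habitat, the landscape characteristics
(elevation, NDVI, slope, aspect) that survive a variance-inflation-factor
screen (cut-off 3, iteratively removing the worst predictor), sampling
date, and the plot type × habitat and plot type × date interactions.
**Backward selection** repeatedly refits without each currently droppable
term (marginality respected: interactions drop before their main effects),
removes the least significant term by likelihood-ratio test while its
p-value exceeds α = 0.05, and stops when all remaining terms are
significant. The trace of every test is recorded.

Pairwise comparisons of factor (or interaction-cell) means are computed as
linear contrasts \(c'\hat\beta\) with SE \(\sqrt{c'Vc}\) and familywise
**single-step** adjustment: adjusted p-values are tail probabilities of
\(\max|z|\) under the joint normal with the correlation implied by the
coefficient covariance, evaluated by seeded Monte-Carlo sampling (default
1e5 draws; with a single contrast this reduces to the raw p-value, and for
independent contrasts to the Šidák formula, both verified in the tests).

Population-level predictions set the random intercept to zero, form a Wald
interval on the link scale and back-transform; seasonal curves are drawn
over the date window at the mean elevation.

Because a retained plot type × habitat interaction makes the plot-type
main coefficient refer only to the reference habitat, the summary
`plot_type_effect()` reports the used-vs-available contrast on the link
scale averaged over habitats, at mean numeric covariates.

## The synthetic study generator

`make_scenario()` generates one complete study from a master seed:

* **Landscape** (`gen_landscape()`): 140 × 140 cells of 25 m. Habitat from
  two independent smooth random fields thresholded at the class-share
  quantiles (defaults 10 % bog, 8 % clearcut, 42 % young, 40 % mature; the
  scenario default adds 3 % "other" so the habitat filter is exercised);
  smooth elevation rescaled to 200–600 m; slope (degrees) and cardinal
  aspect from the elevation gradient; NDVI in [−1, 0.86] increasing with
  local young-forest density (dense regrowth is greener) and reduced on
  bogs.
* **Berry fields** (`berry_field_params()`): per-species hurdle
  coefficients whose habitat, elevation and date effects take the
  magnitudes reported for this system — bilberry occurrence and abundance
  *declining* with date (−0.022, −0.008 per day), lingonberry *rising*
  (+0.07, +0.028), occurrence highest in mature forest for bilberry and on
  clearcuts for lingonberry, and a lingonberry NDVI penalty (−2.3).
  Crowberry is generated rare and highly zero-inflated but never modelled.
  A bear-level random intercept (variance 0.2) on both linear predictors
  provides the grouping structure the mixed models assume.
* **Sugar** (`sugar_params()`): Gaussian TSS around species means 8.48
  (bilberry), 12.04 (lingonberry), 5.57 (crowberry) %Brix with SDs near
  1.4, covariates centred at reference values (400 m, NDVI 0.44, day 233)
  so the marginal means stay at those values; a plot-type effect (+0.579)
  applies to lingonberry only.
* **Movement** (`movement_params()`, `simulate_bear()`): a pragmatic
  3-state (rest / forage / travel) switching walk at 30-min steps — not a
  fitted behavioural model; it only needs to produce the step-length
  regimes the classifier targets (rest < 25 m, forage 25–300 m, travel
  > 300 m) at a realistic tempo (~2 qualifying bouts per bear-day, mean
  bout length ≈ 5 fixes). Forage headings are chosen among 8 candidates
  with probability ∝ exp(w · a), where a is the standardised expected
  bilberry count at the candidate endpoint; fixes fail i.i.d. with
  probability 0.08 (≈ 92 % fix success). Seven bears (four males, three
  females) are tracked for 28 days from day 219.

### Design decisions worth recording

**The generator is exactly the model family.** Berry counts are generated
from the same hurdle family the models fit, so parameter recovery is
well-posed. This has a subtle consequence that shaped the design:

* Unmodelled spatial heterogeneity ("patchiness") can only be placed on
  the **occurrence** predictor. For binary data, an omitted white-noise
  logit component is absorbed as pure attenuation — occurrence data remain
  Bernoulli and all tests stay calibrated. Placed on the **abundance**
  predictor it would turn counts into an NB–lognormal mixture; the
  resulting lack of fit is soaked up by whichever interaction terms
  separate the arms of the design, and the backward-selection
  false-retention rate for null plot-type effects inflated severalfold in
  experiments. The default therefore sets the abundance patchiness SD to 0
  (a deliberate misspecification experiment can switch it back on via
  `berry_field_params()`).
* Consequently, bilberry **occurrence** selection emerges mechanistically:
  bears steer toward cells whose occurrence patch (SD 1.1 on the logit
  scale, white at the 25-m cell scale so plots are independent draws) and
  covariates promise more bilberries. A movement-emergent **abundance**
  effect is impossible under exact-family generation (given covariates,
  abundance is identical everywhere), so the used-plot abundance advantage
  enters as the generator's bilberry plot-type coefficient (0.828 on the
  log scale — the magnitude reported for this system), interpreted as
  within-plot microsite selection by the foraging bear. Lingonberry and
  crowberry have no plot-type effects anywhere: the lingonberry retention
  rate measures the selection procedure's false-positive rate, which for
  three plot-type terms (main + two interactions) at α = 0.05 is the
  familywise ≈ 1 − 0.95³ ≈ 14 %.
* The patch field is white at the cell scale (one lattice point per cell).
  Coarser fields made plots along one bear's track repeated draws of the
  same patch values — spatial pseudoreplication that overdispersed the
  plot-type estimator.
* **Random plots carry the bear structure too.** Each random plot is
  pre-assigned to a bear and its counts include that bear's random
  intercept. Generating the bear effect on the used arm only, while the
  fitted model shares one bear intercept across both arms, makes the
  plot-type estimator overdispersed (the per-bear effects do not cancel
  between arms); with a generator consistent with the fitted model the
  estimator is calibrated.
* Berry plots record the day of the *fix*; the field delay between a fix
  and its plot visit (median 3 days in studies of this kind) is not
  simulated.
* Counts of different species are drawn independently, matching the
  near-zero cross-species count correlation reported for this system.

### What passing tests do and do not show

The generator emulates the hurdle structure, the seasonal trends, the
habitat composition, the movement regimes and the fix-failure process. It
does **not** emulate GPS position error, berry depletion by foraging,
within-plant clustering of lingonberries, observer error in counts, or the
fix-to-visit delay. Recovery and calibration results on synthetic data
therefore validate the *implementation* (likelihoods, quadrature,
selection logic, plumbing) and the *design's* statistical behaviour under
ideal assumptions — not the field validity of any particular biological
conclusion.

## Numerical choices

* Adaptive quadrature, default 10 nodes (`nAGQ = 1` is Laplace). The
  replicated simulation studies in the test suite use 5 nodes; on these
  grouped designs 5 vs 10 nodes change log-likelihoods by ≪ 1e-4.
* Inner Newton for the group modes: ≤ 30 damped steps, tolerance 1e-8,
  warm-started between likelihood evaluations.
* Linear predictors for the count families are clamped at ±30 before
  exponentiation; `log(1 - P(0))` uses the stable `log1mexp` form.
* Boundary variance estimates: \(\log\sigma\) is unconstrained, so
  \(\hat\sigma\) can approach 0 smoothly; "degenerate nesting" tests
  verify that fixed effects then match the no-random-effect fit.
* Nearest-cell raster lookup with a deterministic lower-index tie-break on
  cell boundaries (no interpolation — habitat is categorical and the
  continuous layers follow the same convention for consistency).
* Backward selection refits are warm-started from the enclosing model and
  skip the information matrix until the final model.
* Problem sizes in the test suite are chosen to make each check sharp but
  quick: e.g. the degenerate-nesting comparison uses n = 20 000 in 5
  groups so the boundary variance estimate is numerically negligible
  relative to the 1e-3 agreement tolerance; recovery studies use 200
  replicates of the study-sized design (~350 used + 375 available plots,
  7 bears); selection-pattern studies use 100 full scenario replicates.

## Known limitations

* Only a single random intercept (no crossed or nested random effects, no
  random slopes) — sufficient for these designs, by construction.
* The single-step adjustment is Monte-Carlo based; adjusted p-values carry
  MC error ≈ 0.001–0.005 at the default 1e5 draws.
* The hurdle abundance part refuses to fit with fewer than 30 positive
  rows rather than returning fragile estimates.
* The movement model is phenomenological; it is not suitable for inference
  about movement itself.
* Stepwise selection has the usual selective-inference caveats: the
  false-retention rate for a term family is the familywise α, and
  coefficients of retained borderline terms are winner's-curse inflated.
  The package reports full selection traces so users can see every test.
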