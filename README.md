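# bearberry

Analysis of **selective berry foraging by GPS-collared brown bears** in
managed boreal forest: during autumn hyperphagia, do bears place their
foraging where bilberries (*Vaccinium myrtillus*) and lingonberries
(*V. vitis-idaea*) are more likely to occur, more abundant, and sweeter
than at random locations in the landscape?

The package implements the full used-versus-available pipeline for
movement ecologists and wildlife biostatisticians:

* **Trajectory classification** — berry-foraging bouts are maximal runs of
  ≥ 3 consecutive 30-min GPS fixes whose every step length lies in
  [25, 300] m; failed fixes break runs; segments near attractant sites
  (200-m buffer) are excluded; plots are sampled at the second fix (and
  the second-to-last fix of runs ≥ 7 fixes).
* **Plot protocol** — digit-based 0–9 m offsets, relocation away from
  foraging signs, random available plots, covariate annotation from
  gridded landscape layers (ESRI ASCII).
* **Models** — a single-random-intercept GLMM engine fitted by adaptive
  Gauss–Hermite quadrature with an analytic score and a compiled kernel.
  For counts `y` in plot `i` of bear `j`, the hurdle mixed model is

  ```
  occurrence:  P(y_ij > 0 | b_j)         = logit^-1(x_ij' beta + b_j)
  abundance:   y_ij | y_ij > 0, b_j      ~ ZTNB(mu = exp(x_ij' gamma + b_j), theta)
  b_j ~ N(0, sigma^2),   Var(y) = mu + mu^2 / theta (untruncated scale)
  ```

  plus a plain negative-binomial mixed model for the seasonal species ×
  date × habitat shift at foraging plots, and Gaussian mixed models for
  berry sugar content (total soluble solids, %Brix).
* **Inference** — VIF collinearity screen (cut-off 3), likelihood-ratio
  backward selection with marginality, single-step (max-|z|) adjusted
  pairwise contrasts, and population-level prediction curves.
* **Synthetic studies** — `make_scenario()` generates a landscape, berry
  fields, bear movement and plot inventories with recorded ground truth,
  so the entire pipeline is testable without field data.

## Worked example

```r
library(bearberry)

## one synthetic study: 7 bears x 28 days at 48 fixes/day, 375 random plots
dir <- tempfile()
make_scenario(dir = dir, seed = 1)
report <- run_analysis(dir, out_dir = file.path(dir, "report"), seed = 1)

report$summaries$n_segments
#> [1] 430
round(100 * report$summaries$fix_success, 1)
#> [1] 92.5
round(report$summaries$occurrence_pct$bilberry$foraging, 1)
#> [1] 72.2

## did bears select bilberry-rich plots? (log-scale used-vs-available effect)
subset(report$bilberry$abundance$coefficients, term == "plot_typeBear")
#>            term  estimate         se        z            p
#> 2 plot_typeBear 0.8748308 0.08393647 10.42253 1.956684e-25

## lingonberry abundance: plot type is dropped during backward selection
report$lingonberry$abundance$coefficients$term
#> [1] "(Intercept)"          "habitatclearcut"      "habitatmature_forest"
#> [4] "habitatyoung_forest"  "elevation"            "ndvi"
#> [7] "ordinal_day"

## seasonal shift: lingonberry rises while bilberry declines
subset(report$seasonal$coefficients,
       term == "specieslingonberry:ordinal_day")$estimate
#> [1] 0.06736864
```

The bilberry abundance effect (0.87 on the log scale, i.e. ~2.4× more
berries at used plots) is recovered from the generating value 0.828; the
seasonal species × date interaction (+0.067/day) reflects the generator's
opposing date trends; the lingonberry abundance model keeps habitat, NDVI
and date but drops plot type — the species-specific selection pattern the
pipeline is designed to detect. Exact numbers for other seeds differ by
sampling noise.

## Documentation

The methods vignette (`vignettes/berry-foraging-methods.Rmd`) describes
the models, the quadrature and selection machinery, every tunable
parameter of the synthetic generator with units and defaults, the design
decisions behind it, and known limitations.
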