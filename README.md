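# vasckill

Mechanistic prediction of chemotherapy response in vascularized tumors
from four measurable parameters.

## The problem

How much of a tumor does one round of chemotherapy kill? Cell-intrinsic
sensitivity measured in culture does not answer this: in tissue, drug
reaches cells by diffusing out of blood vessels while being taken up
along the way, so poorly vascularized tumors shield themselves behind a
transport barrier. `vasckill` implements a diffusion–uptake model of
this process for desk-scale analysis of histopathology and cell-culture
data, aimed at quantitative/mathematical oncology work with per-section
immunohistochemistry (IHC) tables and dose-response assays — the
motivating system being murine lymphoma (a drug-sensitive and a
drug-resistant line) treated with doxorubicin.

## The model

Around a straight cylindrical vessel of radius $r_b$, the steady-state
drug concentration $\sigma$ at scaled radius $\hat r = r/L$ satisfies

$$\frac{1}{\hat r}\frac{d}{d\hat r}\left(\hat r \frac{d\sigma}{d\hat r}\right) = \sigma,
\qquad \sigma(\hat r_b) = \sigma_0 ,$$

where $L = \sqrt{D/\lambda}$ is the diffusion penetration distance
(diffusivity over cellular uptake rate). The decaying solution is
$\sigma/\sigma_0 = K_0(\hat r)/K_0(\hat r_b)$ with $K_0$ the modified
Bessel function of the second kind. Averaging this profile over the
tissue annulus served by one vessel — outer radius
$\hat r_t = \hat r_b/\sqrt{BVF}$, where $BVF$ is the blood volume
fraction — and scaling by the maximal in-vitro kill fraction
$f^M_{kill}$ gives the fraction of tumor volume killed in closed form:

$$f_{kill} = f^M_{kill}\, BVF\;
\frac{2\sqrt{BVF}\,K_1(\hat r_b) - 2K_1\!\left(\hat r_b/\sqrt{BVF}\right)}
     {\sqrt{BVF}\,\hat r_b\,K_0(\hat r_b)\,(1 - BVF)} .$$

Everything on the right is measurable before treatment: $BVF$ from CD31
staining, $r_b$ from vessel cross-sections, $L$ from hypoxia-onset
distances, $f^M_{kill}$ from a culture assay.

The package provides, per module:

- **model core** — `kill_fraction()`, `scaled_concentration()`,
  `predict_curve()`, plus an independent adaptive-quadrature oracle
  (`kill_fraction_oracle()`) used by the tests;
- **histology** — `summarize_markers()`, `marker_ratio()`,
  `estimate_bvf()`, `estimate_vessel_radius()`,
  `estimate_penetration_distance()`;
- **in vitro** — `fit_hill_ic50()` (4PL), `fold_difference()`,
  `invitro_kill_ratio()`;
- **calibration** — `rescale_resistant()`, `fit_kill_model()`
  (bounded least squares with the linear parameter profiled out),
  `r_squared()`, with broom-style `tidy()`/`glance()`/`augment()` and
  `autoplot()`;
- **sensitivity** — `sensitivity_coefficient()`,
  `sensitivity_ranking()` (normalized single-parameter-variation
  coefficients);
- **synthetic data** — `synthetic_config()` and generators for every
  input table the pipeline reads;
- **pipeline** — `run_pipeline()` / `validate_inputs()` driven by a
  YAML or list config.

## Worked example

Simulate the study's 11-section kill dataset (5 sensitive + 6 resistant
sections, BVF ~ truncated normal around 0.038, true
$f^M_{kill} = 0.25$, $\hat r_b = 0.068$), rescale the resistant line by
the in-vitro kill ratio, and calibrate:

```r
library(vasckill)

sim <- generate_kill_dataset(synthetic_config(seed = 42, kill_noise_sd = 0))
fit <- sim$data |>
  rescale_resistant(factor = 3.5) |>
  fit_kill_model(seed = 1)
fit
#> <kill_fit>
#>   fkill^M   : 0.25
#>   r_b / L   : 0.068
#>   R-squared : 1
#>   n points  : 11
```

With measurement noise off, the fit recovers the generating parameters
exactly and the coefficient of determination is 1; with the default
noise (SD 0.02 per dead fraction) the estimates scatter around the
truth — `glance(fit)` and `tidy(fit)` report the fit and its standard
errors, and `autoplot(fit)` draws the points against the calibrated
curve.

Single evaluations and the parameter ranking:

```r
p <- model_params(bvf = 0.038, rb_um = 5, L_um = 40, fkill_m = 0.25)
kill_fraction(p)
#> [1] 0.1238993

sensitivity_ranking(p)
#> # A tibble: 4 × 2
#>   parameter mean_abs_S
#>   <chr>          <dbl>
#> 1 fkill_m        1.00
#> 2 bvf            0.332
#> 3 rb_um          0.325
#> 4 L_um           0.312
```

Only half the tissue-averaged kill survives transport
(0.124 of a possible 0.25): at 3.8% blood volume most tissue sits
several penetration distances from a vessel. The ranking says the
output responds one-for-one to the in-vitro kill fraction (it is a pure
multiplier, $|S| = 1$ exactly) and, among the transport parameters,
most strongly to vascularization.

Fold-change anchors from the built-in reference tables:

```r
fold_difference(46.2, 3.5)   # IC50 differential between the lines
#>    fold fold_nearest
#> 1  13.2           13
```

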