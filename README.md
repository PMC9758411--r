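# circlehta

Automated measurement of the **humeral torsion angle (HTA)** — the angle
between the humeral head axis and the transepicondylar axis, positive for
retrotorsion — on digitised axial sections of the proximal humerus.

The package is written for musculoskeletal imaging researchers who want to
study *measurement methodology*: how two competing head-axis constructions
behave, how inter-rater reliability is quantified, and how a Hill-Sachs
impaction defect corrupts one construction but not the other.

Two head-axis constructions are implemented:

* **Circle-method** — fit one circle to the humeral head margin and one to
  the greater tubercle margin; the head axis is the line through the two
  centres. Circle fitting is automated as Pratt-normalised algebraic least
  squares, refined by Gauss–Newton on the orthogonal-distance objective
  `Σ (dᵢ − r)²`, with a deterministic Tukey-biweight IRLS robust variant
  that rejects contour points indented by a lesion.
* **Bernageau–Godefroy (B&G)** — the classical reference: the head axis is
  the perpendicular to the chord joining the anterior and posterior limits
  of the articular cartilage (the anatomical neck).

Then `hta = signed_axis_angle(head_axis, epicondylar_axis)` on the
undirected-axis range (−90°, 90°], with left shoulders sign-normalised onto
the right-side convention.

Because no patient images ship with the package, a **phantom generator**
produces axial sections with known ground-truth torsion, parametric
Hill-Sachs defects, contour noise and a rater landmark-error model, and a
Monte Carlo driver (`run_comparison()`) tabulates per-method bias, SD and
RMSE against truth. The statistics layer provides Cronbach's-α ICC
(ICC(3,k) consistency) with Feldt confidence interval, paired/Welch
t-tests, the 2×2 χ² test, per-group summaries, and n-weighted pooling of
published torsion values (with a bundled transcription of the literature
table).

## Worked example

A phantom with true retrotorsion 25°, a 25°-half-width, 3 mm-deep
Hill-Sachs defect centred on the posterior cartilage limit, observed by a
rater with 1 mm landmark jitter, then measured by both methods:

```r
library(circlehta)

spec   <- phantom_spec(theta_true = 25, sigma_contour = 0.3)
lesion <- lesion_spec(halfwidth_deg = 25, depth_mm = 3)
ph     <- generate_case(spec, lesion, seed = 7)
obs    <- observe_case(ph, rater_model(), seed = 8)

measure_case(obs, methods = c("circle", "bg"),
             robust = TRUE, inlier_threshold = 1) |>
  dplyr::select(method, hta_deg, head_rms_mm, head_n_inliers, head_n_points)
#> # A tibble: 2 × 5
#>   method hta_deg head_rms_mm head_n_inliers head_n_points
#>   <chr>    <dbl>       <dbl>          <int>         <int>
#> 1 circle    24.0       0.381             61            72
#> 2 bg        14.8      NA                 NA            NA
```

The robust circle fit excluded 11 of the 72 head-contour points (the
indented sector plus noise outliers) and lands within ~1° of the true 25°;
the B&G method, whose posterior cartilage landmark was destroyed by the
defect and relocated to the nearest intact contour point, is biased by
roughly half the lesion half-width, to 14.8°. Pooling the bundled
ultrasound literature records:

```r
pool_studies(table1_studies(), modality = "ultrasound")
#> # A tibble: 1 × 5
#>   modality   n_records n_total mean_deg sd_deg
#>   <chr>          <int>   <int>    <dbl>  <dbl>
#> 1 ultrasound        13     705     36.3   23.7
```

i.e. a combined 36° ± 24° over 705 shoulders.

A command-line wrapper is installed at
`system.file("scripts", "hta", package = "circlehta")` with subcommands
`measure`, `phantom`, `simulate`, `icc`, `pool` and `summary`.

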