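---
title: "Measuring humeral torsion with the Circle-method: models, phantoms and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring humeral torsion with the Circle-method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlehta)
library(dplyr)
```

## The measurement problem

Humeral torsion (retrotorsion) is the twist of the humeral head relative to
the elbow: the angle between the humeral head axis, read off an axial
section through the proximal humerus, and the transepicondylar axis, read
off a distal axial section. Reported normal values in the literature range
over tens of degrees depending on modality and method, so the interesting
questions are methodological: how is the head axis constructed, how
reproducible is it across raters, and how does it fail when the anatomy is
damaged?

Two constructions are implemented side by side.

**Bernageau–Godefroy (B&G).** The head axis is the perpendicular to the
chord joining the anterior and posterior limits of the articular cartilage.
It needs exactly two landmarks — which is its weakness: a Hill-Sachs
impaction defect sits precisely where the posterior limit should be, and a
rater must then guess a landmark inside or beside the defect.

**Circle-method.** Fit a circle to the humeral head margin and a second
circle to the greater tubercle margin; the head axis is the line through
the two centres. Because many contour points support each circle, and at
least three points determine a circle, the construction degrades gracefully
when a sector of the margin is missing or indented — provided the fit is
robust to those points.

Both methods share the transepicondylar axis, so any epicondylar
uncertainty hits them equally; the methods differ only in the head axis.

## Geometry layer

Axes are undirected lines; angles live on (−90°, 90°] with the vertical
mapped to +90°, and the HTA is the signed axis difference wrapped back onto
that range. Positive HTA is retrotorsion. Left shoulders are mirror images
of right ones: their sign is flipped (`side = "left"`), putting both sides
on one signed scale. Torsions beyond ±90° would alias under this
representation; observed human values stay far inside the range, and the
limitation is accepted for the simplicity of the undirected algebra.

Circle fitting is a three-stage pipeline:

1. **Algebraic (Pratt) fit** — least squares on the algebraic circle
   equation under Pratt's normalisation, solved as a generalized
   eigenproblem. Unbiased enough on arcs to serve as the initialiser, and
   exact on noise-free circles.
2. **Geometric refinement** — Gauss–Newton on `Σ (dᵢ − r)²` (orthogonal
   distances), iterated until the parameter step is below 1e-10 mm or 100
   iterations; non-convergence is flagged, never silently accepted. The
   test suite checks this fit against a brute-force coarse-to-fine grid
   search of the same objective down to ~1e-5 mm resolution.
3. **Robust variant** — iteratively reweighted Gauss–Newton with the Tukey
   biweight, tuning constant equal to the user's `inlier_threshold` (mm).
   No random sampling (no RANSAC): for a fixed input the result is fully
   deterministic, which keeps every downstream simulation reproducible
   from its seed alone. After IRLS, points with |radial residual| ≤
   threshold are the inliers and the circle is refit on them.

Collinearity is detected as the second singular value of the centred point
matrix falling below 1e-9; degenerate configurations (collinear points,
coincident circle centres, fewer than three surviving inliers) raise
classed errors rather than returning numbers.

The default `inlier_threshold` of 1 mm sits between the contour noise
scale (tenths of a mm, about one image pixel) and the lesion depth scale
(millimetres), so intact points are kept and indented points rejected
without tuning per case.

## The phantom

No imaging data ship with the package, so validation runs on a parametric
phantom whose truth is known by construction:

* head margin: a circle of radius `R_head` (default 25 mm, an adult
  humeral head);
* greater tubercle: a circle of radius `r_tub` (10 mm) whose centre lies
  `d_offset` (27 mm) from the head centre along the true axis; only its
  protruding arc is sampled, as only that margin is visible;
* cartilage limits: on the head circle at ±`cartilage_halfspan` (70°)
  about the direction opposite the tubercle;
* epicondylar landmarks: on a line at `epi_angle`, so the true torsion is
  exactly `theta_true`;
* noise: radial Gaussian on contours (`sigma_contour`, default 0.3 mm —
  about one in-plane pixel of a shoulder MRI);
* left-sided cases are generated by mirroring the section.

The coordinate convention is a right-handed x/y frame in mm with angles
counter-clockwise; the posterior cartilage limit is placed at
axis + 180° + halfspan. Only relative angles enter the HTA, so the
convention is internal.

A **Hill-Sachs lesion** is an angular sector of the head circle indented
inward, positioned relative to the posterior cartilage limit (where these
defects occur). The `chord` profile pushes points onto the sector chord
with the indentation capped at `depth_mm` — so the sector midpoint moves
inward by exactly `min(sagitta, depth)` — and the `arc` profile uses a
cosine taper, full depth at the centre, zero at the edges. The shape of a
real impaction defect is not published in a usable form; these two profiles
bracket "flat floor" and "smooth dish" plausibly.

The **rater model** adds isotropic Gaussian jitter to landmarks (default
1 mm, roughly two pixels of landmark ambiguity) and an extra per-point
jitter to contour picks. Its key ingredient is the *lesion rule*: when the
defect covers the posterior cartilage limit, the landmark a rater would
have picked no longer exists. `nearest_intact` relocates it to the closest
un-lesioned contour point (a rater hugging the intact margin);
`defect_floor` drops it to the deepest point of the defect. No published
protocol states what raters actually do, so both rules are offered and the
choice is explicit in every simulation. This relocation is the entire
mechanism by which a lesion biases B&G: the chord endpoint slides along the
circle by up to the lesion half-width, rotating the perpendicular by about
half that.

```{r truth}
ph <- generate_case(phantom_spec(theta_true = 25, sigma_contour = 0), seed = 1)
measure_case(ph$case) |> select(method, hta_deg)
```

With zero noise and no lesion both methods recover the truth to numerical
precision — the phantom's defining invariant, tested over a grid of
torsions from −60° to 80°.

## The method-comparison simulation

`run_comparison()` sweeps conditions (typically lesion half-widths at fixed
depth via `lesion_sweep()`), generates `n_reps` phantoms per condition,
observes each through the rater model, measures both methods, and reports
per-method bias, SD and RMSE of (measured − true). Degenerate fits are
counted and excluded from the moments; with a single replicate the SD is
reported as 0 and flagged. Seeds for every replicate derive deterministically
from `base_seed`, so tables reproduce bit for bit.

```{r sim, eval = FALSE}
sim <- run_comparison(lesion_sweep(c(0, 10, 20, 30), depth_mm = 3),
                      rater_model(), n_reps = 200, base_seed = 20220)
plot_comparison(sim)
```

Under the default conditions (contour noise 0.3 mm, landmark jitter 1 mm,
nearest-intact rule, 200 replicates — sizes chosen so the full sweep runs
in well under a minute on one core) the B&G RMSE grows from ~2° with no
lesion to ~15° at 30° half-width, while the robust Circle-method stays
near 1.4° throughout. The test suite asserts the qualitative shape:
B&G RMSE non-decreasing in half-width, robust Circle RMSE strictly below
B&G at 30°.

What this does and does not show: the phantom isolates the *geometric*
mechanism — landmark destruction versus robust arc support. It does not
model slice-selection error, through-plane anatomy, reader experience or
training, all of which can mask the mechanism in human data; equal human
performance of the two methods is therefore entirely compatible with these
curves.

## Reliability statistics

Cronbach's α is used as the inter-rater ICC:
α = k/(k−1)·(1 − Σⱼ s²ⱼ / s²_total), with s²ⱼ the variance of rater j's
column and s²_total the variance of per-case sums. This is identical to
the consistency ICC of the k-rater average, ICC(3,k), and the tests verify
the identity against a two-way-ANOVA mean-squares oracle to 1e-12. The 95%
interval is Feldt's, from (1−α) being F-distributed on
(n−1, (n−1)(k−1)) degrees of freedom; no competing interval is implemented
because α is reported descriptively. α is undefined (classed error) when
the case sums have zero variance, and equals 1 exactly when every rater
column is a shift of a common column.

The t-test wrapper defaults to Welch for unpaired comparisons (pooled
Student available by option) and the one-sample t on differences for
paired data; constant inputs raise a degenerate-data error instead of a
meaningless statistic. The χ² test is Pearson's without continuity
correction on a 2×2 table. Group summaries report n, mean, min, max and
the (n−1)-denominator SD at full precision — rounding to whole degrees is
presentation only.

## Literature pooling

Published torsion summaries are pooled per modality as if the raw samples
had been concatenated: n-weighted mean, and a pooled variance from the
within-record and between-record sums of squares. The packaged records
(`table1_studies()`) transcribe one row per *reported subgroup mean*
(side, dominance, stability group, measurement variant), each contributing
its study's shoulder count; mixed living/cadaveric studies contribute only
their living subgroup, and the pooled SD is suppressed whenever any pooled
record lacks one. This row-counting rule is an editorial reconstruction —
sources rarely state how their subgroup means should be recombined — and
is deliberately data-driven (a `cohort` column, not a hard-coded study
list). Pooling is verified against an oracle that realises each record as
an exact raw sample and summarises the concatenation directly.

```{r pool}
bind_rows(pool_studies(table1_studies(), "ct"),
          pool_studies(table1_studies(), "xray"),
          pool_studies(table1_studies(), "ultrasound"))
```

The CT pool has no SD because one included study reported side means
without deviations.

## Numerical choices and limitations

* Convergence: Gauss–Newton step < 1e-10 mm; IRLS step < 1e-10; 100 / 50
  iteration caps with an explicit non-convergence flag.
* Tie-breaks: when a relocated landmark is equidistant from both lesion
  edges, contour ordering decides; simulations treat the resulting bias
  sign as arbitrary and work with RMSE.
* The undirected-axis representation aliases torsions beyond ±90°.
* The phantom is 2-D: no through-plane obliquity, no slice-selection
  variability, no intensity model — contours arrive as if segmentation
  were solved.
* The robust fit's inlier threshold is a length, so it must be rescaled if
  coordinates are rescaled.
* Epicondylar repeat-pairs are averaged by the circular mean of doubled
  angles, the correct mean for undirected lines; a wildly inconsistent
  pair set is averaged, not rejected.
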