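---
title: "Measuring acetabular component position and leg length from landmark annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular component position and leg length from landmark annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmetrics)
```

## The measurement problem

After total hip arthroplasty (THA), the orientation of the acetabular cup and
any change in leg length are routinely assessed on a standing anteroposterior
(AP) pelvic radiograph. Clinical measurement software asks a reviewer to place
a handful of landmarks — the rim of the cup opening, the inferior tips of the
ischial tuberosities, a trochanter point, and the edges of a calibration
marker — and derives three numbers per hip from them:

* **anteversion** $V$: the circular cup opening projects onto the image as an
  ellipse; under a parallel-beam (orthographic) projection the semi-minor to
  semi-major axis ratio gives the forward tilt of the cup as
  $V = \arcsin(b/a)$;
* **inclination** $I$: the acute angle between the ellipse's major axis and a
  transverse pelvic reference line;
* **leg length**: the perpendicular distance from the reference line to the
  trochanter landmark, converted to millimetres with the calibration scale.

`hipmetrics` implements this measurement chain on *annotation files* rather
than on images: the landmark coordinates a reviewer would click are the input,
which makes every numeric step testable against known ground truth. The
package also implements the statistical protocol used to validate such
software against established reference programs (paired differences, Pearson
correlations, within-threshold proportions with chi-square/Fisher tests, and
pooled intraclass correlation coefficients), plus a simulator that generates
annotation sets with known truth.

## Conventions

Coordinates are image-style: origin at the top-left, $x$ to the right, $y$
downward (inferior), units in pixels. Physical units (mm) appear only after
multiplication by the calibration scale, which is computed — never stored —
from the two marker edge points as `known_diameter_mm / pixel_distance`. A
default marker is the 25 mm scaling ball; the femoral head implant of known
diameter serves when no ball was placed.

The reference line is always the **inter-ischial line** through the two
annotated ischial points, for both inclination and leg length. Comparable
clinical programs let the user draw a free-hand "horizontal reference line";
we deliberately replace that free input with a landmark-defined line so runs
are reproducible. Callers who want a different reference can construct one
with `reference_line()` and call `inclination()`/`leg_length()` directly.

Signs: leg length is positive when the trochanter landmark lies on the
inferior (larger-$y$) side of the reference line; for an exactly vertical
line, where "inferior" is undefined, the positive side is larger $x$ (a
tie-break that never occurs on real AP views). A single AP projection cannot
distinguish ante- from retroversion, so anteversion is reported as the
non-negative magnitude in $[0^\circ, 90^\circ]$.

## Ellipse fitting

The one numerical primitive is the ellipse fit (`fit_ellipse()`). We use the
direct least-squares conic fit: minimize the algebraic residual of
$Ax^2+Bxy+Cy^2+Dx+Ey+F$ subject to the ellipse constraint $4AC-B^2=1$, via
the numerically stable block decomposition of the constrained eigenproblem
(Halir & Flusser 1998). The method is closed-form and deterministic — no
iteration and no starting value, so repeated runs are bit-identical — which
we value over the marginally lower bias of iterative geometric
(orthogonal-distance) fitting. A geometric-distance minimizer exists in the
test suite as an independent oracle; on simulated rims (semi-major axis
$\approx 200$ px, 0.5 px landmark noise, anteversion in the clinically
typical 20–45° band) the two agree within 0.1% on the axes and 0.1° on the
orientation. The agreement loosens at the extremes: very thin projections
($V \lesssim 15^\circ$, where the rim noise becomes a large fraction of the
minor axis) let the algebraic and geometric optima drift apart by somewhat
more than 0.1% on $b$, and near-circular ones leave the orientation poorly
determined for any fitter.

Numerical choices:

* data are centered and scaled before building the design matrix, which is
  what makes exact inputs recoverable to ~1e-6 relative error at aspect
  ratios up to 20;
* because the constraint forces an ellipse through *any* data, the fit first
  asks the unconstrained best conic (smallest eigenvector of the normal
  matrix) whether the points actually describe an ellipse, and raises a
  non-elliptical-fit error otherwise (e.g. points sampled from a hyperbola);
* when the fitted $a$ and $b$ agree within 1e-9 relative (a circle), the
  major-axis direction is meaningless: the orientation is reported as 0 with
  an `orientation_indeterminate` flag and inclination becomes `NA`. This
  occurs only at $V \to 90^\circ$, far outside the clinical range;
* orientation is folded to $(-90^\circ, 90^\circ]$, and all angle arithmetic
  uses direction vectors rather than slopes, so vertical lines are legal.

As the projection approaches a circle the major-axis direction degrades
gracefully for *any* fitter: the orientation information content scales like
$1-(b/a)^2$. Anteversion, which depends only on $b/a$, is unaffected.

## The simulator

`sim_config()` defaults encode the study conditions the package is meant to
be exercised under: 135 radiographs read in triplicate, ~6% bilateral, cup
radius 25 mm at 0.125 mm/px (projected semi-major axis ≈ 200 px), anteversion
drawn uniformly on 10–45°, inclination on 30–55° (centred on the clinically
reported means of ≈27° and ≈44°), per-leg length on −15 to 35 mm, 16 rim
points with 0.5 px noise and 1 px landmark noise. The noise magnitudes are
package defaults (no published values exist for landmark placement error);
they produce sub-degree/sub-millimetre mean recovery errors comparable in
spirit to the agreement published for validated clinical programs.

The forward model is orthographic: the cup circle of radius $r$ projects to
an ellipse with $a=r/s$ pixels and $b=a\sin V$, the exact model the arcsine
formula inverts, so measurement ∘ simulation is the identity at zero noise.
Beam divergence, pelvic tilt and rotation are *not* modelled: passing tests
show the software inverts its stated projection model faithfully, not that
the model captures every error source of real radiographs. Rim points are
parametrically equally spaced (not arc-length spaced); fit quality is
insensitive to this at ≥ 8 points.

Determinism: one master seed; each image uses a substream seed derived by a
stable hash of (seed, image index), so extending a simulation never perturbs
existing images. Reviewers and replicates re-noise all landmarks
independently, emulating independent reading sessions.

`simulate_measurement_table()` skips the geometry entirely and draws
measurement values from an additive two-way variance-components model
(subject + program bias + rater + residual); it exists to exercise the
statistics with analytically known targets, e.g. an ICC of
$\sigma^2_s/(\sigma^2_s+\sigma^2_e)$.

## The agreement protocol

The statistics operate on a long-format table keyed by (image, side, program,
reviewer, replicate, parameter). The pairing unit is **(image, side)**, so a
bilateral image contributes two units. Replicates are averaged first; when
several reviewers measured the same unit their averaged values are averaged
again, giving one value per unit per program.

* `difference_summary()` reports signed and absolute paired differences
  (mean ± SD of $d$ and of $|d|$), with $d$ = reference − test so a positive
  mean difference means the reference reads higher.
* `paired_t()` / `one_way_anova()` compare program means (two-sided, α is
  the caller's concern). Zero-variance differences are reported as
  $t=0, p=1$ with a degeneracy flag — identical measurements are "no
  detectable difference", not an error.
* `within_threshold()` computes the proportion of units within 1° and 5°
  (or 1 mm and 5 mm) by default; `proportion_test()` compares two such
  proportions using Pearson's chi-square without continuity correction when
  all expected counts are ≥ 5 and a two-sided Fisher exact test otherwise.
  The Fisher p-value is computed directly from the hypergeometric mass
  (summing all tables with the observed margins that are no more probable
  than the observed one), which the test suite verifies against full
  enumeration for every 2×2 table with $N \le 40$.
* `icc()` is the single-measure, two-way, absolute-agreement intraclass
  correlation ICC(A,1) computed from the ANOVA mean squares — the standard
  choice for fixed raters with repeated measures; the formulation is recorded
  in `form_id` so alternates can be added without ambiguity.
* `pooled_icc()` combines per-reviewer ICCs by Fisher-z averaging (ICCs at
  the boundary are clamped by 1e-12 before the transform, and a set of
  perfect reviewers pools to exactly 1). Pooling over a single reviewer is
  permitted and returns that reviewer's ICC.
* `build_report()` assembles all of the above per parameter, using ANOVA when
  three or more programs measure a parameter and the paired t when exactly
  two do, and skipping a parameter for programs that never record it (some
  clinical viewers have no ellipse tool and therefore no anteversion).

Multiple-testing correction and Bland–Altman limits of agreement are out of
scope by design.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_images = 20, replicates = 3, seed = 7)
gen <- generate_annotation_set(cfg)
wide <- measure_annotation_set(gen$annotations)

tbl <- measurements_to_table(wide)
pooled_icc(tbl, "sim", "anteversion")

# compare against a copy of the same program: all differences vanish
tbl2 <- tbl; tbl2$program_id <- "ref"
report <- build_report(rbind(tbl, tbl2), "ref", "sim")
as.data.frame(report)
```

## Problem sizes and design scope

The bundled verification runs use 135-image simulations with triplicate
readings (the study-scale cohort), 500 single-hip images for noisy-recovery
summaries, 200 Monte-Carlo repetitions for ICC calibration and $10^4$ null
replications for the paired-t type-I rate — sizes chosen so the entire suite
runs comfortably on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances.

Known limitations: no image I/O or automatic landmark detection (annotations
are the input by design); the orthographic projection ignores beam
divergence and patient positioning error; anteversion is unsigned; only AP
geometry is implemented — standing/seated lateral views and spinopelvic
parameters are out of scope.
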