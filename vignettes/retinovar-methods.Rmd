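---
title: "Quantifying individual variability in retinotopic maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual variability in retinotopic maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinovar)
```

## The problem

Early visual cortex (V1, V2, V3) contains retinotopic maps: every cortical
location responds preferentially to a visual-field position, summarized per
surface vertex by a polar angle (clock position, degrees in [0, 360)) and an
eccentricity (distance from fixation, degrees of visual angle). The textbook
model has V2 and V3 wrapped around V1 as mirror-symmetric dorsal and ventral
bands, with vertical- and horizontal-meridian representations delineating the
area borders. Individual brains deviate from this template, most strikingly
in the dorsal portion, where the lower-vertical-meridian representation of
dorsal V3 can bifurcate into a Y-shaped (forked) configuration or stop short
of the vertical meridian entirely (a truncated V3).

`retinovar` implements a complete analysis chain for quantifying and
characterizing such deviations, together with a synthetic map generator so
every stage can be exercised and validated end-to-end without access to a
neuroimaging dataset.

## The individual-variability metric

For one subject, one hemisphere and one stratum (visual area x
dorsal/ventral portion), variability is the mean vertex-wise deviation from
the group-average map:

* polar angle: the circular difference
  `min(|a - b|, |a - b + 360|, |a - b - 360|)`, in degrees in [0, 180]
  (`circ_diff()`);
* eccentricity: the plain absolute difference, since eccentricity is not
  periodic.

The group average uses the circular (resultant-vector) mean per vertex for
polar angle and arithmetic means for everything else (`group_average()`).
If the resultant vanishes (antipodal inputs) the circular mean is undefined;
the first map's value is kept and the vertex is flagged. Vertices enter the
metric only when the *group-average* eccentricity lies in 1-8 degrees
(`eccentricity_mask()`): below 1 degree the foveal confluence is hard to map,
and above 8 degrees typical mapping stimuli provide no signal. The result is
one scalar per subject x hemisphere x area x portion — deliberately a
*large-scale* deviation summary, not a vertex-level statistic.

Three covariates are built the same way (`covariate_variability()`,
`intra_individual_variability()`): curvature variability (mean absolute
deviation from the average curvature map), variability of the mean BOLD
signal after dividing each map by its maximum (`normalize_bold()`; low
values proxy large draining veins), and split-half intra-individual
variability (the same aggregation applied between two pRF fits of half the
data — a reliability proxy). For correlation analyses, polar angle is first
folded to the meridian scale `90 - |90 - (theta mod 180)|`
(`fold_polar_to_meridian()`), so 0 means horizontal and 90 vertical
meridian; without folding, the sign of a polar-angle correlation would be an
artifact of the angular origin.

## The mixed model

Variability is analyzed with a linear mixed-effects model
(`fit_lme()`, REML via `lmerTest`):

```
variability ~ hemisphere * visual_area * portion (+ z-scored covariates)
            + (1 | subject) + (1 | subject:hemisphere)
            + (1 | subject:visual_area) + (1 | subject:portion)
```

Each subject contributes all 12 strata, so observations are clustered by
individual; the nested random intercepts absorb subject-specific shifts per
factor. Treatment coding with references LH, V1 and dorsal makes the
`hemisphere` row the RH - LH difference at reference levels, matching the
convention in which hemispheric and portion effects are usually reported.
Degrees of freedom are Satterthwaite approximations; confidence intervals
are `estimate ± t(df, 0.975) * SE`. Exact degrees of freedom depend on the
estimation software, so equality of df/p across implementations is not a
goal — signs, magnitudes and interval behavior are.

If the full random structure fails to converge, nested terms are dropped one
at a time (area, then portion, then hemisphere) and the structure actually
fitted is recorded in the result; a singular variance estimate is reported
but the fit is retained. Post hoc visual-area contrasts (V2-V1, V3-V1,
V3-V2) are contrasts of estimated marginal means with Bonferroni adjustment
over the three tests (`posthoc_area_contrasts()`; the adjustment choice is
ours, made for its simplicity at three comparisons).

## Discrete-map similarity and clustering

To ask whether maps deviate from the average in shared ways, continuous
polar-angle maps are discretized into four labels anchored on the meridians
(0 for [0, 45], 90 for (45, 180], 270 for [180, 315), 360 for [315, 360));
the value 180 satisfies two clauses of the published rule and resolves to 90
by first match (`discretize_polar()`). Eccentricity uses closed-above
2-degree bins (`discretize_eccentricity()`).

Similarity between two discrete maps is the weighted Jaccard overlap: per
label, intersection over union of the vertex sets; labels are weighted by
their count in the *reference* map, which makes the score directional, so
the two directions are averaged (`directional_jaccard()`,
`pairwise_similarity()`). Labels absent from the reference get weight zero
rather than contributing a spurious zero Jaccard term. Clustering uses the
normalized spectral embedding of the similarity matrix (row-normalized
leading eigenvectors of `D^-1/2 S D^-1/2`, embedding dimension k) followed
by k-means with 10 seed-derived restarts (`spectral_cluster()`); assignments
are deterministic given the seed and are scored against planted structure
with the adjusted Rand index, which is invariant to label permutation. The
default k is 6 (the choice used on real data, where a spare cluster absorbs
unclear maps); validation on planted populations uses k equal to the number
of planted variants. The clustering scope defaults to the dorsal bands,
where the motif variability lives; it is an argument, not a constant.

## Visual field sign

Polar-angle and eccentricity maps are combined into a mirror/non-mirror
classification of each patch of cortex. Because the left hemisphere maps the
right hemifield, its angles cluster around the 360-to-0 wrap; they are first
re-expressed continuously by subtracting 360 from values >= 180
(`shift_wraparound()`; right-hemisphere maps live around 180 degrees and
need no shift). Both fields are interpolated onto a regular grid
(piecewise-linear over a Delaunay triangulation, cells outside the convex
hull masked; `to_grid()`, default 200 x 200 over the bounding box), and
gradients are taken with second-order central differences, one-sided at mask
edges (`grid_gradient()`). The signed angle from the eccentricity gradient
to the polar-angle gradient, evaluated through the planar cross product,
classifies each cell: one sign is a mirror-image representation of the
retina (like V1), the other non-mirror (like V2) (`field_sign()`). Cells
with vanishing or parallel gradients (tolerance 1e-9 per grid unit) carry no
sign. The mapping from cross-product sign to mirror/non-mirror depends on
the handedness of the flat coordinates, which no convention fixes; the
`orientation` flag (per hemisphere: left -1, right +1 for this package's
patch geometry) is chosen so that canonical V1 evaluates as mirror.

The dorsal-V3 discontinuity score (`v3d_discontinuity_score()`) is the
fraction of defined V3d grid cells carrying the opposite sign to the area's
dominant sign, with a flag threshold of 0.10. The V3d grid mask interpolates
the ROI indicator, thresholds at 0.5 and erodes by 3 cells, because cells
hugging an area border have gradient stencils that straddle the border's
polar-angle reversal, where a field sign is not meaningful. Forked maps
contain a genuine opposite-sign pocket and score far above the threshold;
truncated maps preserve a monotone (if compressed) angle progression and
score near zero — reproducing the qualitative contrast between the two
motifs that motivates the analysis.

## The synthetic generator: what it emulates, and what it does not

The generator (`make_flat_patch()`, `canonical_fields()`,
`apply_variant()`, `simulate_population()`) replaces the cortical surface
with a rectangular flat patch: x in [0, 10] carries eccentricity linearly up
to `ecc_max` (default 10 degrees, slightly beyond the 8-degree mask ceiling,
as pRF fits are), and y in [-3, 3] carries six unit-height ROI bands
(V3v, V2v, V1v | V1d, V2d, V3d) whose borders hold the meridian
representations of the canonical zigzag. This preserves exactly what the
analysis consumes — per-vertex values with flat coordinates and ROI labels —
and nothing else.

Map variants implement the dorsal motifs: the *fork* mirrors the polar-angle
progression about a horizontal line inside an elliptical pocket of anterior
V3d (semi-axes 1.8 flat units in x, `fork_depth`/180 in y, default depth 60
degrees), reversing the gradient there, which is precisely what produces an
opposite-field-sign pocket; the real geometry of forks is not quantified
anywhere, so the parameters are exposed rather than asserted. The
*truncated* variant linearly compresses the V3d angular range so its
anterior border reaches `truncation_angle` (default 300 degrees) instead of
270. Compression, not capping, is the right model: a hard cap would create a
zero-gradient plateau whose field sign is dictated by noise, whereas
truncated individuals in practice show an intact (weaker) gradient and no
sign discontinuity.

Between-subject deviations are *spatially smooth* wrapped-Gaussian fields: a
sum of 24 random-phase plane waves with wavelengths of 3-8 flat units
(eccentricity noise: 6-12 units, since real eccentricity maps shift or
compress iso-eccentricity bands without reversing the global gradient). The
marginal SD is exact by construction, so the expected polar variability
metric is `sqrt(2/pi) * sd` to within about 1%, which the planted-effect
acceptance arithmetic relies on. Smoothness matters twice: the metric is
meant to capture large-scale deviations, and field-sign gradients on
vertex-iid noise would be meaningless. Per-vertex noise SD is
`base_polar_sd` times a hemisphere ratio (left noisier), a portion ratio
(dorsal noisier), an area factor (V1 < V2 < V3), and a per-subject log-normal
scale (mean exactly 1, SD 0.10) that plants subject-level clustering for
the mixed model. Defaults (base 23.3 degrees, ratios 1.22, area factors
1/1.13/1.21, eccentricity SD = polar SD / 23) were fixed once to reproduce
the reported scale of variability in a 181-subject reference cohort
(polar-angle metric intercept near 18.6 degrees, eccentricity near 0.8).
Split-half fits add independent smooth noise (defaults 8 degrees polar,
0.35 degrees eccentricity) on top of the subject map. Curvature is a cosine
locked to the band structure (gyral crowns mid-band), giving a planted
negative correlation with folded polar angle; mean BOLD is a positive field
with Gaussian venous depressions at seeded locations.

What the generator does *not* emulate: cortical folding geometry and
surface distortions, pRF size or fit quality, vertex-density gradients,
foveal-confluence topology, twin structure, or any coupling between motif
type and noise level. Passing tests therefore validate the *analysis
machinery* — metric calibration, motif discrimination, cluster recovery,
effect estimation — on data whose statistical structure matches the
analysis assumptions; they are not evidence about effect sizes in real
cortex, where the headline quantities depend on a specific dataset.

## Validation conditions and numerical choices

* Motif discrimination uses angular noise with concentration kappa = 33
  (about 10 degrees SD): forked maps score > 0.10 on the V3d discontinuity,
  truncated maps < 0.05, with wide margins in both hemispheres.
* Cluster recovery uses 60 subjects (20 per variant, exact counts) with
  uniform 5-degree smooth noise and no planted stratum effects. At that
  level the planted motifs are the dominant mode of between-subject
  variation and recovery is exact; at roughly double the noise, coherent
  displacement of the discrete-label boundaries overtakes the motif signal
  and no similarity-based method can recover the partition — a regime the
  within/between Jaccard overlap on real data suggests is the realistic one.
* Mixed-model recovery plants reference-level contrasts of exactly -3.0
  (both RH-LH and ventral-dorsal) by choosing hemisphere and portion ratios
  rho with `sqrt(2/pi) * base_sd * rho * (rho - 1) = 3` at base SD 18;
  populations of 200 subjects on 1000-vertex patches keep each replicate fit
  to a few seconds, and 20 replicates recover both signs in every fit with
  estimates well inside +/- 3 SE.
* All randomness flows through explicit integer seeds; population seeds
  derive per-subject seeds by a single `sample.int()` draw, and k-means uses
  10 restarts from a seeded stream, so every pipeline stage is reproducible
  byte-for-byte.
* Degenerate inputs are errors, not guesses: empty ROI/mask selections name
  the ROI; missing factorial cells name subject and cell; non-finite angles,
  negative eccentricities and non-positive BOLD values are rejected at
  construction.

## Known limitations

* The rectangular patch has no curvature-driven distortion, so curvature is
  a covariate by construction rather than by anatomy; its planted
  correlation is a convenience for testing sign recovery, not a model of
  structure-function coupling.
* The fork/truncation parameterization is one geometry per motif; real
  dorsal variability is a continuum.
* The variability metric averages over strata and so cannot localize
  deviations within an area; the field-sign map partially fills that gap.
* Eccentricity clustering is implemented but uninformative under the
  generator defaults (motifs are polar-angle phenomena), mirroring the
  empirical finding that eccentricity maps cluster weakly.
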