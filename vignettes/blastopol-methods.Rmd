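---
title: "Detecting asynchronous blastomere polarization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting asynchronous blastomere polarization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastopol)
```

## The biological question and the measurement model

At the 8-cell stage, mouse blastomeres assemble an apical domain — a cortical
cap of polarity proteins (EZRIN, PARD6) on their contact-free surface. Most
cells polarize late, around compaction, but a minority polarize within the
first hour after their third cleavage, and these early-polarizing (EP) cells
divide symmetrically more often and contribute preferentially to the
trophectoderm (TE). blastopol implements the full quantification chain needed
to study this asynchrony: cortical intensity profiling, a three-criterion
apical-domain call, polarization-timing classification relative to
compaction, contact-angle and shape measurements, and the contingency
statistics that connect polarization timing to division symmetry and fate.

Everything operates on calibrated image stacks (`T x Z x Y x X`) with
per-cell label masks. No segmentation or tracking is performed: masks and
track identities are inputs, supplied either by the user or by the package's
own synthetic generator.

## The apical-domain call

A cell is called polarized at a time point when three criteria hold
simultaneously (`detection_config()` holds the thresholds):

1. **Length** — the candidate cortical arc spans between 33% and 80%
   (inclusive) of the cell's contact-free cortex.
2. **Intensity** — the arc's mean intensity strictly exceeds 1.5 times the
   mean of the remaining contact-free cortex.
3. **Depth** — arcs passing (1) and (2), with at least 50% mutual angular
   overlap between consecutive optical sections, form a contiguous z-slab of
   at least 3 µm. The slab thickness is counted as `n_slices * z_step`, so a
   single section acquired at a z-step of 3 µm or more can satisfy the
   criterion on its own; with the package defaults (2 µm steps) two
   consecutive sections are needed.

The candidate arc itself comes from an exhaustive search
(`find_candidate_domain()`): over all contiguous windows whose arc length
lies within the length bounds, the window with the maximal length-weighted
mean intensity is selected. Two refinements make this selection stable on
discrete, noisy profiles, and both are deliberate design choices rather than
spec-free behaviour:

* **Near-tie resolution.** Windows whose mean lies within a relative
  tolerance (`candidate_tie_tol`, default 5%) of the maximum are treated as
  tied, and the longest tied window wins. Without this, sampling noise makes
  the search shrink onto the few brightest samples; the excluded domain
  samples then inflate the "remaining cortex" mean and bias the intensity
  ratio downward, which costs sensitivity exactly where profiles are short
  (late compaction). Setting the tolerance to 0 restores exact-tie
  behaviour.
* **Edge trimming.** The longest tied window can absorb a few dim samples at
  its edges. Window ends whose intensity falls below the midpoint of the
  window mean and the remaining-cortex mean are trimmed (never below the
  minimum length fraction). On noise-free arcs this recovers the rendered
  arc to within a sample; on noisy arcs genuine domain samples sit above the
  midpoint and are kept.

Temporal persistence (default 2 consecutive positive frames) is required
before an onset is accepted, rejecting single-frame noise; cells whose
trailing positive run is cut off by the end of imaging are flagged censored
and excluded from proportions rather than called unpolarized.

## Cortical profiles

`extract_contact_free_profile()` samples one value per boundary pixel of the
cell mask, excluding every boundary pixel within a 2-pixel dilation band of
any neighbouring cell (the contact-exclusion band; its width is a package
convention). Arc position is cumulative Euclidean step length in µm, and
angular position is measured counterclockwise from the
embryo-centre-to-cell-centroid axis so that outward-facing arcs are centred
at 0°. Contact exclusions split the profile into contiguity runs; candidate
windows never span a run boundary, except on fully contact-free (closed)
boundaries, where the search wraps.

The local-polynomial smoother (`smooth_profile()`, window 20 samples, order
2, endpoint window shrinkage) reproduces the style of smoothing used for
membrane-profile figures in this literature. The exact smoother behind such
figures is a graphing-program convention; the local order-2 fit is our
explicit, testable interpretation, and it is exact on polynomials up to
order 2. It is intentionally *not* part of the detection path — windowed
means in the candidate search already average noise, and smoothing before a
max-mean search would re-introduce edge smear.

Intensity-ratio quantities (`cortical_enrichment()`,
`nuclear_cytoplasmic_ratio()`, `ep_lp_intensity_ratio()`,
`cdx2_doublet_ratio()`) are all invariant to multiplicative gain, which the
test suite asserts. The "standard portion of cytoplasm" used as the
enrichment control is implemented as a fixed-area region eroded at least
2 µm from both cortex and nucleus (`cytoplasm_region()`); placement is
unspecified in the source literature, so the region nearest the nucleus
centroid is used for reproducibility.

## Contact angles and compaction

The inter-blastomere angle (IEA) is measured at the two endpoints of a cell
pair's shared interface: at each junction the tangent to each cell's
contact-free boundary is estimated and the angle between the two
away-pointing tangents is reported, averaged over both junctions
(`interblastomere_angle()`). An embryo is compacted when every measured IEA
has reached 120° (`compaction_state()`).

Estimating a tangent on a pixelated boundary is the numerically delicate
step, and several simpler estimators were rejected on measured grounds:

* a straight-line fit over a 3 µm arc carries a curvature bias of
  `s / (2 r)` radians (about 8° for a 15 µm blastomere) plus staircase
  quantization;
* algebraic circle fits over short arcs collapse (the sagitta of a short
  pixelated arc is below the half-pixel quantization noise), and their
  fitted centres acquire a *tangential* bias that rotates a
  perpendicular-to-radius tangent.

The implemented estimator smooths the boundary to subpixel positions
(moving average along the contour), fits a Taubin circle over the cell's
contiguous contact-free arc near the junction (by default the whole arc,
`tangent_arc_um = Inf` — cleavage-stage blastomeres are near-spherical, and
this is the stable choice; a finite arc remains available), accepts the
circle only when its RMS residual is within one pixel, and otherwise falls
back to a local principal-axis line fit (which also serves flattened,
straight-edged cells). The junction itself is taken as the midpoint of the
two cells' interface endpoints, cancelling the contact-band overshoot of
each mask. Against the closed-form circle-circle contact angle this
measures within 3° across moderate overlaps (60–130% of the radius) and
orientations, degrading only toward point contact.

The apex-geometry measurement (`apex_geometry_2d()`) is defined pictorially
in the source literature, so the package states its own construction: the
apex is anchored at the apical-domain midpoint (or the contact-free arc
midpoint for unpolarized cells); the basal corners are the two boundary
points farthest from the apex, at least 60° apart about the centroid; the
apex angle is measured at the apex between the converging lines to the
corners; the full length is the mean converging-line length and the side
length is the basal width. This satisfies the qualitative contracts that
matter downstream — wedge-shaped cells report their opening angle, squares
report a length ratio near 1, and wide cells report larger apex angles and
length ratios than tall cells — but absolute values should not be compared
against other software without checking the construction.

3D aspect ratios (`aspect_ratio_3d()`) use second-order voxel moments with
anisotropy correction from the calibration; for a uniform ellipsoid the
eigenvalues are `semi_axis^2 / 5`, so axis ratios are recovered exactly in
the continuum limit (2:1 ellipsoids measure 2.0 within discretization).
This moment-based computation replaces an interactive mesh-deformation
workflow by design: it is deterministic and testable against analytic
shapes. Per-embryo normalization divides by the embryo mean, so normalized
ratios average exactly 1.

## Timing classification

`polarization_onset()` reports the first persistent positive frame at or
after the cell's cleavage completion. `classify_polarity()` calls a cell EP
iff its onset falls within 60 minutes (boundary inclusive — onsets are
quantized to the frame grid, so with 20-minute frames onsets at frames 1–3
post-cleavage qualify) of the reference event *and* the minimum IEA over
the cell's adjacent pairs at the onset frame is below 120°; polarized cells
failing either condition are LP. In `live` mode the reference is the cell's
own third cleavage; in `fixed` mode it is the embryo's last third cleavage
(division completion is used; the mode only matters when cleavages are
asynchronous, and the two agree on synchronous embryos). The minimum over
neighbours is our aggregation choice — the verbal definition ("the angle
between the cell and its neighbours") names no aggregate, and the minimum
is the conservative reading: a cell is EP only if it polarized before *any*
of its junctions compacted.

`onset_histogram()` is descriptive: binned onsets (20-minute bins, matching
the frame interval) with local maxima reported as peaks; no formal
bimodality test is attached, because the bimodality claim in this
literature rests on the plotted distribution.

## Fate statistics

Division symmetry is read off daughter apical-domain calls (both polar =
symmetric, exactly one = asymmetric); divisions with no polar daughter are
anomalous — recorded and excluded from the two-class table, mirroring the
exclusion of ambiguous divisions in the source study. TE assignment requires
an outer position *and* marker positivity.

The statistics layer makes three documented choices:

* `fisher_exact()` uses the probability-mass two-tailed rule (sum over
  tables as or less probable than the observed one) — the dominant
  convention, verified in the tests against exhaustive fixed-margin
  enumeration.
* `two_proportion_ztest()` uses the pooled variance; pooled vs unpooled is
  not specified where the test is cited, and the pooled form is the one
  whose null calibration we verify (empirical type-I error within
  [0.04, 0.06] at the 5% level).
* `binomial_independence_test()` assesses cell autonomy by parametric
  bootstrap: the per-cell rate is estimated from the pooled data, the
  chi-square statistic against Binomial(8, p-hat) expectations is computed,
  and its null distribution is simulated with the rate re-estimated in
  every replicate. An asymptotic chi-square would be anticonservative here
  (expected counts for 3+ EP cells per embryo are below 5 at realistic
  rates), and ignoring the estimated parameter would miscalibrate the
  rejection rate.

`test_selector()` encodes the study's test-selection tree: D'Agostino
K-squared normality per group (implemented from the standard skewness and
kurtosis z-transformations, validated against an independent reference
implementation), then t-test / ANOVA with Welch correction when an F-test
finds unequal variances, else Mann-Whitney / Kruskal-Wallis with Dunn.
Groups below n = 8 default to the rank-based branch.

## The synthetic embryo generator

`render_embryo_movie()` renders 8 equal disc-shaped cells (spherical caps
across z) with centres on a ring; `generate_lineage_table()` draws the
matching per-cell lineage records. The generator's defaults are the study
conditions for every property test in the package:

| parameter | default | rationale |
|---|---|---|
| `frame_interval` | 20 min | time-lapse acquisition interval of the source study |
| `cell_radius` | 15 µm | 8-cell blastomere scale (embryo ~60 µm radius when uncompacted) |
| `pixel_size`, `z_step` | 1 µm, 2 µm | confocal-scale sampling that keeps a movie desk-sized |
| `ep_probability` | 0.1 | per-cell EP rate; control arms in the source study span ~5–13% per cell |
| `ep_onset_window` | 60 min | the EP definition window |
| `lp_onset_mean`, `lp_onset_sd` | 220, 40 min | the late peak is described only as "broader"; these place it after compaction with realistic spread, truncated to stay after both compaction onset and the EP window so ground-truth labels are consistent by construction |
| `domain_arc_fraction` | 0.4 | apical caps subtend well under half of the exposed cortex; also keeps the rendered arc inside the detector's 33–80% admissible band after contact-band trimming at peak compaction |
| `domain_enrichment` | 2.0 | comfortably above the 1.5 detection threshold, as real EZRIN caps are |
| `compaction_start`, `compaction_rate` | 100 min, 1°/min | angles ramp 60° to 170° across the 8-cell stage; the 120° compaction threshold is crossed mid-movie |
| `compaction_max_angle` | 170° | equal discs degenerate (coincident centres) at 180°; the cap is a disc-model artifact, not biology |
| `p_sym_given_ep`, `p_sym_given_lp` | 0.717, 0.387 | the symmetric-division rates reported for EP and LP mothers |
| `p_te_given_polar`, `p_te_given_apolar` | 0.90, 0.20 | the study reports TE rates by *mother* class, which under-determines these daughter-conditional rates; the defaults imply mother-class TE rates of ~80% (EP) and ~69% (LP), near the published 82.8% and 68.3%, and are illustrative |

Compaction is emulated by shrinking the neighbour centre distance to
`d = 2 r cos(theta / 2)` — the closed-form inverse of the circle-circle
contact angle — so the rendered contact angle follows the configured ramp
by construction. Overlapping discs are partitioned by nearest centre
(Voronoi), which makes each cell's contact-free cortex exactly the part of
its circle outside all other discs. All randomness flows from the single
config seed; identical configs produce bit-identical stacks.

What the generator deliberately does **not** emulate: membrane mechanics
and cortical tension, fluorophore photophysics (bleaching, shot noise —
noise is additive Gaussian clipped at zero, the simplest model that
stresses the ratio criteria), nucleus segmentation errors, cell tracking
errors, and 16-cell-stage imagery (division outcomes are tabular). Passing
the recovery and calibration tests therefore demonstrates that the
*measurement chain* is correct under its stated assumptions; it does not
certify performance on real movies with segmentation noise or uneven
illumination.

## Problem sizes and numerical conventions

The package's own validation runs at sizes chosen to make the statistics
meaningful on a desk machine: 50 rendered embryos per noise condition for
onset recovery (about 350 observable onsets each), 5,000 simulated embryos
for EP-frequency calibration, 10,000 replicates for the z-test null and the
independence bootstrap, and exhaustive Fisher enumeration over all tables
of total 16 plus 300 random tables up to total 60. Onsets quantize to the
frame grid (ceiling); cells whose ground-truth onset falls within
`persistence - 1` frames of the movie end are censored by construction and
excluded from recovery denominators. Ties in the candidate search resolve
longest-then-smallest-start; angular positions wrap at ±180° with the
outward direction at 0°.

## Known limitations

* The disc-ring geometry compresses contact-free arcs more aggressively
  than real embryos at extreme compaction; above ~160° the measured IEA
  saturates a few degrees below the nominal ramp.
* `interblastomere_angle()` assumes locally circular or straight free
  boundaries; strongly scalloped cells would need a finite
  `tangent_arc_um`.
* The apex-geometry construction is this package's own; compare absolute
  values across tools with care.
* Image inputs must be pre-segmented; there is no shading correction.
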