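---
title: "Digital assessment of gingival recession coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital assessment of gingival recession coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

After root-coverage surgery (e.g. a coronally advanced tunnel with a
soft-tissue graft), the clinical questions are: by how much did the gingival
margin move coronally, did it reach the cemento-enamel junction (CEJ), and
how much thicker is the buccal soft tissue? Classically these are answered
with a periodontal probe against the CEJ, which is invasive, coarse
(~0.5 mm), and depends on a landmark that is often indistinct. Digitized
dental casts allow the same questions to be answered non-invasively at
scanner precision (~0.01 mm) by superimposing the baseline and follow-up
meshes and measuring on the surfaces.

`recess3d` implements that workflow end to end:

1. **mesh I/O** — STL reading/writing and validation, millimetre units
   throughout;
2. **registration** — principal-axes coarse alignment followed by
   point-to-plane ICP restricted to tooth crowns;
3. **measurement** — per-tooth outcomes: CEJ-dependent recession depth, mean
   root coverage (mRC) and complete root coverage (cRC), and two
   CEJ-independent metrics, recession reduction and a gingival
   thickness-change profile;
4. **statistics** — clustered group comparisons with Scheffé correction,
   intraclass correlation coefficients, and non-inferiority sample-size
   planning;
5. **synthetic data** — an arch generator with per-tooth ground truth that
   underwrites every stage's tests.

## Coordinate conventions

All coordinates are millimetres. No global anatomical frame is assumed:
every measurement is defined relative to per-tooth annotation vectors — a
`coronal_axis` (unit vector pointing coronally; apical is its negation) and
a `buccal_normal` (unit vector out of the buccal surface). The synthetic
generator emits occlusal = +z for mandibular and -z for maxillary arches,
but the measurement layer never relies on that; it reads the annotation
vectors. Transforms are strictly rigid — both timepoints are metric scans of
the same jaw, so no scale estimation is ever performed.

## Registration

The follow-up mesh is mapped into the baseline frame in two stages.

**Coarse alignment** matches centroids and principal axes of the two vertex
clouds. The four proper-rotation sign combinations of the axes are scored by
symmetric nearest-neighbour RMS distance on a 500-vertex subsample, and the
best candidate is kept. Vertex clouds whose covariance is rank-deficient
(e.g. a single triangle) are rejected.

**Refinement** is iterative closest point with a point-to-plane error
metric, which converges much faster than point-to-point on smooth,
locally planar dental surfaces. Design parameters:

* correspondence rejection at 1.0 mm, shrinking by 0.7 per stage to a floor
  of 0.2 mm — generous at first so the coarse alignment only needs ~1 mm
  accuracy, tight at the end so the changed gingiva cannot attract
  correspondences;
* convergence when the relative RMS change drops below 1e-6 (or an absolute
  floor of 1e-12 mm, the exact-overlap fixed point), at most 200 iterations;
* nearest-neighbour ties break to the lowest vertex index, and an iteration
  is only accepted if the RMS does not increase, so runs are deterministic
  and the residual trace monotone;
* rotations are re-orthonormalised (SVD) after every update.

**The crown mask.** Soft tissue changes between timepoints; tooth enamel
does not. Refinement is therefore restricted to vertices on the occlusal
band of the crowns — by default everything at least 5.5 mm coronal of the
CEJ level taken from the annotations. The 5.5 mm offset is chosen so the
band clears every surface that may legitimately differ between scans: the
thickness-gain band can reach ~5.4 mm coronal of the recession apex (i.e.
onto the cervical crown), and impression artifacts are modelled up to
~5.2 mm coronal of it. On synthetic pairs with gingival change but unchanged
crowns, crown-masked ICP recovers the true transform to machine precision,
while full-surface ICP is measurably biased by the changed tissue — the
quantitative version of the practice of selecting tooth surfaces by hand in
inspection software.

## Per-tooth metrics

Let \(a\) be the tooth's coronal axis. The **deepest recession point** of a
margin polyline is the point minimising \(p \cdot a\) (ties to the lowest
index).

**Recession depth** (CEJ-dependent): the margin apex and the CEJ reference
point are projected onto the axis and the difference
\((\mathrm{CEJ} - \mathrm{margin}) \cdot a\) returned; positive when the
margin is apical to the CEJ, negative when coverage overshoots it. The CEJ
reference is the CEJ polyline point nearest to the apex *in the plane
orthogonal to the axis*, so the apex cannot pair with a distant CEJ arm.
Teeth without a CEJ polyline are flagged and excluded from CEJ-dependent
summaries — the digital analogue of excluding casts with an indistinct CEJ.

**mRC** per tooth is \(100(d_{pre} - d_{post})/d_{pre}\); values above 100
(beyond the CEJ) and below 0 (worsening) are legitimate. **cRC** is the
percentage of teeth with \(d_{post} \le 0\), reported to two decimals.

**Recession reduction** (CEJ-independent) is the two-point distance between
the pre- and post-operative margin apices in the common frame. The 3D
distance itself is unsigned; the package attaches the sign of the axial
displacement component so that worsened recessions are representable (mRC
can be negative, so the CEJ-free metric must be too). A configuration
switch (`reduction: euclidean|axial`) selects either the signed Euclidean
distance (default, matching the two-point-distance tool of inspection
software) or the bare axial component; when the margin moves purely along
the axis the two coincide exactly.

**Thickness profile**: through the pre-operative apex a sagittal plane is
spanned by the coronal axis and buccal normal; the baseline surface is
sampled at axial offsets −3 … +3 mm in 1 mm steps, and at each sample the
deviation to the follow-up surface is measured along the buccal normal
(positive = outward gain). Deviations are taken along the annotated buccal
normal rather than each sample's local surface normal: for the near-parallel
surfaces being compared the two are equivalent to first order, and the
annotated direction is reproducible and rater-independent. Samples whose
ray finds no surface within ±3 mm (holes, impression artifacts) are
invalid. If all grid samples are valid the gain is their mean
(`full_profile`); otherwise the measurement falls back to the single
mid-axis sample at the apex (`apex_only`), reproducing the fallback used
when artifacts corrupt parts of the profile. An invalid apex sample is a
measurement failure and excludes the tooth from thickness summaries.
Whether the apex sample itself belongs in the 7-point grid is ambiguous in
the field's descriptions ("every 1 mm up to ±3 mm"); the package includes it
by default (`thickness.include_apex`), which makes the fallback a strict
subset of the full profile.

## The synthetic generator

`generate_arch_pair()` builds the buccal shell of a dental arch segment as a
cylindrical height field: a gingival roll, plus one smooth crown bulge per
tooth (superellipsoid-like cap; per-tooth size and skew variation breaks the
arch's symmetry, which also disambiguates the principal-axes signs during
coarse alignment). No anatomical tooth library is attempted — every metric
depends only on margin/CEJ geometry and local surface offsets.

Per tooth, drawn from a stream hashed from `(seed, tooth_id)` (so draws are
independent of tooth ordering):

| parameter | default distribution | rationale |
|---|---|---|
| recession depth | normal(1.34, 0.92) mm, truncated to [0, 5] | published six-month cohort scale; truncation keeps depths physical |
| coverage fraction | normal(0.65, 0.48), clipped to [0, 1.2] | mean/SD of published mRC; fractions above 1 make beyond-CEJ coverage occur stochastically (~23% of teeth) |
| thickness gain | normal(0.33, 0.30) mm | published mean gain for dermal-matrix grafts |
| artifact probability | 0.10 | reported rate of impression artifacts |

The follow-up mesh differs from baseline by (i) an outward displacement of
the drawn thickness gain along the buccal normal, uniform over a band
covering the ±3 mm sampling grid around the recession apex and
cosine-tapered to zero beyond (~6.8 mm plateau), (ii) face removal inside a
~2 mm crater next to the papilla on artifact teeth (centred 3 mm coronal of
the apex and offset sideways, so coronal profile samples fail while the
apex sample survives — exercising the fallback), (iii) Gaussian vertex
noise (default SD 0.01 mm, the scale of intraoral-scanner accuracy), and
(iv) a random rigid motion (rotation ≤ 10°, translation ≤ 5 mm).

**Margins are landmarks, not geometric steps.** The gingival margin and CEJ
are carried as exact polylines on each mesh's cervical reference surface: a
scalloped curve whose papilla tips sit 2.5 mm coronal of the CEJ and whose
mid-facial zenith sits at the drawn recession depth below it. The
gum-to-tooth step itself is not modelled geometrically — in the emulated
workflow the margin is likewise a manually picked curve, not a crease the
software detects. Two template choices make the generator an exact oracle:
the cervical collar of each tooth is a constant-radius band, and the crown
bulge only starts 1.2 mm coronal of the CEJ (more than the largest possible
overshoot). Margin displacement between timepoints is therefore purely
axial, so the drawn depths, reductions and coverage flags are recovered to
1e-6 mm by the measurement layer in the noise-free, exact-registration
limit — for both reduction modes. Likewise, because the inflation band is
uniform over the sampling grid and deviations are measured radially, the
drawn thickness gain is recovered up to triangulation error (≪ 0.01 mm at
the default mesh resolution).

What the generator does **not** emulate: real crown anatomy and
interproximal geometry, the feathered gum-tissue edge, scanner artifacts
other than local voids, occlusal wear, or any change to the teeth
themselves. Passing parameter-recovery tests therefore demonstrates the
correctness of the computational chain, not clinical validity on real
scans.

Mesh resolution defaults to 0.25 mm edge length — fine enough that
discretisation errors are two orders of magnitude below the measurement
tolerances, while keeping a full study (82 teeth over 19 patient arches)
generatable, registrable and measurable in about a minute.

## Statistical layer

**Group comparisons.** Teeth are clustered within patients. The package's
default fits the outcome with the factor of interest as a fixed effect and
the patient as a *random intercept* (`nlme::lme`), the standard treatment
for teeth-within-patient data; a literal fixed-effect reading
(`patient_effect: "fixed"`, `lm` with a patient factor and a type-II test)
is also provided, since study write-ups sometimes describe the patient term
as fixed while calling the model mixed. Pairwise contrasts come from
`emmeans` with Scheffé adjustment — each contrast's F statistic is divided
by \(k-1\) and referred to \(F_{k-1,df}\) — so adjusted p-values are never
smaller than unadjusted ones and are invariant to contrast ordering.
Simulation checks (fixed seeds) confirm the overall test holds its nominal
5% type-I error over 1000 null tables of 82 teeth in 19 patients, and that
contrast confidence intervals cover a true 0.5 mm group difference at
better than nominal rate (Scheffé intervals are conservative).

**ICC.** Reproducibility of repeated landmark picks is summarised by the
single-measurement intraclass correlation from the two-way mean-squares
decomposition: absolute-agreement ICC(2,1) by default (raters are a random
sample, and systematic rater offsets should count against agreement), with
consistency ICC(3,1) as an option; confidence limits use the standard
F-based construction. Replicate measurements are generated by re-running
the landmark-pick perturbation (`landmark_sd`, mm) per rater × replicate.

**Sample size.** The single-arm non-inferiority computation uses the normal
approximation \(n_0 = \lceil ((z_{1-\alpha/2} + z_{power})\,\sigma /
\delta)^2 \rceil\); with reference 87%, margin 10 points, SD 25 points,
power 0.90 and α = 0.05 this yields 66 teeth. The α is interpreted as the
*two-sided* 5% quantile because that is the interpretation under which the
canonical planning figure of 66 is reproduced. How a variance inflation
factor of 3 for clustered teeth combines with that figure admits no clean
decomposition (66 is already the unadjusted count); the package therefore
reports both the unadjusted \(n_0\) (headline) and
\(\lceil \mathrm{VIF} \cdot n_0^{raw} \rceil\) side by side rather than
guessing a single intent. Degenerate inputs: σ = 0 returns the enforced
minimum of one tooth; power ≤ α or an implausibly large margin
(≥ 10 σ) are parameter errors.

**Replicates in models.** When raters/replicates are present, models and
summaries use per-tooth means, matching the convention of averaging repeated
measurements before analysis; the raw replicates feed only the ICC.

## Numerical choices and degenerate inputs

* Vertex merge tolerance on STL read: 1e-6 mm — below scanner resolution,
  exactly enough to undo the per-facet vertex duplication of the format.
  Binary STL stores float32, so round-trips are exact only to half an ulp
  (~1e-6 mm at dental-cast coordinates); ASCII round-trips are exact to
  17 significant digits.
* Zero-area faces are dropped at validation; NaN coordinates and
  out-of-range indices are hard errors.
* All argmin/nearest selections (deepest point, CEJ reference,
  nearest-neighbour queries) break ties by lowest index.
* Complete-coverage flags use the exact threshold \(d_{post} \le 0\). A
  tooth whose true post-operative margin lies within the registration noise
  floor of the CEJ (of order 1e-3 mm under 0.01 mm vertex noise — about
  1/500 of clinical reading precision) is genuinely undecidable: its flag
  can flip under any estimator, including an oracle with exact
  correspondences. The package does not blur the threshold to hide this;
  such teeth are simply rare (probability ~1e-3 per tooth at study scale).
* Pipeline runs are deterministic given inputs and seed; every random
  stream (generator, landmark perturbation) derives from stable hashes of
  the seed and tooth id.

## Problem sizes used by the test suite

Unit tests run on 4–10-tooth arches (0.25–0.8 mm mesh resolution, the
coarser grids for draw-calibration tests that do not touch the surface);
the end-to-end recovery checks use a full 82-tooth study in 19 patient
arches at default resolution; statistical calibration uses 1000 null
simulations (300 in the quick unit variant) and 150–200 coverage
simulations. These sizes were chosen so the whole suite completes in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The generator's teeth are smooth bulges; there is no occlusal anatomy, so
  registration is easier than on worn or restored dentitions.
* CEJ and margin polylines are taken as given annotations; the package does
  not attempt automatic CEJ detection (which fails on colourless casts) or
  automatic margin tracing.
* The thickness measurement assumes the buccal normal pierces both
  surfaces; extreme malpositions would need per-sample local normals.
* Real inter-rater variability includes systematic landmark interpretation
  differences that a zero-mean Gaussian perturbation does not capture; the
  ICC machinery is validated on the simulated mechanism only.
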