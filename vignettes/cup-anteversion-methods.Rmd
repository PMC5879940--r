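---
title: "Measuring acetabular cup anteversion on plain radiographs: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup anteversion on plain radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupver)
```

## 1. The geometric model

`cupver` models the acetabular component as a zero-thickness hemispherical
shell of outer radius $r$ whose circular opening rim has unit normal
$\mathbf n$ (the *cup axis*), and the prosthetic femoral head as a sphere
concentric with the centre of rotation. The AP film is the coronal plane:
$x$ transverse (toward the patient's left), $y$ superior, the beam along
$+z$ (anterior to posterior); film coordinates are in millimetres.

**Radiographic anteversion** is the angle between the cup axis and the
coronal plane, signed positive for an anteriorly facing opening. Under a
parallel beam the rim projects to an ellipse with semi-major axis $a = r$
and semi-minor axis $b = r \sin(\mathrm{AV})$, so $\mathrm{AV} =
\arcsin(b/a)$; an AP film alone cannot distinguish ante- from retroversion
(both give the same ellipse), which only the lateral view resolves.
**Inclination** is the angle of the projected major axis to the transverse
film axis.

Two beam models are provided. The default is parallel: the published
formulas implicitly assume it, and the clinical acquisition (source-film
distance 115 cm) makes magnification nearly uniform — at that distance the
point-source and parallel axis *ratios* differ by well under 1%, which the
test suite verifies. The point-source model (central projection from 1150 mm,
configurable) is exact: the projected rim is recovered by a direct
least-squares conic fit through densely projected rim points, and rays are
rejected when the cup centre leaves the beam cone (modelled as the 43 cm
cassette field).

### The cross-table lateral

The lateral beam is horizontal, tilted 45° toward the head from the
patient's long axis, entering from the contralateral-medial side; the
cassette is held against the affected flank *perpendicular to the table*,
i.e. its plane contains the vertical and the long axis. The beam therefore
strikes the cassette obliquely, stretching the longitudinal film direction
by $1/\cos 45^\circ$. The Woo–Morrey reading — the signed angle between the
line touching the opening surface (the chord through the two
silhouette-extreme rim points) and the table-perpendicular reference line —
consequently satisfies, at ideal positioning,

$$\tan(\text{reading}) = \tan(\mathrm{AV}) / \cos(\text{cephalad angle}),$$

about $+7^\circ$ at $\mathrm{AV}=19.4^\circ$. This obliquity is a design
choice worth making explicit: had we modelled the cassette perpendicular to
the *beam*, the standardized lateral would read the truth exactly and the
well-documented systematic overestimation of the cross-table method would
vanish. The oblique-cassette model follows the described acquisition
("film fixed perpendicular to the examination table") and reproduces the
overestimation's direction and size; the closed form above is asserted in
the tests.

### The ray-trace oracle

`ray_trace_oracle()` is an independent brute-force check on all the
analytic geometry: one ray per film pixel, intersected with the solid
half-ball $\{|P - C| \le r,\ (P-C)\cdot\mathbf n \le 0\}$ and the head
sphere. Boundary pixels of the rendered mask must lie within one pixel of
the union of the analytic rim ellipse and sphere-outline circle; the
acceptance suite checks this at 0.1 mm/pixel over 50 random poses, and runs
the full edge-detection reference on the images.

## 2. The six measurement methods

On an exact ellipse, four of the five AP methods are algebraically the same
function $\arcsin(b/a)$:

* **Liaw** $= \arcsin(\tan\beta)$, where $\beta$ is the angle at one end of
  the long axis between the long axis and the line to the minor-axis
  end-point: $\tan\beta = b/a$. Requires $\beta \le 45^\circ$.
* **Lewinnek** $= \arcsin(D_1/D_2)$ with $D_1 = 2b$, $D_2 = 2a$.
* **Hassan** $= \arcsin\!\big(h/\sqrt{m(D-m)}\big)$: with the uncovered-rim
  point at head-radius distance $\rho$ from the centre along the long axis,
  $m = a + \rho$ (the larger candidate, as prescribed), $h = b\sqrt{1 -
  \rho^2/a^2}$, and the identity collapses to $\arcsin(b/a)$. The landmark
  exists only while $\rho < a$; at $\rho \ge a$ the extraction errors
  ("unidentifiable") rather than fabricating a point.
* **Ackland** $= \arcsin\!\big(y/\sqrt{2ax - x^2}\big)$ for an arbitrary
  perpendicular tangent at distance $x$ from the ellipse end; exact for any
  $x \in (0, 2a)$, and the noise-free reading is invariant to the choice
  (a property test). We read the printed $2y / 2\sqrt{\cdot}$ with $y$ the
  *half*-chord: under the full-chord reading the argument exceeds 1 for
  typical poses, so the half-chord interpretation is the only one that
  recovers $\arcsin(b/a)$. This is our resolution of an ambiguous figure,
  not a documented authorial intent.
* **Widmer** $= 48.05\,(S/TL) - 0.3$ within $0.2 < S/TL < 0.6$. $S = D_1$
  (stated explicitly), and we fix the under-specified $TL$ as the distance
  from the rim-side end of the short axis through the centre to the dome
  apex of the sphere silhouette, giving $TL = a + b$ and $S/TL =
  2\sin/(1+\sin)$. At $19.4^\circ$ the linear formula then returns
  $\approx 23.7^\circ$ — an overestimate of the same sign and size as the
  clinical finding, which is why this convention was chosen over
  alternatives (e.g. $TL = 2a$, which would make $S/TL = b/a$ and the
  method nearly exact). Outside the validity window the value is still
  returned but flagged. The alternative printed form $\arcsin(S/TL)$ is
  mutually inconsistent with the linear one ($\arcsin 0.5 = 30 \ne
  23.725$); it is exposed as `form = "arcsin"` but the linear form is
  canonical because it carries the validity condition and the observed
  bias direction.

Readings are kept at full precision internally and rounded only at
presentation (2 decimals in the rendered tables). Arcsine arguments within
$10^{-9}$ of $[-1, 1]$ are clamped (floating-point guard); beyond that the
functions error, since a genuinely out-of-range argument means inconsistent
landmarks, not noise.

## 3. The edge-detection reference standard

The commercial reference's algorithm is proprietary and described only
behaviourally (select head points, fit a circle; select shell points, fit a
circle; select rim-edge points, reconstruct the opening ellipse centred on
the centre of rotation). `cupver` implements that description:

* `fit_circle()`: exact circumcircle for 3 points; Kåsa algebraic fit plus
  geometric (orthogonal-distance) Gauss–Newton refinement for more.
* `reconstruct_opening_ellipse()`: centre pinned to the head centre,
  semi-major pinned to the shell radius, orientation and semi-minor
  estimated by least squares on the implicit equation (a 1-D search over
  orientation with a closed-form $1/b^2$ per candidate). Whether the real
  software pins the semi-major is unknown; pinning is our design decision,
  and the suite verifies the constrained fit has lower version RMSE than a
  free 5-parameter conic fit under rim jitter — the constraint *is* the
  design point of a head-centred reconstruction.
* `version_reference()` $= \arcsin(b/a)$, unsigned unless a lateral
  retroversion flag is supplied.

Digitization density: the operator clicks three points per structure to
seed an automatic edge detector that traces "multiple points". We model the
reference's input as 12 jittered boundary points per curve, which places
the reference's reading noise (~0.65°) in the reliability class the
clinical study reports for it (ICC ≈ 0.96); the fits degrade gracefully to
the exact 3-point case.

## 4. The observer-noise model and the synthetic cohort

Every landmark object stores its defining film *points*; scalars
($D_1$, $S$, $TL$, …) are recomputed from the points, so noise enters the
way a human marking film introduces it. `perturb()` applies, per point,

* iid isotropic Gaussian jitter, `landmark_sd_mm` (default **0.5 mm**, the
  prescribed noise scale), redrawn per observer × session × patient, and
* a per-observer systematic offset per landmark role, drawn once per
  observer with sd `observer_bias_mm` (default **0.2 mm** — our choice; the
  near-equal intra- and inter-observer ICCs reported clinically imply
  systematic observer differences well below the random jitter, and 0.2 mm
  ≈ one display pixel). The bias is what separates inter- from
  intra-observer reliability.

Perturbed landmarks are re-validated against their type invariants and
resampled on violation (bounded retries), so impossible measurements
(e.g. $D_1 > D_2$) never reach the formulas.

`cohort_config()` states the simulated world: 71 patients; anteversion
truncated-normal, mean 19.4°, sd 3.5°, range [12.6°, 27.8°] (the reported
mean and range; the sd is chosen so the truncation is mild); inclination
45° ± 5° truncated to (25°, 65°) — an assumption flagged in the provenance
output, since the source reports no inclination summary; cup outer diameter
triangular on 46–60 mm with mode 50 mm snapped to the 2-mm shell sizes;
28 mm heads (typical for these shells; head sizes are not reported);
pelvic tilt and rotation N(0, 2°) per patient (standardized positioning);
3 observers × 2 sessions. All randomness derives from one integer seed;
regeneration is byte-identical, which the suite asserts on the written CSV
and YAML files.

What the generator deliberately does **not** emulate: image-quality
variation between patients (contrast, liner obscuration, overlap), which in
real data adds per-patient, method-specific scatter; CT-grade anatomical
anteversion; excluded-patient logistics. A green test therefore establishes
correctness of the geometry, formulas, noise plumbing and statistics — not
that the synthetic ICCs or p-values will numerically match any particular
clinical cohort.

## 5. Reliability and accuracy statistics

The reliability coefficient is ICC(2,1) — two-way random effects, single
rater, absolute agreement — computed from the two-way ANOVA mean squares
with the McGraw–Wong F-based 95% CI. The form is our decision (the source
names no ICC variant); absolute agreement matches "consistency in
measurement" across interchangeable raters. Intra-observer reliability uses
exactly the two repeat sessions per observer (the "reassessed twice"
reading), averaged across observers; inter-observer uses the three
observers' session-1 readings. The implementation is a direct
row/column-mean decomposition; the tests check it to $10^{-10}$ against an
independent `aov()`-based oracle and against frozen values from an external
reference implementation (pingouin 0.6.1), point estimate and CI.

Accuracy is the paired *t* test of each method against the reference, on
per-patient values averaged over observers and sessions, with raw two-sided
p-values (no multiplicity correction, following the source). Ranges are
reported min–max at 2 decimals.

## 6. Known limitations, and which stated properties fail

Two acceptance properties are *not attainable in the stated world*, and we
keep them red rather than tuning the world toward them; the package's
acceptance suite computes the numbers below at its canonical seed.

1. **"All seven methods' ICCs exceed 0.9 at 0.5 mm noise."** 0.5 mm point
   jitter maps to method-dependent reading noise: about 0.9° for the
   axis-length methods (Lewinnek, Widmer), 0.65–0.8° for the reference and
   the lateral, but 1.5–2.1° for the short-lever methods — Liaw's $\beta$
   sits at a vertex with a ~26 mm lever, Hassan's $h$ is a short chord,
   Ackland's $y$ likewise. Against a truncated-normal truth spread of
   ~3.2°, $\mathrm{ICC} \approx \sigma_T^2/(\sigma_T^2 + \sigma_e^2)$ caps
   Liaw near 0.85, Ackland near 0.8 and Hassan near 0.7. The delta-method
   scale ("0.5 mm on a 12 mm axis ≈ 1–2°") concedes exactly the noise
   magnitude that makes >0.9 impossible for those methods. The real study's
   observers were evidently more precise than 0.5 mm on the short-lever
   landmarks.
2. **"The paired test does not flag Liaw."** With per-observer bias in the
   generator, the Liaw-minus-reference difference contains a systematic
   component drawn once per seed (~N(0, 0.4°)); averaging 6 readings per
   patient shrinks the per-patient scatter to ~0.7°, so a paired *t* at
   n = 71 detects essentially any nonzero bias draw. The clinical data had
   per-patient difference scatter near 3.6°, which swamped biases of that
   size. Liaw's *mean* stays within 1° of the reference (that clause
   holds); its p-value is a seed lottery and at the canonical seed it is
   flagged. Making the test insensitive (single readings, inflated
   per-patient noise) or shrinking the bias after observing the outcome
   would be calibration-to-pass, so the clause stays red with this
   explanation.

Other limitations: zero shell thickness (no formula uses it); no
femoral-stem rendering beyond the head sphere; the lateral branch supports
the parallel beam only; no DICOM/PACS handling; wear measurement — the
reference software's main clinical use — is out of scope.
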