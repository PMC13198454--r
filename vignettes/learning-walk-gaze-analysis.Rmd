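---
title: "Methods: learning-walk gaze analysis under magnetic field alteration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning-walk gaze analysis under magnetic field alteration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antgaze)
```

## The behavioral model

Naïve desert ants calibrate their navigation systems during learning walks:
short excursions around the nest entrance, punctuated by pirouettes — tight
turns about the body axis during which the ant stops repeatedly. During the
longest of those stopping phases the ant's gaze is directed back toward the
nest entrance, even though the entrance itself is invisible. The working
hypothesis behind the experimental design this package supports is that a
magnetic compass steers that gaze: if the horizontal component of the
geomagnetic field (GMF) is rotated by an angle θ while the ant is on the
platform, a magnetically guided ant should direct its longest-stop gaze at
the *fictive* nest — the nest position rotated by θ about the ant's
position at the moment the coil field switches on.

The analysis chain is therefore: per-frame mandible and thorax positions →
per-frame gaze azimuth → stopping phases within annotated pirouettes →
longest-stop gaze relative to the real and the fictive nest → circular
statistics across ants.

## Conventions

* **Arena frame**: x east, y north, origin at the platform center (the nest
  tube exit), units cm. Azimuths are degrees clockwise from +y, in
  [0, 360).
* **Field frame**: X toward magnetic north, Y east, Z down (µT), matching
  the display of a vector magnetometer. Declination is degrees clockwise
  from north in (−180, 180], inclination positive downward in [−90, 90].
* **Alteration sign**: θ > 0 is a clockwise (eastward) rotation viewed from
  above. The *same* sign convention drives the coil geometry
  (`predict_altered_field()`) and the fictive-nest rotation
  (`fictive_nest()`), so one parameter describes the whole manipulation.
* **Relative gaze**: `(heading − bearing(mandible, goal) + 180) mod 360`.
  Perfect fixation of the goal maps to 180°; gazing exactly away maps
  to 0°. Rose plots of goal-directed behavior therefore concentrate
  around 180°.

## Field geometry

For an alteration θ that preserves the horizontal magnitude `B_H`, the coil
must generate the chord vector between the original and the rotated
horizontal component:

* magnitude `B_coil = 2 B_H sin(|θ|/2)` — reducing to `2 B_H` at θ = 180°
  and `2 cos(30°) B_H` at θ = 120°;
* direction `(θ/2 + 90°) mod 360` from magnetic north (for θ > 0).

`coil_field_for_alteration()` reports both the generated-field azimuth and
the geometry of the physical coil frame. The two are easy to conflate in
field protocols: for θ = +120° the generated-field *axis line* lies 30°
from the north–south line while the coil *winding plane* (perpendicular to
the axis) lies 60° from it. Both numbers are reported so a protocol stated
in either convention can be checked.

`verify_alteration()` automates the before/after magnetometer comparison
with explicit tolerances on the declination shift, the horizontal
magnitude, the vertical component and the total intensity. Magnetometer
displays round angles coarsely (the bundled example measurements show
declination and inclination at roughly 0.5° steps), so angle comparisons
always go through user-visible tolerances; the package defaults to 3° and
1 µT. Two caveats in the bundled example file are worth knowing: the
after-180° row is internally inconsistent between its angular and
component values (most plausibly the sensor was reoriented between
readings), and the after-120° row shows a horizontal magnitude about
1.7 µT above its before-row — a real imperfection of the realized field, so
verification of that pair passes only at a 2 µT magnitude tolerance.

## Gaze, goals and the pirouette pair

The gaze axis is the thorax→mandible body axis — exactly the two digitized
landmarks, with no head-articulation model (none is available from
two-point tracking). The bearing to a goal is taken from the mandible
position, for consistency with the fictive-nest construction, which rotates
the mandible→nest vector.

The fictive nest is frozen at the coil switch-on moment: the first frame
with `t ≥ switch_on_t` supplies the mandible position, and the nest is
rotated by θ about it. With θ = 0 the construction returns the real nest,
which gives the pipeline a useful sham-invariance property that the test
suite checks exactly.

Per ant, one pirouette is analyzed on each side of the coil event: the
*last* annotated pirouette ending before switch-on and the *first* one
starting after it, each subject to the distance rule that its mean mandible
position lies at least 5 cm (configurable) from the nest entrance.
Describing the pre-switch pirouette as "the last one before switch-on" is a
deliberate design decision: protocols are sometimes worded ambiguously on
this point, and the last-before choice is the one that pairs the two
pirouettes closest in time around the manipulation. Ants with no qualifying
pirouette are excluded with a machine-readable reason, never silently, and
the per-block sample sizes plus exclusions always add up to the number of
ants.

## Stopping phases

A stopping phase is a maximal frame window inside a pirouette in which

1. every frame's forward (thorax) speed is ≤ `max_forward_speed`,
2. every frame's heading lies within ± `gaze_tol_deg` of the window's
   circular-mean heading, and
3. the window spans at least `min_duration_ms`.

Defaults: 10°, 100 ms, 0.5 cm/s. The tolerance and minimum duration follow
the established stop criterion for this behavior (±10° for at least
100 ms); the speed threshold is not part of that published criterion, so
the default of 0.5 cm/s is an explicit, configurable choice echoed into
every report. Gaze constancy is judged against the window's circular mean
rather than frame-to-frame increments: "±10°" most naturally bounds the
excursion around one constant direction, the definition is
order-independent, and — crucially for testing — it can be checked by
exhaustively enumerating every window. The detector's optimized
implementation (pairwise-spread pruning within slow runs) is validated
against exactly that brute-force oracle on 1,000 random tracks in the test
suite, and must agree frame-for-frame.

Durations count the inter-frame span `(end − start)/fps`: at 50 fps a
5-frame window spans 80 ms and does *not* qualify; 6 frames (100 ms) is the
minimum. This is stated explicitly because frame-counting versus
span-counting is a classic source of off-by-one discrepancies between labs.

Ties for the longest phase are broken by earliest start. "Stop of
rotational movement" is implied by the gaze-constancy bound; an optional
separate angular-speed cap exists but is off by default.

## Circular statistics

For angles α₁…αₙ, the resultant `R = |Σ(cos αᵢ, sin αᵢ)|`, mean resultant
length `r = R/n`, mean direction `µ = atan2(ΣS, ΣC)`, and Rayleigh statistic
`Z = n r²`. The Rayleigh p-value uses the standard approximation
`p = exp(√(1 + 4n + 4(n² − R²)) − (1 + 2n))`, which is accurate to three
decimals at the sample sizes this analysis uses (n ≈ 15) — the test suite
pins it to reference values at that precision, and a 10,000-replicate
simulation confirms a type-I error rate of ~0.05 at n = 15.

The 95% CI for µ is Zar's two-branch formula (branch switch at r = 0.9),
with `χ²₁ = 3.841`. A CI is reported as *not reliable* — bounds suppressed —
when the arccos argument leaves [0, 1] or when the Rayleigh test is not
significant at 0.05: confidence arcs around an undirected sample are
meaningless. Different circular-statistics programs compute this interval
by different methods (dispersion-based and bootstrap variants exist), so
the package validates its CI by coverage simulation — at κ = 8, n = 15 the
interval covers the true goal direction at its nominal rate (the test
accepts 0.90–0.99 over 200 simulated experiments) — rather than by
matching any particular program's printed bounds.

The Mardia–Watson–Wheeler test ranks the combined sample around the circle
(midranks for ties; tie-handling is another point where programs diverge,
so it is stated here), maps ranks to uniform scores `βᵢ = 2π rankᵢ/N`, and
computes `W = 2[(C₁² + S₁²)/n₁ + (C₂² + S₂²)/n₂]`. Under the null W is
asymptotically χ² with 2 df (`p = exp(−W/2)`); for small samples a
Monte-Carlo permutation p-value is available, and `method = "auto"` uses
χ² only when both samples have n ≥ 10. The Monte-Carlo p is
`(hits + 1)/(n_perm + 1)` and is validated against exhaustive enumeration
of all relabelings at n₁ = n₂ = 4. A combined sample of identical angles
is degenerate; it is reported as `W = 0, p = 1` with a flag rather than a
misleading large W from tied midranks.

Histograms use half-open 10° bins `[0, 10), [10, 20), …` matching the
conventional rose-plot binning for this behavior.

## The synthetic generator

`simulate_experiment()` produces datasets with exactly the statistical
structure the pipeline assumes, plus frame-accurate ground truth. Per ant:
a correlated random walk (waypoint-directed, von Mises heading noise,
0.2 cm steps = 10 cm/s at 50 fps) to a pirouette site 8–18 cm from the
nest; a pirouette consisting of alternating rotation segments and stops,
with the thorax anchored up to 0.002 cm Gaussian jitter; then a walk leg
during which the coil switches on at the midpoint frame; then the
after-epoch pirouette aimed at the fictive nest.

Choices that matter:

* **Gaze concentration κ = 8** for the designated longest stop (before and
  after epochs alike). No empirical κ is published for this behavior; κ = 8
  yields sample mean resultant lengths in the 0.5–0.9 range typical of
  n = 15 experiments of this kind, and it is clearly a synthetic choice.
* **Designated stops draw 240–400 ms, decoys 120–180 ms.** The ranges are
  disjoint, so the designated stop is always the longest — ground truth
  stays unambiguous.
* **Stops hold heading exactly constant** (saccade-like fixation), and
  rotation frames adjacent to a stop stay ≥ 25° away from the stop heading
  with 15°/frame steps. Because 25° exceeds twice the 10° gaze tolerance,
  no detection window can bridge a stop boundary, and detected maximal
  windows coincide *frame-exactly* with the ground-truth windows — the
  stop-detection-fidelity test demands identity, not approximation.
* **Decoy stops gaze uniformly at random**: the behavioral claim concerns
  only the longest stopping phase, so the generator is deliberately
  agnostic about the others.
* The designated heading is `bearing(thorax → goal) + ε`, ε ~ von Mises(0, κ).
  The mandible then sits on (or near) the thorax–goal line, so in the
  noise-free limit the relative gaze is exactly 180°; with noise, the
  mandible-based bearing used by the analysis differs from the thorax-based
  one by at most ~0.3°·sin ε at the simulated distances — a zero-mean,
  symmetric perturbation far below the effects of interest.
* The switch-on time is placed per ant at the midpoint of the inter-epoch
  walk leg and recorded in that ant's coil event, since track lengths vary
  between ants.

What the generator does **not** emulate: real gait dynamics and
tracking-noise autocorrelation, head articulation relative to the body
axis, the empirical duration and angular statistics of non-longest stops,
occlusions and digitization error, or any gradient/inhomogeneity of the
coil field. Passing the recovery tests therefore shows that the pipeline
correctly inverts the generative model it targets — it does not certify
robustness to every artifact of real video tracking (the validation
findings of `validate_track()` exist to surface those).

## Numerical choices and degenerate inputs

* Angles wrap via `x %% 360`; signed circular differences live in
  (−180, 180]. A mean direction of a zero-resultant sample is undefined and
  reported as `NA`, never defaulted.
* Degenerate frames (mandible = thorax within 1e−6 cm) are retained in
  tracks, flagged on read, excluded from heading computations, and break
  stopping-phase windows.
* A vertical-only field has undefined declination: `dib_from_xyz()` returns
  `NA` with inclination ±90 rather than guessing.
* Exact-tolerance boundaries are inclusive (`max_dev ≤ tol`,
  `speed ≤ threshold`, `span ≥ min`); the brute-force oracle in the test
  suite uses the same inclusive comparisons.
* Reports serialize deterministically (no timestamps); identical inputs and
  seeds give byte-identical JSON.

## Validation problem sizes

The test suite validates at desk scale: 1,000 random tracks of 20–200
frames against the exhaustive stop oracle; 10,000 uniform replicates for
Rayleigh type-I calibration; exhaustive (70-relabeling) permutation checks
at n₁ = n₂ = 4; and 200 simulated 15-ant experiments per alteration angle
(θ = 120°, 180°) for recovery and CI coverage. These sizes are the
package's own choices, balancing statistical resolution of the checked
rates against a test suite that runs in a few minutes.

## Known limitations

* Only two-point (mandible/thorax) tracks are supported; no pose models.
* The heuristic pirouette detector (`detect_pirouettes()`) is a convenience
  for pre-annotation only; the analysis pipeline trusts manual annotations.
* The Rayleigh p approximation and Zar CI are large-sample formulas; below
  n ≈ 8 their accuracy degrades, and the MWW χ² tail should not be used
  below n = 10 per group (the `auto` method switches to permutation).
* Coil hardware (winding counts, current calibration, field homogeneity) is
  out of scope; the field module handles vector algebra only.
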