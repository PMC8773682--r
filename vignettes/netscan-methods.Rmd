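---
title: "How netscan identifies and quantifies NETs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How netscan identifies and quantifies NETs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay model

`netscan` analyses live-cell, in-situ plate imaging of neutrophils
stained with two DNA dyes: Hoechst 33342 (membrane-permeable, stains
every nucleus) and a membrane-impermeable dye — Sytox Green or propidium
iodide (PI) — that only stains cells whose membrane integrity is lost.
Because no fixation or washing is involved, fragile NET structures stay
intact and the same wells can be imaged repeatedly over time.

Three observable cell states follow from the biology:

* **Live** cells exclude the impermeable dye entirely.
* **NET-forming** cells are permeable *and* show a large, decondensed
  dye-positive chromatin cloud — several-fold the area of a resting
  nucleus.
* **Other dying** cells (necrotic, late apoptotic) are permeable but
  keep a condensed, small nucleus.

The classifier is therefore a pair of per-cell gates: an intensity
reference I\* deciding "is this cell dye-positive?", and an area
reference A\* deciding "is the dye-positive chromatin decondensed?". A
cell at or above both gates is a NET (Type 1); at or above the intensity
gate only, other death (Type 2); below the intensity gate, live
(Type 3). Gates use `>=`: a cell exactly at a reference level counts as
a responder. This boundary convention is arbitrary in principle; it is
fixed, documented and tested so results are reproducible to the cell.

With a fourth channel (Annexin V), Type 2 is refined. Surface-localized
Annexin V — phosphatidylserine exposed on the outer membrane leaflet —
marks apoptosis both before (early) and after (late) membrane
permeabilization; bare PI positivity without surface Annexin marks
necrosis. Precedence is NET > apoptotic > necrotic, for two reasons:
Annexin V also binds the spilled phosphatidylserine of lysed NET-forming
cells, so nuclear decondensation must dominate Annexin positivity; and
surface Annexin must dominate bare PI positivity or late apoptosis would
be miscounted as necrosis.

## Pipeline stages and the parameters that matter

All length parameters are in micrometres and converted internally using
the configured pixel size (default 0.65 µm/px for a 20× objective), so
gates transfer across magnifications.

**Background correction** (`correct_background`). The background is
estimated by grayscale morphological opening with a disc of radius
`background_radius_um` (default 30 µm) and subtracted, clipping at zero.
The radius must exceed the largest nuclear radius, otherwise nuclei are
flattened into the background and erased. A constant image maps to all
zeros, and the operation is idempotent up to rounding. Reflective
padding avoids edge artefacts. No flat-field (calibration-image)
correction is attempted.

**Smoothing** (`smooth`). A separable Gaussian of `smooth_sigma_um`
(default 1 µm) is applied to the nucleus channel *for segmentation
only*: it stabilizes thresholding and object splitting. All intensity
and area features are measured on background-corrected but unsmoothed
pixels, so the gates are never blurred by a preprocessing choice.

**Segmentation** (`identify_primary_objects`). The nucleus-channel
threshold is Otsu's bimodal value multiplied by `threshold_scale`
(default 0.6). The deliberate under-scaling keeps the dimmest objects —
NET remnants whose Hoechst signal fades as chromatin decondenses, and
condensed apoptotic nuclei — inside the analysis; losing them would bias
percent NETosis upward. Touching nuclei are split by a watershed on the
negated Euclidean distance transform, with seed suppression over a
neighbourhood of `segmentation_radius_um` (default 4 µm, the expected
nuclear radius) and an h-maxima tolerance of 0.5 px; ties are resolved
deterministically, so identical inputs always give identical masks.
Objects below `min_object_area_um2` (default 12 µm²) are debris and are
removed. Objects touching the field border are kept in the object table
flagged `border = TRUE` but excluded from quantification: partial nuclei
bias the area gate.

**Target mask** (`build_target_mask`). Each cell's measurement region is
its nuclear mask dilated by `dilation_um` (default 8 µm), chosen so that
a decondensed NET cloud — up to ~6× the resting nuclear area — still
lies inside its own cell's region. Where dilations overlap, each
contested pixel is assigned to the object with the nearer centroid
(ties to the lower label), so regions partition their union and
adjacent NET clouds cannot double-count dye area. A per-object dilation
with centroid arbitration was chosen over a global connected-component
assignment precisely because NET clouds from neighbouring cells merge.

**Channel-2 foreground.** The impermeable-dye channel is thresholded per
field at median + 5×MAD of its background-corrected pixels. A robust
location/scale rule was chosen over Otsu here because control fields
legitimately contain *no* dye-positive cell: there is no bimodality to
find, and an Otsu split of pure noise would manufacture foreground. With
the vast majority of pixels being background, the rule sits just above
the noise floor in stimulated and control fields alike. No size filter
is applied to this mask — NET clouds may be arbitrarily diffuse.

**Features** (`measure_objects`). Per cell: nuclear area; target area
(dye-foreground pixels inside the target region, in µm²); mean dye
intensity over the *full* target region — not only over foreground
pixels — so the intensity gate responds to both brightness and spatial
extent; and mean Hoechst intensity. In four-channel mode two Annexin V
descriptors are added. The *ring ratio* is the mean Annexin intensity in
the perinuclear shell (a band of `shell_width_um`, default 1.5 µm, just
outside the nuclear mask, clipped to the cell's target region) divided
by the mean over the nucleus plus a 1-intensity-unit stabilizer. The
shell is anchored on the nucleus rather than on the outer boundary of
the dilated target region because in a shrunken apoptotic cell the
plasma membrane hugs the condensed nucleus; the outer region boundary
lies ~8 µm further out, where there is no membrane and the ratio would
never respond to genuinely surface-localized staining. The *coefficient
of variation* over the target region is reported as a punctate-staining
descriptor; it is logged and available for stricter gating
(`annexin_cv_ref`, default 0.8) but the default NET branch relies on the
area gate alone, since punctate Annexin is a characteristic of
NET-forming cells rather than a necessary condition.

**Reference levels** (`estimate_reference_levels`). I\* is the
between-class-variance (1-D Otsu) split of per-cell dye intensities
pooled over *all* wells — stimulated cells supply the upper mode,
control cells the lower. Gates are estimated once per plate, not per
well, so every treatment is scored against the same rule. Pooling is
only trusted when Sarle's bimodality coefficient of the pooled sample
reaches 0.555 (the uniform-distribution benchmark); below that — e.g. an
entirely unstimulated plate — I\* falls back to median + 5×MAD of the
control-well intensities. A\* is `area_multiplier` (default 2) times the
median nuclear area of control-well dye-negative cells: "decondensed"
operationalized as at least twice the resting nucleus. Estimation
refuses to run with fewer than 50 control objects and manual gates can
always be supplied; every run's manifest records the effective numeric
gates and their provenance.

Note that "big decondensed nucleus" is measured on the *channel-2
target area* (the dye-accessible chromatin cloud), not on the Hoechst
area: NET DNA stains brightly with the impermeable dye while the
Hoechst signal dims, so channel 2 is where decondensation is visible.

## Quantification and statistics

Percent NETosis per well is 100 × NET cells / total Hoechst-positive
(non-border) cells, pooling all fields of the well. Wells — not fields —
are the replicate unit for statistics, matching how treatments are
assigned; two groups are compared with an unpaired equal-variance t test
(Welch available by flag), more with one-way ANOVA, starred at
p < 0.05/0.01/0.001. No multiple-testing correction is applied and
p-values are reported as unadjusted. Degenerate fixtures (all replicate
values identical) are reported as statistic 0, p = 1 rather than an
error.

## Time-lapse fate classification

Frames 15 min apart at screening densities leave cells essentially
stationary relative to their spacing, so detections are linked by greedy
nearest-pair assignment: candidate (track, detection) pairs are sorted
by distance, assigned greedily, and moves beyond `max_displacement_um`
(default 10 µm per frame interval) are forbidden; up to `max_gap`
(default 1) missed frames are bridged. On sparse fields this greedy rule
coincides with the optimal assignment, which the test suite verifies
against brute-force enumeration. Merges are not specially handled —
neutrophils are terminally differentiated, so no mitosis logic is
needed.

A track's fate follows the permeability/decondensation sequence: LIVE if
the intensity gate never passes; NETOSIS if it passes and the dye area
reaches A\* at or after first permeability; NECROSIS only if the area
stays below A\* *and* the track persists at least `min_follow_min`
(default 45 min, three frames) beyond first permeability — without that
follow-up requirement a cell that would have decondensed after the
observation window would be miscalled, so such tracks are AMBIGUOUS
instead. Tracks with fewer than three detections are not classified.

## What the synthetic generator does and does not emulate

`generate_field` renders the four phenotypes on a 16-bit canvas:
multilobed live nuclei (union of 2–4 offset discs around a 3.5 µm
resting radius), NET clouds as Gaussian-profile blobs whose footprint is
a per-cell decondensation factor drawn uniformly from 2.5–6× the resting
nuclear area (entirely above the area-gate multiplier of 2, so
ground-truth NETs are separable in expectation), condensed bright
necrotic and apoptotic nuclei, and for the four-channel mode an Annexin
ring (apoptosis) or scattered puncta (NETs). Rendering applies a
Gaussian point-spread (0.8 µm), a constant-plus-gradient background,
signal-dependent shot noise and Gaussian read noise. Cell placement uses
rejection sampling with a minimum spacing; per-cell states are drawn
independently from the requested class probabilities, so the total cell
count is exact while the realized composition varies multinomially
between fields — replicate wells therefore carry the sampling variance
that makes ANOVA and t statistics well-posed. Every output is a pure
function of (parameters, seed).

`generate_timelapse` scripts trajectories on fixed cell positions
(jitter < 2 µm/frame): necrosis becomes permeable between 30 and 60 min
with its area constant; NETosis becomes permeable between 60 and 120 min
and grows monotonically to its sampled factor over 3–5 frames; live
cells never become permeable.

The generator deliberately omits: photobleaching, focus drift and
stage drift; illumination falloff beyond a linear gradient; cell
motility and clumping beyond the spacing constraint; vital NETosis
(anuclear live cytoplasts); donor-to-donor variability; and the
irregular, filamentous texture of real NET clouds. Passing the
end-to-end tests therefore demonstrates that the gating logic, the
estimator and the bookkeeping are correct under realistic noise and
density — it does not certify segmentation quality on real micrographs,
which should be spot-checked per instrument with the exported masks.

## Numerical choices

* Coordinates are 0-based (row, col); labels are positive integers with
  0 = background; label masks are relabelled densely and exported as
  16-bit TIFFs.
* Both preprocessing operators use reflective padding; the watershed and
  the contested-pixel arbitration break ties deterministically (lower
  label wins), so the whole pipeline is bit-reproducible.
* The ring-ratio denominator carries a +1 intensity-unit stabilizer
  against empty interiors; the channel-2 robust threshold adds 1e-9 so
  an all-zero field yields an empty foreground.
* Degenerate inputs are classed errors: constant images under automatic
  thresholding, plates without control wells under automatic gate
  estimation, tracks shorter than three frames.
* 12-bit acquisitions are carried in 16-bit TIFF containers; pixel
  values round-trip bit-exactly.

## Test problem sizes

The validation suite runs entirely on generator output: 1024² px fields
with 500 cells per field and six fields per well for the dense recovery
plate; 512² px fields with 150 cells for the dose-ladder (4 doses ×
triplicate wells), inhibitor-contrast and partition checks; and 13-frame
series (0–180 min by 15) with 60–100 cells for tracking. These sizes
give per-well counts in the thousands — comparable to a real 6–10
field/well acquisition at 3×10⁴ cells/well — while keeping the full
suite to a few minutes on one CPU.

## Known limitations

* Heavily overlapping NET clouds from *touching* cells are attributed by
  centroid distance, which is approximate when clouds are very
  asymmetric.
* The live gate consults only the intensity reference; a dye-negative
  cell with a bizarre Hoechst morphology still counts as live.
* Necrosis vs late apoptosis requires the Annexin channel; in
  two-channel mode both fall into "other death".
* Tracking assumes near-stationary cells; chemotactically migrating
  neutrophils at short frame intervals would need a motion model.
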