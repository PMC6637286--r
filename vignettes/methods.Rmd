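---
title: "Methods: phantom-validated quantification of neonatal pulmonary vascular disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated quantification of neonatal pulmonary vascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmovasc)
```

`pulmovasc` implements the quantitative analysis chain used to phenotype
experimental bronchopulmonary dysplasia with secondary pulmonary
hypertension (BPD-PH) in newborn mice, together with seeded phantom
generators that emulate every input with known ground truth. This
vignette records the models, parameter choices and numerical decisions,
and what the phantom validations do and do not show about real data.

## Why phantoms

The study design this package supports measures vascular rarefaction on
animals: micro-CT of iodine-stained lung lobes, *in vivo* subtraction
angiography, precision-cut lung slice (PCLS) reactivity, Doppler
echocardiography and cardiac histology/qPCR. No raw image data of that
kind is redistributable here, and the headline numbers are biological
measurements, not deterministic functions of code. The package therefore
ships generators that emulate the *statistical structure* of each input
— tube geometry and partial volume for CT, contrast arrival over a
static background for angiography, a logistic lumen-area law for PCLS, a
single-peaked ejection envelope for Doppler, group-mean CT tables and
two-class stained sections — with every emplaced structure recorded as
ground truth. Each analysis stage is validated by parameter recovery:
the pipeline must recover what the generator put in, under the group
differences the study reports.

What passing these validations shows: the implementation is internally
consistent, unbiased at the calibres and noise levels the phantoms
cover, and sensitive enough to recover the reported group contrasts.
What it does not show: robustness to reconstruction artifacts, motion,
staining variability, anatomical shape (real vessels curve and taper;
phantom tubes are straight), or operator-dependent steps such as region
selection. Those caveats apply to any claim about real data.

## Micro-CT vessel extraction

**Volume model.** Volumes are isotropic grids at 6.0 um voxel pitch.
Phantom vessels are straight cylinders with hemispherical caps, rendered
by supersampled partial volume: each voxel's value is the fraction of
its volume inside the tube (6^3 subsamples) times the tube amplitude.
This is the crucial modelling choice: the diameter bins of interest
(4-5, 5-6, 6-7 um) are *below* the voxel pitch, so a binary rendering
would collapse them all onto one-voxel-wide lines and no estimator could
tell them apart. Partial volume is also how sub-resolution vessels
present in real CT. Gaussian noise (default sd 2% of amplitude) is
added without clipping, as in float reconstructions.

Per-bin vessel counts are Poisson draws around the condition profile's
expectations. The bundled profiles (`inst/extdata/microct_profiles.yaml`)
encode the reported relative structure: the hyperoxia-vehicle profile
depletes the 4-5, 5-6 and 6-7 um bins to 0.16, 0.17 and 0.24 of the
air-vehicle expectations (the published -84%, -83%, -76%); medium-bin
depletions and the IL-1Ra rescue factors are plausible values in the
reported direction, since no numbers are printed for them. Absolute
counts are free parameters; the defaults (60/50/40/30/15/8/4 per bin per
lobe volume) give enough events for stable ratios at desk scale.
Vessels of the bins at or above 10 um are connected into branching
trees (two children per junction, so every junction has degree three and
every tree edge is one countable segment); smaller vessels are isolated,
with at least 3 voxels of surface clearance between unrelated tubes.

**Edge detection.** Two sequential difference-of-Gaussian band-pass
filters are applied per plane. The published scales (r1 = 2, r2 = 5) are
interpreted as Gaussian sigmas in pixels — the original workflow names the operator
and radii but not the inner/outer convention — with the classic 1.6
ratio for each band-pass. Thresholding is Otsu per plane, guarded by a
robust noise floor (median + 4 MAD of the plane response) so planes
without vessel content yield empty masks; a fixed threshold can be
supplied. Despeckling is a 3x3 majority (binary median) filter.

**Filling.** The fill stage reproduces the published chain: despeckle,
skeletonize each plane, drop skeleton fragments below 5 voxels, detect
tips, connect each tip to its nearest tip within `max_gap` (default 5)
pixels, and fill all fully-enclosed areas. The filled regions are
union-ed with the despeckled input, which makes the operation idempotent
on already-solid masks. On closed contours the result equals a border
flood-fill complement (tested against an independent oracle).

**Tracing.** The band-pass response of a thin tube extends well beyond
its surface, so the filled channel is gated by a smoothed intensity
surface (voxels at 25% of the estimated tube amplitude or more) before
use — the "smoothed surface around the filled data" artifact-removal
step of the original workflow. Small vessels are
detected in the original volume after light 3D smoothing (sigma 0.8
voxels) at 5% of amplitude; the reported small-vessel mask excludes a
2-voxel margin around the large-vessel surface. The *union* of the two
channels is thinned once (6-subiteration directional thinning with the
Malandain-Bertrand simple-point characterization, endpoints preserved),
so a vessel caught partly by each channel cannot be counted twice; each
skeleton path between tips/branch points becomes one segment, classed
by where the majority of its centerline lies. Tip spurs shorter than 8
voxels and junction-junction stubs shorter than 4 voxels are removed as
thinning artifacts.

**Diameters.** The base rule is distance-transform-based: per-point
radius = EDT - 0.5 (the voxel center to the boundary midplane), taking
the neighborhood maximum of the EDT because the thinned skeleton can sit
slightly off the tube center, and the segment diameter is twice the
median per-point radius times the voxel size (the median resists
junction inflation). A one-voxel-wide binary line therefore measures
exactly one voxel (6.0 um). The EDT rule, however, quantizes at the
voxel scale, which is fatal for sub-voxel bins; for grayscale volumes
every segment is therefore refined from integrated partial-volume
intensity: voxels near the centerline are partitioned into per-point
slabs (nearest path point; ties across segments resolved by distance
scaled with the rough radius, so junction voxels go to the thicker
parent), each slab's background-subtracted intensity sum divided by the
local step length (4-step chords, so digital zigzag does not inflate the
length) is a cross-section area, and the median slab area over the
trimmed path gives the diameter. On analytic tubes this estimator is
unbiased from 4 to 30 um, while the EDT rule is biased by up to one
voxel at 25 um. The tube amplitude reference is the median intensity of
voxels at least 1.5 voxels inside the half-maximum boundary of bright
structures; when nothing is thick enough to have an interior the robust
maximum is used, and the reference is then itself partial-volume
limited — a documented limitation for volumes containing only
sub-resolution vessels.

**Binning and normalization.** Diameters are counted into half-open
bins (default edges 4, 5, 6, 7, 10, 15, 20, 30 um, covering the
small-vessel 4-7 um and medium-vessel 7-30 um groupings); vessels below
4 um are discarded as under the resolution limit, and percent-of-total
is relative to all binned vessels of the lobe. Group normalization
multiplies each specimen's percentages by its total count over the mean
total of the air-vehicle group, so between-group differences in overall
vessel number survive the percentage conversion. The reductions quoted
for the hyperoxia group are computed on these normalized values.

## Cine-angiography

Phantom sequences hold a static background (low-frequency smoothed noise
plus high-contrast bars standing in for ribs) and vessel opacity ramping
along a saturating arrival curve after the configured pre-injection
frames; because the background is identical across frames, subtracting
the pre-injection frame isolates the vessels exactly, which is the
point of the published procedure. Median filtering uses a disk of
2-pixel radius. Automated generation counting thresholds the peak
subtraction frame (Otsu), thins it, prunes spurs, takes the widest
segment of each connected component as the inflow root and assigns each
segment its topological depth from the root. Thinning splits wide
branch points (vessels up to 7 px) into nearby sub-junctions; junction
clusters linked by segments shorter than 8 px are contracted before
depth assignment, after which automated counts are exact on all phantom
seeds tested.

The tree phantoms use three children per junction with pruning capped at
one child per junction: removing a single child keeps the junction
degree at 3 or more, so counting stays exact, while the expected
per-generation losses equal the configured fractions (the bundled
hyperoxia profile encodes the reported -18% generation-2 and -21%
generation-3 losses). A binary tree cannot express fractional thinning
without creating degree-2 joints that merge segments. The automated
mode is an extension — the original workflow counts manually placed
color-coded dots, which `count_generations(marks = ...)` reproduces as
a tally — and is validated only against phantoms.

## PCLS concentration-response

Frames show a dark elliptical lumen in brighter tissue; the lumen area
follows the four-parameter logistic law on the percent-initial-area
scale, with multiplicative noise drawn once per concentration step.
Lumen segmentation is Otsu thresholding (within a region of interest
when supplied) plus connected-component selection, with the area as the
pixel sum. The response at each concentration is the percent reduction
of initial area, the plateau being the mean over the final 20% of each
step window and the baseline being the zero-concentration step's
plateau (a window mean rather than a single frame; configurable).

The logistic fit uses `minpack.lm::nlsLM` on log10 concentration with
the Hill slope constrained to [0.5, 5] by default: slopes of
single-receptor vasoconstrictor responses sit near 1, and on 6-point
drug-only designs degenerate shallow-slope fits extrapolate an unstable
top plateau (simulated fitted-max sd 15.7 unconstrained vs 5.2 with the
bound, at a generating maximum of 43); the bound is an argument and can
be widened for atypical pharmacology. Because the response is defined
relative to its own baseline, its zero-drug asymptote is 0 by
construction, and the default fit anchors `bottom = 0`: simulation (50
replicates, 5% noise, 6 drug-only concentrations) showed the
free-bottom fit is unstable (fitted-max sd ~28 against a generating
maximum of 43) while the anchored fit is well behaved (sd ~9, bias
under 2). The free-bottom parameterization remains available. The
bundled agonist profiles place the two log-EC50 values one unit apart
(-8.5 and -7.5) inside the tested ranges (1-100 nM and 3-1000 nM, six
log-spaced points), with maxima of 43% and 38% reduction, matching the
reported potency separation and similar maxima; hyperoxia does not
alter either, so both exposure groups share the profiles.

## Echocardiographic indices

The Doppler phantom produces a single-peaked envelope over one heart
period, zero outside the ejection window, peaking exactly at the
configured time-to-peak. The default envelope is triangular, which has
a useful property: with the ejection window detected as the first/last
crossings of a fixed fraction of peak velocity (5% by default, linearly
interpolated), the TPV/RVET ratio is exactly invariant to that
fraction, so the recovered ratio equals tpv/rvet to within a sample
interval. A raised-cosine envelope is available for a smoother shape.
The bundled timing profiles give ratios of 0.32 (air vehicle), 0.27
(hyperoxia vehicle) and 0.31 (hyperoxia IL-1Ra), the reported group
means; whether the clinical window onset is flow onset or valve timing
is not specified in the original workflow, and the threshold-crossing rule is the
package's choice. Fractional shortening is the standard M-mode index
`100 (LVIDd - LVIDs) / LVIDd`.

## Molecular and histological quantification

Relative expression uses plain ddCT with group-mean dCT differences
(unpaired design) and the most stably expressed housekeeping gene,
chosen by minimal CT standard deviation across samples — the simplest
defensible reading of "most stably expressed"; no amplification
efficiency correction is applied, matching the original protocol. The
bundled group-mean CT table is synthetic, back-computed from the
published fold changes (Lgals3 2.9-fold in hyperoxia with the increase
halved by IL-1Ra; Ccl2 1.8-fold and -59%; Nppb unchanged and -39%),
since raw CT values are not published; its file name marks it
synthetic. Per-sample relative values are returned for SEM reporting,
and a display scaling relative to the lowest expressed gene is provided
alongside the housekeeping-referenced folds, because the study's display convention uses the former while its
quantification protocol describes the latter;
the package computes both rather than resolving the discrepancy.

Positive-pixel scoring classifies stained pixels by a hue window (brown
by default) and intensity bands, darker meaning more stain, and reports
the summed strong-class intensity over the masked tissue area in square
micrometers. Sirius-Red collagen is the red-hue pixel fraction of
non-vessel tissue; tissue is any sufficiently saturated pixel and the
vessel mask is excluded from numerator and denominator. The per-pixel
color rules of the commercial tools are not published, so the hue/band
windows are configurable. The histology phantom paints an exact pixel
count of collagen on non-vessel tissue (blobs trimmed to the count), and
part of each vessel region is painted red so that the exclusion is
genuinely exercised. The bundled fractions (4.0% air, 8.8% hyperoxia)
encode the reported 2.2-fold fibrosis increase at plausible absolute
levels; the recovery check uses the profile fractions directly with
seeds varying only the spatial layout, while the analysis driver adds a
10% between-animal coefficient of variation for realistic group
statistics.

Group statistics follow the study's conventions: normality
(Shapiro-Wilk per group) and equal variance (Brown-Forsythe) checked at
the 0.05 level and reported; two-sided Student's t-test for two groups;
one-way ANOVA with Tukey's multiple comparisons otherwise; significance
at P < 0.05 with means +/- SEM. The original protocol names the 0.05 rejection
threshold but not the specific normality/variance tests; Shapiro-Wilk
and Brown-Forsythe are the package's choices.

## Problem sizes and determinism

Every generator is a pure function of its arguments and seed (RNG state
is restored afterwards). The recovery experiments use 5 + 5 micro-CT
volumes of 128^3 voxels (about 180 and 40 vessels per air/hyperoxia
volume; roughly 15-20 s per volume through the full pipeline on one
CPU), 10 angiogram sequences of 512^2 x 40 frames per group, 8
concentration-response replicates per agonist, and 8 + 8 histology
sections of 256^2 — sizes chosen so Poisson/sampling error stays a
factor below the tolerances being checked while the whole suite runs in
minutes.

## Known limitations

Phantom tubes are straight and uniformly bright; real vessels curve,
taper and sit in textured parenchyma. The amplitude reference degrades
when a volume contains no resolved vessel (see above). The automated
generation counter assumes non-overlapping projected trees; crossing
vessels in a real projection would merge components and confound depth.
The PCLS threshold step assumes a bimodal lumen/tissue histogram, and
the collagen classifier assumes stain hues near the configured windows.
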