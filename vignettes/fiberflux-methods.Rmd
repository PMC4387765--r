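---
title: "Quantifying autophagy flux in striated muscle fibers: models and methods"
author: "fiberflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autophagy flux in striated muscle fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberflux)
```

## Scope

fiberflux quantifies autophagosome and lysosome dynamics in single
skeletal muscle fibers imaged in three confocal channels (LC3-RFP,
MitoTracker, LysoTracker), and reproduces the statistical reporting style
of single-fiber autophagy studies: per-fiber measurements, per-condition
mean ± SEM, pooled two-sample t-tests with star annotations. Since the
kind of data it targets is not publicly deposited, the package is built
around a seeded synthetic generator with full ground truth; every
detector is routinely validated against that truth.

## The measurement model

### Fiber geometry

A fiber segment is an elongated, roughly rectangular band, much longer
than wide, at a shallow angle to the image rows. Segmentation
(`segment_fiber()`) smooths the mitochondrial channel (Gaussian, 1 px),
thresholds by Otsu, fills holes and keeps the largest 8-connected
component (at least 500 px, else a `NoFiberFound`-type error). The
long-axis orientation is first estimated from the component's second
moments. That estimate is only good to about a degree for a nearly
rectangular mask, while baseline flattening (below) needs the axis to a
fraction of a degree, so it is refined against the striations themselves:
the magnitude of the Fourier coefficient of the projected mitochondrial
intensities at the striation frequency is maximized over the angle. Any
angle error smears the striation phase across the transverse direction
and attenuates that coefficient, so the objective peaks sharply at the
true axis; it is also smooth in the angle (no binning), which a
1-D optimizer handles reliably. The striation frequency itself comes from
a periodogram of a crude axial profile; if no spectral peak stands out
(factor 5 over the median power), the moment-based angle is kept — so
non-striated images degrade gracefully.

Axial intensity profiles (`axis_profile()`) are area averages: in-mask
pixels are projected onto the axis and averaged in uniform bins (default
one pixel). Binning uses `round()` so bin centers sit on multiples of the
bin width; with `floor()` an exactly axis-aligned fiber puts every column
on a bin boundary and floating-point jitter splits columns between bins.
Empty bins at the ends are dropped; interior empty bins are linearly
interpolated. Axial coordinates are bin centers in µm from the first
populated bin, with the frame (mask centroid, axis angle) carried as
attributes so profiles from different channels can be compared in
absolute coordinates.

### Z-lines from mitochondrial pairs

Mitochondria sit as double rows flanking each Z-line, so the Z-line is
the arithmetic midpoint of a (left, right) pair of mitochondrial profile
peaks — `infer_zlines()` asserts this midpoint property by construction.
Peaks are local maxima above median + 1·MAD of the profile (plain median
absolute deviation, no consistency scaling — the profile is a periodic
signal, not a Gaussian sample), separated by at least a quarter period,
with three-point parabolic refinement for sub-bin positions (the profile
is sampled at the pixel pitch, and the target localization error is well
below it).

Pairing is greedy by **smallest gap first** among adjacent peaks with
gaps below 0.75 of the period, each peak used once, unpaired peaks
discarded and counted. A left-to-right greedy scan was rejected: with
rows 0.8 µm apart within a pair and 1.2 µm between pairs, both gaps fall
inside the 1.5 µm pairing window, and a field of view that clips a
leading row would lock a left-to-right scan onto the inter-pair gaps,
shifting every inferred Z-line by half a period. Smallest-gap-first
anchors on the tight intra-pair spacing and is immune to that failure.

The sarcomere period is the median successive Z-line difference (NA with
fewer than two Z-lines). LC3 striation alignment
(`lc3_alignment_offset()`) is the mean distance from each Z-line to the
nearest LC3 profile maximum.

### Autophagosome puncta and the area ratio

The detection rule is the study's: a pixel belongs to a punctum when its
intensity is **strictly** greater than 1.1 × background. The 10%-above
reading is multiplicative; an additive reading (background + 10% of the
dynamic range) would be tied to an arbitrary intensity scale, while
confocal intensities are reported in arbitrary units — the multiplicative
rule is scale-equivariant, and the test suite asserts that multiplying
the channel by any positive constant leaves the segmentation labels
unchanged. Background is the in-mask median, robust both to puncta (small
area fraction) and to isolated hot pixels.

The LC3 baseline ridge on the Z-lines would cross that threshold on its
own, so the channel is flattened first (`flatten_striation()`): a
striation template — the per-axial-bin median across the transverse
direction, bins of half a pixel, linearly interpolated at each pixel's
axial coordinate — is subtracted, and the median of the bin medians (the
fiber's background pedestal) is added back. The flattened image therefore
keeps the original background level with the striation modulation
removed, and the 1.1× rule applies on its natural scale. Driving the
flattened values to zero instead would make a multiplicative threshold
degenerate (1.1 × 0), with every positive noise excursion becoming
foreground. Three numerical details matter:

* The ridge is close to the sampling limit, so the template is sampled at
  half-pixel bins and evaluated per pixel by interpolation; a one-pixel
  staircase template leaves residuals comparable to the threshold margin.
* The template is computed in transverse **strips** (default 3), each
  with its own axial template and a shared pedestal. The template error
  from a residual orientation error grows linearly with the transverse
  lever arm (at a tenth of a degree over a 24 µm wide fiber it reaches
  the order of the threshold margin, concentrated on the ridge flanks
  where the slope is maximal); strips cut the lever arm accordingly.
* Medians, not means: a punctum occupies a small fraction of any axial
  bin and must not inflate its own template.

Foreground pixels form 8-connected components; components under
`min_area_px` (default 4 px) are discarded as single-pixel noise. Each
record carries centroid (image and fiber frame), area, mean intensity,
distance from its centroid to the nearest Z-line, and an `off_zline` flag
(distance > 0.15 µm). The headline `area_ratio()` is total punctum area
over mask area; by default **all** above-threshold puncta count, with the
off-Z-line subset reported as a secondary column — the threshold rule
alone defines the quantified ratio, while the off-Z-line morphological
definition of an autophagosome is kept as an annotation. Puncta touching
the fiber boundary are counted. Without a Z-line map, distances are NA,
the flag defaults to TRUE, and the set is marked `zline_map_missing`.

### Lysosomes and contact

`segment_lysosomes()` reuses the same threshold/connectivity/min-area
machinery on the lysosome channel without flattening (no sarcomeric
baseline), with an independently overridable threshold factor since
LysoTracker background differs from LC3-RFP. A fiber is high-lysosome
when it has strictly more than 100 detected lysosomes in the imaged
segment (a count of exactly 100 is not high); `percent_high()` is the
group percentage. The 100/fiber rule is applied per imaged segment,
matching the synthetic field of view.

"Close contact" is quantified as an object boundary gap of at most
0.4 µm (two pixels at the default scale; a configuration knob). Pixels
are treated as unit squares, so the gap between pixels with center
offsets (dx, dy) is sqrt(max(0,|dx|−1)² + max(0,|dy|−1)²): overlapping or
8-adjacent objects have gap zero exactly, and a brute-force all-pairs
oracle in the test suite pins the convention down. `contact_fraction()`
returns the fraction of LC3 puncta with at least one lysosome within the
gap, NA when there are no LC3 puncta.

### Densitometry

Lane profiles sum intensity across the lane width per migration row,
inverting automatically when the lane is darker than the image median
(dark bands on light background), overridable. Band quantification uses
an endpoint-line baseline — the straight line joining the profile values
at the window edges — summed and clamped at zero. A rolling-ball baseline
was rejected as neither closed-form testable nor necessary for lane
profiles with flat flanks; windows are user-supplied per lane (automatic
band calling is out of scope) and should include a flanking baseline
point on each side. Ratios (`relative_intensity()` to the tubulin loading
control, `cleavage_ratio()` for cleaved/pro caspase-3 and p-mTOR/mTOR)
guard against non-positive denominators. Tubulin normalization is per
lane. Global intensity rescaling cancels exactly in all ratios.

### Statistics

Mean ± SEM with SEM = sd/√n (n−1 denominator; NA at n = 1). The t-test
is classic pooled-variance Student (not Welch): the reporting convention
being reproduced states "Student's t-test" with no unequal-variance
caveat. It delegates to `stats::t.test(var.equal = TRUE)` and is checked
against a hand-written closed form to 1e−10; the degenerate case of two
identical constant samples returns t = 0, p = 1. Stars are `**` for
p < 0.01, `*` for 0.01 ≤ p < 0.05, strict on both thresholds. Fibers are
treated as independent replicates within a condition — matching the
per-fiber n of the reporting style being reproduced, and a known
simplification (no mixed-effects animal term). No multiple-testing
correction is applied; comparison tables carry raw p-values.

## The synthetic generator

`sim_config()` fixes geometry, intensity scale and noise: 0.2 µm pixels,
160 × 360 px field, a 60 × 24 µm fiber band at a uniform random
orientation in ±15° (so the geometry stage must genuinely estimate
orientation), sarcomere period 2.0 µm, mitochondrial rows at ±0.4 µm
(Gaussian, σ 0.15 µm), LC3 ridge on the Z-lines (σ 0.25 µm, amplitude
800 a.u. over a 500 a.u. in-fiber background, 50 a.u. outside), puncta
and lysosomes as hard-edged disks at 3 × background amplitude. Noise is
Poisson shot noise on a photon scale (4 photons per intensity unit, so
the noise sd in a.u. is sqrt(intensity/4)) plus Gaussian read noise
(sd 10 a.u.). At these values the threshold margin (10% of background) is
about twice the in-fiber noise sd, so isolated noise pixels essentially
never form 4-pixel 8-connected clusters — the regime a practitioner would
tune an acquisition to.

Condition presets (`build_preset()`) give expected puncta and lysosome
counts per condition. The source study reports its quantities only as
bar charts, so the preset numbers are calibration choices, constrained to
reproduce the qualitative orderings: mutant basal elevation in puncta and
lysosomes at every age, induction raising both in wild type, induction
failing to raise — and past two months lowering — puncta in the mutant,
and mutant lysosome counts unresponsive to induction. Wild-type basal
fibers draw ~60 lysosomes (Poisson), keeping the >100/fiber rate
essentially zero, versus 130–140 for the mutant; puncta means range from
6 (WT basal) to 25 (WT induced).

Object placement is uniform in the fiber band with rejection sampling
(minimum spacing of one mean radius between puncta, 0.4 µm between
lysosomes; 1000 tries, then overlap is accepted) and a 0.5 µm
sarcolemmal margin from the band edge and the raster — the objects are
intracellular, and no detector can follow an object cut by the field of
view. Each LC3 punctum independently receives one adjacent lysosome
(boundary gap uniform in 0–0.2 µm) with probability `contact_prob`; all
other lysosomes keep a boundary gap of at least 0.7 µm from every
punctum, so the pooled fraction of contacted puncta is an unbiased,
unambiguous estimate of `contact_prob`. `lyso_count_mean` is the Poisson
mean of the non-punctum-associated lysosomes.

The manifest's `truth_area_ratio` is the **pixelized** truth footprint
(pixels whose centers fall inside a truth punctum, within the mask) over
the mask area. Truth puncta are only a few pixels across, where the
analytic πr² differs from any raster measurement by up to tens of
percent per punctum; the pixel footprint is the exact rendered truth and
is the right reference for detector recovery.

Per-fiber seeds derive from (master seed, condition index, fiber index),
so cohorts are reproducible regardless of generation order. Cohorts are
written as 16-bit multi-page TIFFs (pages lc3, mito, lyso) with a CSV
manifest; intensities round-trip as integers.

What the generator does **not** emulate: optics beyond the Gaussian row
and ridge profiles (no PSF blur on the disks, no 3-D sectioning),
photobleaching or time series, fiber curvature and sarcomere disarray,
intensity heterogeneity along the fiber, autofluorescence, and
mouse-level clustering of fibers. Passing truth-recovery tests therefore
demonstrates the correctness of the measurement chain on images that
satisfy the stated model, not detector performance on real confocal data
— on real fibers the orientation, flattening and threshold stages face
structure this model excludes.

## Verification sizes

The test suite validates truth recovery at the study's scale while
keeping a full run to minutes: Z-line RMSE pooled over 20 fibers
(noise-free and default noise), per-fiber area-ratio recovery on a
20-fiber cohort, area-ratio monotonicity over puncta abundance
{5, 15, 30, 60} with 20 fibers per level, contact-fraction recovery at
contact probabilities {0.2, 0.5, 0.9} pooling about 600 LC3 puncta per
level (the binomial error of the pooled estimate is then ~0.02), and the
full condition-contrast matrix with 30 fibers per condition — the
per-fiber n typical of the single-fiber literature.

## Known limitations

* Touching puncta are not split (no watershed); merged objects count
  once, with the merged area.
* The striation template assumes one dominant orientation; fibers bent
  within the field of view would need a curved axis model.
* The >100/fiber classification is per imaged segment; absolute
  per-fiber counts would require stitched whole-fiber fields.
* Statistics treat fibers as exchangeable replicates; a mixed model with
  an animal term would be the next step for real cohorts.
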