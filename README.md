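# fiberflux

Quantification of autophagy flux in single skeletal muscle fibers from
multi-channel confocal images.

## The problem

Autophagy delivers misfolded proteins and damaged organelles to lysosomes
for degradation. In live muscle fibers the autophagosome marker LC3-RFP is
not diffuse: before forming vesicles it sits in a striated baseline on the
sarcomeric Z-lines, and autophagosomes appear as discrete bright puncta of
random size and shape on top of that baseline. Measuring autophagy
microscopically in muscle therefore requires several coupled steps:

1. **Fiber geometry.** Segment the fiber from the mitochondrial channel
   and localize Z-lines. Mitochondria form double rows flanking each
   Z-line, so the Z-line is defined as the midpoint of each pair of
   mitochondrial fluorescence peaks along the fiber axis (sarcomere period
   ≈ 2 µm).
2. **Autophagosome quantification.** After removing the striated LC3
   baseline, a pixel belongs to a punctum when its intensity is strictly
   more than 10% above the fiber background (threshold = 1.1 × in-mask
   median). The per-fiber statistic is the **area ratio**: total punctum
   area divided by the area of the imaged fiber segment.
3. **Lysosome activity.** Lysosome puncta (LysoTracker channel) are
   detected with the same rule; a fiber is classified **high-lysosome**
   when it contains strictly more than 100 lysosomes, and groups are
   compared by the percentage of high-lysosome fibers. Autophagosome
   identity is supported by the fraction of LC3 puncta whose boundary lies
   within 0.4 µm of a lysosome (object-based colocalization).
4. **Immunoblot densitometry.** Band intensities from 1-D lane profiles
   with an endpoint-line baseline, normalized to tubulin, plus
   cleaved/pro-caspase-3 and p-mTOR/mTOR ratios.
5. **Group statistics.** Per-condition mean ± SEM (sd/√n), pooled-variance
   two-sample Student's t-tests, and the `*` (p < 0.05) / `**` (p < 0.01)
   annotation scheme.

Because no image data are deposited with the study this pipeline targets,
the package ships a seeded synthetic generator (`sim_config()`,
`build_preset()`, `sample_fiber_truth()`, `render_fiber_image()`,
`generate_cohort()`) that emulates striated fibers with ground truth:
elongated fiber on a dark background, Z-line ridge, mitochondrial double
rows, hard-edged puncta and lysosome disks, Poisson shot noise on a
photon scale plus Gaussian read noise, and condition presets
(WT/G93A × three age groups × basal/induced) whose orderings reproduce the
study's qualitative contrasts. Every detector is validated against this
generator's truth.

## Worked example

```r
library(fiberflux)

cfg <- sim_config(master_seed = 11)
sim <- simulate_fiber(build_preset("G93A", "2-3mo", "basal"), cfg, seed = 11)
sim$truth
#> fiber_truth: angle -6.7 deg, 29 Z-lines, 18 puncta, 150 lysosomes (16 contacting), truth area ratio 0.0111

mask <- segment_fiber(sim$image)
mask
#> fiber_mask: 34849 px (1394.0 um2), axis angle -6.68 deg

zmap <- infer_zlines(detect_mito_pairs(
  axis_profile(sim$image, mask, channel = "mito")))
zmap
#> zline_map: 29 Z-lines, period 2.000 um

puncta <- segment_autophagosomes(sim$image, mask, zmap)
puncta
#> puncta_set (lc3): 18 objects, background 586.4, threshold 645.1
area_ratio(puncta, mask)
#> [1] 0.0115        # truth: 0.0111

lyso <- segment_lysosomes(sim$image, mask)
count_and_classify(lyso)
#> lysosome_result: 150 lysosomes, high (> 100): TRUE
contact_fraction(puncta, lyso)
#> [1] 0.89
```

The generator drew a fiber rotated −6.7°; segmentation recovered the
angle to 0.02°, found all 29 Z-lines at the exact 2 µm period, detected
all 18 truth puncta (measured area ratio 0.0115 vs truth 0.0111), counted
all 150 lysosomes (a high-lysosome fiber, as expected for a mutant basal
condition), and found 89% of LC3 puncta in contact with a lysosome
(generator contact probability 0.9).

`run_pipeline()` runs the whole chain over a simulated or on-disk cohort
and writes per-fiber, per-group (mean ± SEM, percent high-lysosome) and
pairwise-comparison CSVs plus a JSON run log. A thin command-line wrapper
with `simulate` / `quantify` / `stats` subcommands is installed at
`inst/scripts/fiberflux.R`.

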