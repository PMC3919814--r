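---
title: "Quantifying rheotaxis, chemotaxis and lysosome exocytosis with rheotax"
author: "rheotax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rheotaxis, chemotaxis and lysosome exocytosis with rheotax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheotax)
```

## The assays and their statistics

`rheotax` quantifies three readouts of *Dictyostelium* mechanosensing and
taxis studies:

1. **Rheotaxis** — vegetative amoebae adhering in a parallel-plate laminar
   flow chamber orient and migrate with the fluid flow. Cells are imaged
   every 15 s for 10 min and at least 15 cells per experiment are tracked.
   Per cell, the package computes the net displacement along the flow axis
   (Δx, signed; the flow runs right to left, so oriented cells have
   negative Δx), the total path length, the speed (total distance over
   total time, µm/min), and the directional persistence (net over total
   distance, in (0, 1]).
2. **Folate chemotaxis** — a micropipette releasing folate (Δd: final minus
   initial distance of each cell to the tip, negative when approaching) or
   an agar-spot assay (displacement of the population front towards a
   folate well 4 mm away).
3. **Calcium-induced lysosome exocytosis** — cells carrying a bright
   p80-positive membrane patch mark a lysosome fusion event. About 4.1% of
   wild-type cells constitutively show a patch; a sudden shift to 1 mM
   extracellular calcium transiently doubles that fraction, peaking about
   2 min after the shift.

The flow chamber's wall shear stress follows the parallel-plate relation

$$\sigma = \frac{6\,D\,\eta}{w\,h^{2}},$$

with flow rate $D$, viscosity $\eta$, width $w$ and height $h$ in SI
units. At the default operating point (14 ml/min of aqueous buffer through
a 250 µm × 5.5 mm chamber):

```{r}
shearStress(ChamberSpec(flowRate = 14, viscosity = 0.001,
                        height = 250, width = 5.5))
```

about 4.07 Pa — quoted as the nominal 4 Pa. `ChamberSpec()` warns when
$h/w > 0.2$, where the parallel-plate approximation degrades.

## The synthetic motility model

Raw movies of such assays are rarely published, so the package ships a
generator whose output has the statistical structure the analysis assumes.
Motility is a **heading-biased persistent random walk**: at each frame the
heading is corrected by a fraction $\alpha$ (`biasStrength`) of the
angular error towards the target and perturbed by wrapped Gaussian noise,

$$\theta \leftarrow \theta + \alpha\,\mathrm{wrap}(\theta_{\mathrm{target}}
  - \theta) + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_\theta^2),$$

and the cell advances by $v\,\Delta t\,(1 + c_v z)$, truncated at zero. A
heading bias, rather than an additive drift, reproduces the hallmark of
the flow phenotype: orientation changes while speed does not. The target
is a fixed direction for the flow assay (`c(-1, 0)` by convention) or a
point source for the micropipette assay, where the correction strength is
distance-independent (no gradient-decay model; the bias stands in for the
gradient).

Defaults (chosen once): `meanSpeed = 2.5` µm/min (the published random
speed), `dt = 15` s and 41 frames (the published acquisition), 15 cells ×
5 replicates per condition, `turnSd = 0.6` rad and `stepCv = 0.3`. Turning
and step-length distributions are not published for these cells, so those
two values are placeholders calibrated only against the printed speed and
qualitative persistence behaviour — the analyses never depend on their
exact values, and the speed calibration (mean per-cell speed within 5% of
`meanSpeed` when `stepCv = 0`) is enforced in the test suite. With
`stepCv = 0` every step has exactly length $v\,\Delta t$, so the
calibration is exact by construction; the 5% band covers the general
noisy case.

Seeding: one top-level seed; replicate $r$, cell $c$ of condition $k$ use
the child seed `childSeed(seed, k, r, c)` (a Lehmer-style mixer, exact in
double precision). Any subset of a study can therefore be regenerated in
isolation, and identical seeds give bit-identical studies.

```{r}
es <- simulateExperiment(
  list(WT_flow = WalkParams(biasStrength = 0.3,
                            targetMode = "fixed_direction",
                            target = c(-1, 0)),
       WT_noflow = WalkParams()),
  nCells = 15, nReplicates = 5, seed = 1)
summarizeReplicates(es)[, c("condition", "replicate", "delta_x",
                            "speed", "persistence")]
```

## Tracking

`linkDetections()` reconstructs trajectories from per-frame centroids with
greedy globally-nearest linking: candidate (track end, detection) pairs
within `maxDisp` are sorted by distance (ties broken by lower detection
index, then lower track index) and accepted greedily. The default
`maxDisp` of 2.5 µm is four times the mean 15-s step of a 2.5 µm/min
cell. By default a track unmatched in a frame closes immediately — the
strict, auditable contract used by the oracle-equivalence tests, where
linking on well-separated noiseless detections must equal ground truth
exactly. Real detection streams miss detections, and with a 5% miss rate
the probability that a 41-frame track survives gapless is only about
0.12; `maxGap` therefore optionally lets a track survive up to that many
empty frames (search radius growing linearly with the gap, skipped
positions filled by linear interpolation). The robustness test runs at
`maxGap = 2` with a search radius sized for the localization noise. There
is no merging or splitting: the assay is low-density.

Coordinates are continuous µm; when detections come from images, the
origin is the centre of the top-left pixel, x rightward, y downward, so
Δx keeps the right-to-left flow sign convention.

## Patch scoring in synthetic images

`renderPatchImages()` draws each cell as an annular membrane ring
(radius 5 µm, thickness 2 µm, 0.4 µm pixels) placed without overlap by
rejection sampling; with probability $p(t)$ a contiguous arc (default 60°)
is multiplied by `patchGain` (default 3), and Gaussian pixel noise is
added (default SD 10% of the ring intensity). The prevalence schedule is a
Gaussian bump,

$$p(t) = p_0\left(1 + (A - 1)\,
  e^{-(t - t_{\mathrm{peak}})^2 / 2w^2}\right),$$

with $p_0 = 0.041$, $A = 2$, $t_{\mathrm{peak}} = 2$ min and $w = 1$ min
by default (the wild-type phenotype; $A = 1$ gives the flat knockout-like
schedule). The functional form is the package's own choice — only the
baseline, the fold change and the peak time are constrained by the
phenotype — and the timepoint grid defaults to 0, 1, 2, 4, 8 min within
the assay's 0–8 min window.

Scoring chains three steps:

* `segmentCells()` — Otsu threshold on a Gaussian-smoothed image,
  connected components, size filter at 0.25–4× the expected ring area.
  Touching cells merge and are discarded by the filter: a documented
  limitation of global thresholding (the generator avoids overlap by
  construction).
* `membraneProfile()` — mean intensity in 5° angular bins over the
  membrane ring band. The band is *not* the raw mask: a global-threshold
  mask dilates around a bright patch and its plain centroid is dragged
  towards it, which both flattens the patch contrast and breaks the flat
  profile of uniform rings. Instead the cell centre is re-estimated by a
  least-squares (Kåsa) circle fit to the mask and the band is the central
  half of the mask's radial extent, strictly interior to the ring.
* `detectPatch()` — a cell is patch-positive when a contiguous circular
  run of bins, each at least `minContrast` (default 2.0) times the median
  bin, spans at least `minArc` (default 30°). The real assay scores
  patches by eye; these thresholds are exposed, and the test suite
  characterizes them with a sensitivity/specificity sweep against the
  generator's ground truth (both ≥ 0.95 at gain 3 and 10% noise).

`prevalenceTimeCourse()` aggregates calls into per-timepoint prevalences
with Wilson 95% intervals and compares each timepoint to baseline with the
study's standard test (below).

```{r}
p <- PatchSimParams(nCells = 60L, timepoints = c(0, 2), seed = 4)
calls <- scorePatchImages(renderPatchImages(p))
prevalenceTimeCourse(rbind(calls,
                           transform(calls, replicate = "R2")))[,
  c("time_min", "n_cells", "n_patch", "prevalence")]
```

## Replicate-level statistics

The sampling unit is the replicate experiment, not the cell: figure
legends quote *n* as the number of independent experiments, so per-cell
metrics are averaged within each replicate (`summarizeReplicates()`) and
all comparisons run on those means. Values are reported as mean ± s.e.m.
(sample SD over √n) and compared with two-tailed **unpaired pooled-variance
Student t-tests** (`tTestUnpaired()`; Welch is available via
`equalVar = FALSE`). Stars follow the usual thresholds (\* p < 0.05,
\*\* p < 0.01). No multiple-testing correction is applied, mirroring the
reporting convention of the assays this package serves; treat per-timepoint
p-values accordingly (the report prints this caveat). Degenerate
zero-variance inputs are defined explicitly: identical constant samples
give t = 0, p = 1; constant samples with different means give p = 0 and a
`degenerate` flag.

The flow/no-flow **persistence ratio** is oriented as flow over no-flow,
so a responsive wild-type-like strain reads about 2 and a non-responder
about 1. (The source assay's figure legend words the ratio in the opposite
orientation to its running text; the package fixes one orientation and
documents it rather than guessing the figure axis.) The micropipette
assay's distance statistic is likewise written Δd throughout even where
assay protocols label it d.

The **cell front** of the agar assay has no published formal definition;
it is operationalized as the 95th percentile of cell positions projected
on the source axis — robust to single outlier cells, and configurable.

## Numerical and degenerate-input choices

* Δx is computed both as the endpoint difference and as the sum of
  per-step differences and the two are asserted equal, so a non-finite
  step cannot silently telescope away.
* Stationary cells (zero path length) have undefined persistence; they are
  flagged, excluded from aggregation, and counted in the report log, since
  the assays publish no exclusion rule.
* Time spacing must be uniform to 1e-6 relative tolerance; gaps in frames
  are hard errors naming the offending cell.
* Linking ties are broken deterministically (lower detection index);
  wrap-around arcs are handled by circular run analysis.
* All lengths are µm and times s internally; speeds are reported in
  µm/min to match the field's figures.

## What the synthetic data does and does not show

The generator reproduces the *statistical design* of the assays: sample
sizes, replicate structure, frame rates, the published speed scale, an
orientation bias that leaves speed unchanged, and a patch prevalence with
the published baseline and transient. It does **not** model cell shape,
deformation or detachment under flow, folate diffusion, calcium dynamics,
phase-contrast appearance, or cell-cell contact; segmentation performance
on these clean rings says nothing about segmenting real micrographs.
Passing tests therefore validate the *quantification pipeline* — metrics,
linking, patch scoring, statistics — not the biology upstream of it.

Problem sizes in the test-suite property checks are the package's own
choices: 100-run suites at 15 cells × 5 replicates for the phenotype
contrasts, 500-cell image sets for prevalence recovery, 1000-cell samples
for symmetry checks. The exocytosis time-course property uses the
generator's sampling layer (`simulatePatchTruth()`) rather than rendering
tens of thousands of images; the rendering path is exercised separately at
full scale.

## Known limitations

* Global-threshold segmentation merges touching cells; fine at this
  assay's densities, wrong for confluent fields.
* The patch criterion is an operationalization of by-eye scoring; its
  thresholds were characterized on synthetic rings only.
* The per-timepoint baseline comparisons are uncorrected for multiplicity,
  by design; with several timepoints, occasional false positives are
  expected under the null.
* `maxGap > 0` interpolates through missed detections, which slightly
  shortens measured path lengths on wiggly paths.
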