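---
title: "Measuring dot-chromosome behaviour in Drosophila female meiosis I"
author: "SpindleDots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dot-chromosome behaviour in Drosophila female meiosis I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpindleDots)
```

## The biological problem

During Prometaphase of female meiosis I in *Drosophila*, nonexchange
chromosomes — above all the small "dot" chromosome (the Muller F
element) — transiently move out of the main chromosome mass toward the
spindle poles before congressing back to the metaphase plate. Comparing
how far out the two dot homologs sit, how often oocytes are caught with
a chromosome out, and how large the dots are across species speaks to
how the distributive segregation system evolves.

SpindleDots implements the quantitative core of such a survey as
tested, reproducible code:

1. a **measurement protocol** for single-channel (DAPI-like) confocal
   z-stacks of fixed oocytes;
2. a **comparative statistical layer** over per-oocyte and per-species
   tables;
3. a **synthetic stack and table generator** with ground truth, so the
   whole pipeline is testable without microscope data.

## The measurement protocol

All 2D quantities are measured on the **maximum-intensity projection**
of the stack; Z information comes from the section structure.

**Out-classification (50% dip rule).** A chromosome is scored *out on
the spindle* when, along a line profile from the dot across the gap to
the adjacent chromosome, the background-subtracted intensity dips to at
most 50% of the reference peak. Numerical choices, made explicit
because the manual protocol leaves them to the operator:

* the *reference peak* is the lower of the two flanking
  background-subtracted peaks — a dip relative to the dimmer structure
  guarantees a dip relative to both;
* a dip of exactly 50% counts as out (the rule reads "at least" a 50%
  dip);
* profiles with fewer than two detectable peaks are not classifiable
  and the oocyte is flagged abnormal;
* the *background* is the median of the lowest-decile intensities of
  the projected field, a robust statistic of the off-chromosome area.

A useful aside on monotonicity: under this rule, out iff
$(v - b) \le \tfrac12 (p - b)$ for valley $v$, reference peak $p$ and
background $b$, so *raising* the background deepens the relative dip
(the left side falls twice as fast as the right). Lowering the valley
likewise can only push a profile toward "out". The property tests
assert both directions.

**XY distance (outer-edge convention).** The projected distance is
taken between the outer edges of the two dot chromosomes: the span
between the farthest-apart boundary pixels of the two blobs along the
line through their centroids, extended by one pixel on each side (the
outer face of the edge pixels), converted at the pixel size. The
imaging standard is 54 nm pixels. Whether the original manual line-tool
measurement ran outer-edge-to-outer-edge or across the gap only is not
decidable from the protocol description; the convention used here is
logged with every run, not asserted as the original authors' intent.

**Z offset (light cones).** Each dot is localised in Z at the centre of
its light cone: the section maximising the summed intensity over the
blob's XY footprint. The Z distance is the section count between the
two centres times the section thickness. The section thickness of the
original survey is not recorded; the package default is 0.5 µm, typical
for confocal oocyte work, and it is configurable everywhere.

**3D distance.** $d_{3D} = \sqrt{d_{XY}^2 + z^2}$, the Pythagorean
combination of the projected distance and the section offset.

**Segmentation and area.** The projection is thresholded (Otsu by
default, absolute override available — chromosome edges are soft, so
the threshold is exposed and logged) and connected components are
labelled. The largest blob is the main chromosome mass; blobs below
25% of its area are dot candidates, and candidates below 9 px are
discarded as noise specks. Because a single global threshold sits
relative to the much brighter mass, each dot's area is then refined on
a **half-maximum footprint**: a local re-threshold at 50% of the dot's
own background-subtracted peak, hole-filled, keeping the component
containing the peak. Two details matter at realistic noise levels:

* the peak is taken as the median of the 3×3 neighbourhood of the
  maximum, removing the upward selection bias of a noisy argmax;
* the absolute anchor is the **stack-median** background, because a
  maximum projection rectifies noise into an inflated floor that would
  shrink footprints.

Area is the refined pixel count times the squared pixel size.

**Denoising.** Before projection the stack is smoothed with a light
anisotropic Gaussian (default 1 px lateral, 0.5 section axial).
Smoothing the projection instead would be too late: the maximum
projection must see a denoised stack, or its noise floor rises.

**Configuration triage.** Oocytes with both dots on the same side of
the spindle, with additional nonexchange chromosomes out, or otherwise
abnormal are excluded from distance measurement — their dot-dot
distances could be shaped by the other chromosomes — but still count
toward the proportion of oocytes with chromosomes out. Distance is
measured only when both dots are out (`both_out`) or one is out and the
other locatable (`one_out_other_locatable`). When the companion dot is
embedded in the mass, it is searched for as an intensity lobe along the
line from the out dot through the mass centroid (chromatin overlap
makes an embedded dot brighter than the mass around it); its apparent
radius is approximated by the out dot's. This localisation is
necessarily approximate and its recovery tolerance in the tests is
correspondingly looser than for the two-blob case.

**Proportion out.** The number of oocytes with one or more chromosomes
out divided by all oocytes scored as matured past Prophase.

## The statistical layer

* **Species summaries**: mean 3D distance over distance-eligible
  oocytes, proportion out, mean dot area; warnings when the sampling
  targets (30 distance-eligible oocytes, 20 area measurements) are
  unmet.
* **Pairwise contrasts** between closely related species pairs with
  divergent inversion types: Δ = mean(polymorphic) − mean(monomorphic),
  a two-sided Welch t-test on per-oocyte distances (Welch is the
  natural choice for unequal per-species sample sizes; the test flavour
  of the original analysis is not recorded), reported to two
  significant figures. In summary-only mode (species means without
  per-oocyte data) externally supplied p-values are carried through.
* **FDR with custom Q**: with $m$ tests ranked by ascending p, the
  cutoff for rank $i$ is $(i/m)\,Q$ with $Q = 1/(2m)$ by default, i.e.
  $i/(2m^2)$; every test at or below the largest rank whose p falls
  strictly below its cutoff is significant. Ties in p keep their input
  order. The published cutoffs for $m = 6$ print two of the values
  truncated rather than rounded (2/72 and 3/72); the package computes
  exact values.
* **Group comparison**: unweighted means of species mean distances by
  inversion status, Welch t-test on the species means; species without
  a free dot chromosome are excluded.
* **Correlations**: Pearson r on pairwise-complete pairs, two-sided
  regression p via $t = r\sqrt{n-2}/\sqrt{1-r^2}$. Missing values
  (no distance or area for *D. willistoni*, heterochromatin estimates
  for five species) are dropped per analysis.
* **Pair-averaging**: each closely related species pair is replaced by
  the midpoint of its two species' values while unpaired species are
  retained, removing the pseudo-replication of sister species. This is
  deliberately the only phylogenetic correction implemented — no
  independent contrasts or tree-based GLS.

Working from the bundled (rounded, two-decimal) species table means the
recomputed coefficients can differ from published ones computed on
unrounded means by up to about ±0.02; the acceptance tests use exactly
that envelope. One visible instance: the monomorphic group mean
recomputes to 6.81 µm from rounded species means where 6.82 µm was
printed.

## The synthetic generator

`generateOocyteStack()` renders a Prometaphase I karyosome: a bright
ellipsoidal exchange-chromosome mass at the spindle midzone and
spherical dot foci along the spindle axis, as additive binary solids
scaled by intensity, blurred with a separable anisotropic Gaussian
(axial sigma larger than lateral, mimicking the elongated confocal
light cone), plus constant background and additive Gaussian noise.
Dot centres sit on exact section planes, so the ground-truth Z offset
is an integer section count, matching what the light-cone rule can
recover. The ground-truth distances follow the same outer-edge
convention the measurement uses; truth and measurement are directly
comparable, and `sqrt(dXY^2 + z^2)` equals the recorded 3D separation
to machine precision by construction.

Key defaults (all configurable): 54 nm pixels, 0.5 µm sections,
0.08 µm lateral and 0.3 µm axial blur, mass rendered at 30000 of the
16-bit range over a background of 1500, dots at 0.8 of the mass value
(smaller, dimmer chromatin), separations and dot areas in the range
observed across Drosophila species. Signal-to-noise is quoted against
the **dot focus's rendered peak contrast** — the quantity the
classifier and footprint actually see — which after axial blur is
roughly 0.4 of the nominal mass intensity.

Placement flags reproduce the abnormal figures the triage must handle:
`both_same_side` (two foci toward the same pole), `extra_nonexchange`
(three foci out), and a one-out variant whose companion dot is embedded
just inside the mass boundary, where its chromatin adds to the mass
signal and leaves the locatable lobe described above.

`generateSpeciesDataset()` emulates the tabular structure of a slide
survey: Bernoulli out-flags at a species-specific rate, truncated
normal distance draws decomposed into an XY component and an integer
section offset, and two truncated-normal area draws per out oocyte.
The survey gives no per-oocyte variance, so the distance and area
spreads are free parameters of the simulation, not calibrated
quantities.

What the simulator does **not** emulate: real point-spread functions
or photon statistics, multichannel immunofluorescence, chromatin
texture, slide-to-slide variation, or the heterochromatin threads
connecting separated homologs. Passing the recovery tests therefore
shows the protocol is internally consistent and robust to blur and
additive noise — not that it would digest arbitrary real micrographs
unchanged.

## Problem sizes and tolerances in the test-suite

The recovery suite measures 50 seeded stacks of 32 × 192 × 192 voxels
(25 noiseless across separations of 4.6–7 µm and dot radii of
5.5–8 px; 25 at a dot-peak signal-to-noise of 10), asserting noiseless
separations within one voxel diagonal
($\sqrt{2 \cdot 0.054^2 + 0.5^2} \approx 0.51$ µm, dominated by the
section thickness) and areas within 10%, and the same bounds on mean
absolute errors under noise. Monotone degradation with noise is
checked over 20 paired seeds at three noise levels, with an allowance
of the paired Monte-Carlo error plus 1% of a voxel diagonal —
sub-nanometre jitter at the quantisation floor is not degradation.
Property suites run 1000 random line profiles against a brute-force
dip scan and 1000 random p-sets against a textbook step-up loop.

## Known limitations

* Absolute Z truth cannot be compared to the original survey (its
  section thickness is unrecorded); only synthetic ground truth
  anchors the Z scale.
* The one-out companion localisation inside the mass is approximate by
  design; real operators resolve such figures visually.
* Per-oocyte distances behind the published species means are not
  recoverable from summary tables, so pairwise t-test p-values can only
  be checked for their significance pattern, not their exact values.
* The generator's dot placement is axis-aligned along the spindle;
  oblique placements would exercise the same code paths but are not
  currently produced.
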