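# SpindleDots

Quantifying dot-chromosome behaviour during *Drosophila* female
meiosis I.

In Prometaphase I oocytes, nonexchange chromosomes — most prominently
the small dot chromosome (Muller F element) — move out of the main
chromosome mass toward the spindle poles before congressing back.
SpindleDots is an R package for the cytologist comparing this behaviour
across species: it implements the image-measurement protocol for
single-channel confocal z-stacks of fixed oocytes, the comparative
statistics over species summaries, and a synthetic-data generator that
makes the whole pipeline testable without microscope data.

## What it computes

**Per oocyte**, from a z-stack with known pixel size (standard 54 nm)
and section thickness:

* "out on the spindle" classification: a chromosome is out when the
  background-subtracted intensity along a line profile from the dot to
  the adjacent chromosome dips to ≤ 50 % of the reference peak;
* projected XY distance between the dots' outer edges, Z offset from
  the centres of their light cones, and the 3D separation
  `distance = sqrt(d_xy^2 + z^2)`;
* dot cross-sectional area (half-maximum footprint × pixel area);
* configuration triage: oocytes with both dots on the same pole side,
  extra nonexchange chromosomes, or abnormal figures are excluded from
  distance measurement but still counted as "out".

**Per species and across species**: mean distance, proportion of
oocytes with chromosomes out, mean dot area; pairwise contrasts between
inversion-type divergent species pairs with a step-up false discovery
rate rule using cutoffs `(i/m)·Q`, `Q = 1/(2m)`; Welch group
comparisons; Pearson correlations with regression significance
`t = r·sqrt(n-2)/sqrt(1-r^2)`; and phylogenetic pair-averaging.

## Worked example

```r
library(SpindleDots)

t1 <- loadSpeciesSummaryTable()          # bundled per-species summary
g  <- groupMeanComparison(t1)
# polymorphic 7.15 um vs monomorphic 6.81 um (Welch P = 0.75)

pearsonCorrelation(t1$proportion_out, t1$mean_area_um2)
# r = 0.79 (n = 14, P = 7.0e-04)

pairs <- loadSpeciesPairs()
pairwiseContrasts(pairs, summaries = t1, pvalues = pairs$published_p)
#   poly mono delta_printed         p fdr_cutoff significant
# 1  mel  sim          5.20 2.200e-16 0.01388889        TRUE
# 2  yak  ere          1.60 1.700e-02 0.02777778        TRUE
# 3  car  sig         -1.40 1.800e-02 0.04166667        TRUE
# 4  hyd  mea         -0.70 6.500e-02 0.05555556       FALSE
# 5  ame  vir         -0.70 7.550e-02 0.06944444       FALSE
# 6  nic  mul          0.56 1.145e-01 0.08333333       FALSE
```

Species with common inversion polymorphisms do not sit significantly
farther apart than monomorphic species (P = 0.75), while the proportion
of oocytes with chromosomes out correlates strongly with dot size.
Three of the six pairwise contrasts clear their FDR cutoffs — but in
inconsistent directions (the `car`–`sig` contrast is significant with
the *monomorphic* species larger).

Simulate an oocyte and recover its geometry:

```r
sim <- generateOocyteStack(SimulationParams(trueSeparation3d = 6, seed = 7L))
measureOocyte(sim$stack)
#   oocyte_id out_flag configuration d_xy_um z_sections distance_um area1_um2 area2_um2
# 1    oocyte     TRUE      both_out   5.778          3     5.96953  0.373248  0.373248
```

The measured 3D separation (5.97 µm against a ground truth of 6 µm) is
well within one voxel diagonal (≈ 0.51 µm at 54 nm pixels and 0.5 µm
sections).

A thin command-line front end with `generate`, `measure`, `stats` and
`run` subcommands lives at `inst/scripts/spindledots.R`.

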