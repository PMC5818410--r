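---
title: "mitomorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitomorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## Scientific setting

Loss of parkin function in *Drosophila* degenerates the PPL1 cluster of
dopaminergic (DA) neurons while sparing PPM3. mitomorph implements the full
quantification chain used to characterise this phenotype from confocal
z-stacks and behavioural recordings: 3D mitochondrial morphometry inside a
tyrosine-hydroxylase (TH)-defined region, MitoTimer aging ratios,
autophagosome counting and object-based colocalization (mitophagy
initiation), negative-geotaxis climbing metrics with ROC classification,
total-protein western-blot normalization, and the comparison statistics that
tie these measures to genotype and age. Because the underlying study reports
its results only as figure panels, validation here is property-based: a
synthetic-data generator produces stacks, traces and lane tables with known
ground truth, and the pipeline is required to recover that truth.

## Image pipeline

**ROI construction.** The TH channel is thresholded with Otsu's method, and a
binary closing with a one-voxel 26-neighbourhood ball bridges staining gaps.
Somata are 26-connected components of the ROI above a minimum volume
(default 30 µm³, configurable); touching somata are not split — a known
limitation, as per-cell delineation in the source workflow was manual.

**Segmentation.** Each reporter channel is thresholded by Otsu computed from
the voxels inside the ROI (the original analysis used a commercial
"automatic bright threshold" whose algorithm is unpublished; Otsu is the
canonical, oracle-testable choice). Foreground voxels are grouped into
26-connected components (configurable to 6). Objects are then filtered by the
*centroid rule*: an object is kept if its centroid lies inside the ROI, so
objects straddling the boundary are kept or dropped whole rather than
fragmented. Every object carries the intensities of all channels at its
voxels, so colocalization needs no second pass over the stack.

A numerical convention worth stating: the Otsu threshold is returned as the
midpoint between the optimal split level and the next occupied intensity
level, so it falls strictly between separated modes; foreground is
`intensity > threshold`. Ties in the between-class variance resolve to the
lowest threshold.

**Saturation QC.** The acquisition protocol aimed for about 2% overexposed
voxels; `saturationFraction()` measures the fraction at `bitMax` and warns
outside 1–4% by default.

## Morphometry

The study's shape score is the *inverse sphericity* `6V / (D·S)`. "Diameter
surface" is read as diameter × surface area — the only reading under which an
exact sphere scores 1 (`6·(4/3)πr³ / (2r·4πr²) = 1`) and every other shape
scores below 1. Fragmented, rounded mitochondria therefore score near 1;
interconnected tubular networks score low.

* **Volume** is voxel count × voxel volume — exact, and exactly conserved:
  per-channel object volumes sum to the foreground voxel count times the
  voxel volume.
* **Diameter** is the maximum Feret diameter: the largest pairwise distance
  between physical centres of surface voxels, computed exactly (the source
  software's definition is unpublished; max Feret is the standard choice).
* **Surface area** uses marching tetrahedra at level 0.5 on an anti-aliased
  (Gaussian, σ = 1 voxel) copy of the binary mask, with anisotropic voxel
  spacing. The isosurface of the *raw* binary mask overestimates a digitized
  sphere's area by roughly 9% (staircase facets), which would push the
  digitized-sphere inverse sphericity far from 1; light smoothing brings the
  estimate within ~2.5% at r = 10 voxels. Objects too small to survive
  smoothing fall back to the raw binary isosurface, and single voxels to
  their voxel-box area. Accuracy degrades below ~5 voxels radius — comparisons
  between conditions remain valid because the bias is shared, but absolute
  sphericities of very small objects should not be over-interpreted.
* **Size histograms** use the study's rule: bin width = (max − min)/3, three
  bins spanning the data, half-open except the last (the maximum never opens
  a phantom fourth bin), centres at bin midpoints. If all values are equal
  the histogram degenerates to a single bin holding everything.
* **Largest-5% subset**: `ceiling(0.05 n)` objects by volume, ties resolved
  by stable input order (the study does not state its rounding; ceiling
  guarantees a non-empty subset).
* **Network volume per cell**: summed object volume assigned to each soma by
  object centroid, divided by that soma's volume.

## Reporter quantification

MitoTimer totals are sums of per-object volumes per channel; the red:green
ratio indexes mitochondrial aging. A zero green total makes the ratio
undefined; such clusters are flagged and excluded from statistics rather
than propagated as infinities.

Autophagosome puncta are red objects with volume in (0.1, 1] µm³. The source
text prints a lower bound of "0.1 nm³", ten orders of magnitude below a
voxel and unfilterable; it is implemented as 0.1 µm³ and both bounds are
arguments, so the literal value remains available to anyone who disagrees
with that reading.

Colocalization (mitophagy initiation) is object-based: a red punctum counts
as colocalized when the Pearson correlation between its red and green
intensities over its voxels is positive (`r > 0`, threshold configurable).
Undefined correlations — fewer than two voxels, or constant green signal,
i.e. a punctum over no mitochondrial signal — count as *not* colocalized.
One consequence matters for validation design: on a signal-free green
background with additive read noise, the sign of r is a coin flip per
punctum, so a strict `r > 0` rule has no well-defined recovery target there.
The recruitment simulations therefore run in the shot-noise-limited regime
(Poisson noise only), where background green is exactly zero, correlations
over non-colocalized puncta are undefined, and the recovered count has a
clean truth to match. With read-noise-bearing data a positive `rThreshold`
should be used instead.

## Negative geotaxis

Beam index b maps to position `(b − 1) · span/(nBeams − 1)`; the study's
monitor has 17 beams over 51 mm, so the spacing is 3.1875 mm and beam 17 is
51 mm. A *climb* is a maximal non-decreasing run of the 1 Hz position trace
with positive net ascent: flat seconds extend a climb (the definition of
"continuous trajectory to a higher position" is agnostic about pauses; this
choice is pinned by a hand-traced example in the tests), and any downward
move ends it. Total height equals the sum of positive per-second
displacements — an identity the tests verify against a brute-force oracle on
random traces.

The ROC over per-fly scores (average height climbed, the figure's metric;
total height is available) computes AUC as the pairwise concordance
fraction with ties counting ½, and selects the threshold maximizing
Youden's J, breaking ties toward higher sensitivity. Classification uses
`score ≥ threshold`. Ground-truth climber labels are an input: the study
does not state how control flies were labelled, so the synthetic module
supplies labels by construction.

## Western-blot normalization

Lane normalization factors (LNFs) divide each lane's total-protein signal by
the brightest lane on the same blot, so LNFs lie in (0, 1] with maximum
exactly 1; the same rule normalizes each band across lanes. Band LNFs are
divided by the lane's total-protein LNF, cancelling loading exactly in the
noise-free case. Total atg8a is uncleaved + cleaved; percent cleaved is
100 × cleaved/total. Denominators never cross blots. Replicates are averaged
*after* normalization (the order is not stated in the source; averaging
first is available by normalizing per-replicate tables separately).

## Statistics

`normalityGateCompare()` reproduces the study's gate: Shapiro–Wilk per group
at α = 0.05 (per group, not pooled residuals — the source is silent; per
group is the stricter reading); all pass → one-way ANOVA with Dunnett's
comparisons to control; any fail (or any group with n < 3 or constant
values) → Kruskal–Wallis with Dunn's rank comparisons to control, tie
corrected, Holm adjusted (the Dunn variant of the source software is
unspecified). Dunnett probabilities come from multivariate-t integration,
which is quasi-Monte Carlo; the stream is seeded internally so identical
input yields an identical report. Two-way designs fit `y ~ A*B` and compare
marginal means of each factor to its control level with multivariate-t
("Dunnett-style") adjustment. Fisher's exact test, the Mann–Whitney test
(exact for both n ≤ 10 without ties) and the pooled-variance t-test are
delegated to R's stats package; the test suite checks all of them against
independent full-enumeration oracles. Stars follow the figure convention:
\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001 on adjusted p. All
tests are two-sided.

## The synthetic-data generator

`generateStack()` rasterizes analytic primitives — spheres, axis-aligned
ellipsoids, capsules (cylinders with hemispherical caps, so tubes have exact
volume, surface and diameter) — at voxel centres, convolves with a separable
anisotropic Gaussian PSF, applies Poisson shot noise then Gaussian read
noise, and rounds to integer counts. Defaults mirror the acquisition: voxel
size (0.34, 0.24, 0.24) µm in (z, y, x) — the z-step is the study's; the
lateral size is not derivable from the reported optics and is configurable —
and PSF σ_z = 0.44 µm (the 1.039 µm optical section FWHM / 2.355) with
σ_xy = 0.15 µm. Every shape carries its analytic volume, surface, diameter
and inverse sphericity, with the 6V/DS identity holding to 1e-9 by
construction. A `saturationTarget` rescales intensities so a chosen voxel
fraction saturates, emulating the ~2% overexposure capture rule.

`generateCohort()` emulates the genotype × region design: groups of 15
clusters (the study analysed ≥ 10–15 clusters per condition), each one
TH-labelled region containing 6 spheroid mitochondria of volume-equivalent
radius 1.6 µm (≈ 17 µm³, soma-scale network fragments well above the PSF),
with truncated-lognormal per-cluster (σ_log = 0.2) and per-object
(σ_log = 0.25) size variability. Group effects shift the generating
parameters: a volume-preserving aspect-ratio change (the fragmentation/
elongation axis of the phenotype), a volume scale, a red-fraction scale (the
MitoTimer ratio effect; red "aged" signal is a nested co-centred ellipsoid
occupying a controlled volume fraction, 0.3 by default), and a
colocalization probability for the puncta flavour. Object centres sit on a
jittered grid sized so neighbouring objects cannot touch after PSF blurring
for any seed — with rejection sampling in a field this crowded, merged
objects would contaminate the per-cluster means the statistics consume.

Fly motion is a first-order Markov walk over beam indices at 1 Hz with an
optional per-second probability of slipping to the tube bottom. Slips are
what make the climber phenotype measurable: a climber (pUp 0.30, pDown 0.05,
pSlip 0.008) repeatedly re-climbs tens of millimetres, while a non-climber
(pUp = pDown = 0.02) accumulates single-spacing climbs, separating the
average-height score.

What the generator does **not** emulate: photobleaching, stage drift,
chromatic aberration, autofluorescence gradients, touching or overlapping
cells, fly biomechanics beyond the Markov walk, and gel image artefacts
(densitometry is out of scope; lane tables are the input, as in the source
workflow). Passing recovery tests therefore demonstrates the correctness of
the measurement chain under its stated model, not robustness to every
artefact of real microscopy.

## Validation design and problem sizes

The test suite validates each algorithm against an independent oracle:
exhaustive between-class-variance search for Otsu, recursive flood fill for
connected components, all-pairs distances for the Feret diameter, explicit
pair counting for AUC, full enumeration for Fisher and Mann–Whitney,
closed-form prolate surfaces for sphericity, and hand-computed examples for
climbing and normalization arithmetic.

Effect recovery runs two cohorts of 3 × 15 clusters (an affected region with
a 4:1 aspect effect and 2× ratio effect in one group; a matched null
region). Detection calls for planted effects are made at the \*\*\* level
(adjusted p < 0.001): with these effect sizes the true detections sit many
orders of magnitude below that, while per-seed sampling fluctuations of the
cluster means — which are genuine differences in the *sampled* truth, not
errors — peak at α-level p-values. The α = 0.05 family-wise error rate of
the gated procedure itself is verified separately on 1000 matched Gaussian
null cohorts (rejection fraction required within [0.03, 0.07]).
Colocalization recovery uses 20 seeds per mixing fraction at shot-noise SNR
≈ 14. These sizes keep the full suite within a few minutes while leaving
Monte-Carlo margins far wider than the assertion bands.

## Known limitations

* Touching somata and touching mitochondria are not split (no watershed);
  the generator avoids producing them rather than the pipeline resolving
  them.
* Surface area, and hence inverse sphericity, is biased for objects below
  ~5 voxels radius; measured inverse sphericity of PSF-scale objects sits
  well below the analytic value (comparisons remain valid; absolute values
  do not).
* The Otsu threshold adapts per stack; volumes of dim, thin structures are
  inflated relative to bright compact ones — a physical property of
  threshold-based segmentation on blurred data that the cohort design
  accounts for by keeping objects well above the PSF scale.
* Only axis-aligned ellipsoids and z-capsules are generated; arbitrary
  orientation would require numerical truth for the surface area.
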