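---
title: "Models and methods behind punctaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind punctaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflux)
```

punctaflux implements the three quantitative readouts that drive
reporter-based CRISPR screens of autophagy — 3D puncta imaging, tandem-
fluorescent (tf) reporter flow cytometry, and FACS-sorted sgRNA
sequencing — together with ground-truthed simulators for all three data
types. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic validation does and does
not establish about real data.

## The imaging pipeline

### Background model and cell mask

Cell-containing regions are found by a calibrated hypothesis test, not a
free threshold. A z-stack of an *empty field* (same optics, no cells) is
smoothed and a Gaussian is fitted to its intensity distribution by
sample mean and SD (for a Gaussian, the method of moments is also the
maximum-likelihood fit). A voxel of the identically smoothed sample
stack is assigned to cells when the upper-tail probability of its
intensity under that Gaussian falls below `alpha` (default `1e-5`).

Two choices deserve note:

* **Tail direction.** The test is one-sided (upper tail): fluorescent
  foreground is strictly brighter than camera background, so a dim
  outlier is not evidence of a cell.
* **Equivalence to a closed-form cutoff.** Per-voxel p-value masking is
  mathematically identical to thresholding at
  `mu + qnorm(1 - alpha) * sigma`; the test suite verifies the two
  routes agree to floating-point precision on a million random voxels.
  The p-value formulation is kept because it makes `alpha` — a false-
  positive rate per voxel — the interpretable knob.

The smoothing kernel (Gaussian, default SD `(1, 2, 2)` voxels in
`(z, y, x)`) is applied identically during calibration and application;
using different kernels would invalidate the fitted null. Smoothing
deliberately precedes the test: it shrinks the background SD by
averaging, sharpening the foreground/background separation at the cost
of a blurred mask edge — which is exactly why the pipeline later erodes
cell edges.

Debris is removed by deleting 3D connected components (26-connectivity)
smaller than a volume bound, with a *strict* inequality: a component of
exactly the bound survives. The full-frame confocal default is 100,000
voxels; `run_config()` defaults to 1,000 because at the synthetic
default scale an entire cell occupies only ~10,000 voxels.

Out-of-focus planes are removed by a per-plane classifier on three
features (masked-voxel fraction, mean in-mask intensity, mean in-plane
gradient). A linear-kernel SVM can be trained on labelled synthetic
planes; the default is a fixed-threshold fallback (plane out of focus
when its masked fraction is below 0.001), which is what a plane with no
cell signal looks like under the calibrated mask. Plane decisions and
feature vectors are logged to CSV so no plane disappears silently.

### Nuclei, cells, erosion, border removal

Nuclei are segmented from the DAPI channel by *slice-by-slice relative
thresholding*: each plane is cut at `mode + t * (max - mode)` with
`t = 0.5`, the mode estimated from a 256-bin histogram. The rule is
scale-free per slice, which tolerates axial intensity falloff. A plane
whose maximum is within 6 robust SDs of its mode is declared blank and
contributes nothing (otherwise pure-noise planes would seed speckle).
Components are labelled in 3D; a component holding more than one strong
maximum of the Euclidean distance transform (voxels reaching 70% of the
component's EDT maximum) is split by seeded watershed on the negated
EDT. Objects under `min_volume` (default 500 voxels at the synthetic
scale) are discarded.

Cells are grown from nucleus seeds by a geodesic seeded watershed: a
26-neighbour Dijkstra flood of the cell mask in which each masked voxel
joins the cell of its geodesically nearest nucleus. Ties on the
watershed surface resolve to the first-reached seed under a fixed scan
order, so segmentations are bit-reproducible. Axial steps are weighted
2:1 relative to in-plane steps by default, reflecting the coarser z
sampling of confocal stacks.

Cell edges are then eroded (in-plane disk of radius 2, no axial
erosion — anisotropy again) to trim the blurred halo the p-value
transformation admits, and any cell touching the *lateral* field border
is dropped. Axial truncation does not disqualify a cell: confocal
stacks routinely clip cells in z, and the purpose of the filter is to
exclude cells whose area (and hence puncta count) is cropped laterally.

### Puncta segmentation and colocalization

Punctae are segmented per channel by 2D Canny edge detection run plane
by plane: Gaussian smooth (default SD 0.8 px), Sobel gradients,
non-maximum suppression, double-threshold hysteresis, then filling of
closed contours; filled planes are stacked and components connected in
3D. Per-plane 2D processing avoids computing 3D gradients on strongly
anisotropic voxels and mirrors slice-wise practice in this field.

The hysteresis thresholds are the parameters that matter most, and they
are *empirical by nature*. `canny_params()` defaults to quantile
thresholds (q0.90 / q0.99 of the plane's gradient magnitude) — a
reasonable starting point on an unknown imaging configuration — while
`run_config()` ships absolute thresholds (low 180, high 400 gradient
units) calibrated against ground truth on the synthetic default scene.
The governing constraint is physical: the low threshold must clear the
cell-boundary gradient (the diffuse cytoplasm step, ~110 units here),
otherwise cell outlines close into filled blobs that swallow every
punctum inside; the high threshold must stay below the spot-ring
gradient so genuine punctae still seed. With the calibrated defaults
the per-cell count error is 2–5% at the default signal-to-noise ratio.
A blank-plane guard skips planes whose maximum gradient is within 8
robust units of the median — pure noise planes, on which quantile
thresholds would otherwise hallucinate contours.

Components pass a volume gate (default 4–10,000 voxels: no single-voxel
noise, no merged blobs) and, by default, must have their centroid
inside a segmented cell. Whether out-of-cell punctae belong in field
totals is genuinely ambiguous; both behaviours are supported and the
choice is recorded with the result.

Each punctum is assigned to the cell owning the plurality of its
voxels (ties to the smaller label). Colocalization is object-based, the
measure used for contrasts like "fraction of LC3-positive structures
that are WIPI2-positive": a green punctum colocalizes when it shares at
least `min_overlap_vox` voxels (default 1) with any red punctum, and
symmetrically. Intensity-correlation measures (Pearson, Manders) are a
non-goal. Cells with zero punctae in the numerator channel report a
missing fraction, never zero.

## Flux statistics

The tf reporter readout is the per-event Red:Green ratio `RFP/GFP`;
events with non-positive GFP are excluded and tallied. Summaries are
the median, inner quartiles, and 10th/90th percentiles, computed with
linear ("type 7") interpolation — fixed and documented because gating
software does not publish its rule. Summaries are normalized by
dividing every quantile by a reference population's median (typically
the lysosomal-inhibition / BafA1 state); the reference population is an
explicit input because which acquisition should anchor a panel is an
experimental-design decision, not something the package can infer.
A floor of 1,000 events per population is enforced by default.

Bimodal populations (e.g. partially penetrant knockouts) are
deconvolved with a parameter-free gate: the threshold on log10 ratio
that minimizes within-class variance over a 256-bin histogram (Otsu's
criterion, exhaustive scan — the suite checks the scan against a
brute-force oracle). The log domain makes the gate scale-equivariant:
re-scaling all intensities shifts the threshold by the same factor. A
population whose best split explains less than 80% of total variance is
flagged degenerate rather than split; the floor sits above the ~64% an
optimal split of a *unimodal* Gaussian already achieves, which is why
0.5 would be useless as a flag.

Knockout phenotype strength is summarized as **fold repression**:

> (median_gene − median_ATG9A) / (median_control − median_ATG9A)

anchored on the assumption that the ATG9A knockout is a true
autophagy-null (score 0) and the non-targeting control is unaffected
(score 1). Scores outside [0, 1] are reported as-is and flagged, never
clamped — a clamp would hide enhancers and spurious hits. The score is
invariant under affine rescaling of all three medians, so instrument
gain and offset cancel.

## Screen scoring

Reads are assigned to sgRNAs by anchored extraction: the first exact
occurrence of the vector sequence `CACCG` in each read, followed by a
20-nt exact match against the library. Reads without anchor or match
are tallied, never guessed at; barcode error correction is out of
scope. Counts are depth-normalized by median-of-ratios size factors
(the standard count-matrix estimator; the suite cross-checks against
DESeq2's implementation).

The per-gene score is deliberately simple: per sgRNA,
`log2((high + c)/(low + c))` with pseudocount `c = 0.5` on normalized
counts; per gene, the mean over its sgRNAs. It is a stand-in with
beta-score *semantics* (positive = enriched in the high Red:Green bin),
not a reimplementation of an MLE — gene summaries from dedicated screen
software can be fed directly into the downstream steps. Those steps
are: arithmetic averaging across the 2–4 replicates in which a gene was
measured (with the replicate count recorded per cell), and
normalization of every reporter column by its ATG9A score so the
reference row is exactly 1. Normalization happens *after* averaging;
the alternative order is defensible but is not what the heat-map
convention implies, and the choice is logged. A zero or missing
reference flags the column instead of silently skipping it.

## The synthetic generators

The generators define the package's study conditions; their defaults
are fixed, not tuned per experiment.

**Scenes.** A field of 13 planes × 256 × 256 px holds 30 cells:
cylindrical cell bodies (radius 14 px, half-depth 4 planes) with
ellipsoidal nuclei (8 px in-plane, half that axially), diffuse
cytoplasmic signal (75 units above a background of mean 100, read-noise
SD 10), and punctae rendered as Gaussian spots (peak 500 units, SD
1.0 px in-plane) — the diffraction-limited appearance that makes Canny
behave realistically, rather than hard spheres. The whole scene is
blurred with an anisotropic Gaussian PSF (SD 0.8 planes axially,
0.5 px laterally) and corrupted with Poisson shot noise on signal plus
additive Gaussian read noise; both noise terms can be disabled because
real camera statistics are instrument-specific. Green puncta counts are
Poisson per cell (mean 6); each green punctum independently receives a
coincident red partner with probability `coloc_fraction`, and
additional red-only punctae are Poisson (mean 1.5) — so the realized
colocalized fraction is an honest binomial draw that the pipeline's
estimate can be compared against.

This is a *scaled-down* scene. At the one acquisition voxel size the
source experiments state (83 nm × 83 nm × 438 nm, for the correlative
microscopy), a HEK293T cell would span ~350 px and a stack would hold
hundreds of planes; simulating that per test is pointless. The scale
preserves every structural feature the pipeline exercises — anisotropy,
diffuse-vs-punctate contrast, touching cell masks, axial truncation —
at ~1/6 linear scale. Voxel anisotropy is a free parameter throughout.

Placement is by rejection sampling with a retry cap (default 1,000):
cell bodies may not overlap and stay clear of the lateral border, and
the generator fails loudly rather than silently overlapping. Punctae
within a cell take distinct lateral positions (minimum xy separation
5 px): two spots separated only axially are unresolvable at confocal z
sampling, and planting unresolvable truth would make every recovery
metric unattainable by construction rather than informative.

What the scene generator does *not* emulate: spectral bleed-through,
illumination gradients, saturated pixels, mitotic or apoptotic cell
morphologies, and clustered (non-Poisson) puncta spatial statistics.
Passing the recovery tests therefore shows the pipeline is correct
*given its model of the data*; on real stacks the Canny thresholds
remain an empirical choice, exactly as in the experiments this tooling
reproduces.

**Flow populations.** Events are drawn per mode: log10 ratio from
`Normal(log10(median), log_sd)`, GFP log-normal, RFP = ratio × GFP,
with multiplicative channel noise. Medians converge to the specified
values, which is all the flux statistics consume.

**Sorted screens.** Every simulated cell carries one sgRNA (the low-MOI
idealization: one integration per cell); a knockout shifts the cell's
log2 ratio by the gene's effect size; cells are sorted into the top and
bottom thirds of the *realized* ratio distribution, so sorting
misclassification — a cell of a strong suppressor landing in the wrong
tail — is part of the simulation, not assumed away. Reads per bin are
multinomial at a mean depth of 300 reads/sgRNA (within the 200–400
band typical of these screens), with 150–200 cells per sgRNA and 2–4
replicates. The default effect size for planted hits in the validation
(±1.5 log2 units against a cell SD of 1) produces per-sgRNA enrichments
around 16-fold, the regime in which real core-machinery hits live.

## Numerical and degenerate-input choices

* All volumes use axis order `(plane, row, column)`; compiled kernels
  and R code share this single convention.
* Gaussian smoothing uses mirror boundaries and kernels normalized to
  unit sum, so constants are fixed points and the stack mean is
  preserved up to boundary error.
* Connected components and watershed use 26-connectivity in 3D;
  watershed ties break deterministically (first-reached seed, fixed
  scan order).
* The distance transform is the exact separable squared-EDT algorithm
  with per-axis voxel weights.
* Erosion that annihilates a cell drops it with a warning; an empty
  mask, a blank plane, a zero-puncta cell are all ordinary outcomes,
  not errors. Errors are reserved for contract violations (no seeds,
  zero-variance calibration field, mode fractions not summing to 1,
  duplicate library sequences ...), and each carries a condition class
  so callers can test for it.
* Every generator and every pipeline stage is deterministic given its
  seed; `run_config()` fans a root seed out to per-stage seeds so stage
  subsets re-run reproducibly, and full runs are byte-identical.

## Problem sizes in the validation suite

The shipped validation runs 20 default scenes for segmentation
recovery, 20 scene pairs for the colocalization contrast (generator
fractions 0.79 vs 0.08, the regime of interest for
phagophore-maturation phenotypes), 10,000-event flow populations, and
1,000-gene × 4-sgRNA screens at 300 reads/sgRNA with 20 planted hits.
These sizes give the acceptance statistics comfortable Monte-Carlo
margins (e.g. binomial SE on a recovered colocalization fraction of
~0.01) while keeping a full validation run to a few minutes.
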