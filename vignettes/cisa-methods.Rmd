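---
title: "Quantifying immune synapses and spatial colocalization in multiplexed tissue images"
author: "cisa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune synapses and spatial colocalization in multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisa)
```

## The problem

When a T cell recognizes antigen on another cell it reorganizes its surface:
the T-cell receptor complex (proxied by CD3) concentrates at the contact —
the immunological synapse. Multiplexed tissue images (whole-slide confocal
histocytometry, imaging mass cytometry) show each cell's marker intensities
at subcellular resolution, so synapse formation is in principle visible
*in situ*. This package quantifies it from two standard inputs: a
multichannel intensity image and an integer mask of segmented cells.

## Synapse strength

For a reference T cell and one neighbor, the synapse strength is

$$\sigma = \log_2 \frac{\overline{I}_{\text{contact}}}{\overline{I}_{\text{noncontact}}}$$

where the means are taken over the contact and non-contact portions of the
T cell's membrane for the scored marker. The membrane is the internal
boundary of the cell mask — 2 pixels wide for histocytometry, 1 pixel for
the coarser IMC resolution — computed as the cell minus its iterated
8-connected erosion, so cells cut by the image border still have a defined
(flagged) membrane. A neighbor's pixel set dilated with a radius-2 diamond
(L1 ball) marks the contact: its intersection with the reference membrane.
The diamond radius must bridge the neighbor's own membrane thickness; radius
2 reaches across a 2-pixel gap, which is why tangent cells with a one-pixel
background seam still register as contacts. When one T cell touches several
neighbors of the same type, all their contact pixels are removed from a
single shared non-contact pool, so each contact is scored against membrane
genuinely free of that cell type. Scores are directional: σ(T→APC) uses the
T cell's membrane only.

σ is invariant to rescaling the channel (units cancel) and antisymmetric
under swapping the contact and non-contact sets. Per-sample summaries are
arithmetic means of σ over contacts; patients are stratified by the strict
rule σ̄ > 0 (contact with synapse tendency) versus σ̄ ≤ 0 or no contact at
all.

### IMC zero handling

IMC counts are sparse: either membrane mean can be exactly 0. Instead of
discarding such contacts, a per-sample noise term — the mean of the marker
over all pixels of cells *not* of the reference type — provides a fill-in
value for a zero mean. One special case is scored 0 outright: contact mean
0 with non-contact mean below the noise term, i.e. no evidence in either
direction. The fill-in is applied symmetrically when only the non-contact
mean is 0 (the asymmetric case is not distinguishable in practice), and
both fill-ins are flagged in the output. In fluorescence mode a zero mean
simply excludes the score (flagged, not an error), since the fill-in rule
is an IMC-specific correction.

### Seed-and-grow null model

Segmentation bias alone can polarize membrane signal, so observed σ̄ values
are compared against a null in which the "contact" is a random contiguous
membrane region: a seed pixel is drawn uniformly, then uniformly chosen
frontier pixels are added over the 8-connected membrane graph until the
region holds at least 15 pixels (membranes smaller than that are ineligible
and are excluded from observed aggregates too, for symmetry). A cell's null
value averages 5 such regions; an iteration averages the eligible cells;
the null synapse value averages 100 iterations. Each (cell, iteration) pair
draws from its own RNG substream derived from the master seed, so the
result is independent of evaluation order and reproducible under
parallel-friendly reorderings. On a membrane with spatially uniform signal
every region gives a ratio of exactly 1, so the null value is exactly 0.

## Correlation analyses

Whether two markers co-polarize is asked two ways. The contact-referenced
way correlates σ values of the two markers across matched contacts
(pooled, or per sample), Pearson by default — σ is continuous and
approximately log-normal deviations are expected; the choice is
configurable. The contact-naive baseline correlates the two channels over
every pixel of every cell of the type. Pixel pooling conflates cell-to-cell
staining variability with subcellular structure, which is precisely why the
σ-based correlation is expected to be stronger when polarization is real;
the package reproduces that ordering on synthetic co-polarized data (see
the acceptance script). Method comparison uses a paired t test across
samples; a zero-variance difference vector is reported as degenerate rather
than a fabricated p value.

## Radial distribution functions and ΔCDF

The RDF around a reference type counts target cells per 1 µm distance bin
out to 100 µm from each reference cell (centroid-to-centroid, half-open
bins, self excluded), divides by the number of reference cells and by the
annulus area π[(r+1)² − r²], and — deliberately — does *not* divide by the
overall point density: the curve reads as an absolute cell density near the
reference type, which is itself informative. Near image borders part of an
annulus falls outside the observation window; each cell-bin count is
divided by the in-window annulus fraction, the standard unbiased border
correction (multiplying would bias densities downward). The fraction is
computed analytically for rectangular windows from exact circle–rectangle
intersection areas (a piecewise closed-form integral, verified against grid
integration in the tests); the correction matters for TMA-sized fields and
can be disabled for whole-slide runs where it is negligible.

The expected curve permutes cell-type labels within each reference cell's
100 µm neighborhood — distances fixed, 100 permutations, one label token
per held type so multi-label (undersegmented) cells participate once per
label — and averages the recollected curves. Permutation conserves the
label multiset per neighborhood by construction. ΔCDF then normalizes the
observed and expected curves to unit mass, cumulates them, and sums the
100 per-bin CDF differences: positive ΔCDF means observed target mass sits
at shorter range than chance given the local density — colocalization.
Cohort-level ΔCDF is tested with a one-sided (greater) one-sample t test,
matching the package-wide convention of unadjusted p values.

## Adaptive tissue annotation

Tumor/stroma masks come from marker channels (melanoma marker for tumor,
CD45 for leukocytes): Gaussian blur (σ = 1 px, kernel truncated at 4σ,
replicate borders), log2(x+1), then 4-class Multi-Otsu thresholding. The
four classes map onto non-tissue background, tissue background, and low-
and high-intensity foreground; the binarization threshold is the *mean of
the low-intensity-foreground class*, deliberately generous so tumor is not
undersegmented. Multi-Otsu is solved exactly by dynamic programming over
the intensity histogram (256 bins when values are continuous) — the 1-D
K-means objective has an exact optimum, so there is no initialization
sensitivity, and the tests verify equality with exhaustive search over all
threshold triples. Masks are cleaned with a 10×10 square closing, filling
of holes under 2500 px, and removal of 8-connected objects under 2500 px;
stroma is the CD45 mask minus the tumor mask, so the compartments are
disjoint by construction. Cells are assigned to compartments by their
centroid pixel (the mask source does not dictate a rule; a centroid is
cheap, deterministic, and adequate for compact cells).

Cell-type labels use exact 1-D 2-means on per-cell log2(mean + 1)
intensities, per sample and per channel; the positive threshold is the mean
of the upper (membership) cluster, again deliberately conservative.
Antigen-loaded macrophages are called from the *cytoplasm* (cell minus
1-px membrane boundary): the statistic is the mean of cytoplasm values at
or above their 75th percentile (type-7 linear-interpolation quantile;
conventions differ, so this is configurable in code and documented), and
the call reuses the tumor channel's cell-labeling threshold. Cells with an
empty cytoplasm are excluded from loaded/unloaded splits rather than
guessed.

## The synthetic tissue generator

Every quantitative claim in the test suite is made on data with known
ground truth. `generateTissue()` places disk cells on a jittered grid;
designated reference–target pairs are tangent with a one-pixel seam, other
cells are isolated. Marker channels paint each cell's membrane ring at a
base intensity and its interior at a low cytoplasm level. The contact zone
on a reference membrane is defined by the *same* radius-2 diamond dilation
the analyzer uses, and its pixels are multiplied by the polarization factor
f — so in the noiseless case the measured σ equals log2(f) *exactly*, not
approximately, and f = 2 recovers mean σ = 1 to machine precision. Noise
options are additive Gaussian (clipped at 0) and Poisson counts; the
Poisson option at membrane intensity 25 gives SNR = √25 = 5 and produces
the exact-zero pixels that exercise the IMC fill-in rules. For the
two-marker co-polarization scenario, each contact draws a shared latent
log2 polarization (sd 0.8, marker coupling ρ = 0.9) and each cell draws
independent per-marker membrane base intensities (sd 1.0 log2 ≈ two-fold
staining variability, a realistic cell-to-cell range): polarization is
shared, staining level is not, which is the regime where contact-referenced
scoring should beat pixel pooling.

Point patterns for the spatial statistics are homogeneous Poisson
(independent labels — ΔCDF null) and parent–offspring clusters (offspring
uniform within 15 µm — ΔCDF positive control). The two-compartment image
fixture carries the four intensity populations the Multi-Otsu scheme
expects: a non-tissue margin (~1), tissue background (~8), and two-level
block-textured foreground (60/200 in 4 px patches, emulating heterogeneous
staining) for a central tumor disk and the surrounding leukocyte field,
with Gaussian noise (sd 6).

What the generator does *not* emulate: real cell shapes, point-spread
functions, spectral spillover, segmentation errors, or spatially varying
background. Passing tests therefore demonstrate correctness of the
computations under the stated model, not robustness to every imaging
artifact.

## Numerical and design choices

* Problem sizes: validation uses 480 px tissues with 200 designated
  contacts for recovery checks, 100 simulated 300 px samples for the
  correlation comparison, ~1000-point Poisson fields (100 cells/mm² over
  ~10 mm²) for RDF calibration, and 200 replicates each for the ΔCDF null
  and clustered scenarios.
* Coordinates are 0-based row-major; exported centroids are x = column ·
  pixel size, y = row · pixel size. One documented convention prevents
  silent mirroring.
* Intensities are floating point throughout after load. The TIFF writer
  stores integer-valued images as 16-bit samples (bit-exact round trip)
  and fractional images as 32-bit samples quantized at 2⁻³² of full scale.
* Multi-label cells (e.g. CD3⁺CD14⁺ undersegmentation doublets) are kept
  with all labels and participate once per held label in permutations.
* Membrane connectivity is 8-connected (internal boundary and seed-and-grow
  growth); the diamond dilation is L1. Pixel anisotropy is unsupported.
* Degenerate statistics (zero-variance cohorts) are flagged, never silently
  converted into p values.
* RNG: one master seed; derived substreams per (cell, iteration) for the
  null model and per permutation batch for the RDF, so outputs are
  reproducible and order-independent.

## Known limitations

2D geometry only; no sub-pixel boundary estimation; no mature-synapse
calling from reciprocal ligand markers; survival model fitting is left to
dedicated packages (only the σ̄ > 0 grouping rule is provided); cell
segmentation itself is upstream of this package.
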