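# cisa — Computational Immune Synapse Analysis

T cells that recognize antigen on a neighboring cell polarize their T-cell
receptor machinery (CD3) toward the contact, forming an immunological
synapse. `cisa` quantifies this directly in multiplexed tissue images —
whole-slide confocal histocytometry or imaging mass cytometry (IMC) — from
two standard inputs: a multichannel intensity image and an integer mask of
segmented cells.

For a T cell *t* in contact with a neighbor *a*, the synapse strength is

σ(t→a) = log₂( Ī_contact / Ī_noncontact )

the log-ratio of the mean marker intensity on the membrane pixels touching
*a* (the neighbor's mask dilated with a radius-2 diamond, intersected with
the T cell's 2-px internal membrane boundary) over the mean on the rest of
the membrane. σ > 0 means the marker is enriched toward the neighbor.
Around this core the package provides:

* **Contact geometry** — membrane extraction, directional contact records,
  shared non-contact pools across same-type neighbors.
* **IMC zero handling** — a per-sample background noise term fills in
  exact-zero membrane means; ambiguous zeros score 0 by rule.
* **A seed-and-grow null model** — random contiguous ≥15-px membrane
  regions (5 per cell, 100 iterations) control for segmentation bias.
* **Correlation analyses** — σ–σ correlations across contacts per marker
  pair, against the contact-naive pixel-pooled baseline.
* **Spatial statistics** — radial distribution functions in 1 µm bins to
  100 µm with annulus normalization and analytic rectangular-window edge
  correction, a within-100 µm label-permutation expected curve, and the
  ΔCDF colocalization statistic (sum of observed-minus-expected CDF
  differences; positive = closer than chance).
* **Adaptive tissue annotation** — exact 4-class Multi-Otsu tumor/stroma
  segmentation with closing/hole/object cleanup, exact 1-D 2-means cell
  labeling, upper-quartile cytoplasm calls for antigen-loaded macrophages.
* **A synthetic tissue generator** — packed cells with membrane-localized
  markers and a known contact-directed polarization factor f, so that the
  measured σ should equal log₂(f) exactly in the noiseless case; plus
  Poisson/clustered point patterns and two-compartment segmentation
  fixtures.

Classes are S4 (`MarkerImage`, `LabelMask`, `RegionMasks`,
`AnalysisConfig`); file formats are multipage TIFF (images), 16-bit
TIFF/8-bit PNG (masks), CSV (cell tables and results, with a JSON
run-metadata sidecar) and YAML (configuration).

## Worked example

Simulate a tissue whose designated T-cell→APC contacts carry a known
two-fold CD3 polarization under Poisson counting noise, then score it:

```r
library(cisa)

sim <- generateTissue(syntheticTissueConfig(nPairs = 8, nSingles = 6,
                                            polarizationFactor = 2,
                                            noise = "poisson", seed = 42))
res <- synapseAnalysis(sim$image, sim$mask, sim$cellTable)
head(res$scores[, c("ref_id", "neighbor_id", "marker", "sigma", "mode")], 4)
#>   ref_id neighbor_id marker     sigma     mode
#> 1      1           2    CD3 1.2297653 standard
#> 2      3           4    CD3 1.2419639 standard
#> 3      5           6    CD3 0.8059782 standard
#> 4      7           8    CD3 0.9775602 standard

res$summary
#>   sample_id marker target_type region sigma_bar n_contacts
#> 1    sample    CD3         APC    all  1.072072          8
```

Eight contacts scored; per-contact σ scatters around the ground truth
log₂(2) = 1 under the counting noise, and the sample mean σ̄ = 1.07 ≈ 1.
The seed-and-grow null on the same cells centres on zero:

```r
nm <- nullSynapseModel(sim$image, sim$mask, unique(res$scores$ref_id),
                       cisaConfig(rngSeed = 42))
#> null synapse value: -0.0045 (n = 8 cells)
```

A command-line wrapper covers the same pipeline
(`inst/exec/cisa simulate | segment | classify | contacts | synapse |
correlate | rdf`), writing CSV outputs plus a JSON run manifest; identical
seed and config reproduce byte-identical results.

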