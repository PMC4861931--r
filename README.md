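# ribbonQuant

Quantification of cochlear inner hair cell (IHC) ribbon synapses from
two-channel 3D confocal stacks.

Noise exposure can silently remove or reshape the synapses between IHCs and
auditory-nerve fibers (cochlear synaptopathy). Counting and measuring those
synapses means detecting, in deconvolved fluorescence stacks, every
presynaptic ribbon (Ctbp2 channel) and postsynaptic receptor patch (Gria2
channel), deciding which ribbon-receptor couples form a synapse, and mapping
sizes and positions cell by cell. ribbonQuant is for hearing researchers who
want that pipeline as tested, scriptable R functions rather than a chain of
proprietary tools.

## What it computes

- **Richardson-Lucy deconvolution** with a separable Gaussian confocal PSF:
  the ML estimate under Poisson noise, `e_{k+1} = e_k · C'(obs / C(e_k))`.
- **3D segmentation**: maximal 26-connected suprathreshold voxel sets
  (default global Otsu threshold per channel), with physical volumes
  (voxels × voxel volume) and intensity-weighted centroids in µm.
- **Pairing**: greedy mutual-nearest-neighbor matching of ribbons to
  receptor patches within a pairing distance (default 1.0 µm); everything
  unmatched is an orphan, and per-IHC tables satisfy
  total = paired + orphan by construction.
- **Positional clustering**: paired synapses projected onto the
  modiolar-pillar (u) and habenular-cuticular (v) cell axes, per-stack
  centroid alignment, then a full-covariance Gaussian-mixture EM over
  k ∈ {1,2,3} scored by BIC = −2·logL + p·ln n (p = 6k − 1), testing the
  two-population (modiolar/pillar) hypothesis instead of assuming it.
- **Quantile outlier maps** (volumes above the 0.9 quantile) and volume /
  count statistics: rank-sum tests (exact below combined n = 12, corrected
  normal approximation above), Welch t with Bonferroni, Gaussian-KDE volume
  summaries, and an acoustic energy-dose utility
  (energy ∝ duration × 10^(dB/10)).
- **A synthetic-scene generator**: seeded ground-truth IHC scenes with the
  published per-condition count means, log-normal volume mixtures and
  two-cluster positional structure, rendered into noisy 16-bit TIFF stacks
  (PSF blur + Poisson + read noise) with a JSON truth sidecar — the basis of
  all validation.

## Worked example

Simulate three control IHCs, render them, and run the full pipeline:

```r
library(ribbonQuant)
p  <- getPreset("control_12k")
sc <- sampleScene(p, nCells = 3, seed = 42)
st <- renderStack(sc, seed = 42)
pr <- processStack(st)                       # deconvolve + segment + pair
pr
#> PairingResult: 50 pairs, 5 orphan ribbons, 5 orphan receptors (max distance 1.00 um)

assignToCells(pr, cellTable(sc))$perCell
#>   cell_id total_ribbons paired orphan_ribbons orphan_receptors
#> 1       1            22     21              1                3
#> 2       2            16     13              3                2
#> 3       3            17     16              1                0
```

The scene truly contains 55 ribbons of which 50 are paired
(`sum(ribbons(sc)$paired)`), so the pipeline recovered every pair in this
stack; the per-cell table feeds `countSummary()` for mean ± s.e.m. by
condition, and `projectPairs()` / `alignEnsemble()` / `emCluster()` /
`quantileOutlierMap()` continue the positional analysis. The energy-dose
utility reproduces the equal-intensity comparison between exposure
protocols:

```r
energyRatio(exposureDose(105, 30), exposureDose(100, 120))
#> [1] 0.7906
```

A one-command pipeline with a reproducibility manifest is available both as
`runPipeline(defaultPipelineConfig(), "out/")` and as a thin CLI
(`inst/scripts/ribbonquant.R`) with `simulate`, `segment`, `pair`, `run` and
`dose` subcommands.

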