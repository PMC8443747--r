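# mn3d — 3D quantification of micronuclei in fluorescence Z-stacks

Micronuclei — small extranuclear chromatin bodies with an equivalent radius
below 2 µm — are a widely used readout of genomic instability and, in brain
tissue, of inflammation-associated damage in neurons and astrocytes. Counting
them in single optical sections is unreliable: a confocal slice that grazes
the cap of a regular nucleus (major axis 12–15 µm) produces a small
cross-section that is indistinguishable from a genuine micronucleus. `mn3d`
quantifies nuclei and micronuclei by true 3D reconstruction of multi-channel
confocal Z-stacks, so grazing sections are absorbed into their parent nucleus
instead of being miscounted.

The pipeline, for each channel (blue = chromatin/DNA stain, green =
nuclear-envelope or secondary marker, red = cell-type marker):

1. **Bilateral smoothing** — edge-preserving denoising with spatial sigma
   σ_s (voxels) and intensity variance σ_r² (both 0 = off).
2. **Binarization** — locally adaptive discriminant (Otsu) thresholding in
   overlapping windows with a sensitivity multiplier, or a manual global
   threshold; windows without genuine two-class structure fall back to
   slice/stack-global thresholds.
3. **Morphology** — closing with a disk of radius w₁ (fragment reconnection)
   and opening with radius w₂ (speck removal); 0 = off.
4. **Labelling** — 26-connected 3D components (or per-slice 8-connected 2D),
   optional reproducible label edits (delete/merge/split) and clearing of
   components on the lateral x/y borders (z-face contact is kept).
5. **Ellipse fitting** (optional) — fused nuclei in dense regions are split
   by a greedy cover of ratio-constrained ellipses searched over a discrete
   grid of 180/N orientations, re-linked across slices.
6. **Morphometry & classification** — equivalent radius
   R_cal = (3V/4π)^(1/3) from the volume (or √(A_max/π) from the maximum
   cross-sectional area), inclusive size bands (micronucleus 0.2–2.0 µm,
   nucleus 4–10 µm by default), overlap-rate classification of *objective*
   regions (red regions covered ≥ 50 % by the green∪blue mask by default),
   and envelope (e.g. Lamin B1) ± status for micronuclei.

Input is single or sequential 8/16-bit TIFF (multi-page RGB, one file per
channel, or one file per slice); output is a per-region CSV/TXT table, count
summaries, annotated 16-bit label TIFFs and a YAML run log that fully
reproduces the run.

## Worked example

Five nuclei placed in a row with 20 % pairwise overlap fuse into a single
binarized component; ellipse fitting on the chromatin channel recovers them:

```r
library(mn3d)

ph <- dense_scenario(5, overlap_fraction = 0.2, seed = 1)
p  <- mn_params(voxel_spacing = ph$stack$spacing,
                per_channel = list(blue = list(fitting_ellipse_max_ratio = 1.3)))
res <- run_pipeline(ph$stack, p)
res
#> mn3d pipeline result
#>   regions: 6 (channels: blue)
#>   nuclei: 5   micronuclei: 0 (envelope+ 0 / envelope- 0)
#>   objective regions: 0   micronuclei per nucleus: 0.000

head(res$regions[, c("label", "channel", "class", "r_cal_um", "centroid_x_um")])
#>   label channel        class r_cal_um centroid_x_um
#> 1     1    blue      nucleus 5.426927     31.501680
#> 2     2    blue      nucleus 4.179195     23.332379
#> 3     3    blue      nucleus 4.964419     15.713902
#> 4     4    blue      nucleus 4.808631      7.351047
#> 5     5    blue      nucleus 4.596349     40.016902
#> 6     6    blue unclassified 2.893738     23.346059
```

All five nuclei are recovered with equivalent radii close to the constructed
~5 µm, at the constructed ~8 µm centre spacing (the sixth region is a small
unclassified residual between two nuclei, excluded from both size bands).
Without ellipse fitting the same stack yields one fused component. The
grazing-section confound is reproduced by `edge_slice_scenario()`: 2D
analysis of the top slice reports a micronucleus-band region, 3D analysis of
the same stack reports exactly one nucleus and zero micronuclei.

A shell driver wrapping the same functions is installed at
`system.file("exec/mn3d", package = "mn3d")`:

```sh
mn3d phantom disjoint --outdir ph --seed 7
mn3d run --input ph/disjoint_red.tif,ph/disjoint_green.tif,ph/disjoint_blue.tif \
         --config params.yaml --outdir results/
mn3d validate-config --config params.yaml
```

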