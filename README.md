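# wmh3d

Morphometric characterization of 3D white matter hyperintensity (WMH)
lesions in T2 FLAIR MRI, for neuroimaging researchers who have a FLAIR
volume and a co-registered binary lesion mask (e.g. an LST/LPA probability
map thresholded upstream) and want more than a total lesion volume:

* **Shape** — high-order 3D Zernike moments on the unit ball,
  `Z_nl^m = (2n+3) ∫_B f · R_nl(r) Y_l^m(θ,φ) dV`, with orthonormal real
  spherical harmonics and radial polynomials computed by stable normalized
  recursions (orders of 100–250 are routine). The per-(n,l) norms
  `‖Z_nl‖ = (Σ_m |Z_nl^m|²)^{1/2}` form a rotation-invariant shape
  descriptor; truncated reconstruction gives an error-rate control
  `ε_r = |f ⊕ f_M| / |f|`.
* **Texture** — fuzzy intensity histograms: after a 1% low-tail discard and
  min–max normalization, each voxel splits its unit mass linearly between
  the two nearest of 10 bin centers; histograms sum to 1 and are size- and
  rotation-independent.
* **Clustering** — PCA to 99.8% variance, K-means with 1000 seeded
  restarts (best dispersion kept), and gap-statistic selection of the
  cluster count (`N = 20`, `B = 30` reference sets from the bounding box).
* **Potential Growth Index** — around each lesion, 5 one-voxel dilation
  shells; a shell voxel is "growth" when its intensity is at least
  `m − 2.5σ` (99.38% one-sided Gaussian coverage of the subject's pooled
  lesion intensities), outer shells weighted more:
  `PGI = Σ_i GV_i · w_i / V_l`, `w_i = i / Σ_j j`.
* **Statistics** — one-way ANOVAs of PGI (and size) across shape/texture
  clusters with pairwise F tests and Bonferroni thresholds.
* **Synthetic phantoms** — seeded FLAIR-like volumes (ellipsoids, tori,
  sphere-union blobs) with exact ground truth for every stage, so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(wmh3d)

spec <- phantomSpec(dim = c(40, 40, 40), lesions = list(
  list(type = "ellipsoid", center = c(13, 13, 13), radii = c(4, 3, 2.5),
       growthFractions = c(1, 0.8, 0.6, 0.4, 0.2))), seed = 7)
ph <- makePhantom(spec)

lesions <- extractLesions(ph$volume, ph$mask, minVolumeMm3 = 30)
lesions[[1]]
#> Lesion3D subject/1: 119 voxels (119.0 mm^3), centroid (13.0, 13.0, 13.0)

# volume-normalize to 80 voxels, embed, order-16 shape descriptor
shape <- embedInCube(rescaleToTargetVolume(lesions[[1]], 80), 24)
zernikeDescriptor(zernikeMoments(shape, 16))
#> ZernikeDescriptor: order 16 - 81 rotation-invariant entries

fuzzyHistogram(normalizeIntensities(lesions[[1]]), 10)
#> FuzzyHistogram (lesion), 10 bins: 0.655 0.000 0.000 0.000 0.000 0.000 0.000 0.062 0.224 0.059

subjectPGI(ph$volume, lesions)[, c("lesion_id", "PGI")]
#>   lesion_id        PGI
#> 1         1 0.09215295
ph$truth$lesions[[1]]$pgi   # generator's designed value — identical
#> [1] 0.09215295
```

The lesion's 119 voxels sit in the small size group (≤ 250 voxels); its
descriptor is an 81-number rotation-invariant signature at order 16 (the
full-scale default is order 100, 2,601 numbers). The bimodal histogram
reflects the plateau-plus-falloff intensity model, and the PGI of 0.092
matches the phantom's designed growth fractions exactly because shell
membership and threshold placement are known by construction.

`runPipeline()` chains all stages for a manifest of subjects
(extract → size groups → shape descriptors → PCA → gap/K-means → texture →
PGI → ANOVAs) with full seeded determinism;
`inst/scripts/wmh3d-pipeline.R` is a thin command-line wrapper, and
`--stage simulate` writes a synthetic cohort to try it on.

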