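# crownepf

Spectral–spatial classification of UAV hyperspectral imagery with
edge-preserving filters, for extracting the crowns of pest-damaged trees.

## Who this is for, and what it does

Forest-health surveys increasingly fly snapshot hyperspectral imagers (plus
an RGB camera) over damaged stands. A pixel-wise classifier on the spectra
separates damaged crowns from soil, understory and shadow well — but its
label map is noisy and its boundaries ignore the actual crown outlines,
because mixed pixels at crown edges carry blended spectra. `crownepf`
implements the standard repair in probability space:

1. **Classify** every pixel with an SVM using the Gaussian radial-basis
   kernel
   `K(x_i, x) = exp(-‖x − x_i‖² / γ²)`
   (one-vs-one multiclass, Platt-calibrated), producing an H×W×K
   **probability stack**.
2. **Filter** each class-probability map with an edge-preserving filter
   driven by a sharper co-registered **guidance image** (resampled RGB or a
   PCA false-color composite):
   * the **joint bilateral filter** (JBF),
     `Q_i = (1/K_i) Σ_j exp(−‖i−j‖/σ_d²) · exp(−|I_i−I_j|²/σ_r²) · P_j`, and
   * the **guided filter** (GF), the per-window linear model `Q = a_k I + b_k`
     with `a_k = cov(I,P)/(σ_k² + ε)`, averaged over all windows containing
     each pixel.
3. **Fuse** by the maximum-probability criterion, **evaluate** with OA,
   Cohen's kappa, per-class producer accuracy (CADP = producer accuracy of
   the damaged class) and MSSIM, and **extract** the damaged-crown mask as
   8-connected components.

Because real campaigns over damaged stands are rarely redistributable, the
package also ships a **synthetic scene generator** (damaged-dominant stand,
shared canopy-shading speckle, continuous defoliation gradient, correlated
sensor noise, sharper guidance) so the entire pipeline runs, and is tested,
end to end with known ground truth. See the vignette
(`vignettes/spectral-spatial-classification.Rmd`) for the full methods
account.

## Worked example

```r
library(crownepf)

# synthesize a 200x200 four-class scene, classify, filter with both EPFs at
# their optimal settings (C = 20, gamma = 0.5; JBF 1/0.1; GF 1/0.1^2),
# fuse, and score on the 1250 held-out verification samples
res <- run_pipeline(pipeline_config(seed = 0))
#> synth: 200 x 200 scene, K = 4, B = 40, seed 0
#> classify: SVM G-RBF, C = 20, gamma = 0.5
#> guidance: synthetic
#> filter: jbf (sigma_d=1, sigma_r=0.1, spatial_squared=0)
#> filter: gf (r=1, epsilon=0.01)
#> svm  OA = 0.8774  Kappa = 0.8365  CADP = 0.8173
#> jbf  OA = 0.9207  Kappa = 0.8942  CADP = 0.8590
#> gf   OA = 0.9263  Kappa = 0.9017  CADP = 0.8654

print(res$evaluations$gf)
#> <evaluation_report> n = 1248
#>                        predicted
#> truth                   bare_land understory_vegetation shadow damaged_pine
#>   bare_land                   299                     1      7            5
#>   understory_vegetation         2                   294      1           15
#>   shadow                        3                     5    293           11
#>   damaged_pine                  9                    16     17          270
#> OA = 0.9263  Kappa = 0.9017  CADP(damaged_pine) = 0.8654
```

Reading the numbers: the raw SVM already classifies 87.7% of verification
pixels correctly, but the edge-preserving filters lift overall accuracy to
~92–93% and the damaged-crown recall (CADP) from 81.7% to ~86%, with the
guided filter ahead of the joint bilateral filter — the boundary pixels the
filters repair are precisely where the raw classifier errs. `res` also
carries the filtered stacks, label maps and crown-component masks;
`run_pipeline(pipeline_config(seed = 0, out_dir = "out"))` writes every
artifact (ENVI stacks and label maps, PNG guidance, CSV samples, JSON
report) to disk.

The same stages are scriptable from a shell via `inst/cli/crownepf.R`
(`synth`, `classify`, `grid-search`, `filter`, `fuse`, `evaluate`,
`extract`, `mssim`, `defoliation`, `run`).

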