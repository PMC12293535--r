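# vertebraDS

Adult age estimation from vertebral endplate surface roughness.

`vertebraDS` quantifies the cortical roughness of the antero-superior
vertebral endplate as the **DS score** — the mean nearest-point Euclidean
distance between the endplate's extracted boundary and its best-fit
ellipse:

$$\mathrm{DS} = \frac{1}{n}\sum_{i=1}^{n}\min_{q\in\partial E}\lVert p_i - q\rVert \quad [\mathrm{mm}]$$

In young adults the endplate outline is nearly elliptical; with age,
osteophytic ridges push boundary points outward and resorption pits pull
them inward, so DS rises monotonically with cumulative cortical
remodeling. A per-subject panel of 19 DS values (C7, T1–T12, L1–L5, S1)
then drives sex-stratified age regression. The package is aimed at
forensic anthropologists and radiology researchers who want an
observer-independent alternative to subjective degeneration scoring, and
at methodologists who want every stage of such a pipeline testable
without CT data.

The pipeline:

1. **Contour extraction** — Otsu thresholding, external contour tracing
   (8-connectivity, full pixel chain), removal of the straight posterior
   cut line via the modal y-row filter (τ = 2 px default), and mm
   scaling from a reference line (`imageToContour()`).
2. **Ellipse fitting and DS** — bounded Levenberg–Marquardt least
   squares on the internal parameters (x_c, y_c, log a, log b, φ) from a
   PCA initialization, with tangential, curvature and eccentricity
   (`|log(b/a)| ≤ log 3`) penalties; then exact nearest-point distances
   and their mean (`fitEllipse()`).
3. **Cohort statistics** — descriptives, Mann–Whitney sex comparisons,
   Spearman age correlations, an ANCOVA sex×metric interaction screen,
   multiple linear regression with SEE = √(Σ(y−ŷ)²/(n−k−1)) and
   collinearity diagnostics, and cross-validated LASSO (`mlrFit()`,
   `lassoFit()`).
4. **Machine learning** — single 80/20 hold-out split, 10-fold
   leakage-free tuning of SVR (RBF/linear), random forest, k-NN and a
   discretized Gaussian naive-Bayes pseudo-regressor, with bootstrap
   CIs, permutation importance, Bland–Altman limits and learning curves
   (`tuneModel()`, `evaluateModel()`).
5. **Power analysis** — Cohen's f² = R²/(1−R²), non-centrality
   λ = f²·df₂, and achieved power from the non-central F distribution
   (`powerReport()`).
6. **Synthetic phantoms and cohorts** — elliptical outlines with
   controlled radial noise, bumps/pits and an optional cut-line chord;
   cohorts with known sex-specific age–DS structure
   (`makePhantomContour()`, `makeSyntheticCohort()`).

## Worked example

A phantom with known roughness recovers its generating parameters and
noise level:

```r
library(vertebraDS)

spec <- phantomSpec(a_mm = 15, b_mm = 10, sigma_radial_mm = 0.25,
                    n_points = 400, seed = 7)
fit <- fitEllipse(makePhantomContour(spec))
fit
#> EllipseFit on 400 points (converged)
#> EllipseParams: center (0.005468, 0.01832), a = 15.02, b = 10.03, phi = 0.0005091 rad
#>   DS = 0.198618 (max point distance 0.736747)
```

The fitted semi-axes recover the generating 15 × 10 mm ellipse, and the
DS of 0.199 mm matches the expected mean absolute radial deviation of
Gaussian noise, σ·√(2/π) = 0.25·0.798 ≈ 0.199 mm. The image route —
rasterize, threshold, trace, strip the cut line, rescale — is one call:

```r
specB <- phantomSpec(a_mm = 15, b_mm = 10, sigma_radial_mm = 0.25,
                     n_points = 400, include_baseline = TRUE, seed = 7)
img <- rasterizePhantom(makePhantomContour(specB), pixel_size_mm = 0.1)
contour <- imageToContour(img, ref_len_mm = 10, ref_len_px = 100, tau_px = 2)
contour
#> Contour: 941 points [mm], open
#>   x: [-14.921, 16.179]  y: [-11.706, 8.694]
```

On the modeling side, a synthetic 176-subject cohort (94 M / 82 F, ages
21–94) with lumbar-dominant age trends reproduces the classical
benchmark chain down to the power analysis:

```r
cohort <- makeSyntheticCohort(cohortSimSpec(seed = 1))
mlr <- mlrFit(cohort, "M")
sprintf("male MLR: R2 = %.3f, adj R2 = %.3f, SEE = %.2f y",
        mlr$r2, mlr$adj_r2, mlr$see_years)
#> "male MLR: R2 = 0.708, adj R2 = 0.633, SEE = 11.98 y"

powerReport(r2 = 0.399, n = 94, k = 19)
#> PowerReport: R2 = 0.399, f2 = 0.664, df = (19, 74), lambda = 49.13
#>   critical F = 1.729 (alpha = 0.05), achieved power = 0.992
```

Here R² is the share of age variance explained by the 19 DS predictors,
SEE the residual error in years, f² the regression effect size, λ the
non-centrality of the F-test, and the achieved power the probability of
detecting an effect of the observed size at α = 0.05.

Batch processing (`runExtractBatch()`, `runDSBatch()`,
`runFullReport()`) and a thin CLI
(`inst/cli/vertebraDS.R` with subcommands `extract`, `fit`, `stats`,
`ml`, `power`, `report`, `simulate`) wrap the same functions. See
`vignettes/vertebral-roughness-methods.Rmd` for the model, its
assumptions and the numerical choices.

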