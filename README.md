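# specerror

Multivariate measurement-error analysis for replicated spectra from
miniaturized near-infrared (NIR) instruments.

Portable NIR sensors are cheap and widely used on pharmaceutical solids
(pills, tablets), but the errors in their spectra are rarely homoscedastic,
uncorrelated or normal — the assumptions most multivariate methods make.
`specerror` implements a replicate-based workflow for characterising those
errors and for judging how close common preprocessing methods (SNV,
Savitzky–Golay derivatives, MSC) bring them to the i.i.d. ideal:

1. **ASCA** (ANOVA-simultaneous component analysis) screens the
   experimental factors of a replicate design — session, replicate order,
   background timing, power supply — so the error estimation can pool over
   the right cells. The centered data matrix **X** is decomposed into
   additive effect matrices plus residuals,
   `X = X_session + X_timing + ... + X_interactions + E`, each effect
   quantified as the percentage of the total sum of squares and tested by
   permutation (default 2000 permutations, significance at p < 0.05).
   Sub-models expose PCA-style scores and loadings per effect, with
   residual-augmented scores for visualization.
2. **Error surfaces.** The error matrix is the difference between each
   spectrum and the mean of its replicate group; pooling over groups
   (e.g. sessions) gives the error covariance
   `Σcov = EᵀE / (n − g)` and its correlation `Σcor`. The diagonal of
   `Σcov` reveals heteroscedasticity, the off-diagonals channel-to-channel
   error correlation.
3. **K index and image histograms.** With eigenvalues λ₁…λₚ of `Σcor` and
   explained variances `EVₘ = λₘ / Σλ`, the redundancy index

       K = Σₘ |EVₘ − 1/p| / (2 (p − 1) / p)

   is 0 for fully uncorrelated variables and 1 under perfect correlation.
   An error matrix of rank r < p cannot reach 0: the *imbedded* minimum is
   `(p − r)/(p − 1)`, so the distance `K − K_min` measures how much
   experiment-dependent correlation a preprocessing method failed to
   remove. `Σcor` rendered as a gray-scale image (`g = (ρ + 1)/2`) is
   summarised by its histogram: an ideal unstructured error is symmetric
   around gray 0.5.
4. **Synthetic factorial generator.** A full-factorial simulator
   (multiplicative scatter, smooth session offsets, background-timing
   drift, heteroscedastic channel-correlated noise with a known
   ground-truth covariance) makes every stage testable without instrument
   data.

The data container is an S4 `SpectraSet` extending
`SummarizedExperiment`: wavelength channels as features, acquisitions as
columns, the design table in `colData`.

## Worked example

Simulate one sample measured in 3 sessions × 15 replicates × 2 background
timings with scatter-dominated noise, screen the factors, and compare
preprocessing variants by K index:

```r
library(specerror)

cfg <- simConfig(channels = 60, samples = 1, sessions = 3,
                 replicates = 15, scatterLogSd = 0.05, seed = 1)
s <- simulateSpectra(buildDesign(cfg), cfg)
s
#> SpectraSet with 90 acquisitions x 60 channels
#>   wavelengths: 972.0-1701.0 nm
#>   design factors: sample (1), session (3), replicate_order (15),
#>     background_timing (2), instrument_config (1)

dec <- ascaDecompose(s, c("session", "background_timing"))
ascaEffectTable(s, dec, nPerm = 2000, seed = 1)
#>                      effect percent pValue significant
#> 1                   session  19.179 0.0005        TRUE
#> 2         background_timing  12.958 0.0005        TRUE
#> 3 session:background_timing   0.377 0.9725       FALSE
#> 4                 residuals  67.486     NA          NA

for (v in list(raw = "none", SNV = "snv",
               deriv = list(step = "savgol", window = 7,
                            polyorder = 2, derivorder = 1))) {
  sv <- applyPreprocess(s, v)
  e <- errorMatrix(sv)                       # replicate-mean subtraction
  surf <- correlationMatrix(pooledCovariance(e))
  print(kIndex(surf@sigmaCor, rank = e@rankBound))
}
#> KIndexResult: K = 0.950 (p = 60); imbedded minimum 0.000 at rank 60 ...
#> KIndexResult: K = 0.728 (p = 60); imbedded minimum 0.000 at rank 60 ...
#> KIndexResult: K = 0.702 (p = 54); imbedded minimum 0.000 at rank 54 ...
```

Session and background timing are significant (so the error is pooled
within session × timing cells, here 6 groups of 15 — `e@rankBound` is
90 − 6 = 84, capped at the channel count), and the K ordering
raw > SNV > first derivative shows the derivative removing the most
error correlation: the expected behaviour under scatter-dominated noise.

`runWorkflow(workflowConfig(...))` chains all stages — simulate/load,
outlier screening, preprocessing variants, ASCA tables, error surfaces,
K indices, histograms — into a CSV/JSON report bundle with a manifest;
`inst/scripts/specerror-workflow.R` is a command-line wrapper driven by a
YAML config.

### File formats

Spectra are wide CSV (one header row of wavelengths in nm, one row per
acquisition, full `%.17g` precision); the design is a CSV of categorical
factor levels aligned by row order. `readSpectraCSV()` /
`writeSpectraCSV()` round-trip both exactly.

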