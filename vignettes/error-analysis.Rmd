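---
title: "Characterising multivariate measurement error in replicated NIR spectra"
author: "specerror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising multivariate measurement error in replicated NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specerror)
```

## The problem

Miniaturized NIR spectrometers make it easy to collect replicated
reflectance spectra of solid samples, but the measurement errors in those
spectra are typically heteroscedastic across wavelength channels and
correlated between channels, and their structure changes with the
acquisition conditions (analytical session, background-reference timing,
power supply) and with every preprocessing step. Most chemometric models
implicitly assume i.i.d. errors, so knowing how far a given
instrument/preprocessing combination is from that ideal — and which
experimental factors drive the departure — is a prerequisite for trusting
downstream models. `specerror` implements that error-analysis workflow on
replicated, design-annotated spectra.

## The procedure

### ASCA factor screening

For a matrix $X$ ($n$ acquisitions $\times$ $p$ channels), ASCA combines
ANOVA with simultaneous component analysis. After subtracting the grand
mean, each design factor receives the matrix of its level means, each
requested two-way interaction its cell means minus both main effects,
and the remainder is the residual matrix:

$$X_c = \sum_k X_k + E .$$

On balanced designs these matrices are mutually orthogonal, so their
squared Frobenius norms (sums of squares, SS) partition the total and the
percentage contributions sum to 100. Assumptions are the usual ANOVA ones
— additive effects, exchangeable errors within levels — plus the linearity
inherited from PCA when the effect matrices are inspected through their
SVD sub-models. Pure effect scores collapse onto one point per level, so
the package reports residual-augmented scores
($(X_k + E)\,P_k$) as the default visualization, with per-level centroids.

Significance is assessed by permutation: the tested term's labels are
freely permuted across rows (for an interaction, the two label columns are
permuted jointly), the term's SS recomputed under the same cell-mean
scheme, and $p = (\#\{SS^{perm} \ge SS^{obs}\} + 1)/(B + 1)$ with $B =
2000$ by default and significance declared at $p < 0.05$. Freely permuting
the raw labels is the simplest exchangeability-based scheme; for
interactions it is an approximation (the main effects are not removed
before permuting) and is recorded as such in the result object's `scheme`
field. Mildly unbalanced designs (e.g. after outlier removal) are handled
by the same cell-mean estimators with a warning: SS additivity is then
only approximate, and the decomposition flags itself `balanced = FALSE`.

### Replicate-based error estimation

The error matrix is each spectrum minus the mean of its replicate group.
Groups default to the sample × session × background-timing cells: ASCA
typically shows session and timing to matter, and pooling within those
cells keeps their systematic differences out of the error estimate while
still accumulating degrees of freedom across cells. Grouping is
configurable and recorded, since which factors to pool over is a judgment
the screening stage informs. Each of the $g$ groups spends one degree of
freedom on its mean, so the error matrix has rank at most $n - g$ and the
pooled covariance is

$$\Sigma_{cov} = E^\top E / (n - g),$$

the classical dof-weighted pooled estimator (for a single group it is the
ordinary sample covariance). $\Sigma_{cor}$ rescales it to correlations;
channels whose error variance falls below $10^{-12}$ times the maximum
variance are excluded and listed rather than producing 0/0 artifacts
(this arises for degenerate channels, e.g. after derivative edge
truncation of a constant region).

Because preprocessing and replicate-mean subtraction do not commute,
error matrices are always computed by re-running the pipeline on
preprocessed spectra, never by transforming a raw error matrix.

### K index, imbedded minimum, image histograms

With eigenvalues $\lambda_1 \ge \dots \ge \lambda_p$ of $\Sigma_{cor}$ and
explained variances $EV_m = \lambda_m / \sum \lambda$,

$$K = \frac{\sum_m |EV_m - 1/p|}{2(p-1)/p} \in [0, 1],$$

0 when all channels are uncorrelated and 1 under perfect correlation.
When $\Sigma_{cor}$ is estimated from an error matrix of rank $r < p$,
$K$ cannot fall below the *imbedded* minimum: by the triangle inequality
the $p - r$ zero eigenvalues contribute $(p-r)/p$ and the nonzero ones at
least as much, so $K \ge (p-r)/(p-1)$, with equality when the $r$ nonzero
explained variances are equal. `imbeddedK()` evaluates the closed form and
cross-checks it against the K formula applied to that equal-eigenvalue
spectrum ($r$ eigenvalues of $p/r$, the rest 0), requiring agreement to
$10^{-12}$. For the two studied configurations: $p = 236, r = 45 - 3 =
42$ gives 0.826, and $p = 74, r = 45$ gives 0.397. The distance
$K - K_{\min}$ is the package's headline diagnostic: small distance means
the preprocessing removed nearly all experiment-dependent correlation.
Two rank conventions circulate — pooled replicates minus group means
($n - g$) versus raw replicate count — so `kIndex()` takes the rank
explicitly and the workflow reports which value it used ($n - g$ by
default, capped at $p$ since a $p$-variable correlation matrix cannot
exceed rank $p$).

For the histograms, correlations map to gray levels $g = (\rho + 1)/2$
and are binned over $[0,1]$ (256 bins by default, the 8-bit image
convention; bins left-closed, last bin right-inclusive so $g = 1$ is
counted). The full matrix including the unit diagonal is histogrammed by
default — the diagonal spike at gray 1 is part of the image a practitioner
sees — and `includeDiagonal = FALSE` excludes it. An ideal unstructured
error yields a symmetric distribution centred at 0.5; the summary reports
mode, skewness and configurable tail masses.

## Preprocessing operators

* **SNV** centres each spectrum and scales it to unit sample standard
  deviation (the $n-1$ denominator, consistent with the covariance
  bookkeeping). Constant spectra are an error, not a silent NaN.
* **MSC** fits $x = a + b\,\mathrm{ref} + e$ per spectrum by least squares
  and returns $(x - a)/b$; the reference defaults to the mean spectrum,
  and slopes below $10^{-10}$ are an error.
* **Savitzky–Golay derivative** (default window 7, polynomial order 2,
  first derivative) uses the centred filter coefficients from the
  `signal` package. Derivatives are scaled per channel-index step — the
  common chemometrics convention, and only shapes matter downstream — with
  a `perNm` flag for per-nm scaling using the mean grid spacing. Edges are
  truncated, not padded: the $(\mathrm{window}-1)/2$ channels on each side
  leave both the matrix and the wavelength grid, which is why a
  236-channel spectrum yields 230 derivative channels.
* **Mean-centering** is applied internally by ASCA; the explicit operator
  exists for user pipelines but is not duplicated before decomposition.

Every applied step is appended to the object's metadata, so the
provenance of any downstream error surface is inspectable.

Gross-outlier screening fits a PCA to the centred matrix and flags rows
exceeding either the Hotelling-$T^2$ limit (F-distribution) or the
Q-residual limit (Jackson–Mudholkar approximation) at $1-\alpha$, with
$\alpha = 0.01$ by default and the component count chosen to reach 90%
explained variance. Flags are returned, never applied automatically:
dropping rows changes design balance, so removal is a separate explicit
step.

## The synthetic generator

`simConfig()`/`simulateSpectra()` emulate a full-factorial replicate
study. Each acquisition is

$$x_i = m_i\,(b_{s(i)} + o_{\mathrm{session}(i)} + d_i + u_i) + a_i
  + \varepsilon_i$$

with per-sample baselines $b_s$ (sums of Gaussian reflectance bands; two
darker and two brighter defaults echoing compact pills versus whitish
tablets), smooth random session offsets $o$ (low-order cosine basis),
a background drift $d$ linear in replicate order and present only at the
session-start background level (a single background reference lets the
instrument drift over the session), an optional power-supply offset $u$,
log-normal multiplicative scatter $m_i$, a Gaussian additive offset
$a_i$, and noise $\varepsilon_i \sim N(0, \Sigma)$ with

$$\Sigma = D^{1/2} R D^{1/2}, \qquad
  R = w R_{\mathrm{smooth}} + (1-w) R_{\mathrm{band}},$$

where $R_{\mathrm{band}}(i,j) = \rho^{|i-j|}$, $R_{\mathrm{smooth}}$ is a
squared-exponential correlation, and $D$ is a smooth heteroscedastic
variance profile (noise sd doubled at the detector edges). The defaults —
236 channels over 972–1701 nm, 15 replicates × 4 samples × 3 sessions ×
2 background timings (360 rows; the 74-channel, 1351–2559 nm variant with
a 2-level power-supply factor gives 720), reflectance-scale effect
magnitudes of order 0.002–0.01, noise sd 0.003, $\rho = 0.9$, $w = 0.3$ —
were chosen once as plausible for miniaturized NIR reflectance data at
replicate precision; no quantitative effect sizes are published for such
studies, so they are testability choices, not calibrated fidelity. A root
seed first draws the session curves, then a per-acquisition substream
seed, making simulations reproducible and stable under subsetting.

What the generator deliberately does *not* emulate: radiometric physics
(integrating sphere versus fiber optics appear only as different
noise/scatter magnitudes), heavy-tailed noise, moisture kinetics or any
chemistry-driven structured error. Passing tests therefore demonstrate
that the estimators recover *known* structure of this kind — not that any
particular instrument behaves this way.

## Numerical choices

* Sample standard deviations use the $n-1$ denominator throughout,
  matching the pooled-covariance dof accounting.
* Correlation-matrix eigenvalues are clipped at 0 before computing
  explained variances: exact-arithmetic correlation matrices from
  rank-deficient error matrices are PSD, so negative values are numerical
  noise. Near-singular inputs limit the achievable accuracy of the
  minimum-K inequality to about $10^{-6}$ (eigendecomposition accuracy),
  while the K summation itself agrees with a direct oracle to $10^{-12}$.
* The simulator draws noise through the symmetric PSD square root
  (eigenvalue clipping) rather than Cholesky, so noiseless and
  rank-deficient covariances are valid configurations.
* Degenerate inputs fail loudly and specifically: singleton replicate
  cells name the cell, constant spectra name the row, confounded factors
  name the pair, non-monotone wavelength headers and misaligned CSV pairs
  name the counts.

## Design decisions that were genuinely open

* **Config format.** Workflow and simulation configurations serialize as
  YAML (`readWorkflowConfig()`), a format the R ecosystem parses natively.
* **CLI.** The R functions are the primary interface;
  `inst/scripts/specerror-workflow.R` provides `simulate` and `run`
  subcommands as a thin wrapper for shell use.
* **Permutation scheme** and **unbalance handling** as described above;
  both are recorded in outputs so reports are self-describing.
* **Error grouping** defaults to every design factor except replicate
  order, the conservative choice that never lets a screened factor inflate
  the error; users narrow it after inspecting the ASCA table.

## Validation problem sizes

The test suite validates the statistical claims at deliberately compact
sizes: permutation-test calibration uses 500 null simulations of a
30 × 20 design at 200 permutations (type-I error within [0.03, 0.07] at
$\alpha = 0.05$) and a 3-point session-effect grid of 200 repeats each for
power monotonicity; covariance recovery uses 2000 simulated noise spectra
at 74 channels (≤ 10% relative Frobenius error against the ground truth);
the preprocessing K-ordering tendency (raw > SNV > first derivative under
scatter-dominated noise) is checked over 20 seeded 45 × 60 simulations.
These sizes were chosen as the smallest at which the corresponding
asymptotic statements are comfortably observable.

## Known limitations

* No shrinkage or maximum-likelihood covariance estimation: with few
  pooled replicates and many channels, $\Sigma_{cov}$ is rank-deficient by
  construction, and downstream use beyond the K/histogram summaries (e.g.
  error-covariance-weighted regression) is out of scope.
* The interaction permutation test is approximate, as noted.
* ASCA assumes additive effects; strong multiplicative factor effects
  should be handled by preprocessing before decomposition, as the
  workflow's variant structure encourages.
* K compresses the whole eigenvalue spectrum into one number; two very
  different correlation structures can share a K value, which is why the
  workflow always pairs it with the image histogram and the variance
  diagonal.
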