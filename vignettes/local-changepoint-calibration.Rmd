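---
title: "Local changepoint calibration for spectral phenotype prediction"
author: "SpectraCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local changepoint calibration for spectral phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Mid-infrared (MIR) spectroscopy of milk yields, for every sample, an
absorbance value at several hundred wavenumbers.  Partial least squares
regression (PLSR) is the standard way to relate such collinear,
high-dimensional spectra to a reference phenotype — here the milk
technological traits rennet coagulation time (RCT), curd-firming time
(k20), curd firmness at 30 and 60 minutes (a30, a60), casein micelle size
(CMS) and pH.  A *global* calibration fits one equation per target sample
(the predictand) on all remaining samples.  *Local* calibrations instead
select, per predictand, a subset of similar spectra (neighbours) and fit
only on those, on the premise that dissimilar samples add noise rather
than information — particularly for predictands at the edge of the
spectral distribution.

`SpectraCP` implements three strategies behind one benchmarking surface:

* **global** — PLSR on all other samples; the number of latent factors is
  chosen per predictand by leave-one-out (LOO) cross-validation.
* **local (LOCAL)** — the classical fixed-size approach: neighbours are
  the `k` spectra with the highest Pearson correlation to the predictand
  (grids of k = 25/50/100 with 5/10/20 fixed factors are conventional).
* **local changepoint** — the data-driven approach this package exists
  for: the neighbour count itself is chosen per predictand by changepoint
  analysis of its sorted distance profile.

## The local changepoint model

For a predictand $x_0$ and candidates $x_1, \dots, x_{n-1}$:

1. Fit a principal-component space on the spectra (standardised or not; 4
   components by default) and project all samples.
2. Compute Mahalanobis distances between scores,
   $d_i = \sqrt{\sum_k (t_{0k} - t_{ik})^2 / \lambda_k}$, where
   $\lambda_k$ is the $k$-th eigenvalue: PC scores are uncorrelated, so
   their covariance is exactly the diagonal eigenvalue matrix and no
   covariance re-estimation is needed.
3. Sort the distances increasingly and run a change-in-mean segmentation
   on the sorted vector.  A changepoint marks the index where the
   distance level shifts — the boundary between "similar" and
   "dissimilar" candidates.
4. The neighbour count is the **first changepoint of at least 20**; the
   floor guarantees the subsequent LOO factor search has data to work
   with.  If no changepoint qualifies, the selection falls back to all
   candidates (with a warning): a flat profile means there is no local
   structure to exploit, and the global benchmark is then the natural
   model.
5. Fit PLSR on the selected neighbours, with LOO-CV factor selection
   capped at $\min(20, k - 2)$, and predict the predictand's trait.

The predictand's own trait value never enters any model that predicts it;
this is asserted by instrumentation in the test suite.

## Changepoint engine

Both AMOC (at most one change) and PELT (pruned exact linear time,
multiple changes) are implemented for the Gaussian change-in-mean model.
Conventions, fixed once and documented rather than tuned:

* Segment cost $C(s,t) = \sum_{i=s}^{t} (y_i - \bar y_{s:t})^2 / \sigma^2$
  (twice the negative profile log-likelihood up to constants).
* Penalties: SIC $\beta = 2\log n$ (one mean plus one location parameter
  per changepoint); MBIC $\beta = 3\log n$ plus an additive
  $\log(\text{segment length})$ term per segment, after the
  Zhang–Siegmund refinement.
* Noise variance $\sigma^2$: the default is the first-difference
  estimator $\widehat{\mathrm{Var}}(y_{i+1}-y_i)/2$, which is robust to
  the very mean shifts being sought; `fixed_one` (common package default)
  and a global MLE are available.  A near-zero estimate is floored at
  machine-epsilon scale.
* Minimum segment length 2, so every segment mean (and the MBIC
  log-length term) is well defined.
* Ties in the dynamic programme break toward the smaller index.
* PELT pruning is exactness-safe: under MBIC the log-length term is not
  superadditive, so the pruning test keeps a $\log n$ slack; the result
  is always identical to exhaustive optimal partitioning (verified
  against a no-pruning dynamic programme on hundreds of random vectors).

AMOC is kept for completeness; on sorted distance vectors it tends to
place its single split far into the tail and therefore selects very many
neighbours, which is why PELT is the default.

## PLS conventions

Single-response NIPALS (orthogonal scores) on centred predictors and
response.  Predictors are *not* scaled inside the regression —
standardisation, where requested, belongs to the neighbour-selection
geometry only.  With factors equal to the predictor rank, predictions
coincide with least squares; the implementation is verified against an
established PLS implementation to $10^{-6}$ relative error.

LOO-CV factor selection refits on every fold and picks the RMSECV
argmin, ties to the fewest factors.  For the global benchmark this is a
nested LOO (per predictand, per fold), which is quadratic in $n$; the
benchmark therefore uses an exact pair-deleted formulation: the PLS1
coefficient after $a$ factors is the Galerkin solution on the Krylov
space $\mathrm{span}\{s, Ms, \dots, M^{a-1}s\}$ with $M = X_c'X_c$ and
$s = X_c'y_c$, so each fold's $M$ is a rank-two downdate of one
precomputed Gram matrix and each unordered pair of held-out samples
shares one fit.  The batched path is asserted equal (to $10^{-8}$) to
the naive fit-per-fold route in the tests.  When $p > n$ the predictors
are first rotated onto an orthonormal basis of their row space, which
leaves PLS predictions unchanged.

## Editing pipeline

`editSpectra()` applies, in this fixed order: animal-level deduplication
(keep the record with the greatest Mahalanobis distance from the centre
of the dataset-wide PC space, maximising retained variability), removal
of high-noise wavenumber windows (defaults 1580–1710, 2990–3690 and
> 3822 cm$^{-1}$; closed intervals, the last open at its lower end),
transmittance-to-absorbance transform $A = \log_{10}(1/T)$, then per-trait
outlier removal (beyond 3 SD from the trait mean, computed once on the
pre-filter values in a single pass) and completeness filtering.  Counts
are logged per stage.  The deduplication PC space uses standardised
spectra and 4 components by default; whether to standardise there is
genuinely open, so a flag exposes the choice.

## Synthetic data

No reference milk dataset is distributed, so the generator emulates one:
Beer–Lambert-style linear mixing of five latent component profiles (sums
of Gaussian peaks on a 531-point retained-region wavenumber grid), a
smooth low-order baseline (SDs 0.005/0.005/0.002 absorbance units —
small relative to component signals, as baseline drift is in practice),
and i.i.d. noise (SD 0.002).  Traits are linear in the latent
concentrations plus noise of equal SD (giving accuracies in the range
typical of milk technological traits), affinely rescaled to realistic
milk moments (e.g. RCT 17.24 ± 6.61 min, pH 6.66 ± 0.09).

Heterogeneous regimes draw log-concentrations from cluster-specific
means placed symmetrically along the leading latent axes, so the
between-cluster direction carries dominant spectral variance and
survives into the leading PCs.  With `clusterSpecificTraits = TRUE` the
first trait becomes a pure cluster-by-composition interaction (its
loadings flip sign between clusters and act on centred concentrations):
no single linear calibration can represent it, while a within-cluster
one can — the regime in which locality genuinely helps.

The planted neighbour fixture places a tight core (spread
`separation/150`) inside a diffuse background *shell* at radius
`separation` (10 % radial jitter) in a 4-dimensional latent space mapped
to spectra through orthonormalised smooth profiles, so the latent
geometry carries over exactly.  From a core predictand the sorted
distance vector is flat over the core segment and jumps at the group
boundary; the core also sits at the centre of the overall PC space while
the shell forms its edge, which is what makes the edge-versus-centre
neighbour-count ordering testable.  The shell construction (rather than
a displaced Gaussian cloud) is deliberate: a second Gaussian cloud would
drift into the gap and blur the planted boundary.

What the generator does **not** emulate: instrument-specific noise
spectra, water-vapour interference, wavelength drift, non-linear
detector response, or repeated-measures correlation beyond simple
duplicate records.  Passing tests on synthetic data therefore
demonstrate correctness of the machinery and the qualitative
global-versus-local behaviour, not expected accuracy on any real
dataset.

## Problem sizes and numerical choices

The benchmark tests run at n = 300 samples × 120 wavelengths × 6 traits
× 10 seeds per regime — large enough for the nested-LOO global benchmark
to be meaningfully compared with the local approaches, small enough to
run routinely.  Oracle-equivalence checks use 200 random vectors of
length ≤ 50 (changepoints) and 50 random problems (PLS).  Edge subsets
round half away from zero (5 % of 348 samples is a subset of 17);
ties at any cut break by sample-id order, so every result is
deterministic and CLI runs with the same seed are byte-identical.

Two whitening facts discovered during design are worth recording.
First, Mahalanobis distance on PC scores divides each component by its
eigenvalue, so a two-cluster structure — however separated in raw
units — has whitened between-centroid distance bounded near 2 for
balanced clusters; neighbour sets near cluster boundaries can therefore
contain a few cross-cluster members even for dramatic separations.  The
package's cluster benchmarks measure what matters (prediction error),
not perfect membership purity.  Second, per-wavelength standardisation
can *mask* cluster structure by flattening the dominant direction;
separability assertions on synthetic data use the unstandardised
geometry, and both options are exposed throughout, as the choice
genuinely changes which neighbours are selected.

## Limitations

* The changepoint penalty constants are a documented convention; other
  conventions (e.g. different SIC parameter counts) shift neighbour
  counts moderately.
* The LOCAL grid uses fixed factor counts by design; no inner CV is run
  for it, so its results depend on the grid being sensible for the data.
* `pc_fit_scope = "full_dataset"` mirrors the single global PC space of
  the method as described (the predictand contributes to the geometry,
  though never to the regression targets); `"exclude_predictand"` gives
  strictly leakage-free geometry at extra cost.
* Nested-LOO global benchmarking is exact but quadratic in n; for
  datasets much beyond a thousand samples, k-fold inner CV would be the
  practical substitute (not implemented).
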