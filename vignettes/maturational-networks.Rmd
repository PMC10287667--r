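---
title: "Maturational networks: estimating resting-state networks from age-related change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maturational networks: estimating resting-state networks from age-related change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(matnets)
```

## The problem

Group-level network analysis of resting-state fMRI usually assumes that a
functional network has a canonical spatial layout shared across subjects:
group ICA factorises the group-average correlation structure, and per-subject
deviations are treated as noise around that canon. In a rapidly developing
cohort — fetal imaging is the extreme case — that assumption inverts the
object of interest. Connectivity is *emerging*: the informative signal is the
age-related change in voxel-pair correlations, not their cross-sectional
average, and the average itself is dominated by artefactual short-range
structure (motion and effective-resolution smearing) that swamps long-range
organisation.

This package implements the maturational-network ("matnet") reading: networks
are defined by the similarity of voxels' *age-related changes* in
connectivity. Where temporal correlation determines a voxel's membership in a
group-ICA component, the similarity of its emerging-connectivity profile
determines its matnet membership.

## The model

For each of K subjects, the dense connectome is the N x N matrix of Pearson
correlations between all in-mask voxel timecourses
(`denseConnectome()`). Each element is then regressed across subjects on the
two-parameter design [1, age]:

r_ij^(s) = beta0_ij + beta_ij * age_s + e_ij^(s)

and summarised as t_ij = beta_ij / se(beta_ij) with df = K - 2
(`fitAgeEffect()`). The t matrix — the maturational dense connectome — is
thresholded at zero (`thresholdPositive()`), keeping only age-related
*increases*, then reduced by incremental block SVD (`incrementalBlockSVD()`,
the same engine used for temporal concatenation in the group-ICA reference
pipeline) and factorised by fixed-point spatial ICA with the logcosh
contrast (`spatialIca()`). The M resulting z-scored maps are the matnets.

Downstream, each matnet's *complementary map* is the row of slope
coefficients from regressing the matnet maps against every column of the
thresholded t matrix (`connectivityProfiles()`): the territory towards which
that network's connectivity grows. Correlations between complementary maps
form the maturational connectome (`maturationalConnectome()`), which is
embedded in 3 dimensions via the spectrum of the symmetric normalised graph
Laplacian (`laplacianEmbedding()`), grouped by Ward clustering with a
finest-no-singleton rule (`wardPartition()`), and summarised per group by the
first principal component of the group's complementary maps — the
maturational hubs (`hubMaps()`). Per-subject coupling between a matnet and
its complementary map, tracked against age with a BIC-selected polynomial,
gives coupling trajectories (`couplingTrajectory()`).

The reference pipeline (`groupIca()`, `dualRegression()`,
`massUnivariateAge()`, `mapAgeEffectBias()`) and the univariate diagnostics
(`seedToBrain()`, `homologousConnectivity()`, `distanceSimilarity()`,
`fdGlobal()`) reproduce the standard analyses the matnet approach is
compared against.

## Parameters that matter

- **M, number of components** (default 25): fixed by precedent for real
  cohorts; no automatic model-order selection is attempted. Toy analyses use
  the number of planted networks.
- **Reduction rank R** (default 500, capped at N/4 on small grids): the rank
  retained by the incremental SVD. Retained rows are weighted by their
  singular values so subsequent reductions see correctly scaled variance; an
  unweighted variant exists (`weighted = FALSE`) but sacrifices variance
  fidelity.
- **Block count** (default 200): purely a memory/accuracy trade-off; block
  order is the natural column order and is deterministic.
- **ICA settings**: tolerance 1e-6, at most 1000 fixed-point iterations, 5
  random restarts, seed from the caller. Maps are z-scored (plain mean/sd
  over the mask — no mixture-model calibration), sign-fixed to non-negative
  skewness, and ordered by explained variance.
- **Age regression**: raw correlations are regressed by default; a
  `fisher = TRUE` flag enables variance-stabilised `atanh(r)` fitting, with
  the caveat that the slope's units change. Framewise displacement is
  deliberately *not* a covariate in the default model: the FD principal
  component (`fdGlobal()`) is provided so its collinearity with age can be
  examined, which is the analysis that justifies the omission.
- **Laplacian affinity**: the similarity graph uses the positive part of the
  profile correlations (negatives are weak or absent in practice); a
  `(1 + r) / 2` alternative is available (`affinity = "shifted"`) for small
  noisy connectomes where the positive part may disconnect.
- **Coupling trajectories**: both maps are thresholded at z > 5 to reduce
  spatial overlap; "best-fitting polynomial" is made concrete as BIC
  selection over orders {1, 2, 3}; the confidence band is the pointwise OLS
  band at alpha = 0.05.

## The synthetic cohort generator

Real fetal cohorts are not available at desk scale, so every stage is
validated against `generateCohort()`, which emulates the statistical
structure the method assumes — latent-first: P spatial networks with
per-subject network timecourses drawn from a latent covariance
Sigma(age) = baseline + slope * (age - 25), projected to voxels, plus noise.

Defaults (chosen once, as study conditions, and not revisited):

- grid 16 x 16 x 12 at 2.2 mm, ellipsoidal mask (N = 1608), bilateral
  mirror-symmetric Gaussian blob networks with pairwise-disjoint supports
  (a planted "static" network must not share territory with an emerging
  one, or it is not static as planted);
- P = 5 networks; couplings on edges (1,2) and (3,4) grow by 0.045/week from
  0 at 25 weeks to ~0.6 at 38 weeks; network 5 has no coupling change;
  positive definiteness of Sigma(age) is checked over the sampled age range;
- T = 350 volumes per subject, a typical fetal resting-state acquisition
  length; noise sd 0.5 against blob peak amplitude 1;
- noise is spatially smeared with a Gaussian kernel whose FWHM falls
  linearly from 6 mm at 25 weeks to 3 mm at 38 weeks, emulating the
  common-space smearing of smaller, younger brains (the period spans a
  roughly 3-fold volume growth). Smoothed noise is renormalised by its exact
  per-voxel standard deviation, so smearing alters only autocorrelation,
  never marginal variance — the planted age effect is purely the
  resolution mechanism. A `smearSignal` switch additionally smears the
  network maps themselves (peak-preserving), which is what produces the
  dual-regression bias phenomenon;
- an optional motion factor with target corr(age, motion) = -0.25 drives
  one-factor motion traces (6 parameters x 16 stacks) for the FD analyses.

What the generator does *not* emulate: haemodynamics, physiological noise
spectra, scanner artefacts, registration error beyond isotropic smearing,
and multi-timecourse (non-rank-1) network dynamics. Passing tests therefore
show that the algorithms do what they claim under the assumed generative
structure, not that real fetal data satisfy that structure.

## Numerical choices and degenerate inputs

- Voxel order is lexicographic on the (x, y, z) lattice index, fixed by the
  mask and identical across subjects; every N-length vector in the package
  uses it.
- Zero-variance voxels are flagged and their connectome rows zeroed, never
  dropped, so indices stay aligned.
- Elements with zero residual variance in the age regression get a +/-Inf
  sentinel; they are excluded (zeroed, with a warning) before factorisation.
  Constancy and perfect fits are distinguished by relative tolerances
  (1e-14 on the variance scale, 1e-12 on the residual scale) rather than
  exact zero tests, which floating accumulation would break.
- The age regression streams sufficient statistics (three N x N
  accumulators), so memory is independent of K and the result is exactly the
  per-element OLS fit.
- Embedding eigenvalues below 1e-10 are treated as the zero mode; the
  coordinates are plain eigenvectors (no eigenvalue scaling by default — a
  `scaleByEigenvalues` option exists), for the three smallest strictly
  positive eigenvalues in ascending order.
- Ward linkage uses the proper Ward criterion on Euclidean distances
  (`ward.D2`); ties and duplicate coordinates are legal.
- Hub PCA treats maps as observations (rows), centring across maps, so the
  first right singular vector is itself an N-length map; its sign is aligned
  to the group-mean map.
- Connected components for seed clusters use 26-connectivity on the lattice.
- Parcellation uses seeded k-means on voxel mm-coordinates with multiple
  starts; empty parcels trigger a reseeded re-run before erroring.

## Design choices where the design was open

- **"Thresholded at 0"** is read as clamping negatives to zero, keeping the
  dense shape, rather than deleting entries — factorisation then needs no
  sparse bookkeeping and the idempotence of the operation is trivial.
- **Profile regression** includes an intercept and demeans the map
  regressors, so slopes are covariance-scaled and an all-zero connectome
  column yields all-zero slopes.
- **Dense-matrix persistence** uses serialised R objects carrying a mask
  fingerprint, K and df, verified on load, so a factorisation cannot silently
  run against the wrong mask.
- **Dual regression** variance-normalises stage-1 timecourses before stage 2
  and the group pipeline variance-normalises voxel timecourses before
  concatenation; both are flags, and the exact-recovery contracts hold with
  the flags off (with zero noise, variance normalisation necessarily
  flattens within-map amplitude structure to a support indicator).
- **Mirror pairing** is taken from the mask (reflection about the first-axis
  mid-plane); template symmetrisation itself is out of scope.

## Known limitations

- Dual regression on pure noise reproduces the group maps themselves (the
  stage-2 population coefficients equal the map design); subject-map
  "recovery" alone is therefore not evidence of subject-level signal. The
  package's bias diagnostic is built on age-*dependence*, which this
  constant reproduction does not generate.
- At desk-scale K, chance correlations between age and a network's realised
  in-sample coupling can survive positive thresholding as a weak rank-one
  block on that network's territory. With the default conditions (K = 60,
  T = 350) the static network's best-matched |r| stays well below the
  emerging networks' (~0.95), but it fluctuates with the realisation — an
  intrinsic finite-sample property of cross-sectional maturational
  regression, worth remembering when interpreting weak matnets in real
  cohorts.
- Problem sizes in the tests and the acceptance script (N ~ 1.6k voxels,
  K = 40-144, reduction ranks 20-100) are chosen so the full suite runs in
  minutes on one CPU; they are three orders of magnitude below a real
  voxelwise analysis, which changes none of the algebra but all of the
  engineering (a real run should stream connectomes from disk via
  `fitAgeEffect()`'s function interface).
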