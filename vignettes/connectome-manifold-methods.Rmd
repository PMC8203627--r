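---
title: "Methods: gradient manifolds, phenotype association, and spatial decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient manifolds, phenotype association, and spatial decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connectomeManifold)
```

# Overview

`connectomeManifold` implements a complete analysis chain for relating
inter-individual variation in a continuous phenotype (the motivating
case is body mass index, BMI, in kg/m^2) to the macroscale organisation
of functional connectomes:

1. **Connectome construction** — Pearson correlation of parcel time
   series, Fisher r-to-z, row-wise density thresholding.
2. **Manifold estimation** — normalized-angle affinity, diffusion map
   embedding, Procrustes alignment of individual embeddings to a group
   template.
3. **Summary measures** — manifold eccentricity; within-module degree,
   participation coefficient, Louvain communities, centralities.
4. **Inference** — parcel-wise Hotelling T^2 for a single design term
   across the gradient coordinates, BH-FDR; partial-correlation
   permutation tests; spherical-rotation (spin) spatial nulls.
5. **Transcriptomic decoding** — per-donor gene-map correlations,
   spin-null and donor-consistency filtering, hypergeometric gene-set
   and cell-type (pSI) enrichment.
6. **Synthetic cohorts** — a generator that plants a known
   connectivity-phenotype coupling so every claim above is testable.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical conventions, and the design decisions
taken where more than one reasonable choice existed.

# The embedding model

For an affinity matrix $A$ (symmetric, nonnegative, unit diagonal) the
diffusion map uses the $\alpha$-normalised kernel
$W = D^{-\alpha} A D^{-\alpha}$ with $D = \mathrm{diag}(A\mathbf{1})$,
and the Markov operator $P = D_W^{-1} W$. Eigenvectors are computed
from the symmetric conjugate $S = D_W^{-1/2} W D_W^{-1/2}$ (stable
symmetric solver) and mapped back by $u = D_W^{-1/2} v$. The leading
eigenvector of $P$ is constant (eigenvalue 1) and is discarded; a
second eigenvalue within $10^{-8}$ of 1 indicates a disconnected
affinity graph and raises an error rather than returning a meaningless
embedding.

**Parameters.** $\alpha = 0.5$ (default) discounts sampling density,
approximating Laplace–Beltrami geometry; $t$ scales the spectrum. The
default $t = 0$ selects the *multiscale* convention, scaling component
$i$ by $\lambda_i / (1 - \lambda_i)$ — the documented behaviour of the
gradient-analysis tools this package interoperates with — rather than
$\lambda_i^0 = 1$; any $t \neq 0$ uses plain $\lambda_i^t$ scaling.
Connection density defaults to 0.10 (each parcel keeps its top 10% of
connections); sensitivity sweeps use 0.05–0.20.

**Determinism.** Eigenvector sign is arbitrary, so each template column
is flipped to make its largest-magnitude entry positive; subject
embeddings inherit orientation through alignment. With this pinning,
repeated runs are bit-identical, which the test suite asserts on
artifact digests.

**Variance explained** is reported as
$\lambda_i / \sum_j \lambda_j$ over all nontrivial nonnegative
eigenvalues of the computed spectrum. Other denominator conventions
(e.g. only the reported components) exist; this one is recorded in
every embedding sidecar so the convention travels with the number.

**Alignment.** Ten components are computed internally and three (E1–E3)
are reported. Orthogonal Procrustes (SVD solution, reflections allowed,
no centering, no scaling) is solved in the full ten-dimensional space
and the aligned E1–E3 are then extracted. Aligning only the reported
three was found to leak global eigenvalue-scaling variation into
parcels far from any true effect; the full-space rotation absorbs it.
Alignment is single-pass against a fixed template (no generalized
Procrustes iteration), since the template is estimated once from the
group-average connectome.

# Thresholding conventions

Row-wise retention keeps the $k = \lceil d (n-1) \rceil$ largest
*signed* entries per row (so strong negative correlations are
effectively dropped at typical densities), zeroes the rest, and keeps
all values tied with the cutoff — deterministic without ordering
assumptions. Thresholding operates on the z-valued matrix; because
atanh is monotone the ranking is identical to thresholding r. In an
already-thresholded matrix, exact zeros are treated as removed edges
when re-ranking, which makes the operation idempotent at a fixed
density. Fisher z is clipped at $|r| = 1 - 10^{-7}$ so degenerate
(duplicate-series) inputs stay finite.

# Inference

**Hotelling GLM.** Per parcel, the multivariate linear model
$Y = Xb + E$ is fitted by least squares with $Y$ the $n \times k$
matrix of aligned gradient coordinates ($k = 3$ by default) and $X$ the
design (intercept, age in years, sex as 0/1, BMI in kg/m^2,
optional confounds; regional structural indices may be appended
per parcel). For a single tested column all classical MANOVA statistics
coincide, and $T^2$ converts exactly to
$F = T^2 (n - p - k + 1) / (k (n - p))$ with $(k, n - p - k + 1)$
degrees of freedom; for $k = 1$ this is the squared t statistic. BMI
enters untransformed and covariates are not standardised (the statistic
is scale-invariant). Noise-free degenerate fits (zero residual
covariance) return statistic 0 when the coefficient is zero, infinity
otherwise. p-values are BH-adjusted across parcels; flags are
`q < 0.05` by default.

**Permutation tests** residualise both variables on the nuisance
design and permute the residualised response (Freedman–Lane), which
preserves the covariate structure; the add-one rule
$p = (1 + \#\{|r_0| \ge |r|\}) / (n_{perm} + 1)$ keeps p-values
strictly positive. Default 5000 permutations.

**Spin nulls** draw uniform random 3D rotations (QR of a Gaussian
matrix, sign-corrected into SO(3)), rotate the parcel centroids, and
reassign each parcel the value of the nearest rotated centroid
(duplicates allowed). One rotation per null map; the synthetic atlas is
a single sphere, so no hemisphere mirroring is involved. Default 100
rotations, giving a minimal attainable p of 1/101.

**Graph metrics** operate on the symmetrised
($\max(W, W^\top)$) thresholded matrix with negative weights zeroed.
Within-module degree uses the population-SD z-score (modules with zero
variance, including singletons, map to z = 0); the participation
coefficient is $1 - \sum_m (\kappa_{pm}/\kappa_p)^2$ with isolated
nodes set to 0. Louvain runs 100 seeded restarts at resolution 1.0 and
keeps the maximum-modularity partition. Betweenness uses edge lengths
$1/w$ normalised by $(n-1)(n-2)/2$; eigenvector centrality is the
nonnegative unit-norm principal eigenvector.

# Transcriptomic decoding

The gene–map association is a deliberate simplification of a donor
mixed-effect model: per-donor Pearson correlations between a gene's
parcel profile and the statistic map are Fisher-z transformed, averaged
across donors (back-transformed for reporting), and tested with a
one-sample t across donors. Genes constant within a donor are skipped
for that donor. The spin filter recomputes these statistics against
rotated maps and BH-filters the candidate genes (by default those
passing parametric FDR); the consistency filter requires a positive
mean pairwise donor–donor profile correlation (one-sample one-sided t
across the $\binom{d}{2}$ pairs; with exactly one pair a normal test on
the single z-value with variance $1/(n_{parcels} - 3)$ substitutes).
Enrichment uses the one-sided hypergeometric tail via `phyper`, with a
normal-approximation z-score reported alongside, since the exact
"z-score modification" used by external cell-type enrichment services
is not published; the nested pSI thresholds (0.05, 0.01, 0.001,
0.0001) mirror that ecosystem's ring structure.

# The synthetic cohort generator

Each module $m$ tracks a global latent factor with squared loading
`baseCoupling` (0.3); the affected modules (default: the first two)
additionally share a private factor with subject-specific squared
loading
$$ w_s = \mathrm{affectedCoupling} - \beta \, z(\mathrm{BMI}_s), $$
clipped at 0 with a warning. Parcel signals are their module latent
plus white noise (`noiseSd = 1`). Higher BMI therefore yields weaker
coupling between the affected modules — greater segregation — while
every correlation involving unaffected modules is constant in
expectation, so the planted effect is spatially specific and lives in
connectivity, the quantity the pipeline measures. BMI is log-normal
with moments matched to mean 26.3, SD 5.16 kg/m^2 (positive support and
right skew consistent with adult cohorts); age is uniform on 22–36
years; sex is Bernoulli(0.55). Atlas centroids form a deterministic
Fibonacci lattice on the sphere; modules are balanced contiguous
latitude bands and each module carries one of four hierarchy levels.

**Effect-size calibration.** The default $\beta = 0.13$ was fixed once
by calibration at the package's standard validation conditions (150
subjects, 100 parcels, 7 modules, 200 timepoints): it is the value at
which the median, over affected parcels, of the partial canonical
correlation between standardised BMI and the parcel's aligned E1–E3 is
approximately 0.5 — a moderate standardized multivariate effect. At
that operating point the pipeline flags essentially all affected
parcels at FDR < 0.05 with a false-positive rate near zero among
unaffected parcels.

**What the generator does not emulate:** fMRI autocorrelation, scanner
drift and physiological noise, head motion, hemispheric structure,
geodesic (rather than modular) connectivity gradients, and spatial
smoothness within modules. Passing tests therefore demonstrate the
statistical machinery under the stated generative model, not
performance on real neuroimaging data.

# Problem sizes and numerical checks

The test suite validates eigenpairs against a dense symmetric solver
(up to 20 nodes, tolerance $10^{-8}$), the hypergeometric p against
exhaustive `choose()` summation (universes up to 60, all set/overlap
configurations), closed-form kernel and participation values, and
Hotelling/permutation type-I error on null cohorts of 60 subjects, 100
parcels and 200 timepoints (200 Monte-Carlo parcel replicates; nominal
5% within [3.5%, 6.5%]). End-to-end recovery and decoding checks use
150 subjects and the panel configuration 200 genes / 20 signal genes /
4 donors / 100 rotations. These sizes were chosen as the smallest that
make the Monte-Carlo bands meaningful.

# Known limitations

- **Component ordering.** Which contrasts occupy E1–E3 depends on the
  eigenvalue ranking; in small cohorts or short scans the planted
  contrast can fall below the reported components, abruptly reducing
  sensitivity. The per-component variance explained in every embedding
  sidecar is the diagnostic to check.
- **Azimuthally symmetric maps.** Module labels are latitude bands, so
  module-driven statistic maps are nearly invariant to rotations about
  the polar axis, inflating spin-null correlations for such maps.
  Decoding validation therefore uses spatially rough target maps.
- **FDR flags at `q <` threshold.** Rejection uses a strict
  inequality; ties exactly at the threshold are not rejected.
- The mixed-effect decoding model and the exact cell-type-enrichment
  z-modification are approximated as documented above, not
  reconstructed.
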