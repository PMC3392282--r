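---
title: "Eigenvector-plot geometry of admixed populations"
author: "admixPCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector-plot geometry of admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixPCA)
```

## The model

admixPCA works in the *individuals-as-features* orientation of PCA for
population structure: the sampled individuals are the features and the
genotyped markers are treated as exchangeable random realizations. For a
random marker, the variant-allele count $x_{ki} \in \{0,1,2\}$ of individual
$i$ from population $k$ is random through two mechanisms: the marker's
allele frequency vector $(p_1,\dots,p_K)$ is random across markers, and the
genotype is binomial with two draws given the frequency (Hardy–Weinberg
equilibrium). Because the individuals are fixed features, the second moments
of the counts are population-level parameters that can be written down *a
priori*:

* $\sigma_k^2 = \mathrm{Var}(x_{ki})$ — the count variance,
* $\sigma_{kk} = \mathrm{Cov}(x_{ki}, x_{kj})$, $i \ne j$ — the
  within-population covariance,
* $\sigma_{kl} = \mathrm{Cov}(x_{ki}, x_{lj})$, $k \ne l$ — the
  between-population covariance.

Conditioning on the frequency vector with means $\mu_k$ and
variance–covariance matrix $C = (c_{kl})$ gives the exact moment map
implemented by `alleleCountMoments()`:

$$\sigma_k^2 = 2\mu_k(1-\mu_k) + 2c_{kk}, \qquad
  \sigma_{kk} = 4c_{kk}, \qquad \sigma_{kl} = 4c_{kl}.$$

The term $d_k = \sigma_k^2 - \sigma_{kk} = 2\mu_k(1-\mu_k) - 2c_{kk} \ge 0$
is the *diagonal excess*: the binomial genotype-sampling noise of a single
individual on top of the shared frequency signal.

## Admixture at the frequency level

An admixed population $A$ with parents $1,\dots,k$ and proportions
$\lambda_i$ ($\sum_i \lambda_i = 1$) has marker frequency
$p_A = \sum_i \lambda_i p_i$. All of its second moments are therefore linear
(or bilinear) in $\lambda$:

$$\mu_A = \textstyle\sum_i \lambda_i \mu_i, \quad
  \mathrm{Cov}(p_A, p_X) = \textstyle\sum_i \lambda_i c_{iX}, \quad
  \mathrm{Cov}(p_A, p_B) = \textstyle\sum_{ij} \lambda_i \eta_j c_{ij}, \quad
  \mathrm{Var}(p_A) = \textstyle\sum_{ij} \lambda_i \lambda_j c_{ij},$$

covering covariances with any population unrelated to the admixture and
with a second admixed population with proportions $\eta$.
`extendWithAdmixture()` implements this as one weight-matrix conjugation,
$C \mapsto W C_0 W'$, which also makes the *sum rule* immediate: the
$\sigma$-row of an admixed population is the $\lambda$-weighted combination
of its parents' rows, for every column. Only single-level admixture is
supported (parents must be non-admixed); nothing in the geometry below
needs deeper pedigrees, and multi-level mixtures can always be rewritten as
single-level ones over the base populations.

## The reduced eigenequation

The $N \times N$ covariance matrix of the grand-mean-adjusted counts is
block-structured: it is constant within population blocks except on the
diagonal. Its eigenvectors therefore split into block-constant ones —
which carry all the between-population structure — and within-block
contrasts. The block-constant eigenpairs solve a $K \times K$ *reduced
eigenequation*, built by `buildReducedExact()`:

$$A_{kl} = n_l\left[\sigma_{kl} - \bar{s}_k - \bar{s}_l + \bar{s}
  - \frac{d_k + d_l}{N} + \frac{\bar{d}}{N}\right] + \delta_{kl} d_k,$$

with $\bar{s}_k = \sum_m f_m \sigma_{km}$ (diagonal $\sigma_{kk}$),
$\bar{s} = \sum_{m,m'} f_m f_{m'} \sigma_{mm'}$, $f_m = n_m / N$ and
$\bar{d} = \sum_m f_m d_m$. Three exact properties pin this operator down
and are enforced in the test suite:

1. $A \mathbf{1} = 0$: the constant vector is an exact null eigenvector
   (the *trivial* eigenvector created by the mean adjustment).
2. The trace of $A$ equals the sum of all $K$ reduced eigenvalues.
3. For any parameter set, the eigenpairs of $A$ coincide with the
   block-constant eigenpairs of the explicitly assembled $N \times N$
   covariance (`fullCovarianceOracle()`, kept to $N \le 500$).

`buildReducedAsymptotic()` drops the $d$-terms and rescales per individual,
$A^\infty_{kl} = f_l(\sigma_{kl} - \bar{s}_k - \bar{s}_l + \bar{s})$: the
large-sample limit in which eigenvalues of the exact operator approach $N$
times the asymptotic ones. The asymptotic operator inherits the sum rule
exactly, which yields two structural theorems used as diagnostics:

* **Rank law.** Adding an admixed population whose parents are present does
  not increase the number of non-zero eigenvalues — admixture adds no axis
  of variation.
* **Convex-combination law.** On every structural eigenvector, the admixed
  population's coordinate is the $\lambda$-weighted combination of its
  parents' coordinates. This is exact for the asymptotic operator and holds
  to $O(d/N)$ for the exact one, because $d_A$ is not linear in $\lambda$;
  at the sample sizes of the worked example the discrepancy is below the
  printed 2-decimal resolution.

`solveReduced()` symmetrizes the operator by the similarity
$B = W^{1/2}[\cdot]W^{1/2} + \mathrm{diag}(d)$ (weights $n$ or $f$), so
eigenvalues are real by construction; eigenvectors are reported with unit
Euclidean norm over the $K$ population coordinates — the normalization that
reproduces the published worked example, where the trivial vector at $K=4$
prints as $0.50$ per component — sorted by descending eigenvalue, with the
sign fixed so the highest-index coordinate of magnitude above $10^{-6}$ is
positive. Near-zero negative eigenvalues are reported as computed.

## Geometry of the eigenvector-plot and proportion estimation

Because of the convex-combination law, an admixed population sits at the
$\lambda$-weighted average of its parents' positions in the plot spanned by
the structural eigenvectors:

* two parents — on the segment joining them, dividing it as
  $\lambda : (1-\lambda)$ (`segmentRatio()`);
* three parents — inside their triangle, dividing it into three
  sub-triangles whose areas are proportional to the $\lambda_i$
  (`triangleAreaProportions()`, signed areas so the estimate extends
  continuously outside the triangle);
* $k$ parents — barycentric coordinates with respect to the parental
  simplex, solved from the affine system $[P; \mathbf{1}']\lambda =
  [q; 1]$ (`barycentricProportions()`; the determinant-ratio form of the
  general solution equals this solve).

Real queries never lie exactly on the parental affine hull, so every
estimator first projects the query orthogonally onto the hull and reports
the orthogonal distance — absolutely and relative to the largest pairwise
parental distance — as the admixture diagnostic (`affineResidual()`). No
hard residual threshold is applied, and proportions are deliberately *not*
clipped to $[0,1]$: slightly negative values are informative scatter, and
`insideHull` flags them. All three routes agree to machine precision on
their common domains, and the proportions are invariant under any joint
invertible affine transformation of the plot — which is why the estimates
are insensitive to axis scaling, sign conventions and rotations of the PCA.

`individualProportions()` applies the barycentric solution per admixed
individual, anchoring the parents at their cluster centroids on the
structural eigenvectors. With $K'$ non-admixed populations the first
$K' - 1$ eigenvectors are structural; when populations beyond the parents
are present the parental hull is a *slanted* segment (or inclined triangle)
inside that higher-dimensional plot, and the projection contract handles it
without special cases. Eigenvectors with eigenvalue below $10^{-8}$ of the
largest, and the trivial vector, are excluded as non-structural.

## Empirical PCA

`empiricalPCA()` subtracts each marker's grand mean over all individuals,
then eigendecomposes the $N \times N$ sample covariance of the adjusted
counts across markers (per-individual means subtracted, denominator $M$ —
markers are realizations, so the maximum-likelihood form is used and the
same convention is fixed in `estimateSigma()`). The covariance is raw by
default; dividing markers by $\sqrt{\hat p(1-\hat p)}$ is available behind
`scaleMarkers = TRUE` but off, since the formulation is covariance-based.
Missing genotypes are replaced by the marker's grand mean (pairwise-complete
markers in `estimateSigma()`, with the minimum complete count recorded).
Reported $\hat\sigma$ values depend on the allele coding of the input; a
`recodeMinor` flag fixes a minor-allele convention when the parameters
themselves are of interest. The plot geometry is insensitive to the coding.

## The simulator

`simulateParentalPanel()` implements the Balding–Nichols construction:
ancestral frequencies $p \sim U(0.1, 0.9)$ per marker (the conventional
range; configurable), population frequencies
$\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ — mean $p$, variance $Fp(1-p)$ —
and binomial genotypes. $F = 0$ degenerates to a point mass at $p$. Each
stage (ancestral draw, each population's frequencies, each population's
genotypes, each admixed group) runs in its own named RNG stream derived from
the master seed, so panels are bit-reproducible and adding an admixed group
never perturbs the parental draws.

For admixed individuals, each of the two allele copies independently
inherits from a parent chosen by the individual's proportions, making the
genotype $\mathrm{Binomial}(2, \sum_i \lambda_i p_i)$ given the parental
frequencies. This is the reading consistent with Hardy–Weinberg equilibrium
in a well-admixed population and it reproduces the admixture moment algebra
exactly; drawing a single origin per genotype would put both alleles in the
same parent and inflate the admixed count variance by
$2(\sum_i \lambda_i p_i^2 - p_A^2)$ without changing any covariance.
`simulateAdmixedHomogeneous()` gives every individual the same proportions;
`simulateAdmixedRecent()` draws per-individual proportions once from
$\mathrm{Beta}(5,5)$ by default for two parents (heterogeneity typical of
recent admixture; the two-way Beta generalizes to a Dirichlet for $k$
parents) and stores them as truth. The simulator draws marker frequencies
independently: there is no linkage disequilibrium, no mutation/ascertainment
model and no genotyping error, so passing tests demonstrate statistical
correctness of the estimators under the model, not robustness to the LD
structure or artifacts of real assays.

## Ancestry-informative markers

`rankAIMs()` projects the grand-mean-adjusted count matrix onto each
structural eigenvector, $u_g(t) = \sum_i \tilde X_{gi} v_i(t)$, ranks
markers by $|u|$ per eigenvector and merges the per-eigenvector lists by
round-robin until the requested panel size, skipping duplicates. With $K'$
distinct non-admixed populations, $K'-1$ eigenvectors are used; admixed
populations are excluded from the count (they add no axis) and passing one
as distinct only warns. Mean adjustment makes monomorphic markers project
to zero (ranked last) and annihilates the constant direction exactly. The
round-robin merge balances information per axis; ties in $|u|$ break by
marker index for determinism.

## Numerical choices and degenerate inputs

* Degenerate parental geometry (affinely dependent parents, at tolerance
  $10^{-8}$ of the largest pairwise distance) is a hard error naming the
  offending parents; coincident segment endpoints likewise.
* Negative diagonal excess can occur in *estimated* parameter sets; it
  warns, and is clipped to zero only under `allowClip = TRUE`.
* The trivial eigenvector is identified by overlap $> 0.999$ with the
  constant direction; structural-vector exclusion uses eigenvalue
  $< 10^{-8} \times$ the largest.
* Proportion sums are exact by construction (the affine constraint is part
  of each solve).

## Problem sizes used in the checks

The deterministic worked example runs at $K=4$ in milliseconds. Simulated
recoveries use $M = 10{,}000$ markers throughout — the package's default
figure-scale size — with two-way designs at 50 + 50 parental and 35 admixed
individuals and the three-way design at 15/25/10 parental, 20 additional
and 30 admixed individuals; stochastic claims are assessed as means over 5
fixed replicate seeds, since single replicates at these small sample sizes
have per-component spread approaching the 0.05 band itself. Monte-Carlo
moment checks use $10^5$ markers with small $n$ and block standard errors
(25 blocks). At these sizes the full suite runs in well under a minute.

## Known limitations

* Individual-level proportion estimates are noise-limited by the marker
  count: at $M = 10{,}000$, $F_{ST} = 0.01$ designs the per-individual mean
  absolute error plateaus near 0.06 (it scales as $1/\sqrt{M}$), while
  group means are an order of magnitude tighter.
* Only single-level admixture pedigrees are modeled.
* Markers are exchangeable: no LD, so the simulator cannot emulate
  wavelet/segment-based dating of admixture or local-ancestry structure.
* The variance–covariance parameters (not the geometry) are allele-coding
  dependent; comparisons across datasets require a fixed coding convention.
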