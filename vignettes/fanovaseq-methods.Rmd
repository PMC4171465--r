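---
title: "Functional ANOVA for region-based association: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional ANOVA for region-based association: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanovaseq)
```

This vignette is the package's own account of the statistical machinery: the
model and its assumptions, the tunable parameters and their defaults, the
numerical conventions, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.

## Model

A subject's genotypes across a region — minor-allele counts $g_i(t_j) \in
\{0,1,2\}$ at positions $t_1 < \dots < t_p$ rescaled affinely to $[0,1]$ —
are treated as noisy evaluations of a smooth genotype function, expanded in
cubic B-splines:
$$x_i(t) = \sum_k c_{ik}\,\phi_k(t).$$
Within phenotype group $g$ the curves are modeled as a Gaussian process with
group mean $\mu_g(t)$ and a common covariance function; the null hypothesis
is $\mu_1 = \dots = \mu_k$. With curves discretized on $T$ equally spaced
grid points (weight $\Delta = 1/T$), between- and within-group variation are
integrated over the region and compared by the F-type ratio
$$F = \frac{\mathrm{SSR}/(k-1)}{\mathrm{SSE}/(n-k)},$$
which for $T = 1$ collapses exactly to classical one-way ANOVA. The
Gaussian-process assumption is an approximation for genotype curves (sums of
thresholded, skewed variables); the permutation route below is free of it.

## Smoothing strategies and their numerics

Three strategies convert profiles to curves, all cubic (order 4) B-splines
on $[0,1]$:

* **small** — `n_knots_small` equally spaced knots (default 6, hence 8 basis
  functions), unpenalized least squares. Heavily smoothed; insensitive to
  genotype relabeling.
* **every-other** — an unpenalized basis with a knot at every other variant
  position plus both endpoints (81 positions give 42 knots). Tracks the data
  closely and oscillates. The knot set uses the even-index interior
  positions plus the two endpoints; the count convention is anchored to the
  42-for-81 example rather than odd-index placement, which would give 41.
* **penalized** (recommended) — a knot at every position, roughness penalty
  $\lambda \int x''(t)^2\,dt$, with $\lambda$ chosen per subject by GCV.

The penalty matrix $P_{jk} = \int \phi_j''\phi_k''$ is computed exactly
(3-point Gauss–Legendre per inter-knot interval; the integrand is piecewise
quadratic, so this is exact, not a finite-difference surrogate). Its null
space is the straight lines, so the $\lambda \to \infty$ limit of the fit is
exactly the least-squares line — a property the tests assert.

Penalized fits for a whole $\lambda$ grid are obtained from a single
Demmler–Reinsch-type reparameterization: with $A = B'B$ and $S = A + P$
(positive definite whenever at least four distinct positions are observed),
factor $S = LL'$ and diagonalize $L^{-1}AL^{-T} = U\,\mathrm{diag}(d)\,U'$
with $d \in [0,1]$. Hat-matrix traces, residual sums of squares and
coefficients then cost $O(q)$ per subject per $\lambda$, which is what makes
per-subject GCV affordable inside Monte-Carlo experiments. The tests pin
this fast path against direct normal-equations solves.

**GCV.** $\mathrm{GCV}(\lambda) = m\,\mathrm{RSS}(\lambda)/(m -
\mathrm{tr}\,H_\lambda)^2$ is minimized over a default grid of 50 log-spaced
values in $[10^{-8}, 10^8]$, followed by one golden-section refinement
between the winning grid point's neighbors (in $\log\lambda$). The wide
upper end is deliberate: a subject whose observed codes are all equal has a
flat GCV profile and receives the grid maximum by convention, i.e. a
straight-line (here constant) fit. Missing genotypes are handled by fitting
each subject on their observed positions only; the unpenalized strategies
fall back to a ridge jitter $\lambda = 10^{-8}$ with a warning if their
system is singular.

**Grid convention.** Curves are evaluated on $T = 2p$ equally spaced points
*including both endpoints*, and integrals use the plain weight
$\Delta = 1/T$. $\Delta$ cancels in the F ratio and in the permutation test,
so only the distance matrix's absolute scale depends on it. The FLM design
integrals do not enjoy that cancellation and use trapezoid weights instead
(below).

## Genotype relabeling

Which homozygote is coded 0 versus 2 is arbitrary, but the smoothness of the
profile is not invariant to it: minor alleles of neighboring variants in
*repulsion* (negative LD) produce persistent $0\!-\!2$ adjacencies that
force oscillations into any faithful smoother. The relabeling objective is
the total flip count
$$\sum_i \sum_{j} \mathbf{1}\{(g_{ij}, g_{i,j+1}) \in \{(0,2),(2,0)\}\},$$
with heterozygotes contributing nothing. Minimization is exact: variants
form a chain with two states each (flip / keep), so dynamic programming over
the four per-adjacent-pair transition costs finds a global minimum in
$O(np)$; the tests verify it against exhaustive search over all $2^p$ flip
vectors. Among cost-ties the solution with fewer flips is preferred,
remaining ties resolved toward "keep" at the leftmost differing variant, so
results are deterministic. Relabeling is applied after imputation (the
objective needs complete data) and before smoothing.

## The FANOVA p-values

**Satterthwaite.** Under the Gaussian null the numerator of $F$ is a mixture
$\sum_r \lambda_r \chi^2_{k-1}$ governed by the eigenvalues of the
covariance function. Matching two moments collapses it to a scaled
chi-square with the adjustment factor $\kappa =
\mathrm{tr}(\Sigma)^2/\mathrm{tr}(\Sigma^2)$, and $F$ is referred to
$F_{(k-1)\kappa,\,(n-k)\kappa}$. Estimating $\kappa$ from the pooled
empirical covariance deserves care: sampling noise inflates
$\mathrm{tr}(\hat\Sigma^2)$ by roughly the factor $1 + T/(n-k)$, so the
naive plug-in ratio is biased low — badly so when the grid is finer than the
sample is large ($T = 2p \gg n$ is the typical regime here), which makes the
test visibly conservative. The default estimator removes the bias exactly
under Gaussianity using the Wishart moments of $(n-k)\hat\Sigma$:
$$\hat\kappa_{\mathrm{adj}} = \frac{(\nu+1)\,\mathrm{tr}(\hat\Sigma)^2 -
2\,\mathrm{tr}(\hat\Sigma^2)}{\nu\,\mathrm{tr}(\hat\Sigma^2) -
\mathrm{tr}(\hat\Sigma)^2}, \qquad \nu = n-k,$$
clamped to the feasible $(0, T]$; it equals 1 exactly at $T = 1$, preserving
the ANOVA reduction, and recovers $\kappa = T$ for white-noise curves where
the naive ratio returns about $T/(1+T/\nu)$. The naive estimator remains
available (`kappa_method = "naive"`). Both traces are computed through the
$n \times n$ residual cross-product, so a fine grid costs $O(n^2 T)$ rather
than $O(T^2 n)$ memory-heavy covariance assembly; the $T \times T$ matrix is
materialized only on request. A two-moment approximation calibrates the
rejection rate at conventional levels well but its p-values need not be
uniform over the whole unit interval when the covariance spectrum is very
uneven — the tests check exactly that: full uniformity in the near-spherical
regime, tail calibration in the smooth regime.

**Permutation.** $F$ is a function of the pairwise squared-$L^2$ distance
matrix via $\mathrm{SST} = \frac1n\sum_{i<j} d^2_{ij}$ and $\mathrm{SSW} =
\sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$, and simultaneous row/column
permutation of the distance matrix is equivalent to permuting subjects, so
the null is sampled by shuffling labels against a fixed matrix (default
$B = 999$). The add-one convention $p = (1 + \#\{F_b \ge F_{obs}\})/(B+1)$
guarantees $p \in (0,1]$. The distance/direct algebraic identity is asserted
to $10^{-10}$ in the tests.

## The FLM comparator

The scalar-on-function linear model regresses the 0/1 phenotype on the
genotype function through a basis expansion of the coefficient function
(default: the small 6-knot basis, $K = 8$, keeping $K \ll n$), giving an
ordinary design with entries $\int x_i(t)\phi_k(t)\,dt$. These integrals use
trapezoid quadrature — the rectangle rule's $O(1/T)$ error is material here
because nothing cancels it, whereas trapezoid agreement between the default
and a 10-fold finer grid is within $10^{-3}$. The Wald statistic
$W = \hat b'\hat V^{-1}\hat b$ is referred to $\chi^2_K$; rank-deficient
designs are pivoted down with $K$ reduced accordingly. A linear (not
logistic) model on the binary response is used deliberately, leaning on the
classical equivalence of chi-squared and ANOVA tests for dichotomous data.
The permutation p-value shuffles the phenotype and counts permuted
chi-square p-values at or below the observed one, again with the add-one
convention. (The alternative literal reading — counting permuted p-values
*exceeding* the observed — is the complement and would reward poor fits; we
document rather than adopt it.)

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a sequenced ~30 kb region
without requiring external haplotype panels:

* **Allele frequencies.** Half the variants (default `rare_fraction = 0.5`)
  receive rare targets, MAF drawn from a Beta(0.2, 20) truncated to
  (0.0005, 0.01); the rest from Beta(0.5, 2) truncated to (0.01, 0.5). The
  result is the L-shaped spectrum of sequencing data. Variants monomorphic
  in the sampled cohort are removed, so a 100-variant region delivers
  roughly 60–80 polymorphic variants at $n = 50$.
* **LD.** Haplotypes come from a latent AR(1) Gaussian copula with
  adjacent-variant correlation `ld_rho = 0.95`, chosen so the latent
  correlation halves roughly every 4 kb at the default ~300 bp spacing —
  the kilobase-scale decay seen for common variants in real data. Each
  variant's minor allele is assigned to a random latent tail: same-tail
  neighbors are in attraction (positive LD), opposite-tail neighbors in
  repulsion (negative LD). The repulsion component is essential — it is what
  produces the persistent 0–2 patterns that relabeling exists to remove.
* **Phenotype.** $\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum_c
  \beta_c g_{ic}$ over a causal subset of `causal_fraction`$\times p$
  variants, effects drawn once per dataset from
  $N(\mu, \sigma^2)$ ($\mu = 0$: bidirectional effects; $\mu > 0$: mostly
  deleterious; defaults $\sigma = 0.25$, baseline prevalence 0.1 via
  $\beta_0$). Cohorts are sampled retrospectively: batches are drawn and
  subjects accepted until the case and control quotas are met exactly.
* **Missingness.** MCAR dropout at `missing_rate = 0.02`, applied last.

What it does **not** emulate: empirical haplotype block boundaries and
recombination hotspots, population structure and relatedness, allele-
frequency-dependent call quality, batch effects, or indels/multi-allelic
sites. Null calibration and qualitative power orderings transfer to real
data only insofar as these omissions are orthogonal to the test statistics;
the absolute power numbers certainly do not transfer.

## Experiment sizes

The packaged experiments run at desk scale, chosen as the smallest sizes at
which the Monte-Carlo error is useful: size experiments use 1,000 null
replicates at 25 cases / 25 controls with 100 simulated variants (binomial
SE ≈ 0.007 at the 5% level) and 10,000 replicates with 60 variants for the
$10^{-3}$-level tail (SE ≈ 0.0004); power comparisons use 300 replicates
per configuration at 50/50 subjects. The power experiment spans causal
fractions 0.1/0.4/0.8 at $\mu = 0.25$, and the relabeling contrast uses
causal fraction 0.5 at $\mu = 0$, where effects of both signs make curve
shape, not level, carry the signal.

## Degenerate inputs and tie-breaks

* Variants with an exact 0.5 sample allele frequency keep the ALT allele
  coded (reading from VCF); the relabeler makes downstream tests largely
  insensitive to this choice.
* Modal imputation breaks frequency ties toward the smaller code.
* All-identical curves give $F = 0$ and $p = 1$ with a degenerate flag, as
  does an all-zero distance matrix in the permutation test.
* A constant genotype profile receives the maximum grid $\lambda$ (straight
  line fit).
* The relabeling DP prefers, among cost-optimal solutions, fewer flips, then
  "keep" at the leftmost differing variant.

## Known limitations

* The asymptotic test leans on a Gaussian-process approximation; genotype
  curves built from rare variants are skewed, and at very small $n$ the
  Satterthwaite tail can drift a little above the nominal level (visible at
  the $10^{-3}$ level) while remaining accurate at conventional levels. The
  permutation p-value is the fallback when exactness matters.
* The unpenalized every-other-knot strategy runs liberal; it is included as
  a comparison point, not a recommendation.
* Covariate adjustment, multi-phenotype models, and subregion follow-up
  testing are out of scope.
* Imputation is single-pass (mode or empirical draw); uncertainty across
  imputations is not propagated.
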