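---
title: "Information-rescaled principal component maps for genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-rescaled principal component maps for genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipca)
```

## The problem

A two-dimensional PCA map of a genotype matrix places sample $i$ at
$(\rho_{i1}\sqrt{\lambda_1},\ \rho_{i2}\sqrt{\lambda_2})$, where
$\rho_{ij}$ is the correlation of the sample with principal component $j$
and $\lambda_j$ the component's eigenvalue. Distances read off such maps
inherit the defects of correlation as a measure of association: it is not
additive across subsets of the domain, and equal correlation increments do
not carry equal statistical information — the step from $\rho = 0.5$ to
$0.7$ carries far more association than the step from $0$ to $0.2$.

For jointly Gaussian variables the mutual information is a closed-form
monotone function of the correlation,
$$I(\rho) = -\tfrac12 \log(1-\rho^2),$$
which *is* additive, diverges as $|\rho| \to 1$, and is zero exactly at
independence. `mipca` transforms correlation-based map coordinates through
the signed version
$$r(\rho) = -\operatorname{sgn}(\rho)\,\tfrac12 \log(1-\rho^2),$$
so the map coordinate of sample $i$ on axis $j$ becomes
$r(\rho_{ij})\sqrt{\lambda_j}$. Because $r$ is odd and strictly
increasing, per-axis orderings are exactly preserved (the package asserts
rank equality, not near-equality); only cardinal distances change, and they
change nonuniformly: each sample's own correlation is transformed, which
stretches the periphery of an axis and contracts its middle. We deliberately
do *not* implement the transform as a single per-axis multiplier — that
would be a linear zoom with no effect on relative distances, and it would
contradict the defining property $M' = r(M)$ applied entrywise to the
loadings matrix.

## The PCA engine and why $M = U$

Genotypes are encoded additively: at each biallelic SNP, the code is the
number of *minor* alleles carried (0, 1, 2), where the minor allele is the
rarer one **in the loaded cohort** (ties broken toward the
lexicographically smaller allele label so runs are deterministic). VCF ALT
dosages and PLINK `traw` COUNTED dosages are re-oriented to this convention
on input, with flips recorded per locus.

The matrix $G$ ($m$ samples $\times$ $n$ loci, $m \ll n$) is standardized
**by rows**: each sample row is centered by its mean and divided by its
sample standard deviation (denominator $n-1$). Then
$C = ZZ^\top/(n-1)$ is exactly the matrix of pairwise Pearson correlations
between samples, with unit diagonal. The thin SVD $Z = USV^\top$
diagonalizes $C$ with eigenvalues $\lambda_j = S_j^2/(n-1)$ (so
$\sum_j \lambda_j = m$ at full rank); component rows $P = U^\top Z$ are
mutually orthogonal with diagonal covariance. Row centering with the
ordinary mean (divisor $n$) is required for these identities to hold
exactly; a column ("snp") mode is provided for comparability with
column-standardized pipelines, under which (and only under which) PC
scores sum to zero across samples.

The loadings matrix that the rescaling acts on is
$$M \;=\; [\operatorname{cov}(Z,Z^\top)]^{-1/2}\,
          \operatorname{cov}(Z,P^\top)\,
          [\operatorname{cov}(P,P^\top)]^{-1/2} \;=\; U .$$
Note that this is the *matrix-whitened* correlation, not the entrywise
Pearson correlation of sample rows with component rows — the entrywise
version equals $\sqrt{\lambda_j}\,U_{ij}$ and is therefore not a common
correlation scale across axes. `correlation_loadings()` computes the
whitened form directly from $Z$ and $P$ (with an eigendecomposition of $C$
independent of the SVD path) and verifies $\max|M-U| \le 10^{-8}$ at every
call, so a normalization regression cannot pass silently. Entries of $U$
lie in $[-1,1]$ because its columns are orthonormal, which is what makes
the entrywise rescaling $M' = r(U)$ well defined. Components with
$\lambda_j < 10^{-12}\lambda_1$ are treated as null: their correlations are
undefined and set to zero with a flag.

PCA columns carry an arbitrary sign; we fix each $U$ column so its
largest-magnitude entry is positive, making maps and files reproducible
across SVD implementations.

## Mutual information: closed forms, estimation, additivity

All internal computation is in nats; outputs convert to bits by an exact
factor $1/\log 2$ on request. $|\rho| \ge 1 - 10^{-12}$ (e.g. duplicated
samples) is clamped to $1-10^{-12}$ with a warning so coordinates stay
finite; a strict mode raises instead. $1-\rho^2$ is evaluated as
$\mathrm{log1p}(-\rho)+\mathrm{log1p}(\rho)$ for accuracy near $|\rho|=1$.

**Student-t correction.** For a bivariate Student-t pair with tail
parameter $\alpha$, zero correlation does not mean independence; the
mutual information is $-\tfrac12\log(1-\rho^2) + \lambda_\alpha$ with
$$\lambda_\alpha = -\tfrac{2}{\alpha} + \log\alpha
 + 2\pi(\alpha+1)\csc(\pi\alpha) + 2\log B(\tfrac\alpha2,\tfrac12)
 - (\alpha+1)H_{-\alpha/2} + (\alpha+1)H_{-\alpha/2-1/2} - 1 - \log 2\pi,$$
where $H_x$ is the harmonic number of fractional argument
($H_x = \psi(x+1) + \gamma$). The cosecant and the harmonic-number
difference have simple poles at every integer $\alpha$ that cancel
*exactly*: by the digamma reflection formula,
$$2\pi(\alpha+1)\csc(\pi\alpha)
  + (\alpha+1)\left(H_{-\alpha/2-1/2}-H_{-\alpha/2}\right)
  = (\alpha+1)\left(\psi(\tfrac{\alpha+1}{2})-\psi(\tfrac\alpha2)\right).$$
The default implementation evaluates this pole-free grouping, which is
finite and numerically stable for every $\alpha > 0$ (the literal form
suffers catastrophic cancellation at large $\alpha$ and needs a limit at
integers). The literal expression is kept as `method = "printed"`, taking
the two-sided numerical limit at integer $\alpha$ with offset $10^{-4}$ —
chosen because the $O(\delta^2)$ limit error and the $1/\delta$
amplification of digamma argument rounding are then both below $10^{-6}$.
Tests cross-check both forms against the independent entropy-difference
route $2h_1(\alpha) - h_2(\alpha)$ and against a Monte-Carlo Kraskov
estimate on simulated t pairs; $\lambda_\alpha \to 0$ as
$\alpha \to \infty$ recovers the Gaussian case.

**Empirical estimation.** `empirical_mi()` implements the
Kraskov-Stoegbauer-Grassberger neighbour estimator (variant 1, $k = 3$ by
default) in C++, with marginal neighbour counts taken strictly inside the
max-norm distance to the $k$-th neighbour. Margins are standardized first:
mutual information is invariant under marginal scaling, and without it the
max-norm neighbourhoods degenerate into slabs when the two margins live on
very different scales (for instance PC scores with well-separated
eigenvalues), biasing the estimate upward. Duplicate values receive a
vanishing deterministic jitter ($10^{-10}$ of a standard deviation), since
the estimator assumes continuous data. A histogram plug-in alternative
with Freedman-Diaconis bins and the Miller-Madow correction is provided;
with the same correction applied to `binned_entropy()`, the estimate at
perfect dependence ($y = x$) equals the margin's entropy exactly. Raw
estimates can be slightly negative; they are clipped at zero with the raw
value retained in an attribute.

**Additivity.** Unlike correlation, mutual information is an integral of a
density against the domain and so is additive over partitions.
`mi_additivity_check()` demonstrates this by adaptive quadrature: nested
one-dimensional `integrate()` calls (tolerance $10^{-11}$ per level,
domain truncated at $\pm 9$ standard deviations, neglected mass below
$10^{-17}$), which reproduces the closed form to machine precision —
two-dimensional cubature routines were an order $10^{-5}$ less accurate at
comparable settings, which is why the nested form is used.

## Cluster separability and the $0.618$ threshold

Project two cluster centers of mass onto the leading component, with
center-of-mass correlations $0 < \rho_1 < \rho_2 < 1$. In units of
$\sigma^2/\lambda_1$ ($\sigma$ the pooled within-cluster standard
deviation), the linear squared separation is $(\rho_2-\rho_1)^2$ and the
information-rescaled one is
$$\tfrac14\left(\log\frac{1-\rho_2^2}{1-\rho_1^2}\right)^2
  = \left(r(\rho_2) - r(\rho_1)\right)^2,$$
an identity the tests assert on a grid. For nearly coincident centers the
difference linearizes to
$$\left(\frac{\rho_1^2}{(1-\rho_1^2)^2} - 1\right)(\rho_2-\rho_1)^2,$$
whose coefficient changes sign at the root of $\rho^2 = (1-\rho^2)^2$:
$$\rho^* = \sqrt{\tfrac{3-\sqrt5}{2}} = 0.6180340\ldots,$$
the inverse golden ratio. Below $\rho^*$ rescaling contracts small cluster
gaps, above it it amplifies them — the same constant at which the
derivative $r'(\rho) = \rho/(1-\rho^2)$ crosses one. `critical_threshold()`
finds the root by bisection to $10^{-12}$ and is checked against the
closed form.

Whether a cluster sits above the threshold is tested one-tailed against
$H_0: \rho \le \rho^*$. No test statistic is fully specified by the name
"t-test" for a *nonzero* null correlation (the classical t statistic only
tests $\rho = 0$), so the package uses the Fisher z-transform,
$z = (\operatorname{atanh} r - \operatorname{atanh}\rho^*)\sqrt{n-3}$; its
size at the null is verified by simulation (rejection rate at level 0.05
within $[0.03, 0.07]$ over 2000 replicates). `compare_separations()`
estimates each cluster's center-of-mass correlation as the mean of its
members' loadings — the natural plug-in given that loadings are the
per-sample correlations; how to estimate this quantity from finite samples
is otherwise underdetermined — and applies the gate test to the smaller of
the two estimates with that cluster's member count. The comparison is
defined for the positive-correlation regime; negative estimated centers
are an error rather than silently reflected, since reflecting an axis is a
decision the analyst should make explicitly.

## The synthetic-data generator

Real-world population panels are replaced by the Balding-Nichols model:
per locus an ancestral frequency $p$ is drawn uniformly from
$[0.05, 0.5]$ (the common-variant spectrum typical of genotyping arrays —
rare variants are largely removed by MAF filters anyway), each population
$k$ receives $p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$ with mean $p$ and variance $Fp(1-p)$, and
genotypes are $\mathrm{Binomial}(2, p_k)$. $F$ is interpretable as the
fixation index FST of each population against the ancestral pool, and a
Hudson-type ratio-of-averages estimator recovers it
(F = 0.1 is estimated within $[0.08, 0.12]$ at 3 populations $\times$ 50
samples $\times$ 5000 loci). One root seed drives deterministic per-locus
substreams, so the first $L$ loci of a long run equal a short run of $L$
loci.

The generator emulates drift-driven divergence with unlinked loci and
Hardy-Weinberg genotypes within populations. It does **not** emulate
linkage disequilibrium, admixture gradients, IBD/runs-of-homozygosity
structure, genotyping batch effects or ascertainment bias. Tests passing
on this generator therefore demonstrate the algebraic and statistical
behavior of the method (order preservation, threshold behavior, cluster
recovery at a known FST), not robustness to those real-data features.

The segregating-sites utility returns $4N_e\mu\sum_{k\le N} 1/k$ with the
sum running to $N$ exactly as stated in the population-genetics framing
the package follows; the common coalescent convention sums to $N-1$, a
difference of $4N_e\mu/N$ that is immaterial at the sample sizes where the
logarithmic-growth interpretation (branching events, not branch lengths)
matters.

## Numerical choices and validation sizes

* Standardization requires strictly positive row variance; constant
  samples are dropped with a warning (or rejected in strict mode).
* Eigenvalue ties keep the SVD's column order; the deterministic sign
  convention fixes the rest of the gauge.
* The embedding TSV stores 17 significant digits, so write/read round
  trips are lossless at double precision.
* Validation problem sizes were chosen to make sampling error negligible
  relative to each tolerance while keeping the whole suite around ten
  seconds: Kraskov convergence at $n = 2\times10^4$ (observed error
  $\le 0.005$ nats against closed forms, asserted at 0.05), PC
  independence at $n = 5000$ draws (asserted at 0.02 nats), eigen/SVD
  cross-checks up to $50 \times 2000$, end-to-end recovery at 3
  populations $\times$ 50 samples $\times$ 2000 loci with adjusted Rand
  index $> 0.9$ on both coordinate systems.

## Known limitations

* The rescaling presumes approximate joint Gaussianity of the underlying
  scores; for heavy-tailed data the Student-t correction quantifies how
  much information zero correlation still hides, but the map transform
  itself remains the Gaussian $r(\rho)$.
* Center-of-mass correlations estimated as mean member loadings shrink
  toward zero as the number of samples grows (loadings columns are unit
  vectors), so the $\rho^*$ gate is most meaningful for coarse clusters on
  dominant axes, not for many small clusters.
* There is no canonical normalization that assigns finite "total
  information" to $|\rho| = 1$ (the Gaussian MI diverges there), so the
  package reports absolute information in nats/bits and deliberately does
  not offer a 0-to-1 normalized scale.
* Out of scope by design: out-of-sample projection, Tracy-Widom
  eigenvalue significance, LD pruning and kinship filtering, multivariate
  (Hotelling-type) extensions of the gate test, and t-SNE/UMAP-style
  nonlinear embeddings.
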