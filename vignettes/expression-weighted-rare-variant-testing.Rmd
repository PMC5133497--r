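---
title: "Expression-weighted rare-variant association testing in families"
author: "rvexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted rare-variant association testing in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvexpress)
```

# The problem

Rare variants (minor allele frequency below 1%) are poorly served by
single-marker association tests: almost all carriers are singletons, so the
per-variant signal is tiny. Gene-level tests pool the rare variants of a gene
into one regressor and test that pooled burden against a quantitative trait.
Two further complications motivate this package:

* **Families.** In family cohorts the phenotypes of relatives are correlated
  through shared polygenic background, so observations are not exchangeable
  and naive permutation inference is invalid.
* **Wasted external information.** When expression data are available for the
  same individuals, a gene whose rare-allele load measurably shifts one of
  its expression probes, and whose probe in turn tracks the phenotype, is a
  far better candidate than its p-value alone suggests.

`rvexpress` implements a complete pipeline for this setting: kinship-based
phenotype decorrelation, a data-adaptive gene-level score test with
permutation p-values, and expression-informed p-value re-weighting with
family-wise error rate (FWER) control. A synthetic family-data generator with
known causal truth makes every step testable without access-restricted cohort
data.

# The model, step by step

## Phenotype preparation

Each individual's summary phenotype is the arithmetic mean of the measurement
over available visits (`averageVisits()`). Relatedness is estimated from a
genome-wide common-marker panel as the standard allele-frequency-standardized
genetic relationship matrix (GRM),

$$\Sigma_{kl} = \frac{1}{M}\sum_{m=1}^{M}
  \frac{(g_{km} - 2p_m)(g_{lm} - 2p_m)}{2p_m(1-p_m)},$$

so self-relatedness is near 1 and full sibs near 0.5 (`estimateKinship()`).

The phenotype is then whitened so that family members become exchangeable.
A common idealization whitens by $\Sigma^{-1/2}$ directly, which is exact
only when the phenotypic covariance is *proportional* to $\Sigma$ — a fully
heritable trait. For a partially heritable trait with covariance
$\sigma_A^2\Sigma + \sigma_e^2 I$, whitening by $\Sigma^{-1/2}$ overshoots:
the transformed values of relatives become *negatively* correlated (the
off-diagonals of $\Sigma^{-1}$ are negative within family blocks), while
rare-allele burdens remain positively clustered in families. The permutation
null then stochastically dominates the observed statistic and the test loses
essentially all power-relevant calibration; in our null simulations the mean
p-value rose to about 0.78. `transformPhenotype()` therefore whitens by

$$\big(h^2\,\Sigma + (1 - h^2)\,I\big)^{-1/2},$$

with the heritability $h^2$ estimated by Haseman–Elston moment regression of
phenotypic cross-products on relatedness (`estimateHeritability()`) — a
closed-form estimator, deliberately simpler than a variance-components REML
fit. Setting `h2 = 1` reproduces the raw $\Sigma^{-1/2}$ transform. The
overall variance scale of the whitening matrix is irrelevant because
permutation inference is scale-invariant.

Population stratification is handled by classical (Torgerson)
multidimensional scaling of the standardized common-marker genotypes, which
equals the leading principal-component scores; the first $K = 3$ axes are
regressed out of the whitened phenotype (`stratificationAxes()`,
`residualize()`). Axis signs are fixed deterministically (largest-magnitude
coordinate positive). All downstream analysis uses this decorrelated,
residualized value.

## The gene-level test

For a gene with $k$ rare variants, let $\mathrm{SNP}_i$ be the rare-allele
count of variant $i$. The pooled regressor is
$\sum_i \nu_i s_i\,\mathrm{SNP}_i$ with per-variant weights $\nu_i$ (all 1 by
default) and codings $s_i \in \{+1, -1, 0\}$ — risk, protective, or
excluded. The codings are selected greedily: starting from all $+1$, a single
forward pass in genomic order sets each $s_i$ to the value maximizing the
score statistic

$$T = \frac{\big(\sum_k (x_k - \bar x)(y_k - \bar y)\big)^2}
          {\hat\sigma^2_y \sum_k (x_k - \bar x)^2},$$

holding the other codings fixed (`selectVariantSigns()`); $T = n r^2$ for
Pearson correlation $r$. Monomorphic variants are pinned to 0. Exact ties
between candidate codings keep the coding under which the pooled regressor
is *positively* associated — necessary because $T$ is sign-symmetric, so for
a single-variant gene a pure preference order could never label a protective
variant — and otherwise prefer $+1$ over $-1$ over $0$. A single pass is the
default (`passes` is exposed); more passes change results only marginally
and cost proportionally.

Significance comes from permuting the decorrelated residual phenotype
(`seqASumVS()`): the whitening exists precisely to make this permutation
valid. Crucially, the sign selection is **re-run on every permuted
phenotype**, so the optimism of the adaptive search is present in the null
distribution as well; freezing the observed coding (`reselect = FALSE`,
retained only as a demonstration) measurably inflates the type-I error, and
a regression test guards that behavior. The p-value is the always-positive
estimator $p = (b + 1)/(B + 1)$, whose floor at the reference $B = 500$ is
$1/501 < 0.002$. The observed + permuted statistics for a gene are computed
by a small compiled kernel that works on the $k \times k$ Gram matrix and
the $k \times (B{+}1)$ cross-product matrix, so runtime per gene is
essentially independent of sample size once those are formed; an R
reference implementation (`selectVariantSigns()`) is kept and the two are
cross-checked in the tests. Per-gene RNG streams are derived by hashing the
gene id with the root seed, making results independent of gene order.

## Expression-informed weights

For gene $i$, collapse its rare-variant columns to a burden
$g_i$ (`collapseGeneBurden()`). For every expression probe $j$, two ordinary
least-squares fits give two squared Wald statistics:

* burden to expression: $E_j = \beta_0 + \beta_{gE}\,g_i + \gamma P +
  \epsilon$, with $w_{gE} = (\hat\beta_{gE}/\mathrm{SE})^2$
  (`weightGeneExpression()`);
* expression to phenotype: $P = \beta_0 + \beta_{EP}\,E_j + \gamma g_i +
  \epsilon$, with $w_{EP} = (\hat\beta_{EP}/\mathrm{SE})^2$
  (`weightExpressionPhenotype()`).

The crude gene weight is the best product over all probes,
$w_i = \max_j\, w_{gE}(j)\, w_{EP}(j)$ (`crudeWeight()`): a probe supports a
gene only if the burden moves its expression *and* its expression tracks the
phenotype; if either link is absent the product vanishes. Degenerate fits
(constant burden, collinearity) yield weight 0 rather than an error — zero
weight meaning "no usable expression evidence". Standard errors use the
unbiased $n - 3$ denominator, i.e. exactly what `lm()` reports; the
all-probes scan is vectorized through one shared design solve and a
Frisch–Waugh partialling step, and is verified against per-probe `lm()`
fits.

Crude weights are divided by their mean over the tested gene family so the
normalized weights $w^*_i$ average exactly 1 (`normalizeWeights()`) — the
condition under which the weighted decision rule
$p_i / w^*_i \le \alpha$ retains FWER control. Adjusted p-values are
$\min(1,\, p_i / w^*_i)$ (`adjustPvalues()`). The pipeline reports both raw
and adjusted significance flags, because a gene can act on the phenotype
without shifting expression: genes worth follow-up are those with *either*
small raw *or* small adjusted p-values. Weight normalization is
per-phenotype over exactly the genes that received a test p-value.

# The synthetic-data generator

`simConfig()` fixes the reference conditions; `generateDataset()` writes a
complete bundle (VCF 4.2 with rare and common markers, BED4 gene intervals,
expression and visit-level phenotype TSVs, truth table, pedigree).

* **Pedigrees**: nuclear families of two unrelated founders and (by default)
  two children; 65 families give 260 individuals, about the size of cohort
  this method targets.
* **Genotypes**: founder haplotypes are Bernoulli draws at the variant's
  population MAF; offspring receive one uniformly chosen haplotype per
  parent per variant (Mendelian gene-dropping, no linkage). Genes carry 2–49
  rare variants with population MAF in (0.001, 0.01); a separate panel of
  2000 common markers (MAF 0.05–0.5) feeds kinship and stratification.
* **Expression and phenotype**: linear-Gaussian structural equations. For a
  causal-chain gene, $E = b_{gE}\,g + \epsilon_1$ and the phenotype gains
  $b_{EP} E$; a reactive gene adds $b_{gP}\,g$ to the phenotype and its
  probe responds to the phenotype; a direct gene affects the phenotype with
  expression untouched. The phenotype always receives a polygenic family
  effect $\mathrm{MVN}(0, \sigma_A^2 \Sigma_{\mathrm{expected}})$ plus
  environmental noise, and each of 3 visits adds independent measurement
  noise. Defaults: $b_{gE} = 1$, $b_{EP} = 0.5$, $b_{gP} = 0.5$, all noise
  SDs 1, $\sigma_A = 0.5$, 20 probes, 10% causal genes. With these values a
  causal gene's burden explains roughly 20% of its probe's variance and a
  few percent of the phenotype's — a strong eQTL feeding a modest trait
  effect, the regime the weighting is designed for.

What the generator does *not* emulate: linkage disequilibrium among rare
variants, genotyping or imputation error, admixture beyond a two-population
founder option, and visit-level covariates. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated model,
not robustness to those real-data features.

# Numerical and design choices

* **MAF** is always the in-sample frequency over non-missing calls,
  $\min(f, 1-f)$; a variant is "rare" when $0 < \mathrm{MAF} < 0.01$
  (monomorphic columns carry no information and are not counted). Genes
  enter the analysis with between 2 and 49 rare variants.
* **Coordinates**: VCF positions are 1-based, BED intervals 0-based
  half-open; a variant at 1-based position $p$ belongs to BED gene
  $[s, e)$ when $s \le p - 1 < e$.
* **Missing genotypes** are mean-imputed per variant ($2\hat p$), which
  preserves allele frequency; missing expression values fall back to
  per-probe complete-case regression (probe-mean imputation is available at
  read time).
* **Multiallelic sites** are rejected by default and split into per-ALT
  pseudo-variants on request.
* **Eigenvalue floor** $10^{-6}$ before $\Lambda^{-1/2}$: empirical GRMs are
  near-singular.
* **Degenerate regressors** (zero-variance pooled burden, $s'As \le$
  tolerance) score 0 rather than erroring.
* **Determinism**: one root seed; per-gene streams by stable string hashing;
  MDS axis signs fixed; identical inputs and seed give byte-identical output
  files.

# Calibration and power studies

Three study functions re-derive the operating characteristics at reference
problem sizes chosen to run comfortably on one CPU (the same sizes the
acceptance script uses):

* `typeIErrorStudy()` — 500 independent null genes on a 300-person family
  structure, $B = 200$: the rejection rate at $\alpha = 0.05$ should sit in
  the binomial band $[0.032, 0.071]$. Each gene is an independent
  (genotype, phenotype) draw so the band is actually valid; with one shared
  cohort phenotype the gene-level rejections are positively correlated and
  the rate's spread is far wider than binomial.
* `fwerStudy()` — 200 global-null cohorts of 200 genes (200 individuals,
  $B = 200$): the probability that the weighted-Bonferroni rule rejects any
  gene must stay at or below $\alpha$. Note the discreteness interaction:
  with $m = 200$ genes the per-gene threshold $\alpha/m$ sits below the
  permutation floor $1/(B{+}1)$, so a rejection additionally requires a
  normalized weight around 20 or larger — the observed family-wise error is
  therefore typically far below $\alpha$, not just at it.
* `powerStudy()` — 200 causal-chain cohorts of 20 genes (260 individuals,
  $B = 500$; 20 genes keep the Bonferroni threshold $0.05/20$ above the
  permutation floor $1/501$): power of the weighted rule on causal genes
  should match or exceed plain Bonferroni, with discordant decisions
  favoring the weighted rule.

The vignette states no numbers these functions do not themselves compute;
run them (or `scripts/acceptance.R`) to reproduce the rates.

# Known limitations

* The greedy single-pass selection is not guaranteed to find the global
  optimum over the $3^k$ codings; the permutation null uses the same search,
  so validity is unaffected, only power.
* Heritability is estimated by a moment method; a REML variance-components
  fit would be more efficient but is intentionally out of scope.
* Genes with 50 or more rare variants are excluded rather than windowed.
* The case–control (logistic) variant of the test is not implemented; the
  trait link is identity throughout.
* Weight regressions scan all probes genome-wide; with very large probe
  panels a cis-window restriction would be the natural speedup.
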