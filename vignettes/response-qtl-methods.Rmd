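---
title: "Models and methods for multi-condition response-QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-condition response-QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respqtl)
```

## The problem

respqtl maps genetic variants that modulate a molecular response to a
graded perturbation — the canonical design being a panel of cell lines from
related individuals, each assayed by RNA-seq under several ordered
treatment concentrations. Three features make this harder than ordinary
eQTL mapping: repeat measures (one individual contributes a sample per
condition), relatedness (kinship induces covariance between individuals),
and latent confounding (batch and state effects that dominate expression
variation). A *response* QTL (reQTL) is a variant whose effect on
expression differs across conditions — a genotype-by-treatment
interaction — as opposed to a *marginal* eQTL whose effect is constant.

## The two-step mixed model

**Step 1** learns a global covariance structure jointly across genes. For
gene $g$, the vector $y_{:g}$ over all samples is modeled as

$$y_{:g} \sim \mathrm{MVN}\!\left(V v_{:g},\;
  \sum_k \sigma_k^2 x_{:k} x_{:k}^\top + \sigma_u^2 U +
  \sigma_\xi^2 \Sigma + \sigma_e^2 I\right)$$

where $V$ maps conditions to samples, $v_{cg}$ are per-gene condition
means, $x_{:k}$ are latent factor columns shared by all genes (with the
factor loadings integrated out, contributing $\sigma_k^2 x x^\top$), $U$
indicates same-individual sample pairs, and $\Sigma$ is the kinship matrix
(expected genetic covariance, twice the kinship coefficient).
`fit_latent_factors()` maximizes the summed log-likelihood over $x$, the
variances (log-scale) and $v$ (profiled out in closed form by GLS) with
L-BFGS and analytic gradients. Identifiability conventions: factor columns
are unit-norm with magnitude carried by $\sigma_k^2$, the
largest-magnitude entry of each column is positive, and columns are
ordered by decreasing variance. Initialization: principal components of
the condition-mean-centered data for $x$, $\sigma_e^2 = 0.5\,
\mathrm{Var}(Y)$, $\sigma_u^2 = \sigma_\xi^2 = 0.1$. The number of factors
`K` is a tuning choice (default 10); shrinkage of $\sigma_k^2$ prunes
unneeded factors and `effective_K` counts those above $10^{-4}$ of the
total variance. Phenotypes are first rank-normalized per gene
(`quantile_normalize_features()`, rankit offset 0.5, average ranks on
ties) so the Gaussian likelihood is tenable. Note the rankit transform
gives rows an exactly zero mean but a sample SD slightly below 1 (about
0.993 at n = 217); nothing downstream assumes unit variance.

**Step 2** tests each gene–SNP pair with the confounder covariance fixed:
$\Sigma_\pi = \sum_k \sigma_k^2 x x^\top + \sigma_u^2 U + \sigma_\xi^2
\Sigma$ (`build_sigma_pi()`), and per-pair covariance $\sigma_\pi^2
\Sigma_\pi + \sigma_e^2 I$ with both scales refit per pair so each gene can
follow the global pattern more or less. Three nested mean models:

* Model 0: condition means only, $\mathbb{E}[y] = v_c$;
* Model 1: adds a marginal dosage effect $\beta d$;
* Model 2: condition-specific effects $\beta_c d$.

In the eigenbasis of $\Sigma_\pi$ the covariance is diagonal, so a
likelihood evaluation is $O(S)$ after one rotation; the variance ratio
$\delta = \sigma_e^2/\sigma_\pi^2$ is profiled on a 64-point log grid over
$[10^{-5}, 10^5]$ refined by golden-section search, with the fixed effects
solved by weighted least squares at each $\delta$. Likelihood-ratio tests:
marginal (M1 vs M0, df 1), response (M2 vs M1, df $C-1$), combined (M2 vs
M0, df $C$). Multiplicity: Bonferroni over SNPs within gene (lead SNP =
argmin p, ties to the smallest genomic position), then Benjamini–Hochberg
across genes.

Because the variance scales are estimated, the $\chi^2$ reference is only
asymptotic and finite-sample p-values for the interaction test are
somewhat anti-conservative; no permutation scheme is valid for
interactions. `parametric_bootstrap_fdr()` therefore simulates expression
from each gene's fitted Model 1 (lead SNP, no interaction), refits Models
1 and 2 for all of the gene's SNPs, applies the identical
LRT-plus-Bonferroni pipeline, and pools the per-gene null p-values. The
estimated true FDR of a nominal-level discovery set is the plug-in: mean
bootstrap count of per-gene p-values below the BH rejection threshold,
scaled to the number of genes, divided by the real discovery count, capped
at 1. This plug-in is the package's choice of estimator, and its
calibration is exercised on pure-null simulations in the test suite.

## Allele-specific expression

At heterozygous exonic SNPs, the two alleles' read counts measure
cis-regulation within individuals. For exonic SNP $k$ of a gene in
individual $n$ at condition $c$:

$$y_{nkc} \mid r_{nkc} \sim \mathrm{BB}\!\left(r_{nkc},\,
  \sigma(\mu + \phi_{nk}\beta_c),\, \gamma\right)$$

with the logistic $\sigma$, reference-bias intercept $\mu$, per-gene
concentration $\gamma$ (pseudo-counts $a = p\gamma$, $b = (1-p)\gamma$),
and phased heterozygosity $\phi_{nk} \in \{-1, 0, +1\}$ of the regulatory
SNP ($\phi = 0$ rows still inform $\mu$ and $\gamma$). Phasing is taken as
given. $\gamma$ carries a Gamma(1.001, 0.001) shape–rate prior (mean
$\approx 1001$, near-flat, keeping $\gamma$ off zero). Fits are
quasi-Newton on $(\mu, \beta_\cdot, \log\gamma)$. The response null is
$\beta_c \equiv \beta$; conditions with no allelic reads lose their
$\beta_c$ and the df drops accordingly. Multiple exonic SNPs are treated
as conditionally independent given $(\mu, \beta_c, \gamma)$; reads
spanning two exonic SNPs are double-counted — a documented limitation.

Total and allelic evidence combine by adding log likelihood ratios: twice
the sum is asymptotically $\chi^2$ with the summed df (usually $4 + 4 = 8$
at $C = 5$). Eligibility: the total-expression component requires at
least 5 alternative alleles of the regulatory SNP; the allelic component
at least 2000 supporting reads for the gene (both inclusive).

## Response-pattern clustering

Genes are clustered by dose-response profile with a $K$-component Gaussian
mixture: $\pi \sim \mathrm{Dir}(1/K, \ldots)$, $z_g \sim \pi$,
$y_{gs} \mid z_g = k \sim N(\theta_{c(s),k}, \sigma^2)$, labels
marginalized. With large $K$ and the sparse Dirichlet prior this
approximates a Dirichlet-process mixture that picks its own number of
clusters. The MAP is found by EM with the truncated Dirichlet weight
update $\pi_k \propto \max(N_k + 1/K - 1, 0)$: components whose effective
count falls below $1 - 1/K$ are annihilated, and an even split of one data
cluster across duplicates is an unstable fixed point, so surplus
components die. We deliberately do not use direct gradient ascent on the
constrained-scale MAP: for Dirichlet concentration below 1 that density is
unbounded at the simplex boundary, and in our experiments a quasi-Newton
ascent reliably fell into the degenerate ravine. A backward merge phase
(merge the closest pair of surviving components, re-run EM, accept while
the BIC improves; `merge = TRUE`) guards against the residual failure mode
of one response pattern being carved into overlapping pieces. Input
profiles should be standardized per gene so cluster means share a scale;
note that standardizing *data that were not generated by this mixture*
creates amplitude jitter between genes of a common pattern, which the
model may legitimately resolve into sub-clusters — the merge phase is what
keeps the reported structure interpretable.

For a significant reQTL, each allele is assigned a pattern via
$y_{nc} \sim N\!\left(\tfrac{d_n}{2}\theta_{c,z_A} +
\tfrac{2-d_n}{2}\theta_{c,z_a},\, \sigma^2\right)$ with $(\theta,
\sigma^2)$ fixed from the mixture fit: dosage-2 homozygotes follow
pattern $z_A$, dosage-0 homozygotes $z_a$, heterozygotes the average; all
$K^2$ pairs are scored and an allele with no carriers is flagged and tied
to the other allele's cluster.

Per-condition effect profiles $\beta_c$ of significant reQTLs are
normalized by the entry with the largest absolute value (first index on
ties), so the peak effect is exactly 1, and clustered by k-means
(k-means++ seeding, best of 10 starts, default k = 9 — a presentation
choice, exposed as a flag).

## Splicing phenotypes

Intron excision ratios within an alternative-splicing cluster (ASC) are
$\psi = (\text{count} + 0.5)/(\text{ASC total} + 0.5\,n_\text{introns})$;
samples with no ASC reads are imputed to the intron's mean over other
samples; rows are z-scored and then rank-normalized. The normalization
axis after z-scoring is ambiguous in principle (within-sample across
introns vs per-intron across samples); both are implemented behind
`qn_axis`, defaulting to per-intron across samples for consistency with
the gene-expression pipeline. Splicing QTL mapping then treats each
intron as a phenotype with a 100 kb window around either junction end
(gene expression uses 1 Mb around the TSS; both windows inclusive,
1-based, strand ignored).

Splicing disruption is summarized by the entropy $h_c = -\sum_i \psi_{ci}
\log \psi_{ci}$ (nats) of each ASC's excision proportions per condition,
normalized by its mean across conditions and k-means clustered. Introns
with $\max_c \psi - \min_c \psi > 0.1$ (strict) are standardized,
clustered (k = 8) and classified by whether both/one/neither end matches
an annotated exon boundary, ignoring transcript structure; per-cluster
enrichment of cryptic (unannotated) ends is a one-sided hypergeometric
test against all other clusters.

## Replication without power confounding

To compare two sets of paired p-values (e.g. the same gene–SNP pairs
tested in two tissues), a four-component mixture

$$ (p_{i1}, p_{i2}) \sim \pi_{00} U U + \pi_{10} B(a_1,b_1) U +
   \pi_{01} U B(a_2,b_2) + \pi_{11} B(a_1,b_1) B(a_2,b_2) $$

with $a_j \in [0,1]$, $b_j \ge 1$ (so non-null components concentrate near
zero) is fit on a 100×100 grid of bin counts, density evaluated at bin
centers, by quasi-Newton with 5 random restarts (the surface is
multimodal). Sharing is summarized by the mutual information of the fitted
2×2 table, $\mathrm{MI} = \sum_{kj} \pi_{kj} \log \frac{\pi_{kj}}{\pi_k
\pi'_j}$ in nats, which controls for each study's power — unlike naive
replication rates. When both marginals are uniform the Beta(1,1)
components are non-identifiable from the null; mass can drift between
degenerate components without changing the fit, so only identifiable
summaries (MI, the null marginals) should be interpreted there.

## The synthetic-data generator

Because the original study's genotypes are restricted, all tests run on
synthetic data with known ground truth. The generator mirrors the study
conditions: 45 individuals, $C = 5$ ordered conditions, ~217 samples after
a few random dropouts, pedigree-structured genotypes by Mendelian gene
dropping with kinship equal to twice the pedigree kinship coefficients,
orthonormal latent factors with geometrically decreasing variances
(dominant confounders first), condition-mean profiles from a library of
six qualitative patterns (monotone down, up-then-down, up, down at low
dose, up at low dose, down-then-recover), planted marginal and
condition-specific SNP effects, beta-binomial allelic counts with
reference bias, and mixture-drawn p-value pairs. Every generator records
its seed and all planted parameters; the same seed reproduces the data
bit for bit. What the generator does *not* emulate: linkage
disequilibrium beyond pedigree transmission, read-level noise (counts are
drawn at the model level), library-size variation, and non-Gaussian
expression tails — so passing tests demonstrate correctness of the
statistical machinery under its own assumptions, not robustness to every
artifact of real RNA-seq data.

## Numerical choices and problem sizes

Tolerances: factor-model convergence at $10^{-8}$ relative objective
change; eigenvalues in $[-10^{-8}, 0)$ clipped to zero; nested
log-likelihood ordering enforced up to $10^{-4}$ with small negatives
clamped; mixture EM tolerance $10^{-13}$ relative. Degenerate inputs:
constant phenotype rows are zeroed and flagged; constant dosages make a
pair untestable (flagged, not errored); singular designs raise an error
naming the collinear columns; all-homozygous allelic tables fit only
$(\mu, \gamma)$ and are flagged.

The test-suite and acceptance-script simulations use deliberately modest
sizes — e.g. 400 genes × 5 SNPs for the 2000-pair null calibration, 50
pure-null replicates of 15 genes × 2 SNPs for the bootstrap-FDR
calibration, 200 replicates for the combined-vs-total power comparison,
600 genes for factor recovery — chosen so the full statistical story runs
in minutes on one core while keeping Monte-Carlo error well inside the
asserted bands.

## Known limitations

Single-SNP tests only (no conditional or multi-SNP fine-mapping); the
trans analysis is the same machinery applied to a user-supplied SNP list.
The ASE model does not correct read-level reference bias (beyond $\mu$) or
double-counting across exonic SNPs. The bootstrap FDR estimator is a
plug-in, not an upper confidence bound. K (factors), k (k-means), and the
mixture truncation level are tuning parameters with stated defaults, not
estimated quantities.
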