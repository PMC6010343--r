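Package: respqtl
Title: Mapping Genetic Variants that Modulate Molecular Response to a
    Graded Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for response-QTL mapping in
    multi-condition molecular experiments with related individuals and
    repeat measures. Implements a two-step linear mixed model with
    latent confounding factors and kinship: step one learns factors,
    per-gene condition means and variance components jointly across
    genes; step two tests per gene-SNP nested models (no effect,
    marginal genotype effect, condition-specific genotype effect) by
    likelihood-ratio tests with eigendecomposition-accelerated
    likelihoods, Bonferroni/Benjamini-Hochberg control and a parametric
    bootstrap estimate of the true false discovery rate for interaction
    tests. Also provides a beta-binomial allele-specific expression
    model with combined total+allelic likelihood-ratio testing, a
    Dirichlet-regularized mixture model for clustering dose-response
    expression patterns with allele-to-cluster assignment, k-means
    clustering of normalized genotype effect-size profiles, splicing
    entropy profiles with cryptic-splice-site enrichment, a
    Uniform-by-Beta mixture over paired p-values with a
    mutual-information sharing statistic, and a synthetic-data
    generator (pedigree genotypes, confounded multi-condition
    expression, allelic counts, p-value pairs) with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
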