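# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# small multi-condition design: n_ind individuals x C conditions, complete
tiny_design <- function(n_ind = 6, C = 3) {
  d <- expand.grid(individual_id = paste0("ind", seq_len(n_ind)),
                   condition = seq_len(C), stringsAsFactors = FALSE)
  sample_design(sample_id = paste0(d$individual_id, "_c", d$condition),
                individual_id = d$individual_id, condition = d$condition)
}

# three-generation pedigree over 12 individuals: 6 founders, 3 sib pairs
tiny_pedigree <- function() {
  data.frame(
    id = paste0("ind", 1:12),
    father = c(rep(NA, 6), "ind1", "ind1", "ind3", "ind3", "ind5", "ind5"),
    mother = c(rep(NA, 6), "ind2", "ind2", "ind4", "ind4", "ind6", "ind6"),
    stringsAsFactors = FALSE)
}

# dosage matrix + positions for n unrelated individuals
tiny_genotypes <- function(n_ind = 6, n_snps = 8, seed = 11,
                           chrom = "chr1") {
  set.seed(seed)
  dos <- matrix(rbinom(n_snps * n_ind, 2, 0.4), n_snps, n_ind,
                dimnames = list(paste0("snp", seq_len(n_snps)),
                                paste0("ind", seq_len(n_ind))))
  genotype_data(dos,
                positions = data.frame(snp_id = rownames(dos),
                                       chrom = chrom,
                                       pos = seq(1e5, by = 5e4,
                                                 length.out = n_snps)),
                kinship = diag(n_ind))
}

# independent oracle: hypergeometric upper tail by direct summation
hyper_tail_bruteforce <- function(q, m, n, k) {
  # P(X >= q), X = #white drawn with k draws from m white + n black
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= q])
}

# independent oracle: Storey pi0 at lambda = 0.5
storey_pi0 <- function(p, lambda = 0.5) {
  min(1, mean(p > lambda) / (1 - lambda))
}

# dense-likelihood oracle for a mixed-model fit: maximize the exact MVN
# log-likelihood over (sigma_pi2, sigma_e2) by direct 2-d optimization with
# GLS fixed effects, no rotation trick
dense_fit_oracle <- function(y, X, Sigma_pi) {
  S <- length(y)
  nll <- function(lpar) {
    Sig <- exp(lpar[1]) * Sigma_pi + exp(lpar[2]) * diag(S)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Si <- chol2inv(ch)
    XtSi <- crossprod(X, Si)
    b <- solve(XtSi %*% X, XtSi %*% y)
    r <- y - X %*% b
    0.5 * (S * log(2 * pi) + 2 * sum(log(diag(ch))) +
             as.numeric(crossprod(r, Si %*% r)))
  }
  o <- optim(c(0, 0), nll, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-12))
  -o$value
}
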