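# Synthetic-data generators. Every generator takes an explicit seed and
# returns a `truth` component recording all planted parameters, so that
# parameter-recovery and calibration tests can compare estimates against
# ground truth. Defaults mirror the study shape: 45 individuals, C = 5
# ordered conditions, ~217 samples after light random dropout.

#' Pedigree kinship coefficients (recursive)
#'
#' Computes the matrix of kinship coefficients phi for a pedigree given as
#' id/father/mother (NA parents = founder), founders assumed unrelated and
#' non-inbred. The expected genetic covariance used in the mixed models is
#' `2 * phi`.
#'
#' @param pedigree data frame with columns `id`, `father`, `mother`.
#' @return kinship coefficient matrix (individuals x individuals).
#' @export
pedigree_kinship <- function(pedigree) {
  ids <- as.character(pedigree$id)
  fa <- as.character(pedigree$father)
  mo <- as.character(pedigree$mother)
  n <- length(ids)
  # topological order: parents before children; detects cycles
  placed <- character(0)
  remaining <- seq_len(n)
  order_idx <- integer(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(fa[i]) || fa[i] %in% placed) &&
        (is.na(mo[i]) || mo[i] %in% placed)
    }, logical(1))]
    if (!length(ready))
      stop_respqtl("pedigree contains a cycle or missing parent",
                   "respqtl_pedigree_cycle")
    order_idx <- c(order_idx, ready)
    placed <- c(placed, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (pos in seq_along(order_idx)) {
    i <- order_idx[pos]
    founder <- is.na(fa[i]) && is.na(mo[i])
    if (founder) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 + 0.5 * phi[fa[i], mo[i]]
    }
    if (pos > 1) {
      for (j in order_idx[seq_len(pos - 1)]) {
        v <- 0
        if (!is.na(fa[i])) v <- v + 0.5 * phi[fa[i], ids[j]]
        if (!is.na(mo[i])) v <- v + 0.5 * phi[mo[i], ids[j]]
        phi[i, j] <- phi[j, i] <- v
      }
    }
  }
  phi
}

#' Simulate pedigree-structured genotypes
#'
#' Founder haplotypes are drawn per SNP at a MAF sampled uniformly from
#' `maf_range`; descendants receive alleles by Mendelian gene dropping
#' (independent per SNP). The returned kinship is twice the pedigree
#' kinship coefficient matrix.
#'
#' @param n_founders number of founders when `pedigree` is `NULL`
#'   (unrelated panel).
#' @param pedigree optional data frame `id`, `father`, `mother` (NA =
#'   founder); overrides `n_founders`.
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param chrom chromosome label for all SNPs.
#' @param seed integer RNG seed.
#' @return list: `genotypes` ([genotype_data()]), `truth` (MAFs, pedigree,
#'   seed).
#' @export
simulate_genotypes <- function(n_founders = 45, pedigree = NULL,
                               n_snps = 100, maf_range = c(0.1, 0.5),
                               chrom = "chr1", seed = 1) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)
  if (is.null(pedigree)) {
    pedigree <- data.frame(id = paste0("ind", seq_len(n_founders)),
                           father = NA_character_, mother = NA_character_,
                           stringsAsFactors = FALSE)
  }
  phi <- pedigree_kinship(pedigree)  # also validates acyclicity
  ids <- rownames(phi)
  n <- length(ids)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  hap1 <- hap2 <- matrix(NA_integer_, n_snps, n,
                         dimnames = list(NULL, ids))
  fa <- as.character(pedigree$father)[match(ids, pedigree$id)]
  mo <- as.character(pedigree$mother)[match(ids, pedigree$id)]
  # process in pedigree order (parents first, guaranteed by kinship pass)
  done <- character(0)
  queue <- ids
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ii <- match(i, ids)
    if (is.na(fa[ii]) && is.na(mo[ii])) {
      hap1[, i] <- stats::rbinom(n_snps, 1, maf)
      hap2[, i] <- stats::rbinom(n_snps, 1, maf)
    } else if (fa[ii] %in% done && mo[ii] %in% done) {
      pick1 <- stats::rbinom(n_snps, 1, 0.5)
      pick2 <- stats::rbinom(n_snps, 1, 0.5)
      hap1[, i] <- ifelse(pick1 == 1, hap1[, fa[ii]], hap2[, fa[ii]])
      hap2[, i] <- ifelse(pick2 == 1, hap1[, mo[ii]], hap2[, mo[ii]])
    } else {
      queue <- c(queue, i)
      next
    }
    done <- c(done, i)
  }
  dos <- hap1 + hap2
  snp_ids <- paste0("snp", seq_len(n_snps))
  rownames(dos) <- snp_ids
  pos <- data.frame(snp_id = snp_ids, chrom = chrom,
                    pos = sort(sample.int(2e8, n_snps)),
                    stringsAsFactors = FALSE)
  g <- genotype_data(dos, pos, kinship = 2 * phi)
  list(genotypes = g,
       truth = list(maf = maf, pedigree = pedigree, seed = seed))
}

# Built-in library of qualitative condition-mean response patterns for C
# conditions (monotone down, up-then-down, monotone up, down at low doses
# only, up at low doses only, down-then-recover).
response_pattern_library <- function(C, amplitude = 1) {
  t <- seq(0, 1, length.out = C)
  pats <- rbind(
    down        = -t,
    up_down     = sin(pi * t) - t,
    up          = t,
    down_low    = -exp(-3 * t) + exp(-3),
    up_low      = exp(-3 * t) - exp(-3),
    down_recover = -sin(pi * t))
  amplitude * pats
}

#' Simulate multi-condition expression with confounding and planted QTLs
#'
#' Draws each gene's sample vector from the multivariate normal implied by
#' the factor model: mean `V v_g + effect * d`, covariance
#' `sum_k sigma_k^2 x_k x_k' + sigma_u^2 U + sigma_xi^2 Sigma +
#' sigma_e^2 I`, with orthonormal latent factors `x` fixed per dataset and
#' geometrically decreasing factor variances (dominant confounders first).
#' Condition-mean profiles come from a small pattern library; pattern
#' labels are kept as clustering ground truth.
#'
#' @param genotypes a [genotype_data()] (used for kinship and planted SNP
#'   dosages).
#' @param design a [sample_design()] whose individuals appear in
#'   `genotypes`.
#' @param n_genes number of genes.
#' @param K number of latent factors to plant (0 allowed).
#' @param variances list with `sigma_k2` (length K), `sigma_u2`,
#'   `sigma_xi2`, `sigma_e2`.
#' @param effects optional data frame: `gene` (index), `snp_id`, and either
#'   `beta` (marginal) or columns `beta_c1..beta_cC` (condition-specific).
#' @param pattern_amplitude scale of the condition-mean patterns (0 = flat
#'   means).
#' @param seed integer RNG seed.
#' @return list: `expr` ([expr_matrix()], `quantile_normal`-scale values as
#'   generated, i.e. unit-variance-ish Gaussians), `truth` (factors,
#'   variances, pattern assignment `z`, effects, assembled covariance).
#' @export
simulate_expression <- function(genotypes, design, n_genes = 500, K = 2,
                                variances = list(sigma_k2 = NULL,
                                                 sigma_u2 = 0.2,
                                                 sigma_xi2 = 0.2,
                                                 sigma_e2 = 1),
                                effects = NULL, pattern_amplitude = 1,
                                seed = 1) {
  set.seed(seed)
  S <- nrow(design)
  C <- n_conditions(design)
  if (is.null(variances$sigma_k2))
    variances$sigma_k2 <- if (K > 0) 2 * 0.5 ^ (seq_len(K) - 1) else numeric(0)
  stopifnot(length(variances$sigma_k2) == K)
  U <- individual_matrix(design)
  Kin <- genotypes$kinship[design$individual_id, design$individual_id]
  V <- condition_matrix(design)
  x <- if (K > 0) qr.Q(qr(matrix(stats::rnorm(S * K), S, K))) else
    matrix(0, S, 0)
  Sigma <- variances$sigma_u2 * U + variances$sigma_xi2 * Kin +
    variances$sigma_e2 * diag(S)
  if (K > 0)
    Sigma <- Sigma + x %*% (variances$sigma_k2 * t(x))
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_respqtl("assembled covariance is not PSD", "respqtl_invalid_covariance")
  L <- chol((Sigma + t(Sigma)) / 2)

  pats <- response_pattern_library(C, pattern_amplitude)
  z <- sample.int(nrow(pats), n_genes, replace = TRUE)
  means <- V %*% t(pats[z, , drop = FALSE])  # S x n_genes

  beta_c <- matrix(0, n_genes, C)
  planted_snp <- rep(NA_character_, n_genes)
  if (!is.null(effects)) {
    bcols <- paste0("beta_c", seq_len(C))
    for (r in seq_len(nrow(effects))) {
      gi <- effects$gene[r]
      snp <- effects$snp_id[r]
      planted_snp[gi] <- snp
      bc <- if (all(bcols %in% names(effects)))
        as.numeric(effects[r, bcols]) else rep(effects$beta[r], C)
      beta_c[gi, ] <- bc
      d_samp <- genotypes$dosages[snp, design$individual_id]
      means[, gi] <- means[, gi] + bc[design$condition] * d_samp
    }
  }
  Y <- means + t(L) %*% matrix(stats::rnorm(S * n_genes), S, n_genes)
  Y <- t(Y)  # genes x samples
  dimnames(Y) <- list(paste0("gene", seq_len(n_genes)), design$sample_id)
  # values are Gaussian by construction; the state marks them ready for the
  # mixed-model tests (which assume per-gene Gaussian phenotypes)
  list(expr = expr_matrix(Y, "quantile_normal"),
       truth = list(x = x, variances = variances, z = z,
                    patterns = pats, beta_c = beta_c,
                    snp = planted_snp, Sigma = Sigma, seed = seed))
}

# Beta-binomial sampler in mean/concentration parameterization.
rbetabinom_mu <- function(n, size, p, gamma) {
  pr <- stats::rbeta(n, p * gamma, (1 - p) * gamma)
  stats::rbinom(n, size, pr)
}

#' Simulate phased allelic counts under the beta-binomial ASE model
#'
#' Alt counts are drawn `BB(r, plogis(mu + phase * beta_c), gamma)`: `mu`
#' is the reference-bias intercept, `beta_c` the per-condition allelic
#' effect of the regulatory SNP, `gamma` the concentration, and `phase` the
#' phased heterozygosity (0 for regulatory-SNP homozygotes).
#'
#' @param design a [sample_design()].
#' @param n_exonic_snps exonic SNPs per gene.
#' @param coverage mean read coverage per (sample, exonic SNP); totals are
#'   Poisson with this mean.
#' @param mu intercept (logit scale).
#' @param beta_c numeric length C (or scalar, recycled): allelic effect per
#'   condition.
#' @param gamma beta-binomial concentration (> 0).
#' @param phase_probs probabilities of phase -1, 0, +1 per individual.
#' @param gene gene id label.
#' @param seed integer RNG seed.
#' @return list: `table` ([allelic_count_table()]), `truth`.
#' @export
simulate_allelic_counts <- function(design, n_exonic_snps = 2, coverage = 50,
                                    mu = 0, beta_c = 0, gamma = 30,
                                    phase_probs = c(0.25, 0.5, 0.25),
                                    gene = "gene1", seed = 1) {
  stopifnot(gamma > 0)
  set.seed(seed)
  C <- n_conditions(design)
  beta_c <- rep(beta_c, length.out = C)
  inds <- unique(design$individual_id)
  phase_ind <- sample(c(-1L, 0L, 1L), length(inds), replace = TRUE,
                      prob = phase_probs)
  names(phase_ind) <- inds
  rows <- do.call(rbind, lapply(seq_len(n_exonic_snps), function(k) {
    data.frame(gene = gene, exonic_snp = paste0("esnp", k),
               individual = design$individual_id,
               condition = design$condition,
               stringsAsFactors = FALSE)
  }))
  rows$phase <- phase_ind[rows$individual]
  rows$total <- stats::rpois(nrow(rows), coverage)
  p <- stats::plogis(mu + rows$phase * beta_c[rows$condition])
  rows$alt <- rbetabinom_mu(nrow(rows), rows$total, p, gamma)
  tab <- allelic_count_table(rows$gene, rows$exonic_snp, rows$individual,
                             rows$condition, rows$alt, rows$total,
                             rows$phase)
  list(table = tab,
       truth = list(mu = mu, beta_c = beta_c, gamma = gamma,
                    phase = phase_ind, seed = seed))
}

#' Simulate paired p-values from the four-component overlap mixture
#'
#' Each pair is drawn from one of four components chosen with weights
#' `pi = (pi00, pi10, pi01, pi11)`: a coordinate is Uniform(0,1) when its
#' study is null for that component and Beta(aj, bj) when non-null.
#'
#' @param pi length-4 nonnegative weights summing to 1, ordered
#'   (00, 10, 01, 11).
#' @param a1,b1,a2,b2 Beta hyperparameters with `a in [0, 1]`, `b >= 1`.
#' @param n number of pairs.
#' @param seed integer RNG seed.
#' @return list: `p1`, `p2` (length-n vectors), `truth` (component labels
#'   and parameters).
#' @export
simulate_pvalue_pairs <- function(pi, a1 = 0.5, b1 = 10, a2 = 0.5, b2 = 10,
                                  n = 1000, seed = 1) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop_respqtl("pi must be a length-4 simplex vector",
                 "respqtl_invalid_mixture")
  if (a1 < 0 || a1 > 1 || a2 < 0 || a2 > 1 || b1 < 1 || b2 < 1)
    stop_respqtl("need a in [0,1] and b >= 1", "respqtl_invalid_mixture")
  set.seed(seed)
  comp <- sample.int(4, n, replace = TRUE, prob = pi)
  nn1 <- comp %in% c(2, 4)  # study-1 non-null: components 10, 11
  nn2 <- comp %in% c(3, 4)
  p1 <- ifelse(nn1, stats::rbeta(n, a1, b1), stats::runif(n))
  p2 <- ifelse(nn2, stats::rbeta(n, a2, b2), stats::runif(n))
  list(p1 = p1, p2 = p2,
       truth = list(component = comp, pi = pi, a1 = a1, b1 = b1, a2 = a2,
                    b2 = b2, seed = seed))
}

#' Default study-shaped design
#'
#' A convenience constructor mirroring the study's shape: `n_ind`
#' individuals by `C` ordered conditions, with `dropout` samples removed at
#' random (emulating QC loss).
#'
#' @param n_ind number of individuals.
#' @param C number of conditions.
#' @param dropout number of individual-condition pairs dropped.
#' @param seed integer RNG seed.
#' @return a [sample_design()].
#' @export
study_design <- function(n_ind = 45, C = 5, dropout = 8, seed = 1) {
  set.seed(seed)
  d <- expand.grid(individual_id = paste0("ind", seq_len(n_ind)),
                   condition = seq_len(C), stringsAsFactors = FALSE)
  if (dropout > 0) d <- d[-sample.int(nrow(d), dropout), ]
  sample_design(sample_id = paste0(d$individual_id, "_c", d$condition),
                individual_id = d$individual_id, condition = d$condition)
}
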