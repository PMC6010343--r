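# Step 2 of the response-QTL mixed model: per gene-SNP nested model fits
# with covariance sigma_pi^2 * Sigma_pi + sigma_e^2 * I, likelihood-ratio
# tests, Bonferroni/BH control and the parametric-bootstrap FDR estimate
# for interaction (response) tests.
#
# All likelihoods are evaluated in the basis of the eigenvectors Q of
# Sigma_pi: there the covariance is diagonal, sigma_pi^2 * (Lambda + delta)
# with delta = sigma_e^2 / sigma_pi^2, so each evaluation is O(S) after a
# one-off rotation. The variance ratio delta is profiled on a log-spaced
# grid refined by golden-section search; sigma_pi^2 then has a closed-form
# ML solution and the fixed effects are weighted least squares.

# Weighted-least-squares profile log-likelihood at one delta.
wls_profile <- function(yt, Xt, lam, delta) {
  w <- lam + delta
  sw <- 1 / sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xt)) return(NULL)
  b <- qr.coef(qrX, yw)
  r <- yw - Xw %*% b
  rss <- sum(r ^ 2)
  S <- length(yt)
  s2 <- rss / S
  ll <- -0.5 * (S * log(2 * pi * s2) + sum(log(w)) + S)
  list(ll = ll, beta = as.numeric(b), sigma_pi2 = s2, rss = rss, qrX = qrX)
}

# Profile the variance ratio over a log grid plus golden-section refinement.
fit_rotated <- function(yt, Xt, lam, grid_n = 64,
                        grid_range = c(1e-5, 1e5)) {
  if (qr(Xt)$rank < ncol(Xt)) {
    cn <- colnames(Xt)
    stop_respqtl(paste0("singular design; collinear columns among: ",
                        paste(cn, collapse = ",")),
                 "respqtl_singular_design")
  }
  lgrid <- seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_n)
  lls <- vapply(lgrid, function(ld) {
    f <- wls_profile(yt, Xt, lam, exp(ld))
    if (is.null(f)) -Inf else f$ll
  }, numeric(1))
  i <- which.max(lls)
  lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(grid_n, i + 1)]
  opt <- stats::optimize(function(ld) wls_profile(yt, Xt, lam, exp(ld))$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  f <- wls_profile(yt, Xt, lam, delta)
  # GLS covariance of the fixed effects for standard errors
  Rq <- qr.R(f$qrX)
  XtX_inv <- chol2inv(Rq)
  se <- sqrt(pmax(diag(XtX_inv), 0) * f$sigma_pi2)
  list(beta = f$beta, se = se, sigma_pi2 = f$sigma_pi2,
       sigma_e2 = delta * f$sigma_pi2, delta = delta, loglik = f$ll)
}

# Build the rotated fixed-effect design for one model id.
model_design <- function(model, Vt, dt, dVt) {
  switch(as.character(model),
         "0" = Vt,
         "1" = cbind(Vt, d = dt),
         "2" = cbind(Vt, dVt),
         stop_respqtl("model must be 0, 1 or 2", "respqtl_invalid_model"))
}

#' Precompute the rotated test context for a design
#'
#' Rotates the condition design into the eigenbasis of `Sigma_pi` once, so
#' that repeated per-gene-SNP fits are cheap.
#'
#' @param decomp a [build_sigma_pi()] decomposition.
#' @param design the [sample_design()] used to fit the factor model.
#' @return list with `Qt`, `Vt`, `lam`, `design`.
#' @export
qtl_context <- function(decomp, design) {
  stopifnot(inherits(decomp, "covariance_decomposition"))
  Qt <- t(decomp$vectors)
  V <- condition_matrix(design)
  list(Qt = Qt, Vt = Qt %*% V, lam = decomp$values, design = design,
       C = n_conditions(design))
}

#' Fit one nested mixed model for a gene-SNP pair
#'
#' Model 0: condition means only (SNP-independent, fit once per gene).
#' Model 1: adds a marginal genotype-dosage effect `beta`. Model 2: adds a
#' condition-specific genotype effect `beta_c` (genotype x condition
#' interaction). The covariance is `sigma_pi^2 Sigma_pi + sigma_e^2 I`,
#' refit for every model.
#'
#' @param y phenotype vector over samples (quantile-normalized).
#' @param dosage dosage per sample (mean-imputed; expanded from
#'   individuals), ignored for model 0.
#' @param ctx a [qtl_context()].
#' @param model 0, 1 or 2.
#' @return A `model_fit`: list with `model`, `beta` (all fixed effects,
#'   condition means first), `se`, `sigma_pi2`, `sigma_e2`, `loglik`,
#'   `untestable` flag (constant dosage for models 1/2).
#' @export
fit_gene_snp <- function(y, dosage = NULL, ctx, model) {
  yt <- as.numeric(ctx$Qt %*% y)
  if (model == 0) {
    f <- fit_rotated(yt, ctx$Vt, ctx$lam)
    return(structure(c(f, list(model = 0L, untestable = FALSE)),
                     class = "model_fit"))
  }
  stopifnot(!is.null(dosage))
  if (max(dosage) - min(dosage) == 0) {
    return(structure(list(model = as.integer(model), untestable = TRUE,
                          loglik = NA_real_), class = "model_fit"))
  }
  dt <- as.numeric(ctx$Qt %*% dosage)
  dVt <- NULL
  if (model == 2) {
    V <- condition_matrix(ctx$design)
    dV <- V * dosage
    colnames(dV) <- paste0("d_c", seq_len(ncol(V)))
    dVt <- ctx$Qt %*% dV
  }
  Xt <- model_design(model, ctx$Vt, dt, dVt)
  f <- fit_rotated(yt, Xt, ctx$lam)
  structure(c(f, list(model = as.integer(model), untestable = FALSE)),
            class = "model_fit")
}

#' Likelihood-ratio tests comparing the three nested models
#'
#' Marginal: Model 1 vs 0, df 1. Response (interaction): Model 2 vs 1,
#' df C - 1. Combined (any genotype effect): Model 2 vs 0, df C. Negative
#' likelihood-ratio statistics (optimizer noise) are clamped to zero;
#' clamping beyond 1e-4 is flagged via warning.
#'
#' @param fit0,fit1,fit2 `model_fit` objects for models 0, 1, 2 on the
#'   same data.
#' @param C number of conditions.
#' @return list with `lr_marginal`, `p_marginal`, `lr_response`,
#'   `p_response`, `lr_combined`, `p_combined`, `df` (named vector).
#' @export
likelihood_ratio_tests <- function(fit0, fit1, fit2, C) {
  if (is.null(fit0) || is.null(fit1) || is.null(fit2))
    stop_respqtl("all three model fits are required", "respqtl_missing_fit")
  lr <- c(marginal = 2 * (fit1$loglik - fit0$loglik),
          response = 2 * (fit2$loglik - fit1$loglik),
          combined = 2 * (fit2$loglik - fit0$loglik))
  if (any(lr < -1e-4, na.rm = TRUE))
    warning(sprintf("nested log-likelihood ordering violated by %.3g",
                    -min(lr, na.rm = TRUE)))
  lr <- pmax(lr, 0)
  df <- c(marginal = 1, response = C - 1, combined = C)
  p <- stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr_marginal = lr[["marginal"]], p_marginal = p[["marginal"]],
       lr_response = lr[["response"]], p_response = p[["response"]],
       lr_combined = lr[["combined"]], p_combined = p[["combined"]],
       df = df)
}

#' Map QTLs for a set of genes against their cis SNPs
#'
#' For each gene: Model 0 fit once; Models 1 and 2 fit per cis SNP;
#' marginal, response and combined LRT p-values reported per pair.
#'
#' @param expr [expr_matrix()] in `quantile_normal` state.
#' @param genotypes [genotype_data()] with complete dosages (see
#'   [impute_dosages()]).
#' @param design [sample_design()].
#' @param decomp [build_sigma_pi()] decomposition.
#' @param cis named list: for each gene id, the character vector of SNP ids
#'   to test (e.g. from [select_cis_snps()]); genes with no SNPs are
#'   skipped.
#' @return data frame: gene, snp, chrom, pos, beta (marginal), beta_c
#'   columns, lr/p for the three tests.
#' @export
map_qtl <- function(expr, genotypes, design, decomp, cis) {
  ctx <- qtl_context(decomp, design)
  C <- ctx$C
  out <- list()
  for (gene in names(cis)) {
    snps <- cis[[gene]]
    if (!length(snps)) next
    y <- expr$values[gene, ]
    fit0 <- fit_gene_snp(y, NULL, ctx, 0)
    for (snp in snps) {
      d <- genotypes$dosages[snp, design$individual_id]
      fit1 <- fit_gene_snp(y, d, ctx, 1)
      fit2 <- fit_gene_snp(y, d, ctx, 2)
      if (isTRUE(fit1$untestable) || isTRUE(fit2$untestable)) next
      lrt <- likelihood_ratio_tests(fit0, fit1, fit2, C)
      pos <- genotypes$positions[match(snp, genotypes$positions$snp_id), ]
      bc <- fit2$beta[C + seq_len(C)]
      row <- data.frame(gene = gene, snp = snp, chrom = pos$chrom,
                        pos = pos$pos,
                        beta = fit1$beta[C + 1],
                        lr_marginal = lrt$lr_marginal,
                        p_marginal = lrt$p_marginal,
                        lr_response = lrt$lr_response,
                        p_response = lrt$p_response,
                        lr_combined = lrt$lr_combined,
                        p_combined = lrt$p_combined,
                        stringsAsFactors = FALSE)
      row[paste0("beta_c", seq_len(C))] <- as.list(bc)
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Gene-level significance: Bonferroni within gene, BH across genes
#'
#' Per gene, the minimum p across its SNPs is Bonferroni-corrected by the
#' number of SNPs tested for that gene (capped at 1) and the lead SNP is
#' the argmin (ties broken by smallest genomic position); BH is then
#' applied across genes to the Bonferroni p-values.
#'
#' @param results data frame with columns `gene`, `snp`, `pos`, and the
#'   p-value column named by `p_col`.
#' @param p_col which p-value column to control (e.g. `"p_response"`).
#' @return data frame: gene, lead_snp, n_snps, p_lead, bonf_p, q_value.
#' @export
gene_level_significance <- function(results, p_col = "p_response") {
  stopifnot(p_col %in% names(results))
  sp <- split(results, results$gene)
  rows <- lapply(sp, function(d) {
    p <- d[[p_col]]
    best <- which(p == min(p))
    if (length(best) > 1) best <- best[which.min(d$pos[best])]
    data.frame(gene = d$gene[1], lead_snp = d$snp[best],
               n_snps = nrow(d), p_lead = p[best],
               bonf_p = min(1, nrow(d) * p[best]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$bonf_p, method = "BH")
  out
}

# BH rejection threshold on a p-value vector at level alpha: the largest
# p_(i) with p_(i) <= i/n * alpha (0 if none).
bh_threshold <- function(p, alpha) {
  n <- length(p)
  ps <- sort(p)
  ok <- ps <= seq_len(n) / n * alpha
  if (!any(ok)) 0 else ps[max(which(ok))]
}

#' Parametric-bootstrap estimate of the true FDR for response-QTL calls
#'
#' The asymptotic chi-square null for the interaction LRT is
#' anti-conservative at finite sample size (variances are estimated), and
#' no valid permutation scheme exists for interaction effects. This
#' routine therefore simulates expression from each gene's fitted Model 1
#' (marginal effect of the lead SNP, no interaction), refits Models 1 and
#' 2 for all of the gene's SNPs on the simulated data, and applies the
#' identical LRT + per-gene Bonferroni pipeline, pooling the resulting
#' per-gene null p-values across genes and replicates. The estimated true
#' FDR of the real discovery set at `nominal_fdr` is the plug-in
#'
#'   mean bootstrap count of per-gene p below the BH threshold,
#'   scaled to the number of genes, divided by the real discovery count,
#'
#' capped at 1.
#'
#' @param expr,genotypes,design,decomp,cis as in [map_qtl()].
#' @param n_boot bootstrap replicates per gene (>= 1).
#' @param nominal_fdr nominal BH level defining the discovery set.
#' @param seed integer RNG seed.
#' @return list: `estimated_fdr` (`NA` if there are no discoveries),
#'   `n_discoveries`, `bh_cut` (per-gene Bonferroni p threshold),
#'   `null_bonf_p` (pooled bootstrap per-gene p-values), `gene_table`
#'   (real-data gene-level results).
#' @export
parametric_bootstrap_fdr <- function(expr, genotypes, design, decomp, cis,
                                     n_boot = 10, nominal_fdr = 0.05,
                                     seed = 1) {
  if (n_boot < 1)
    stop_respqtl("n_boot must be >= 1", "respqtl_invalid_bootstrap")
  set.seed(seed)
  res <- map_qtl(expr, genotypes, design, decomp, cis)
  gl <- gene_level_significance(res, "p_response")
  n_disc <- sum(gl$q_value <= nominal_fdr)
  cut <- bh_threshold(gl$bonf_p, nominal_fdr)
  ctx <- qtl_context(decomp, design)
  C <- ctx$C
  null_p <- numeric(0)
  for (gene in gl$gene) {
    snps <- cis[[gene]]
    y <- expr$values[gene, ]
    lead <- gl$lead_snp[gl$gene == gene]
    d_lead <- genotypes$dosages[lead, design$individual_id]
    f1 <- fit_gene_snp(y, d_lead, ctx, 1)
    # simulate in the rotated basis: mean X1 b1, diagonal covariance
    dt <- as.numeric(ctx$Qt %*% d_lead)
    X1t <- cbind(ctx$Vt, d = dt)
    mean_t <- as.numeric(X1t %*% f1$beta)
    sd_t <- sqrt(f1$sigma_pi2 * ctx$lam + f1$sigma_e2)
    dts <- lapply(snps, function(s)
      as.numeric(ctx$Qt %*% genotypes$dosages[s, design$individual_id]))
    dVts <- lapply(snps, function(s) {
      V <- condition_matrix(design)
      dV <- V * genotypes$dosages[s, design$individual_id]
      colnames(dV) <- paste0("d_c", seq_len(C))
      ctx$Qt %*% dV
    })
    for (b in seq_len(n_boot)) {
      yt_star <- mean_t + stats::rnorm(length(mean_t), sd = sd_t)
      pvals <- vapply(seq_along(snps), function(i) {
        f1b <- fit_rotated(yt_star, cbind(ctx$Vt, d = dts[[i]]), ctx$lam)
        f2b <- fit_rotated(yt_star, cbind(ctx$Vt, dVts[[i]]), ctx$lam)
        lr <- max(0, 2 * (f2b$loglik - f1b$loglik))
        stats::pchisq(lr, C - 1, lower.tail = FALSE)
      }, numeric(1))
      null_p <- c(null_p, min(1, length(snps) * min(pvals)))
    }
  }
  est <- if (n_disc == 0) NA_real_ else
    min(1, (sum(null_p <= cut) / n_boot) / n_disc)
  list(estimated_fdr = est, n_discoveries = n_disc, bh_cut = cut,
       null_bonf_p = null_p, gene_table = gl)
}
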