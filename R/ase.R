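# Allele-specific expression: beta-binomial GLM on phased allelic counts,
# and combination of the allelic and total-expression likelihood ratios
# into one chi-square test.
#
# Model, for exonic SNP k of a gene in individual n at condition c:
#   y_nkc | r_nkc ~ BB(r_nkc, plogis(mu + phase_nk * beta_c), gamma)
# mu absorbs reference mapping bias, gamma is the per-gene concentration
# (inverse overdispersion; pseudo-counts a = p*gamma, b = (1-p)*gamma),
# and phase in {-1, 0, +1} is the phased heterozygosity of the regulatory
# SNP (0 = homozygous; those rows still inform mu and gamma). gamma gets a
# Gamma(1.001, 0.001) shape-rate prior (mean ~ 1001, essentially flat but
# keeping gamma away from 0).

#' Beta-binomial log-density, mean/concentration parameterization
#'
#' `BB(n, p, gamma)` with pseudo-counts `a = p * gamma`,
#' `b = (1 - p) * gamma`.
#'
#' @param y successes, `0 <= y <= n`.
#' @param n totals.
#' @param p mean in (0, 1).
#' @param gamma concentration (> 0).
#' @return log-density vector.
#' @export
dbetabinom_mu <- function(y, n, p, gamma) {
  a <- p * gamma
  b <- (1 - p) * gamma
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

# Penalized negative log-likelihood for the ASE model.
# par = (mu, beta over estimable conditions or single beta, log gamma).
ase_negll <- function(par, tab, cond_map, n_beta) {
  mu <- par[1]
  betas <- if (n_beta > 0) par[1 + seq_len(n_beta)] else numeric(0)
  lg <- par[length(par)]
  gamma <- exp(lg)
  eta <- mu + if (n_beta > 0) tab$phase * betas[cond_map] else 0
  p <- stats::plogis(eta)
  ll <- sum(dbetabinom_mu(tab$alt, tab$total, p, gamma)) +
    stats::dgamma(gamma, shape = 1.001, rate = 0.001, log = TRUE)
  -ll
}

#' Fit the beta-binomial allelic model for one gene x regulatory SNP
#'
#' Maximizes the beta-binomial log-likelihood plus the Gamma(1.001, 0.001)
#' log-prior on the concentration, by quasi-Newton (BFGS) on
#' `(mu, beta, log gamma)`. Three hypotheses:
#' * `"null0"`: no allelic effect (mu, gamma only);
#' * `"null"`: constant allelic effect, `beta_c = beta` for all c;
#' * `"alt"`: free per-condition `beta_c`.
#'
#' Conditions with no allelic reads among phase != 0 rows carry no
#' `beta_c`; they are dropped and the test degrees of freedom reduce
#' accordingly. If all rows have phase 0 the effect is unidentifiable:
#' only (mu, gamma) are fit and the result is flagged.
#'
#' @param table an [allelic_count_table()] restricted to one gene and one
#'   regulatory SNP's phases.
#' @param hypothesis `"null0"`, `"null"` or `"alt"`.
#' @param C number of conditions in the study.
#' @return An `ase_fit`: list with `mu`, `beta` (per estimable condition
#'   for `"alt"`, scalar for `"null"`, `NULL` for `"null0"`), `gamma`,
#'   `loglik` (penalized), `estimable_conditions`, `n_beta`,
#'   `identifiable`.
#' @export
fit_allelic_model <- function(table, hypothesis = c("alt", "null", "null0"),
                              C = max(table$condition)) {
  hypothesis <- match.arg(hypothesis)
  tab <- table[table$total > 0, , drop = FALSE]
  if (!nrow(tab))
    stop_respqtl("no allelic reads", "respqtl_invalid_counts")
  het <- tab$phase != 0
  estimable <- sort(unique(tab$condition[het & tab$total > 0]))
  identifiable <- length(estimable) > 0
  if (!identifiable) hypothesis <- "null0"
  n_beta <- switch(hypothesis, null0 = 0L, null = 1L,
                   alt = length(estimable))
  cond_map <- switch(hypothesis,
                     null0 = rep(1L, nrow(tab)),
                     null = rep(1L, nrow(tab)),
                     alt = match(tab$condition, estimable))
  # rows in non-estimable conditions have phase 0 there, so cond_map NA is
  # harmless (phase multiplies it out); replace NA to keep arithmetic clean
  if (anyNA(cond_map)) cond_map[is.na(cond_map)] <- 1L
  par0 <- c(stats::qlogis(pmin(pmax(sum(tab$alt) / sum(tab$total), 0.05),
                               0.95)),
            rep(0, n_beta), log(30))
  opt <- stats::optim(par0, ase_negll, tab = tab, cond_map = cond_map,
                      n_beta = n_beta, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- if (n_beta > 0) opt$par[1 + seq_len(n_beta)] else NULL
  if (hypothesis == "alt" && !is.null(beta)) names(beta) <-
    paste0("c", estimable)
  structure(list(mu = opt$par[1], beta = beta,
                 gamma = exp(opt$par[length(opt$par)]),
                 loglik = -opt$value,
                 estimable_conditions = estimable,
                 n_beta = n_beta, hypothesis = hypothesis,
                 identifiable = identifiable),
            class = "ase_fit")
}

#' Allelic response likelihood ratio for one gene x regulatory SNP
#'
#' Fits the constant-effect null and the free-`beta_c` alternative and
#' returns the log likelihood ratio with its degrees of freedom
#' (`#estimable conditions - 1`).
#'
#' @inheritParams fit_allelic_model
#' @return list: `loglr` (`>= 0`), `df`, `fit_null`, `fit_alt`.
#' @export
ase_response_lrt <- function(table, C = max(table$condition)) {
  f0 <- fit_allelic_model(table, "null", C = C)
  f1 <- fit_allelic_model(table, "alt", C = C)
  if (!f1$identifiable)
    return(list(loglr = NA_real_, df = 0L, fit_null = f0, fit_alt = f1))
  list(loglr = max(0, f1$loglik - f0$loglik),
       df = length(f1$estimable_conditions) - 1L,
       fit_null = f0, fit_alt = f1)
}

#' Eligibility of a gene x regulatory SNP pair for the two test components
#'
#' The total-expression component requires at least `min_alt_alleles`
#' (default 5) alternative alleles of the regulatory SNP among the
#' phenotyped individuals; the allele-specific component requires at least
#' `min_allelic_reads` (default 2000) supporting allelic reads for the
#' gene. Both thresholds are inclusive.
#'
#' @param table [allelic_count_table()] rows for the gene.
#' @param dosages dosage vector of the regulatory SNP over phenotyped
#'   individuals.
#' @param min_alt_alleles,min_allelic_reads thresholds.
#' @return list: `fit_total`, `fit_ase` (logicals).
#' @export
ase_eligibility <- function(table, dosages, min_alt_alleles = 5,
                            min_allelic_reads = 2000) {
  list(fit_total = sum(dosages, na.rm = TRUE) >= min_alt_alleles,
       fit_ase = sum(table$total) >= min_allelic_reads)
}

#' Combine total-expression and allelic likelihood ratios
#'
#' Log likelihood ratios of independent components add, so twice the sum
#' is asymptotically chi-square with the summed degrees of freedom
#' (typically `(C-1) + (C-1) = 8` for a response test at C = 5). An absent
#' component contributes 0 to the statistic and 0 df; both absent is an
#' error.
#'
#' @param loglr_total,df_total total-expression component: log
#'   likelihood-ratio (i.e. the difference of maximized log-likelihoods,
#'   not yet doubled) and its df; `NULL`/`NA` if absent.
#' @param loglr_ase,df_ase allelic component, same convention.
#' @return list: `statistic` (twice the summed log LR), `df`, `p`.
#' @export
combine_likelihood_ratios <- function(loglr_total = NULL, df_total = 0,
                                      loglr_ase = NULL, df_ase = 0) {
  has_tot <- !is.null(loglr_total) && !is.na(loglr_total)
  has_ase <- !is.null(loglr_ase) && !is.na(loglr_ase)
  if (!has_tot && !has_ase)
    stop_respqtl("both components absent: pair untestable",
                 "respqtl_untestable")
  stat <- 2 * ((if (has_tot) loglr_total else 0) +
                 (if (has_ase) loglr_ase else 0))
  df <- (if (has_tot) df_total else 0) + (if (has_ase) df_ase else 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
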