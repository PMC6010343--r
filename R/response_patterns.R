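# Response-pattern machinery: a Dirichlet-regularized Gaussian mixture over
# per-gene dose-response profiles, assignment of reQTL major/minor alleles
# to the learned patterns, k-means clustering of normalized genotype
# effect-size profiles, and splicing entropy / cryptic-splice-site
# characterization.

# ---- mixture over response patterns ---------------------------------------
#
# Generative model with K components:
#   pi ~ Dir(1/K, ..., 1/K);  z_g ~ Discrete(pi)
#   y_gs | z_g = k ~ N(theta_{c(s),k}, sigma^2)
# The cluster labels z are marginalized and the MAP of (pi, theta, sigma)
# is found by EM with the Dirichlet-MAP weight update
# pi_k proportional to max(N_k + 1/K - 1, 0): components whose effective
# gene count drops below 1 - 1/K are annihilated, and an even split of one
# data cluster across duplicate components is an unstable fixed point, so
# with large K the surplus components die off and the model chooses its
# own effective number of clusters, approximating a Dirichlet process
# mixture. (A direct gradient ascent on the constrained-scale MAP is not
# well-posed here: for concentration < 1 the Dirichlet density is
# unbounded at the simplex boundary.)

# sufficient statistics per gene x condition
mixture_suffstats <- function(Y, design) {
  C <- n_conditions(design)
  G <- nrow(Y)
  M <- matrix(0, G, C)   # sum of y per condition
  Qc <- matrix(0, G, C)  # sum of y^2 per condition
  n_c <- integer(C)
  for (c in seq_len(C)) {
    idx <- which(design$condition == c)
    n_c[c] <- length(idx)
    M[, c] <- rowSums(Y[, idx, drop = FALSE])
    Qc[, c] <- rowSums(Y[, idx, drop = FALSE] ^ 2)
  }
  list(M = M, q_tot = rowSums(Qc), n_c = n_c, S = sum(n_c), G = G, C = C)
}

# Per-gene per-component log joint (up to the shared prior term) and
# squared distances, via the per-condition sufficient statistics.
mixture_loglik_parts <- function(ss, pi_alive, theta_alive, sigma2) {
  G <- ss$G
  Ka <- length(pi_alive)
  Q <- matrix(ss$q_tot, G, Ka) - 2 * ss$M %*% theta_alive +
    matrix(colSums(ss$n_c * theta_alive ^ 2), G, Ka, byrow = TRUE)
  L <- matrix(log(pi_alive), G, Ka, byrow = TRUE) -
    0.5 * ss$S * log(2 * pi * sigma2) - Q / (2 * sigma2)
  mx <- apply(L, 1, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  list(Q = Q, L = L, lse = lse)
}

# One EM run from a given state (pi, theta, sigma2, alive) to convergence.
# M-step weights use the truncated Dirichlet-MAP update; annihilated
# components stay dead. Returns the updated state plus the objective trace
# and a convergence flag.
run_mixture_em <- function(ss, st, a, maxit, tol) {
  G <- ss$G
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    ka <- which(st$alive)
    parts <- mixture_loglik_parts(ss, st$pi[ka],
                                  st$theta[, ka, drop = FALSE], st$sigma2)
    obj <- sum(parts$lse) + (a - 1) * sum(log(st$pi[ka]))
    trace <- c(trace, obj)
    R <- exp(parts$L - parts$lse)
    Nk <- colSums(R)
    w <- pmax(Nk + a - 1, 0)
    pruned <- any(w == 0)
    if (pruned) {
      dead <- ka[w == 0]
      st$alive[dead] <- FALSE
      st$pi[dead] <- 0
      st$theta[, dead] <- NA_real_
    }
    keep <- w > 0
    st$pi[ka[keep]] <- w[keep] / sum(w[keep])
    MR <- crossprod(ss$M, R)  # C x alive
    for (j in which(keep))
      st$theta[, ka[j]] <- MR[, j] / (ss$n_c * Nk[j])
    st$sigma2 <- sum(R * parts$Q) / (G * ss$S)
    if (it > 5 && !pruned &&
        abs(trace[it] - trace[it - 1]) < tol * abs(trace[it])) {
      converged <- TRUE
      break
    }
  }
  st$trace <- trace
  st$converged <- converged
  st
}

#' Fit the response-pattern mixture model
#'
#' Clusters genes by their dose-response profile using a K-component
#' Gaussian mixture with a Dirichlet(1/K) prior on the weights, fit by MAP
#' gradient ascent with the labels marginalized. Input values should be
#' standardized per gene (mean 0, SD 1 across samples) so cluster means
#' share a scale.
#'
#' @param Y genes x samples matrix (or [expr_matrix()]), standardized per
#'   gene.
#' @param design matching [sample_design()].
#' @param K number of mixture components (>= 2); default 20 — with the
#'   sparsifying prior the model keeps only the needed ones.
#' @param seed integer seed (initialization).
#' @param maxit maximum EM iterations.
#' @param tol relative objective-change convergence tolerance.
#' @param merge if `TRUE` (default), a backward pass merges the closest
#'   pair of surviving components while the merge improves the BIC,
#'   guarding against one response pattern being carved into overlapping
#'   pieces.
#' @return A `response_mixture`: list with `pi` (length K; annihilated
#'   components have weight 0), `theta` (C x K cluster mean profiles, `NA`
#'   for dead components), `sigma2`, `resp` (responsibilities, zero
#'   columns for dead components), `labels` (MAP cluster per gene),
#'   `effective_K` (`#\{k: pi_k > 1/(10K)\}`), `loglik` (marginal data
#'   log-likelihood at the MAP), `trace` (objective per iteration of the
#'   final accepted EM run), `converged`.
#' @export
fit_response_mixture <- function(Y, design, K = 20, seed = 1,
                                 maxit = 5000, tol = 1e-13,
                                 merge = TRUE) {
  if (inherits(Y, "expr_matrix")) Y <- Y$values
  if (K < 2)
    stop_respqtl("K must be >= 2", "respqtl_invalid_mixture")
  set.seed(seed)
  ss <- mixture_suffstats(Y, design)
  G <- ss$G; C <- ss$C; a <- 1 / K
  prof <- sweep(ss$M, 2, ss$n_c, "/")
  km <- kmeans_pp(prof, min(K, max(2, nrow(prof) - 1)), nstart = 10,
                  seed = seed)
  theta <- matrix(NA_real_, C, K)
  theta[, seq_len(nrow(km$centers))] <- t(km$centers)
  # surplus columns (K > distinct centers) start as jittered copies
  for (k in seq_len(K)[-seq_len(nrow(km$centers))])
    theta[, k] <- km$centers[sample.int(nrow(km$centers), 1), ] +
      stats::rnorm(C, sd = 0.05)
  st <- list(pi = rep(1 / K, K), theta = theta,
             sigma2 = 0.5 * stats::var(as.numeric(Y)),
             alive = rep(TRUE, K))
  st <- run_mixture_em(ss, st, a, maxit, tol)
  trace <- st$trace
  # backward merge phase: EM can retain components that carve one response
  # pattern into overlapping pieces for a small likelihood gain; merging
  # the closest pair is accepted while it improves the BIC, so the final
  # number of components is chosen by a dimension-consistent criterion.
  if (merge) {
    repeat {
      ka <- which(st$alive)
      if (length(ka) < 2) break
      cur_ll <- sum(mixture_loglik_parts(ss, st$pi[ka],
                                         st$theta[, ka, drop = FALSE],
                                         st$sigma2)$lse)
      cur_bic <- -2 * cur_ll + length(ka) * (C + 1) * log(G)
      dd <- as.matrix(stats::dist(t(st$theta[, ka, drop = FALSE])))
      diag(dd) <- Inf
      ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      i <- ka[ij[1]]; j <- ka[ij[2]]
      trial <- st
      trial$theta[, i] <- (st$pi[i] * st$theta[, i] +
                             st$pi[j] * st$theta[, j]) /
        (st$pi[i] + st$pi[j])
      trial$pi[i] <- st$pi[i] + st$pi[j]
      trial$pi[j] <- 0
      trial$alive[j] <- FALSE
      trial$theta[, j] <- NA_real_
      trial <- run_mixture_em(ss, trial, a, maxit, tol)
      kt <- which(trial$alive)
      new_ll <- sum(mixture_loglik_parts(ss, trial$pi[kt],
                                         trial$theta[, kt, drop = FALSE],
                                         trial$sigma2)$lse)
      new_bic <- -2 * new_ll + length(kt) * (C + 1) * log(G)
      if (new_bic < cur_bic) {
        st <- trial
        trace <- trial$trace  # trace of the accepted (final) EM run
      } else break
    }
  }
  pi_k <- st$pi; theta <- st$theta; sigma2 <- st$sigma2
  converged <- st$converged
  ka <- which(st$alive)
  parts <- mixture_loglik_parts(ss, pi_k[ka], theta[, ka, drop = FALSE],
                                sigma2)
  resp <- matrix(0, G, K)
  resp[, ka] <- exp(parts$L - parts$lse)
  labels <- max.col(resp)
  structure(list(pi = pi_k, theta = theta, sigma2 = sigma2,
                 resp = resp, labels = labels,
                 effective_K = sum(pi_k > 1 / (10 * K)),
                 loglik = sum(parts$lse), trace = trace,
                 converged = converged, K = K),
            class = "response_mixture")
}

#' @export
print.response_mixture <- function(x, ...) {
  cat(sprintf("<response_mixture> K=%d, effective clusters=%d\n",
              x$K, x$effective_K))
  invisible(x)
}

#' Assign the two alleles of a reQTL to response clusters
#'
#' For a significant reQTL, each allele's response is matched to one of the
#' learned patterns using
#' `y_nc ~ N(d_n/2 * theta_{c,zA} + (2 - d_n)/2 * theta_{c,za}, sigma^2)`:
#' dosage-2 homozygotes follow pattern `zA`, dosage-0 homozygotes pattern
#' `za`, heterozygotes the average. All K^2 assignment pairs are scored
#' and the maximum-likelihood pair returned; an allele with no carriers is
#' non-identifiable and tied to the other allele's cluster.
#'
#' @param y phenotype vector over samples (standardized like the mixture
#'   input).
#' @param dosage per-sample dosage in \{0, 1, 2\}.
#' @param design matching [sample_design()].
#' @param theta C x K cluster means from [fit_response_mixture()].
#' @param sigma2 noise variance from the same fit.
#' @return An `allele_assignment`: list with `z_major` (pattern of the
#'   dosage-2 allele), `z_minor`, `loglik`, `identifiable` (named logical
#'   pair).
#' @export
assign_reqtl_alleles <- function(y, dosage, design, theta, sigma2) {
  if (is.null(theta))
    stop_respqtl("theta is required", "respqtl_missing_fit")
  live <- which(!apply(theta, 2, anyNA))  # skip annihilated components
  theta <- theta[, live, drop = FALSE]
  K <- ncol(theta)
  cidx <- design$condition
  wA <- dosage / 2
  wa <- (2 - dosage) / 2
  ll <- matrix(NA_real_, K, K)
  for (zA in seq_len(K)) {
    for (za in seq_len(K)) {
      mu <- wA * theta[cidx, zA] + wa * theta[cidx, za]
      ll[zA, za] <- sum(stats::dnorm(y, mu, sqrt(sigma2), log = TRUE))
    }
  }
  idA <- any(dosage > 0)
  ida <- any(dosage < 2)
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  zA <- best[1]; za <- best[2]
  if (!ida) za <- zA       # no minor-allele carriers: tie to major
  if (!idA) zA <- za
  zA <- live[zA]; za <- live[za]  # report in the caller's column indexing
  structure(list(z_major = unname(zA), z_minor = unname(za),
                 loglik = max(ll),
                 identifiable = c(major = idA, minor = ida)),
            class = "allele_assignment")
}

# ---- k-means with k-means++ seeding ---------------------------------------

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ]) ^ 2)
  for (j in seq_len(k - 1) + 1) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = pr), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ]) ^ 2))
  }
  centers
}

#' k-means with k-means++ seeding, best of several starts
#'
#' @param X numeric matrix (rows = observations).
#' @param k number of clusters.
#' @param nstart number of k-means++ initializations (default 10); the
#'   solution with the lowest total within-cluster sum of squares wins.
#' @param seed integer seed.
#' @return a `stats::kmeans` result.
#' @export
kmeans_pp <- function(X, k, nstart = 10, seed = 1) {
  set.seed(seed)
  X <- as.matrix(X)
  if (k >= nrow(X)) {
    # as many centers as points: every point is its own cluster
    return(list(cluster = seq_len(nrow(X)), centers = X,
                tot.withinss = 0, withinss = rep(0, nrow(X)),
                size = rep(1L, nrow(X))))
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    km <- tryCatch(
      stats::kmeans(X, centers = kmeanspp_centers(X, k), iter.max = 100),
      error = function(e) NULL)
    if (!is.null(km) &&
        (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best))
    stop_respqtl("k-means failed for all starts", "respqtl_kmeans_failure")
  best
}

#' Cluster normalized genotype effect-size profiles
#'
#' Each reQTL's per-condition effects `beta_c` are normalized by the
#' (signed) effect with the largest absolute value —
#' `beta_c / beta_argmax|beta_c'|`, first index on ties — so the largest
#' genotype effect is always exactly 1 and all entries lie in [-1, 1];
#' profiles are then k-means clustered (k-means++, best of 10 starts).
#'
#' @param beta_mat reQTLs x C matrix of fitted per-condition effects.
#' @param k number of clusters (default 9).
#' @param seed integer seed.
#' @return list: `normalized` (profiles actually clustered), `labels`,
#'   `centers`, `excluded` (all-zero profiles).
#' @export
cluster_effect_profiles <- function(beta_mat, k = 9, seed = 1) {
  beta_mat <- as.matrix(beta_mat)
  if (any(!is.finite(beta_mat)))
    stop_respqtl("effect profiles must be finite", "respqtl_invalid_profiles")
  zero <- apply(beta_mat, 1, function(b) all(b == 0))
  if (any(zero))
    warning(sprintf("%d all-zero profiles excluded", sum(zero)))
  B <- beta_mat[!zero, , drop = FALSE]
  norm <- t(apply(B, 1, function(b) b / b[which.max(abs(b))]))
  dimnames(norm) <- dimnames(B)
  km <- kmeans_pp(norm, k, nstart = 10, seed = seed)
  excl <- if (is.null(rownames(beta_mat))) which(zero)
          else rownames(beta_mat)[zero]
  list(normalized = norm, labels = km$cluster, centers = km$centers,
       excluded = excl)
}

# ---- splicing entropy and cryptic splice sites ----------------------------

# entropy in nats with the 0 * log 0 = 0 convention
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Splicing-choice entropy profiles per ASC, clustered
#'
#' For each alternative-splicing cluster, the entropy
#' `h_c = -sum_i psi_ci log psi_ci` (natural log) of the intron excision
#' proportions is computed at every condition; profiles are normalized by
#' their mean across conditions (`h_c / mean(h)`) and k-means clustered.
#' A condition with no data (`NA` column) is imputed with the mean of the
#' other conditions and flagged.
#'
#' @param psi_list named list: per ASC, an introns x C matrix of excision
#'   proportions (each column summing to 1, or `NA` if absent).
#' @param k number of k-means clusters.
#' @param seed integer seed.
#' @return list: `entropy` (ASC x C), `normalized`, `labels`, `centers`,
#'   `imputed` (ASC/condition pairs).
#' @export
splicing_entropy_profiles <- function(psi_list, k = 9, seed = 1) {
  C <- ncol(psi_list[[1]])
  ent <- t(vapply(psi_list, function(m) {
    apply(m, 2, function(p) if (anyNA(p)) NA_real_ else shannon_entropy(p))
  }, numeric(C)))
  imputed <- which(is.na(ent), arr.ind = TRUE)
  for (r in seq_len(nrow(ent))) {
    miss <- is.na(ent[r, ])
    if (any(miss)) {
      if (all(miss))
        stop_respqtl("ASC absent at every condition", "respqtl_invalid_splicing")
      ent[r, miss] <- mean(ent[r, !miss])
    }
  }
  norm <- ent / rowMeans(ent)
  norm[rowMeans(ent) == 0, ] <- 1  # zero-entropy ASC: flat profile
  km <- kmeans_pp(norm, k, nstart = 10, seed = seed)
  list(entropy = ent, normalized = norm, labels = km$cluster,
       centers = km$centers, imputed = imputed)
}

#' Classify differentially excised introns by cryptic splice-site usage
#'
#' Introns with a psi range `max_c psi - min_c psi > 0.1` (strict) are
#' standardized (per-intron mean 0, SD 1 across conditions), k-means
#' clustered, and classified by whether both, one, or neither end matches
#' an annotated exon boundary (transcript structure ignored: the
#' annotation is the union of boundary positions per chromosome). Each
#' cluster is tested for enrichment of introns with at least one
#' unannotated end against all other clusters by a one-sided
#' hypergeometric test; odds ratios are reported.
#'
#' @param introns data frame: `intron_id`, `chrom`, `start`, `end`.
#' @param psi introns x C matrix of excision proportions (rows matching
#'   `introns`).
#' @param boundaries data frame of annotated exon boundaries: `chrom`,
#'   `pos`.
#' @param k number of clusters (default 8).
#' @param seed integer seed.
#' @param delta_psi inclusion threshold on the psi range (default 0.1,
#'   strict).
#' @return list: `table` (per intron: cluster, annotation class),
#'   `enrichment` (per cluster: counts, hypergeometric `p`, `odds_ratio`),
#'   `kept` (logical filter).
#' @export
classify_cryptic_usage <- function(introns, psi, boundaries, k = 8,
                                   seed = 1, delta_psi = 0.1) {
  psi <- as.matrix(psi)
  stopifnot(nrow(introns) == nrow(psi))
  rng <- apply(psi, 1, function(p) max(p) - min(p))
  kept <- rng > delta_psi
  if (!any(kept))
    stop_respqtl("no introns pass the delta-psi filter",
                 "respqtl_invalid_splicing")
  intr <- introns[kept, , drop = FALSE]
  Z <- t(apply(psi[kept, , drop = FALSE], 1, function(p) {
    s <- stats::sd(p)
    if (s == 0) rep(0, length(p)) else (p - mean(p)) / s
  }))
  km <- kmeans_pp(Z, min(k, nrow(Z)), nstart = 10, seed = seed)
  if (nrow(boundaries) == 0) {
    warning("empty exon-boundary annotation: all introns classified 'neither'")
  }
  key <- paste(boundaries$chrom, boundaries$pos)
  start_ann <- paste(intr$chrom, intr$start) %in% key
  end_ann <- paste(intr$chrom, intr$end) %in% key
  n_ann <- start_ann + end_ann
  klass <- c("neither", "one_end", "both_ends")[n_ann + 1]
  cryptic <- n_ann < 2   # at least one unannotated end
  tab <- data.frame(intron_id = intr$intron_id, cluster = km$cluster,
                    annotation = klass, cryptic = cryptic,
                    stringsAsFactors = FALSE)
  enr <- do.call(rbind, lapply(sort(unique(km$cluster)), function(cl) {
    inc <- km$cluster == cl
    q <- sum(cryptic & inc); m <- sum(cryptic); nn <- sum(!cryptic)
    kk <- sum(inc)
    p <- stats::phyper(q - 1, m, nn, kk, lower.tail = FALSE)
    o <- (q * sum(!cryptic & !inc)) /
      max(1e-12, sum(!cryptic & inc) * sum(cryptic & !inc))
    data.frame(cluster = cl, n = kk, n_cryptic = q, p = p, odds_ratio = o)
  }))
  list(table = tab, enrichment = enr, kept = kept)
}
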