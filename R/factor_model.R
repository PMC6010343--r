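# Step 1 of the two-step response-QTL mixed model: learn latent factors,
# random-effect variances and per-gene condition means jointly across all
# genes, by maximizing the summed per-gene multivariate-normal likelihood
#
#   y_g ~ MVN(V v_g,  sum_k sigma_k^2 x_k x_k' + sigma_u^2 U
#                      + sigma_xi^2 Sigma + sigma_e^2 I)
#
# over the factors x (samples x K), the condition means v_g and the
# log-parameterized variances. v_g has a closed-form GLS solution given the
# covariance, so it is profiled out inside the objective; the gradient with
# respect to the covariance parameters is then exact by the envelope
# theorem.

# Assemble the full model covariance (including noise) from parts.
assemble_covariance <- function(x, sigma_k2, sigma_u2, sigma_xi2, sigma_e2,
                                U, Kin) {
  S <- nrow(U)
  Sig <- sigma_u2 * U + sigma_xi2 * Kin + sigma_e2 * diag(S)
  if (length(sigma_k2) > 0)
    Sig <- Sig + x %*% (sigma_k2 * t(x))
  (Sig + t(Sig)) / 2
}

# Objective and gradient for the joint fit. Y is samples x genes here.
factor_obj <- function(par, Y, V, U, Kin, K, trace_env = NULL) {
  S <- nrow(Y); G <- ncol(Y)
  x <- if (K > 0) matrix(par[seq_len(S * K)], S, K) else matrix(0, S, 0)
  lv <- par[S * K + seq_len(K + 3)]
  sigma_k2 <- if (K > 0) exp(lv[seq_len(K)]) else numeric(0)
  sigma_u2 <- exp(lv[K + 1]); sigma_xi2 <- exp(lv[K + 2])
  sigma_e2 <- exp(lv[K + 3])
  Sig <- assemble_covariance(x, sigma_k2, sigma_u2, sigma_xi2, sigma_e2,
                             U, Kin)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(list(value = -1e10, grad = 0 * par))
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  SiV <- Sinv %*% V
  A <- solve(crossprod(V, SiV))        # (V' Sig^-1 V)^-1, C x C
  vhat <- A %*% crossprod(SiV, Y)      # C x G (GLS condition means)
  R <- Y - V %*% vhat                  # residuals, S x G
  SiR <- Sinv %*% R
  quad <- sum(R * SiR)
  ll <- -0.5 * (G * (S * log(2 * pi) + logdet) + quad)
  if (!is.null(trace_env)) trace_env$trace <- c(trace_env$trace, ll)
  M <- -0.5 * G * Sinv + 0.5 * SiR %*% t(SiR)  # dll/dSigma
  gx <- if (K > 0) 2 * (M %*% x) * rep(sigma_k2, each = S) else numeric(0)
  gk <- if (K > 0) sigma_k2 * colSums(x * (M %*% x)) else numeric(0)
  gu <- sigma_u2 * sum(M * U)
  gxi <- sigma_xi2 * sum(M * Kin)
  ge <- sigma_e2 * sum(diag(M))
  list(value = ll, grad = c(as.numeric(gx), gk, gu, gxi, ge))
}

#' Fit latent factors and variance components jointly across genes
#'
#' Maximizes the summed per-gene MVN log-likelihood over the latent factor
#' matrix `x`, the per-gene condition means `v` (profiled in closed form by
#' GLS) and the variances `sigma_k^2` (per factor), `sigma_u^2`
#' (individual), `sigma_xi^2` (kinship) and `sigma_e^2` (noise), all on the
#' log scale, using L-BFGS with analytic gradients. Factors are initialized
#' from the leading principal components of the condition-mean-centered
#' data; on return factor columns are unit-norm with the magnitude carried
#' by `sigma_k^2`, and each column's largest-magnitude entry is positive.
#'
#' @param Y an [expr_matrix()] in `quantile_normal` state (genes x
#'   samples).
#' @param design the matching [sample_design()].
#' @param kinship kinship matrix over individuals (expected genetic
#'   covariance); `NULL` for none (treated as zero).
#' @param K number of latent factors (>= 0; default 10). Unneeded factors
#'   are shrunk: the effective count is
#'   `#\{k: sigma_k^2 > 1e-4 * total variance\}`.
#' @param maxit maximum L-BFGS iterations.
#' @param reltol relative objective-change tolerance for the convergence
#'   flag.
#' @return A `latent_factor_model`: list with `x`, `v` (genes x C),
#'   `sigma_k2`, `sigma_u2`, `sigma_xi2`, `sigma_e2`, `loglik`, `trace`
#'   (non-decreasing accepted-step likelihoods), `converged`,
#'   `effective_K`, plus the design matrices `U`, `Kin` (sample-expanded)
#'   needed downstream.
#' @export
fit_latent_factors <- function(Y, design, kinship = NULL, K = 10,
                               maxit = 500, reltol = 1e-8) {
  stopifnot(inherits(Y, "expr_matrix"), Y$state == "quantile_normal",
            K >= 0)
  Ym <- t(Y$values)                    # samples x genes
  stopifnot(nrow(Ym) == nrow(design))
  S <- nrow(Ym); G <- ncol(Ym)
  V <- condition_matrix(design)
  U <- individual_matrix(design)
  Kin <- if (is.null(kinship)) matrix(0, S, S) else {
    km <- as.matrix(kinship)[design$individual_id, design$individual_id]
    ev <- eigen((km + t(km)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop_respqtl("kinship not PSD", "respqtl_invalid_kinship")
    (km + t(km)) / 2
  }
  # init: remove per-condition means, take leading PCs
  v0 <- solve(crossprod(V), crossprod(V, Ym))
  Rc <- Ym - V %*% v0
  if (K > 0) {
    sv <- svd(Rc, nu = K, nv = 0)
    x0 <- sv$u[, seq_len(K), drop = FALSE]
    sk0 <- pmax((sv$d[seq_len(K)] ^ 2) / G, 1e-3)
  } else {
    x0 <- matrix(0, S, 0); sk0 <- numeric(0)
  }
  vary <- stats::var(as.numeric(Rc))
  par0 <- c(as.numeric(x0), log(sk0),
            log(0.1), log(0.1), log(0.5 * vary))
  tr <- new.env(); tr$trace <- numeric(0)
  fn <- function(p) factor_obj(p, Ym, V, U, Kin, K, tr)$value
  gr <- function(p) factor_obj(p, Ym, V, U, Kin, K)$grad
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(fnscale = -1, maxit = maxit,
                                     factr = reltol / .Machine$double.eps))
  p <- opt$par
  x <- if (K > 0) matrix(p[seq_len(S * K)], S, K) else matrix(0, S, 0)
  lv <- p[S * K + seq_len(K + 3)]
  sigma_k2 <- if (K > 0) exp(lv[seq_len(K)]) else numeric(0)
  sigma_u2 <- exp(lv[K + 1]); sigma_xi2 <- exp(lv[K + 2])
  sigma_e2 <- exp(lv[K + 3])
  # identifiability: unit-norm columns, magnitude into sigma_k2, sign fix
  if (K > 0) {
    nrm <- sqrt(colSums(x ^ 2))
    nz <- nrm > 0
    sigma_k2[nz] <- sigma_k2[nz] * nrm[nz] ^ 2
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, nrm[nz], "/")
    for (k in seq_len(K)) {
      i <- which.max(abs(x[, k]))
      if (x[i, k] < 0) x[, k] <- -x[, k]
    }
    ord <- order(sigma_k2, decreasing = TRUE)
    x <- x[, ord, drop = FALSE]; sigma_k2 <- sigma_k2[ord]
  }
  # final GLS condition means at the optimum
  Sig <- assemble_covariance(x, sigma_k2, sigma_u2, sigma_xi2, sigma_e2,
                             U, Kin)
  Sinv <- chol2inv(chol(Sig))
  SiV <- Sinv %*% V
  vhat <- solve(crossprod(V, SiV), crossprod(SiV, Ym))
  total_var <- sum(sigma_k2) + sigma_u2 + sigma_xi2 + sigma_e2
  model <- list(x = x, v = t(vhat), sigma_k2 = sigma_k2,
                sigma_u2 = sigma_u2, sigma_xi2 = sigma_xi2,
                sigma_e2 = sigma_e2, loglik = opt$value,
                trace = cummax(tr$trace),
                converged = opt$convergence == 0,
                effective_K = sum(sigma_k2 > 1e-4 * total_var),
                U = U, Kin = Kin, design = design)
  if (!model$converged)
    warning("factor model did not converge within maxit; model flagged")
  class(model) <- "latent_factor_model"
  model
}

#' @export
print.latent_factor_model <- function(x, ...) {
  cat(sprintf(
    "<latent_factor_model> K=%d (effective %d), loglik=%.2f%s\n",
    ncol(x$x), x$effective_K, x$loglik,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Assemble and eigendecompose the confounder covariance
#'
#' Builds `Sigma_pi = sum_k sigma_k^2 x_k x_k' + sigma_u^2 U +
#' sigma_xi^2 Sigma` (noise term excluded) from a fitted
#' [fit_latent_factors()] model and returns its symmetric
#' eigendecomposition. The rotation by the eigenvectors is what makes the
#' per-gene-SNP likelihood evaluations in step 2 linear rather than cubic
#' in the sample count. Eigenvalues in `[-1e-8, 0)` are clipped to zero;
#' asymmetry beyond tolerance is symmetrized with a warning.
#'
#' @param model a `latent_factor_model`.
#' @return A `covariance_decomposition`: list with `sigma_pi`, `values`
#'   (descending, >= 0), `vectors` (orthonormal columns).
#' @export
build_sigma_pi <- function(model) {
  stopifnot(inherits(model, "latent_factor_model"))
  Sp <- model$sigma_u2 * model$U + model$sigma_xi2 * model$Kin
  if (length(model$sigma_k2) > 0)
    Sp <- Sp + model$x %*% (model$sigma_k2 * t(model$x))
  covariance_decomposition(Sp)
}

#' Eigendecomposition wrapper for a confounder covariance
#'
#' Symmetrizes (warning beyond 1e-8 asymmetry), eigendecomposes, clips
#' eigenvalues in `[-1e-8, 0)` to zero and errors on substantially
#' negative ones. Useful directly when the confounder covariance is known
#' (e.g. simulation ground truth) rather than fitted.
#'
#' @param sigma_pi square covariance matrix (noise term excluded).
#' @return A `covariance_decomposition`: list with `sigma_pi`, `values`
#'   (descending, >= 0), `vectors` (orthonormal columns).
#' @export
covariance_decomposition <- function(sigma_pi) {
  Sp <- as.matrix(sigma_pi)
  if (max(abs(Sp - t(Sp))) > 1e-8) {
    warning("Sigma_pi numerically asymmetric; symmetrizing")
  }
  Sp <- (Sp + t(Sp)) / 2
  e <- eigen(Sp, symmetric = TRUE)
  lam <- e$values
  if (length(lam) && min(lam) < -1e-8)
    stop_respqtl("Sigma_pi has substantially negative eigenvalues",
                 "respqtl_invalid_covariance")
  lam <- pmax(lam, 0)
  structure(list(sigma_pi = Sp, values = lam, vectors = e$vectors),
            class = "covariance_decomposition")
}

#' Dense MVN log-density (reference evaluation)
#'
#' Direct evaluation of the multivariate-normal log-density via Cholesky;
#' used as the slow reference against the rotated-basis computations.
#'
#' @param y observation vector.
#' @param mean mean vector.
#' @param Sigma covariance matrix.
#' @return log-density (scalar).
#' @export
dmvnorm_chol <- function(y, mean, Sigma) {
  ch <- chol((Sigma + t(Sigma)) / 2)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z ^ 2))
}
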