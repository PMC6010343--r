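# Power-controlled replication statistic for two sets of paired p-values:
# a four-component Uniform x Beta mixture,
#
#   (p_i1, p_i2) ~ pi00 U U + pi10 B(a1,b1) U + pi01 U B(a2,b2)
#                  + pi11 B(a1,b1) B(a2,b2),
#
# with a_j in [0, 1] and b_j >= 1 so non-null components concentrate near
# zero, fit on a regular grid of bin counts; sharing is then summarized by
# the mutual information of the fitted 2x2 null/non-null distribution,
# which controls for per-study power (unlike naive replication rates).

overlap_negll <- function(par, counts, centers1, centers2) {
  lpi <- par[1:4] - max(par[1:4])
  lpi <- lpi - log(sum(exp(lpi)))
  pi_ <- exp(lpi)
  # cap the b transform: values beyond ~5e8 are indistinguishable in a
  # binned likelihood and only provoke lgamma underflow noise
  a1 <- stats::plogis(par[5]); b1 <- 1 + exp(min(par[6], 20))
  a2 <- stats::plogis(par[7]); b2 <- 1 + exp(min(par[8], 20))
  f1 <- suppressWarnings(stats::dbeta(centers1, a1, b1))  # per col-1 bin
  f2 <- suppressWarnings(stats::dbeta(centers2, a2, b2))
  # component density at each bin (outer over the two coordinates)
  dens <- pi_[1] +
    pi_[2] * matrix(f1, length(centers1), length(centers2)) +
    pi_[3] * matrix(f2, length(centers1), length(centers2), byrow = TRUE) +
    pi_[4] * outer(f1, f2)
  -sum(counts * log(pmax(dens, 1e-300)))
}

#' Fit the four-component p-value overlap mixture
#'
#' Pairs are binned on a regular `grid x grid` lattice over the unit
#' square; the count-weighted mixture log-likelihood (component densities
#' evaluated at bin centers) is maximized by quasi-Newton over the
#' weights (softmax transform) and the Beta hyperparameters
#' (`a = plogis`, `b = 1 + exp` transforms enforce `a in [0,1]`,
#' `b >= 1`), taking the best of `restarts` random initializations.
#'
#' @param p1,p2 paired p-value vectors on the same tests, in [0, 1].
#' @param grid bins per axis (default 100).
#' @param restarts random initializations (default 5).
#' @param seed integer seed.
#' @return An `overlap_fit`: list with `pi` (named `pi00, pi10, pi01,
#'   pi11`), `a1`, `b1`, `a2`, `b2`, `loglik`, `grid`, `counts`, `mi`.
#' @export
fit_pvalue_overlap <- function(p1, p2, grid = 100, restarts = 5, seed = 1) {
  if (length(p1) != length(p2))
    stop_respqtl("p1 and p2 must be aligned on the same tests",
                 "respqtl_dimension_mismatch")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop_respqtl("p-values must lie in [0, 1]", "respqtl_invalid_pvalues")
  if (length(p1) < grid ^ 2 / 100)
    warning("few pairs relative to the grid: bins will be sparse")
  set.seed(seed)
  br <- seq(0, 1, length.out = grid + 1)
  centers <- (br[-1] + br[-(grid + 1)]) / 2
  i1 <- pmin(pmax(findInterval(p1, br, rightmost.closed = TRUE), 1), grid)
  i2 <- pmin(pmax(findInterval(p2, br, rightmost.closed = TRUE), 1), grid)
  counts <- matrix(0, grid, grid)
  tt <- table(factor(i1, levels = 1:grid), factor(i2, levels = 1:grid))
  counts[] <- as.numeric(tt)
  best <- NULL
  for (r in seq_len(restarts)) {
    # initialization inside the box: b < 1 is impossible by construction
    par0 <- c(stats::rnorm(4, 0, 0.5),
              stats::qlogis(stats::runif(1, 0.1, 0.9)),
              log(stats::runif(1, 1, 50)),
              stats::qlogis(stats::runif(1, 0.1, 0.9)),
              log(stats::runif(1, 1, 50)))
    opt <- tryCatch(
      stats::optim(par0, overlap_negll, counts = counts,
                   centers1 = centers, centers2 = centers,
                   method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  p <- best$par
  lpi <- p[1:4] - max(p[1:4]); lpi <- lpi - log(sum(exp(lpi)))
  pi_ <- exp(lpi)
  names(pi_) <- c("pi00", "pi10", "pi01", "pi11")
  fit <- structure(list(pi = pi_,
                        a1 = stats::plogis(p[5]),
                        b1 = 1 + exp(min(p[6], 20)),
                        a2 = stats::plogis(p[7]),
                        b2 = 1 + exp(min(p[8], 20)),
                        loglik = -best$value, grid = grid, counts = counts),
                   class = "overlap_fit")
  fit$mi <- mutual_information(fit)
  fit
}

#' @export
print.overlap_fit <- function(x, ...) {
  cat(sprintf(
    "<overlap_fit> pi=(%.3f, %.3f, %.3f, %.3f)  MI=%.4f nats\n",
    x$pi[1], x$pi[2], x$pi[3], x$pi[4], x$mi))
  invisible(x)
}

#' Mutual information of the fitted null/non-null sharing structure
#'
#' `MI = sum_kj pi_kj log(pi_kj / (pi_k pi'_j))` in nats, with marginals
#' `pi_k = sum_j pi_kj`, `pi'_j = sum_k pi_kj` and the `0 log 0 = 0`
#' convention. Zero iff the two studies' null/non-null indicators are
#' independent under the fit.
#'
#' @param fit an `overlap_fit`, or a length-4 simplex vector ordered
#'   `(pi00, pi10, pi01, pi11)`.
#' @return MI in nats (>= 0).
#' @export
mutual_information <- function(fit) {
  pvec <- if (inherits(fit, "overlap_fit")) fit$pi else fit
  if (abs(sum(pvec) - 1) > 1e-8 || any(pvec < 0))
    stop_respqtl("pi must be on the simplex", "respqtl_invalid_mixture")
  # column-major: rows index the study-1 state (null, non-null), columns
  # the study-2 state, so rowSums/colSums are the two marginals
  P <- matrix(pvec, 2, 2)
  rk <- rowSums(P); cj <- colSums(P)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (P[i, j] > 0) mi <- mi + P[i, j] * log(P[i, j] / (rk[i] * cj[j]))
  }
  max(mi, 0)
}
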