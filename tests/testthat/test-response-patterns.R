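# Response-pattern mixture, allele-to-cluster assignment, effect-profile
# clustering, splicing entropy and cryptic splice-site enrichment.

# data drawn from the mixture's own generative process
mixture_fixture <- function(des, theta, z, sigma = 0.5, seed = 42) {
  set.seed(seed)
  S <- nrow(des)
  Y <- t(sapply(z, function(k)
    theta[des$condition, k] + rnorm(S, 0, sigma)))
  colnames(Y) <- des$sample_id
  rownames(Y) <- paste0("gene", seq_along(z))
  Y
}

test_that("two well-separated patterns yield exactly two effective clusters", {
  des <- tiny_design(40, 5)
  theta_true <- cbind(seq(1.2, -1.2, length.out = 5),
                      seq(-1.2, 1.2, length.out = 5))
  z <- rep(1:2, times = c(55, 65))
  Y <- mixture_fixture(des, theta_true, z, sigma = 0.5)
  fit <- fit_response_mixture(Y, des, K = 20, seed = 9)
  expect_equal(fit$effective_K, 2)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-8)
  expect_true(all(abs(rowSums(fit$resp) - 1) < 1e-8))
  expect_gt(fit$sigma2, 0)
  # recovered means match the planted patterns (up to label order)
  alive <- which(fit$pi > 0.1)
  dists <- sapply(1:2, function(tk)
    sapply(alive, function(fk)
      sqrt(mean((fit$theta[, fk] - theta_true[, tk]) ^ 2))))
  se_theta <- 0.5 / sqrt(min(table(z)) * nrow(des) / 5)
  expect_lt(max(apply(dists, 2, min)), 3 * se_theta + 0.05)
  # MAP objective non-decreasing between annihilation events
  expect_true(all(diff(tail(fit$trace, 50)) > -1e-6))
})

test_that("the marginal likelihood is invariant to label permutation", {
  des <- tiny_design(10, 3)
  theta <- cbind(c(1, 0, -1), c(-1, 0, 1), c(0.5, 0.5, -1))
  Y <- mixture_fixture(des, theta, rep(1:3, each = 10), seed = 2)
  ss <- respqtl:::mixture_suffstats(Y, des)
  pi_ <- c(0.5, 0.3, 0.2)
  l1 <- sum(respqtl:::mixture_loglik_parts(ss, pi_, theta, 0.3)$lse)
  perm <- c(3, 1, 2)
  l2 <- sum(respqtl:::mixture_loglik_parts(ss, pi_[perm],
                                           theta[, perm], 0.3)$lse)
  expect_equal(l1, l2, tolerance = 1e-10)
  expect_error(fit_response_mixture(Y, des, K = 1),
               class = "respqtl_invalid_mixture")
})

test_that("allele assignment recovers planted pattern pairs", {
  des <- tiny_design(30, 5)
  theta <- cbind(seq(1.2, -1.2, length.out = 5),
                 seq(-1.2, 1.2, length.out = 5),
                 c(0, 1, 0, -1, 0))
  sigma2 <- 0.09
  set.seed(11)
  d_ind <- sample(0:2, 30, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  d <- d_ind[match(des$individual_id, paste0("ind", 1:30))]
  mu <- (d / 2) * theta[des$condition, 1] +
    ((2 - d) / 2) * theta[des$condition, 2]
  y <- mu + rnorm(nrow(des), 0, sqrt(sigma2))
  aa <- assign_reqtl_alleles(y, d, des, theta, sigma2)
  expect_equal(aa$z_major, 1)
  expect_equal(aa$z_minor, 2)
  expect_true(all(aa$identifiable))
  # d = 2 for everyone: minor allele unobserved, tie broken to the major
  y2 <- theta[des$condition, 3] + rnorm(nrow(des), 0, sqrt(sigma2))
  aa2 <- assign_reqtl_alleles(y2, rep(2, nrow(des)), des, theta, sigma2)
  expect_equal(aa2$z_major, 3)
  expect_equal(aa2$z_minor, 3)
  expect_false(aa2$identifiable["minor"])
  expect_error(assign_reqtl_alleles(y, d, des, NULL, sigma2),
               class = "respqtl_missing_fit")
})

test_that("heterozygote means are the average of the homozygote patterns", {
  des <- tiny_design(3, 4)
  theta <- cbind(c(2, 1, 0, -1), c(-2, -1, 0, 1))
  # construct noiseless data for d = 1: exactly the average pattern
  d <- rep(1, nrow(des))
  y <- 0.5 * theta[des$condition, 1] + 0.5 * theta[des$condition, 2]
  aa <- assign_reqtl_alleles(y, d, des, theta, 0.01)
  # the (1,2) and (2,1) pairs tie at the maximum; both explain y exactly
  ll12 <- sum(dnorm(y, 0.5 * theta[des$condition, aa$z_major] +
                      0.5 * theta[des$condition, aa$z_minor],
                    0.1, log = TRUE))
  expect_equal(ll12, sum(dnorm(y, y, 0.1, log = TRUE)))
})

test_that("effect profiles normalize to a maximum of exactly one", {
  b <- rbind(c(1, -2, 4, 3, 2), c(-1, -3, 2, 1, 0.5), c(0, 0, 0, 0, 0))
  expect_warning(res <- cluster_effect_profiles(b, k = 2, seed = 1),
                 "all-zero")
  expect_equal(unname(res$normalized[1, ]), c(0.25, -0.5, 1, 0.75, 0.5))
  expect_true(all(apply(res$normalized, 1, max) == 1))
  expect_true(all(res$normalized >= -1 & res$normalized <= 1))
  expect_equal(length(res$excluded), 1)
  # tie on |beta|: first (lowest-concentration) index wins
  bt <- matrix(c(-2, 2, 1, 0, 0), 1)
  rt <- suppressWarnings(cluster_effect_profiles(rbind(bt, bt), k = 1,
                                                 seed = 1))
  expect_equal(unname(rt$normalized[1, ]), c(1, -1, -0.5, 0, 0))
})

test_that("planted effect-profile shapes are perfectly separated by k-means", {
  set.seed(3)
  shape1 <- c(0.1, 0.2, 0.5, 0.8, 1)
  shape2 <- c(1, 0.6, 0.2, -0.2, -0.5)
  B <- rbind(t(replicate(20, shape1 * runif(1, 1, 3) + rnorm(5, 0, 0.05))),
             t(replicate(20, shape2 * runif(1, 1, 3) + rnorm(5, 0, 0.05))))
  res <- cluster_effect_profiles(B, k = 2, seed = 5)
  truth <- rep(1:2, each = 20)
  # Rand index = 1: labels agree up to renaming
  expect_equal(length(unique(res$labels[truth == 1])), 1)
  expect_equal(length(unique(res$labels[truth == 2])), 1)
  expect_false(res$labels[1] == res$labels[40])
})

test_that("splicing entropy has its closed forms and maximality property", {
  expect_equal(respqtl:::shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(respqtl:::shannon_entropy(c(1, 0)), 0)
  # maximal iff uniform, on grids of distribution size
  for (m in 2:5) {
    expect_equal(respqtl:::shannon_entropy(rep(1 / m, m)), log(m))
    set.seed(m)
    for (r in 1:20) {
      p <- as.numeric(rmultinom(1, 50, runif(m)) / 50)
      if (max(abs(p - 1 / m)) > 1e-12)
        expect_lt(respqtl:::shannon_entropy(p), log(m))
    }
  }
  # profiles normalized by their mean have mean one
  psi_list <- list(
    a = rbind(c(0.5, 0.7, 0.9), c(0.5, 0.3, 0.1)),
    b = rbind(c(0.9, 0.5, NA), c(0.1, 0.5, NA)),
    c = rbind(c(0.6, 0.6, 0.6), c(0.4, 0.4, 0.4)),
    d = rbind(c(0.99, 0.5, 0.8), c(0.01, 0.5, 0.2)))
  res <- splicing_entropy_profiles(psi_list, k = 2, seed = 1)
  expect_equal(unname(rowMeans(res$normalized)),
               rep(1, 4))
  expect_equal(unname(res$entropy["a", 1]), log(2))
  # the NA condition was imputed with the mean of the others and flagged
  expect_equal(unname(res$entropy["b", 3]),
               mean(res$entropy["b", 1:2]))
  expect_true(any(res$imputed[, 1] == 2))
})

test_that("cryptic splice-site classification and enrichment are exact", {
  # toy geometry: boundaries annotate some intron ends
  bounds <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400))
  set.seed(8)
  n <- 40
  introns <- data.frame(
    intron_id = paste0("i", 1:n), chrom = "chr1",
    start = c(rep(100, 10), rep(999, 8), rep(100, 12), rep(300, 10)),
    end = c(rep(200, 10), rep(888, 8), rep(777, 12), rep(400, 10)))
  # psi profiles: two groups so k-means splits predictably, plus one flat
  # intron below the delta-psi threshold
  psi <- rbind(t(replicate(18, c(0.1, 0.3, 0.5, 0.7, 0.9) +
                             rnorm(5, 0, 0.01))),
               t(replicate(22, c(0.9, 0.7, 0.5, 0.3, 0.1) +
                             rnorm(5, 0, 0.01))))
  flat <- introns[1, ]; flat$intron_id <- "flat"
  introns2 <- rbind(introns, flat)
  psi2 <- rbind(psi, c(0.5, 0.6, 0.5, 0.5, 0.5))  # range 0.1: excluded
  res <- classify_cryptic_usage(introns2, psi2, bounds, k = 2, seed = 3)
  expect_false("flat" %in% res$table$intron_id)
  expect_equal(res$table$annotation[1], "both_ends")
  expect_equal(res$table$annotation[11], "neither")
  expect_equal(res$table$annotation[19], "one_end")
  # hypergeometric tail matches brute-force summation for each cluster
  for (r in seq_len(nrow(res$enrichment))) {
    e <- res$enrichment[r, ]
    m <- sum(res$table$cryptic); nn <- sum(!res$table$cryptic)
    expect_equal(e$p, hyper_tail_bruteforce(e$n_cryptic, m, nn, e$n),
                 tolerance = 1e-12)
  }
  expect_warning(
    classify_cryptic_usage(introns2, psi2,
                           data.frame(chrom = character(0),
                                      pos = numeric(0)),
                           k = 2, seed = 3),
    "empty")
})
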