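test_that("Gauss-Hermite rule has the exact low-order moments", {
  gh <- gauss_hermite(2)
  expect_equal(gh$nodes, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(gh$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  gh7 <- gauss_hermite(7)
  expect_equal(sum(gh7$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh7$weights * gh7$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh7$weights * gh7$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-12)
})

test_that("degenerate reductions: closed form and independent logistic fits", {
  # one cluster, one patient, both outcomes, beta = 0, D -> 0
  th0 <- theta_pack(matrix(0, 2, 2), diag(1e-10, 2))
  ll <- glmm_loglik(th0, matrix(c(1, 0), 1, 2), matrix(c(1, 0), 1, 2), 1,
                    nq = 15)$loglik
  expect_equal(ll, 2 * log(0.5), tolerance = 1e-9)

  # D -> 0 equals the sum of two ordinary logistic log-likelihoods
  sim <- sim_clustered(15, 6, matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1),
                                     2, 3, byrow = TRUE),
                       diag(0.5, 2), seed = 21)
  th <- theta_pack(sim$beta, diag(1e-12, 2))
  ll2 <- glmm_loglik(th, sim$y, sim$X, sim$cluster, nq = 15)$loglik
  ll_glm <- sum(vapply(1:2, function(r) {
    eta <- sim$X %*% sim$beta[r, ]
    sum(sim$y[, r] * eta - log1p(exp(eta)))
  }, numeric(1)))
  expect_equal(ll2, ll_glm, tolerance = 1e-8)
})

test_that("quadrature matches brute-force Monte-Carlo integration", {
  sim <- sim_clustered(5, 4, matrix(c(0.4, -0.3, 0.6, -0.2, 0.5, 0.3),
                                    2, 3, byrow = TRUE),
                       matrix(c(0.9, 0.5, 0.5, 1.1), 2), seed = 33)
  th <- theta_pack(sim$beta, sim$D)
  ll_q <- glmm_loglik(th, sim$y, sim$X, sim$cluster, nq = 15)$cluster_loglik

  set.seed(77)
  B <- 1e6
  bdraw <- matrix(rnorm(B * 2), B, 2) %*% chol(sim$D)
  for (j in 1:5) {
    rows <- which(sim$cluster == j)
    eta0 <- sim$X[rows, ] %*% t(sim$beta)
    lik <- rep(1, B)
    # P(y | b) as a product over the cluster's patients and outcomes
    for (a in seq_along(rows)) {
      for (r in 1:2) {
        pr <- plogis(eta0[a, r] + bdraw[, r])
        lik <- lik * (if (sim$y[rows[a], r] == 1) pr else 1 - pr)
      }
    }
    mc <- mean(lik)
    mc_se <- sd(lik) / sqrt(B)
    expect_lt(abs(exp(ll_q[j]) - mc), 3 * mc_se)
  }
})

test_that("node count is converged and the fit is invariant to relabeling", {
  sim <- sim_clustered(40, 8, matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1),
                                     2, 3, byrow = TRUE),
                       matrix(c(0.8, 0.4, 0.4, 0.6), 2), seed = 2)
  fit <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 15)
  l15 <- glmm_loglik(fit$theta, sim$y, sim$X, sim$cluster, nq = 15)$loglik
  l25 <- glmm_loglik(fit$theta, sim$y, sim$X, sim$cluster, nq = 25)$loglik
  expect_lt(abs(l15 - l25), 1e-4)

  # converged: scaled score below tolerance; refits identically
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  fit2 <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 15)
  expect_identical(fit$theta, fit2$theta)

  # relabel clusters and permute rows: same loglik and estimates
  set.seed(4)
  perm <- sample(nrow(sim$y))
  relab <- paste0("clinic_", sim$cluster + 100)
  fit3 <- fit_glmm(sim$y[perm, ], sim$X[perm, ], relab[perm], nq = 15)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit3$theta, fit$theta, tolerance = 1e-4)
})

test_that("per-cluster scores sum to the total and Hessian blocks to the total Hessian", {
  sim <- sim_clustered(25, 6, matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1),
                                     2, 3, byrow = TRUE),
                       matrix(c(0.8, 0.4, 0.4, 0.6), 2), seed = 6)
  fit <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 9)
  expect_lt(max(abs(colSums(fit$cluster_scores))), 1e-5 * fit$n_clusters)
  ch <- cluster_hessians(fit)
  expect_equal(apply(ch, c(2, 3), sum), fit$hessian, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("sigma2 = 0 truth pushes the variance to the boundary and matches glm", {
  sim <- sim_clustered(60, 10, matrix(c(0.4, -0.6, 0.3), 1, 3),
                       matrix(0, 1, 1), seed = 10)
  fit <- fit_univariate <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 15)
  expect_lt(fit$D[1, 1], 0.05)
  g <- glm(sim$y ~ sim$X - 1, family = binomial())
  se_g <- sqrt(diag(vcov(g)))
  expect_true(all(abs(fit$beta[1, ] - coef(g)) < 2 * se_g))
})

test_that("self-pairing an outcome drives the correlation to the boundary flag", {
  sim <- sim_clustered(50, 8, matrix(c(0.2, -0.4, 0.3), 1, 3),
                       matrix(0.8, 1, 1), seed = 14)
  ydup <- cbind(sim$y[, 1], sim$y[, 1])
  fit <- fit_glmm(ydup, sim$X, sim$cluster, nq = 7)
  expect_true(fit$boundary)
  expect_gt(cov2cor(fit$D)[1, 2], 0.95)
})

test_that("bivariate ML recovers generating parameters on one realization", {
  Dt <- matrix(c(0.9, 0.45, 0.45, 0.8), 2)
  bt <- matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1), 2, 3, byrow = TRUE)
  sim <- sim_clustered(250, 10, bt, Dt, seed = 17)
  fit <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 7)
  se <- sqrt(diag(fit$vcov))[1:6]
  expect_true(all(abs(as.vector(t(fit$beta)) - as.vector(t(bt))) < 3.5 * se))
  expect_lt(abs(fit$D[1, 2] - Dt[1, 2]), 0.35)
})

test_that("uncorrelated random intercepts are estimated near zero covariance", {
  Dt <- diag(c(0.8, 0.7))
  sim <- sim_clustered(200, 10, matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1),
                                       2, 3, byrow = TRUE), Dt, seed = 19)
  fit <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 7)
  # model-based SE of the covariance via the delta method on theta
  expect_lt(abs(fit$D[1, 2]), 0.3)
})

test_that("the trivariate oracle agrees with the bivariate path and is capped", {
  d <- desk_trial_data(seed = 23)
  ana <- exclude_missing_cluster(attr(d, "complete"))$data
  f2 <- fit_bivariate(ana, c(1, 2), nq = 7)
  fj <- full_joint_fit(ana, c(1, 2), nq = 7)
  expect_equal(fj$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(fj$theta, f2$theta, tolerance = 1e-3)
  expect_error(full_joint_fit(ana, c(1, 2, 3, 4)), "pairwise")
  expect_error(fit_glmm(cbind(ana$y1, ana$y1, ana$y2, ana$y2),
                        trial_design(ana)[, 1:3], ana$clinician_id),
               "pairwise|p > 3")
})

test_that("non-finite linear predictors raise an error naming the cluster", {
  sim <- sim_clustered(5, 4, matrix(0, 1, 3), matrix(0.5, 1, 1), seed = 1)
  X <- sim$X
  X[1, 2] <- Inf
  th <- theta_pack(matrix(c(0, 1, 0), 1, 3), matrix(0.5, 1, 1))
  expect_error(glmm_loglik(th, sim$y[, 1, drop = FALSE], X, sim$cluster),
               "non-finite linear predictor in cluster 1")
})
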