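test_that("pair enumeration is lexicographic with Q = p(p-1)/2", {
  i9 <- enumerate_pairs(9)
  expect_equal(i9$Q, 36)
  expect_equal(i9$pairs[1, ], c(r = 1, s = 2))
  expect_equal(i9$pairs[36, ], c(r = 8, s = 9))
  i2 <- enumerate_pairs(2)
  expect_equal(i2$Q, 1)
  expect_equal(unname(i2$pairs), matrix(c(1L, 2L), 1))
  i4 <- enumerate_pairs(4)
  expect_equal(i4$Q, 6)
  for (r in 1:4) expect_equal(sum(i4$pairs == r), 3)
  expect_true(all(i4$pairs[, 1] < i4$pairs[, 2]))
  expect_error(enumerate_pairs(1), ">= 2")
})

test_that("stacking gives the documented order and is input-order invariant", {
  idx <- enumerate_pairs(9)
  fits <- lapply(seq_len(idx$Q), function(q) fake_bivfit(idx$pairs[q, ], 13))
  st <- stack_fits(fits, idx, 13)
  expect_length(st$beta, 936)
  # block q holds pair q's coefficients, outcome r before outcome s
  expect_equal(unname(st$beta[1:26]), as.vector(t(fits[[1]]$beta)))

  st_perm <- stack_fits(rev(fits), idx, 13)
  expect_identical(st$beta, st_perm$beta)

  expect_error(stack_fits(fits[-1], idx, 13), "missing pair")
  expect_error(stack_fits(c(fits, fits[1]), idx, 13), "duplicate")

  idx2 <- enumerate_pairs(2)
  st2 <- stack_fits(list(fake_bivfit(c(1, 2), 3)), idx2, 3)
  expect_length(st2$beta, 6)
})

test_that("the weight matrix averages duplicates exactly", {
  A <- build_weight_matrix(9, 13)
  expect_equal(dim(A), c(117, 936))
  expect_true(all(abs(rowSums(A) - 1) < 1e-14))
  expect_true(all(A %in% c(0, 1 / 8)))

  A32 <- build_weight_matrix(3, 2)
  expect_equal(dim(A32), c(6, 12))
  expect_true(all(A32 %in% c(0, 0.5)))
  expect_equal(rowSums(A32 != 0), rep(2, 6), ignore_attr = TRUE)
  # hand enumeration: pairs (1,2), (1,3), (2,3); coefficient 1 of outcome 1
  # sits at stacked positions 1 (pair 1) and 5 (pair 2)
  expect_equal(which(A32[1, ] != 0), c(1, 5))
  # coefficient 2 of outcome 3 sits in pairs (1,3) and (2,3), slot s
  expect_equal(which(A32[6, ] != 0), c(8, 12))

  # a duplicate-consistent stack is reproduced without floating drift
  idx <- enumerate_pairs(5)
  k <- 4
  per_outcome <- matrix(rnorm(5 * k), 5, k)
  fits <- lapply(seq_len(idx$Q), function(q) {
    rs <- idx$pairs[q, ]
    fake_bivfit(rs, k, beta = per_outcome[rs, ])
  })
  st <- stack_fits(fits, idx, k)
  A5 <- build_weight_matrix(5, k)
  expect_equal(as.vector(A5 %*% st$beta), as.vector(t(per_outcome)),
               tolerance = 1e-12)
})

test_that("the single-pair sandwich equals the direct cluster-robust sandwich", {
  sim <- sim_clustered(80, 8, matrix(c(0.3, -0.5, 0.2, -0.2, 0.7, 0.1),
                                     2, 3, byrow = TRUE),
                       matrix(c(0.8, 0.4, 0.4, 0.6), 2), seed = 41)
  fit <- fit_glmm(sim$y, sim$X, sim$cluster, nq = 7)
  fit$pair <- c(1L, 2L)
  st <- stack_fits(list(fit), enumerate_pairs(2), 3)
  sw <- sandwich_empirical(st)
  Hi <- solve(-fit$hessian)
  direct <- (Hi %*% crossprod(fit$cluster_scores) %*% Hi)[1:6, 1:6]
  expect_equal(sw$var_beta, direct, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pairs on disjoint cluster sets have exactly zero cross-pair G blocks", {
  idx <- enumerate_pairs(3)
  k <- 2
  nt <- 2 * k + 3
  mk <- function(pair, cls) {
    fake_bivfit(pair, k, cluster_levels = cls,
                cluster_scores = matrix(rnorm(length(cls) * nt),
                                        length(cls), nt))
  }
  set.seed(3)
  fits <- list(mk(c(1, 2), c("a", "b")), mk(c(1, 3), c("c", "d")),
               mk(c(2, 3), c("e", "f")))
  st <- stack_fits(fits, idx, k)
  sw <- sandwich_empirical(st)
  G <- sw$G
  expect_true(all(G[1:nt, nt + seq_len(2 * nt)] == 0))
  expect_true(all(G[nt + seq_len(nt), 2 * nt + seq_len(nt)] == 0))
  expect_false(all(G[1:nt, 1:nt] == 0))
})

test_that("the printed-recipe sandwich matches an independent matrix oracle", {
  # toy fixture: p = 3 outcomes, k = 2 terms, N = 4 patients; the oracle
  # materializes every patient's 2-row design block and multiplies matrices
  # directly, independent of the kronecker shortcut used by the engine
  set.seed(8)
  k <- 2
  N <- 4
  Xp <- cbind(1, rnorm(N))
  idx <- enumerate_pairs(3)
  Ds <- list(matrix(c(0.9, 0.3, 0.3, 0.7), 2),
             matrix(c(1.1, -0.2, -0.2, 0.5), 2),
             matrix(c(0.6, 0.1, 0.1, 0.8), 2))
  fits <- lapply(seq_len(idx$Q), function(q) {
    f <- fake_bivfit(idx$pairs[q, ], k, D = Ds[[q]], xtx = crossprod(Xp),
                     n_obs = N)
    f
  })
  st <- stack_fits(fits, idx, k)
  sw <- suppressWarnings(sandwich_printed_recipe(st))

  # oracle: K_q = [X_1' T_1, ..., X_N' T_N] with X_i = I_2 (x) x_i', T_i = D_q
  Kq <- lapply(1:3, function(q) {
    do.call(cbind, lapply(seq_len(N), function(i) {
      Xi <- kronecker(diag(2), t(Xp[i, , drop = FALSE])) # 2k x 2
      Xi %*% Ds[[q]]
    }))
  })
  Jq <- lapply(1:3, function(q) {
    Reduce(`+`, lapply(seq_len(N), function(i) {
      Xi <- kronecker(diag(2), t(Xp[i, , drop = FALSE]))
      Xi %*% Ds[[q]] %*% t(Xi)
    }))
  })
  Jm <- matrix(0, 12, 12)
  for (q in 1:3) Jm[(q - 1) * 4 + 1:4, (q - 1) * 4 + 1:4] <- Jq[[q]]
  Km <- do.call(rbind, Kq)
  H_or <- Jm / N
  G_or <- Km %*% t(Km) / N
  O_or <- solve(H_or) %*% G_or %*% solve(H_or)
  expect_equal(sw$H, H_or, tolerance = 1e-10)
  expect_equal(sw$G, G_or, tolerance = 1e-10)
  expect_equal(sw$Omega, O_or, tolerance = 1e-8)
  expect_equal(dim(sw$H), c(12, 12))

  # Z = 0 (no random effects): T = 0, J = 0, literal singularity surfaces
  fits0 <- lapply(seq_len(idx$Q), function(q) {
    fake_bivfit(idx$pairs[q, ], k, D = matrix(0, 2, 2), xtx = crossprod(Xp),
                n_obs = N)
  })
  st0 <- stack_fits(fits0, idx, k)
  expect_error(suppressWarnings(sandwich_printed_recipe(st0)), "singular")
  expect_warning(sandwich_printed_recipe(st), "omits")
})

test_that("combining averages estimates and transports the covariance", {
  idx <- enumerate_pairs(3)
  k <- 1
  fits <- lapply(seq_len(idx$Q), function(q) {
    fake_bivfit(idx$pairs[q, ], k, beta = matrix(c(1, 1), 2, 1))
  })
  st <- stack_fits(fits, idx, k)
  A <- build_weight_matrix(3, 1)
  sw <- structure(list(var_beta = diag(6)), class = "sandwich_fit")
  cmb <- combine_estimates(A, st, sw)
  # identity stacked covariance: each row has two 1/2 entries -> 2 (1/2)^2
  expect_equal(unname(diag(cmb$sigma_star)), rep(0.5, 3))
  expect_equal(unname(cmb$beta_star), rep(1, 3))
  expect_error(combine_estimates(build_weight_matrix(4, 1), st, sw), "shape")
})

test_that("Rubin pooling reproduces hand arithmetic", {
  mk <- function(est, v) {
    structure(list(beta_star = est, sigma_star = diag(v, length(est)),
                   se = sqrt(rep(v, length(est))), p = 1, k = length(est),
                   m = 1), class = "combined_estimates")
  }
  pooled <- rubin_pool(list(mk(1, 0.5), mk(3, 0.5)))
  expect_equal(unname(pooled$beta_bar), 2)
  expect_equal(unname(diag(pooled$W)), 0.5)
  expect_equal(unname(diag(pooled$B)), 2)      # (1-2)^2 + (3-2)^2 over M-1
  expect_equal(unname(diag(pooled$V)), 0.5 + 1.5 * 2)

  same <- rubin_pool(list(mk(c(1, 2), 0.3), mk(c(1, 2), 0.3),
                          mk(c(1, 2), 0.3)))
  expect_equal(unname(diag(same$B)), c(0, 0))
  expect_equal(same$V, same$W)
  # the between-variance inflation factor is (M+1)/M
  m20 <- rubin_pool(lapply(seq_len(20), function(m) mk(m, 1)))
  expect_equal(diag(m20$V), diag(m20$W) + (21 / 20) * diag(m20$B),
               ignore_attr = TRUE)
  expect_error(rubin_pool(list(mk(1, 1))), "M >= 2")
})

test_that("joint Wald contrasts select one term per outcome", {
  ws <- build_L("time_arm", 9, 13)
  expect_equal(dim(ws$L), c(9, 117))
  expect_equal(ws$df, 9)
  expect_equal(which(t(ws$L) != 0) %% 117, seq(13, 117, by = 13) %% 117)
  expect_equal(unname(rowSums(ws$L != 0)), rep(1, 9))
  expect_equal(as.vector(ws$L %*% rep(0, 117)), rep(0, 9))
  expect_error(build_L("no_such_term", 9, 13), "unknown")

  # L beta = 0 exactly
  beta <- rep(0, 117)
  V <- diag(117)
  t0 <- wald_joint_test(ws, beta, V)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 9)

  # a 1-df contrast equals the squared z statistic
  beta1 <- c(0.7, rep(0, 116))
  V1 <- diag(117) * 0.04
  L1 <- list(L = matrix(c(1, rep(0, 116)), 1), label = "one")
  t1 <- wald_joint_test(L1, beta1, V1)
  expect_equal(t1$statistic, (0.7 / 0.2)^2, tolerance = 1e-12)
  expect_equal(t1$p_value, 2 * pnorm(-abs(0.7 / 0.2)), tolerance = 1e-12)

  expect_error(wald_joint_test(list(L = matrix(1, 1, 117)), beta,
                               matrix(0, 117, 117)), "singular")
})
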