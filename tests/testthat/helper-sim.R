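# simulation helpers shared across test files

# generic clustered p-variate logistic data with random intercepts
sim_clustered <- function(J, n_per, beta, D, seed = 1) {
  set.seed(seed)
  p <- nrow(rbind(beta))
  beta <- rbind(beta)
  k <- ncol(beta)
  N <- J * n_per
  cl <- rep(seq_len(J), each = n_per)
  X <- cbind(1, matrix(rnorm(N * (k - 1)), N, k - 1))
  if (k >= 3) X[, 3] <- rbinom(N, 1, 0.5)
  b <- matrix(rnorm(J * p), J, p) %*% chol(D + diag(1e-12, p))
  eta <- X %*% t(beta) + b[cl, , drop = FALSE]
  y <- matrix(rbinom(N * p, 1, plogis(eta)), N, p)
  list(y = y, X = X, cluster = cl, b = b, beta = beta, D = D)
}

# minimal bivariate-fit stand-in for structural tests that never touch the
# likelihood (stacking, weight-matrix, association bookkeeping)
fake_bivfit <- function(pair, k, beta = NULL, D = NULL, n_clusters = 3,
                        cluster_levels = NULL, cluster_scores = NULL,
                        hessian = NULL, xtx = NULL, n_obs = 4) {
  nt <- 2 * k + 3
  if (is.null(beta)) {
    beta <- matrix(seq_len(2 * k) / 10 + sum(pair), 2, k, byrow = TRUE)
  }
  if (is.null(D)) D <- diag(2) * 0.5
  if (is.null(cluster_levels)) cluster_levels <- paste0("c", seq_len(n_clusters))
  if (is.null(cluster_scores)) {
    cluster_scores <- matrix(0, length(cluster_levels), nt)
  }
  if (is.null(hessian)) hessian <- -diag(nt)
  if (is.null(xtx)) xtx <- diag(k)
  structure(list(pair = as.integer(pair), p = 2L, k = as.integer(k),
                 beta = beta, D = D, theta = numeric(nt),
                 hessian = hessian, cluster_scores = cluster_scores,
                 cluster_levels = cluster_levels, xtx = xtx,
                 n_obs = n_obs, n_clusters = length(cluster_levels)),
            class = "pjmm_fit")
}

# desk-scale trial dataset used by several suites
desk_trial_data <- function(seed = 42, ...) {
  simulate_trial(desk_params(seed = seed, ...))
}
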