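#' @name glmm_core
#' @title Maximum-likelihood logistic random-intercept models by adaptive
#'   Gauss-Hermite quadrature
#'
#' @description
#' The analysis models are logistic mixed models with one random intercept
#' per outcome at the clinician (cluster) level. For a set of p outcomes the
#' cluster-level random intercepts are jointly normal with covariance D, the
#' outcomes are conditionally independent given the intercepts, and the
#' marginal likelihood integrates the p-dimensional normal out by adaptive
#' Gauss-Hermite quadrature centred at each cluster's conditional mode.
#' `fit_glmm()` is the generic fitter (p = 1, 2 or 3); `fit_univariate()`,
#' `fit_bivariate()` and `full_joint_fit()` wrap it for the trial data
#' layout. The trivariate fit exists as a testing oracle for the pairwise
#' machinery; larger p is refused because the pairwise path is the intended
#' route there.
NULL

# ---- parameter vector layout -------------------------------------------

#' Pack coefficients and a random-intercept covariance into a parameter vector
#'
#' The parameter vector stacks the fixed effects outcome-major (all k
#' coefficients of outcome 1, then outcome 2, ...) followed by the
#' log-Cholesky factor of D (lower triangle, column-major, logarithm on the
#' diagonal) which keeps the covariance positive semidefinite during
#' unconstrained optimization.
#'
#' @param beta p x k matrix of fixed effects (row r = outcome r)
#' @param D p x p random-intercept covariance (positive definite)
#' @return numeric parameter vector of length p*k + p(p+1)/2
#' @export
theta_pack <- function(beta, D) {
  beta <- rbind(beta)
  p <- nrow(beta)
  stopifnot(nrow(D) == p, ncol(D) == p)
  L <- t(chol(D))
  ch <- numeric(0)
  for (cc in seq_len(p)) {
    for (rr in cc:p) {
      v <- L[rr, cc]
      ch <- c(ch, if (rr == cc) log(v) else v)
    }
  }
  c(as.vector(t(beta)), ch)
}

#' Unpack a parameter vector
#'
#' @param theta parameter vector as produced by [theta_pack()]
#' @param p number of outcomes
#' @param k number of fixed-effect terms per outcome
#' @return list with `beta` (p x k), `L` (lower Cholesky) and `D`
#' @export
theta_unpack <- function(theta, p, k) {
  stopifnot(length(theta) == p * k + p * (p + 1) / 2)
  beta <- matrix(theta[seq_len(p * k)], nrow = p, ncol = k, byrow = TRUE)
  L <- matrix(0, p, p)
  pos <- p * k
  for (cc in seq_len(p)) {
    for (rr in cc:p) {
      pos <- pos + 1L
      L[rr, cc] <- if (rr == cc) exp(theta[pos]) else theta[pos]
    }
  }
  list(beta = beta, L = L, D = L %*% t(L))
}

theta_labels <- function(p, k, terms = NULL, outcomes = NULL) {
  if (is.null(terms)) terms <- paste0("t", seq_len(k))
  if (is.null(outcomes)) outcomes <- paste0("y", seq_len(p))
  bl <- as.vector(t(outer(outcomes, terms, paste, sep = ":")))
  ch <- character(0)
  for (cc in seq_len(p)) {
    for (rr in cc:p) {
      ch <- c(ch, if (rr == cc) paste0("logL.", rr, rr) else paste0("L.", rr, cc))
    }
  }
  c(bl, ch)
}

# ---- likelihood ---------------------------------------------------------

prepare_cluster <- function(cluster) {
  f <- factor(cluster)
  list(idx = as.integer(f), levels = levels(f), J = nlevels(f))
}

#' Marginal log-likelihood of a p-variate logistic random-intercept model
#'
#' Evaluates the adaptive Gauss-Hermite approximation to
#' sum over clusters of log integral prod_i prod_r Bernoulli(y | logit^-1(x'b_r + b_jr))
#' phi(b; 0, D) db, optionally with the per-cluster score vectors obtained by
#' the Fisher identity (posterior-weighted complete-data scores on the same
#' quadrature grid). Deterministic given its inputs.
#'
#' @param theta parameter vector ([theta_pack()])
#' @param y N x p matrix of 0/1 outcomes
#' @param X N x k design matrix
#' @param cluster length-N cluster identifier
#' @param nq quadrature nodes per dimension (default 15)
#' @param score also return score vectors?
#' @return list with `loglik`, `cluster_loglik` and, if requested, `score`
#'   and `cluster_scores` (J x ntheta, rows ordered by `cluster_levels`)
#' @export
glmm_loglik <- function(theta, y, X, cluster, nq = 15, score = FALSE) {
  y <- as.matrix(y); X <- as.matrix(X)
  p <- ncol(y); k <- ncol(X)
  stopifnot(nrow(y) == nrow(X), nrow(y) == length(cluster))
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1")
  cl <- prepare_cluster(cluster)
  pr <- theta_unpack(theta, p, k) # validates length
  eta <- X %*% t(pr$beta)
  if (!all(is.finite(eta))) {
    bad <- cl$levels[cl$idx[which(!is.finite(rowSums(eta)))[1]]]
    stop("non-finite linear predictor in cluster ", bad)
  }
  gh <- gauss_hermite(nq)
  out <- aghq_eval_cpp(theta, y, X, cl$idx, cl$J, gh$nodes, gh$logw, score)
  out$cluster_levels <- cl$levels
  out
}

fd_hessian_score <- function(theta, score_fun) {
  nt <- length(theta)
  H <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    h <- 1e-5 * (1 + abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    H[, i] <- (score_fun(tp) - score_fun(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a p-variate logistic random-intercept model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the adaptive-quadrature log-likelihood
#' using the quadrature-based analytic score, followed by Newton polishing
#' with a finite-difference Hessian until the score max-norm (scaled by the
#' number of clusters) falls below `tol_grad`. Starting values are per-outcome
#' plain logistic regressions, random-intercept variances 0.5 and
#' covariances 0 unless `start` is supplied.
#'
#' @param y N x p matrix of 0/1 outcomes (p <= 3)
#' @param X N x k design matrix (must be full column rank on the rows used)
#' @param cluster length-N cluster identifier
#' @param nq quadrature nodes per dimension
#' @param outcomes optional outcome labels/indices recorded on the fit
#' @param terms optional term labels
#' @param start optional full parameter vector
#' @param max_iter BFGS iteration cap
#' @param tol_grad convergence tolerance for max|score|/J
#' @return object of class `pjmm_fit`: beta, D, loglik, theta, vcov
#'   (inverse observed information), hessian, per-cluster scores, convergence
#'   and boundary flags, plus the model frame needed to recompute
#'   cluster-level derivatives
#' @export
fit_glmm <- function(y, X, cluster, nq = 15, outcomes = NULL, terms = NULL,
                     start = NULL, max_iter = 500, tol_grad = 1e-5) {
  y <- as.matrix(y); X <- as.matrix(X)
  p <- ncol(y); k <- ncol(X)
  if (p > 3) stop("p > 3 not supported; use the pairwise path for high-dimensional outcomes")
  if (qr(X)$rank < k) stop("design matrix is rank deficient")
  cl <- prepare_cluster(cluster)
  nt <- p * k + p * (p + 1) / 2

  if (is.null(start)) {
    b0 <- t(vapply(seq_len(p), function(r) {
      unname(glm.fit2(X, y[, r]))
    }, numeric(k)))
    start <- theta_pack(b0, diag(0.5, p))
  }
  stopifnot(length(start) == nt)
  # starts must sit strictly inside the feasible box below (a warm start
  # from a separated fit would otherwise strand the optimizer on the barrier)
  bidx <- seq_len(p * k)
  start[bidx] <- pmax(pmin(start[bidx], 9.5), -9.5)

  gh <- gauss_hermite(nq)
  cache <- new.env(parent = emptyenv())
  evalf <- function(th, want_score) {
    key <- paste0(format(th, digits = 17), collapse = ",")
    hit <- cache$key
    if (!is.null(hit) && identical(hit, key) && (!want_score || !is.null(cache$val$score))) {
      return(cache$val)
    }
    v <- aghq_eval_cpp(th, y, X, cl$idx, cl$J, gh$nodes, gh$logw, want_score)
    cache$key <- key; cache$val <- v
    v
  }
  # soft box on the log-Cholesky diagonal: bounds variances away from the
  # degenerate region (roughly [3e-4, 3e3]) so the information matrix stays
  # conditioned and line searches do not wander; solutions at the box are
  # boundary-flagged, not hidden
  chd <- p * k + cumsum(c(1, if (p > 1) (p:2)))[seq_len(p)]
  choff <- setdiff(p * k + seq_len(p * (p + 1) / 2), chd)
  start[chd] <- pmax(pmin(start[chd], 3.8), -3.8)
  start[choff] <- pmax(pmin(start[choff], 50), -50)
  negll <- function(th) {
    if (any(abs(th[bidx]) > 10) || any(abs(th[chd]) > 4) ||
        any(abs(th[choff]) > exp(4))) {
      return(1e10)
    }
    -evalf(th, FALSE)$loglik
  }
  neggr <- function(th) -evalf(th, TRUE)$score
  opt <- optim(start, negll, neggr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-9))
  theta <- opt$par

  score_fun <- function(th) aghq_eval_cpp(th, y, X, cl$idx, cl$J,
                                          gh$nodes, gh$logw, TRUE)$score
  # Newton polish on the estimating equation score(theta) = 0 (step-halving
  # on the score max-norm): drives the quadrature score to its root even when
  # low node counts make score and log-likelihood marginally inconsistent
  sc <- score_fun(theta)
  H <- NULL
  for (it in seq_len(6)) {
    if (max(abs(sc)) / cl$J < tol_grad) break
    H <- fd_hessian_score(theta, score_fun)
    step <- tryCatch(-solve(H, sc), error = function(e) NULL)
    if (is.null(step)) break
    s0 <- max(abs(sc))
    lam <- 1
    improved <- FALSE
    in_box <- function(th) {
      all(abs(th[bidx]) <= 10) && all(abs(th[chd]) <= 4) &&
        all(abs(th[choff]) <= exp(4))
    }
    for (h in 1:20) {
      cand <- theta + lam * step
      sc1 <- if (in_box(cand)) {
        tryCatch(score_fun(cand), error = function(e) NULL)
      } else NULL
      if (!is.null(sc1) && all(is.finite(sc1)) && max(abs(sc1)) < s0) {
        theta <- cand; sc <- sc1; improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (is.null(H)) H <- fd_hessian_score(theta, score_fun)

  fin <- glmm_loglik(theta, y, X, cluster, nq = nq, score = TRUE)
  pr <- theta_unpack(theta, p, k)
  corr <- suppressWarnings(stats::cov2cor(pr$D))
  boundary <- any(diag(pr$D) < 1e-3) ||
    (p > 1 && any(abs(corr[lower.tri(corr)]) > 0.99))
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, nt, nt))
  grad_norm <- max(abs(fin$score)) / cl$J

  structure(list(
    beta = pr$beta, D = pr$D, loglik = fin$loglik, theta = theta,
    theta_names = theta_labels(p, k, terms, outcomes),
    vcov = vcov, hessian = H,
    cluster_scores = fin$cluster_scores,
    cluster_levels = fin$cluster_levels,
    converged = grad_norm < tol_grad, grad_norm = grad_norm,
    boundary = boundary, nq = nq, p = p, k = k,
    n_clusters = cl$J, n_obs = nrow(y),
    outcomes = outcomes, terms = terms,
    model = list(y = y, X = X, cluster = cluster)
  ), class = "pjmm_fit")
}

# stats::glm.fit wrapper returning coefficients even for separated fits
glm.fit2 <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  b <- fit$coefficients
  b[!is.finite(b)] <- 0
  pmax(pmin(b, 10), -10)
}

#' @export
print.pjmm_fit <- function(x, ...) {
  cat(sprintf("%d-variate logistic random-intercept fit: %d obs, %d clusters\n",
              x$p, x$n_obs, x$n_clusters))
  cat(sprintf("logLik %.4f  converged %s  max|score|/J %.2e%s\n",
              x$loglik, x$converged, x$grad_norm,
              if (x$boundary) "  [boundary]" else ""))
  cat("random-intercept covariance D:\n")
  print(round(x$D, 4))
  invisible(x)
}

#' Per-cluster Hessian blocks of a fitted model
#'
#' Central finite differences of the per-cluster score vectors with step
#' 1e-5 * (1 + |theta|), evaluated at the optimum. The blocks sum to the
#' fit's total Hessian.
#'
#' @param fit a `pjmm_fit`
#' @return array J x ntheta x ntheta (cluster order = `fit$cluster_levels`)
#' @export
cluster_hessians <- function(fit) {
  stopifnot(inherits(fit, "pjmm_fit"))
  m <- fit$model
  nt <- length(fit$theta)
  gh <- gauss_hermite(fit$nq)
  cl <- prepare_cluster(m$cluster)
  cs <- function(th) aghq_eval_cpp(th, m$y, m$X, cl$idx, cl$J,
                                   gh$nodes, gh$logw, TRUE)$cluster_scores
  out <- array(0, dim = c(cl$J, nt, nt))
  for (i in seq_len(nt)) {
    h <- 1e-5 * (1 + abs(fit$theta[i]))
    tp <- fit$theta; tp[i] <- tp[i] + h
    tm <- fit$theta; tm[i] <- tm[i] - h
    out[, , i] <- (cs(tp) - cs(tm)) / (2 * h)
  }
  for (j in seq_len(cl$J)) out[j, , ] <- (out[j, , ] + t(out[j, , ])) / 2
  dimnames(out) <- list(cl$levels, fit$theta_names, fit$theta_names)
  out
}

# ---- trial-data wrappers ------------------------------------------------

#' Fixed-effect terms of the trial analysis model
#' @return character vector of the 13 term labels, intercept first, the
#'   arm-by-time interaction last
#' @export
trial_terms <- function() {
  c("(Intercept)", "age_grp", "pat_sex", "comorb0", "comorb1", "comorb2",
    "cadre", "clin_sex", "workload", "malaria", "time", "arm", "time_arm")
}

#' Design matrix of the trial analysis model
#'
#' Builds the 13-column design used by all analysis models: intercept, infant
#' age group, patient sex, three comorbidity-count contrasts (0/1/2 against
#' the 3+ reference), clinician cadre, clinician sex, hospital admission
#' workload, hospital malaria endemicity, follow-up time in months, trial
#' arm, and the arm-by-time interaction. Rows with missing covariates yield
#' NA rows (callers decide between complete-case deletion and imputation).
#'
#' @param data trial data frame (see [read_trial_csv()] for the schema)
#' @return N x 13 numeric matrix with `trial_terms()` column names
#' @export
trial_design <- function(data) {
  X <- cbind(
    1,
    data$age_group,
    data$pat_sex,
    as.numeric(data$comorbid == 0),
    as.numeric(data$comorbid == 1),
    as.numeric(data$comorbid == 2),
    data$cadre,
    data$clin_sex,
    data$workload,
    data$malaria,
    data$time_months,
    data$arm,
    data$time_months * data$arm
  )
  colnames(X) <- trial_terms()
  X
}

fit_trial_outcomes <- function(data, outcomes, nq, start = NULL) {
  ycols <- paste0("y", outcomes)
  stopifnot(all(ycols %in% names(data)))
  X <- trial_design(data)
  keep <- complete.cases(X) & !is.na(data$clinician_id)
  y <- as.matrix(data[keep, ycols, drop = FALSE])
  fit <- fit_glmm(y, X[keep, , drop = FALSE], data$clinician_id[keep],
                  nq = nq, outcomes = ycols, terms = trial_terms(),
                  start = start)
  fit$n_dropped <- sum(!keep)
  fit
}

#' Univariate analysis model for one trial outcome
#' @param data trial data frame
#' @param outcome outcome index in 1..9
#' @param nq quadrature nodes
#' @param start optional parameter start
#' @return `pjmm_fit` with p = 1
#' @export
fit_univariate <- function(data, outcome, nq = 15, start = NULL) {
  stopifnot(length(outcome) == 1)
  fit_trial_outcomes(data, outcome, nq, start)
}

#' Bivariate pairwise joint model for two trial outcomes
#'
#' One of the Q = p(p-1)/2 building blocks of the pairwise pseudo-likelihood:
#' both outcomes get the full 13-term fixed-effect design and a clinician-
#' level random intercept; the two intercepts are bivariate normal with an
#' unstructured 2 x 2 covariance.
#'
#' @param data trial data frame
#' @param pair integer vector c(r, s), r < s
#' @param nq quadrature nodes per dimension
#' @param start optional parameter start
#' @return `pjmm_fit` with p = 2 and a `pair` field
#' @export
fit_bivariate <- function(data, pair, nq = 15, start = NULL) {
  stopifnot(length(pair) == 2, pair[1] < pair[2])
  fit <- fit_trial_outcomes(data, pair, nq, start)
  fit$pair <- as.integer(pair)
  fit
}

#' Full joint fit for up to three outcomes (testing oracle)
#'
#' Direct maximum likelihood for the p-outcome joint model with a p x p
#' random-intercept covariance and p-dimensional adaptive quadrature. This is
#' deliberately capped at p = 3: it exists to check the pairwise-combined
#' estimates against the full-joint MLE at desk scale, and the pairwise path
#' is the supported route for more outcomes.
#'
#' @inheritParams fit_bivariate
#' @param outcomes integer vector of 2 or 3 outcome indices
#' @return `pjmm_fit`
#' @export
full_joint_fit <- function(data, outcomes, nq = 15, start = NULL) {
  if (length(outcomes) > 3) {
    stop("full joint fit is limited to p <= 3; use the pairwise path for more outcomes")
  }
  fit_trial_outcomes(data, outcomes, nq, start)
}
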