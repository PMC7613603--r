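#' @name mi_latent_normal
#' @title Two-level latent-normal multiple imputation by Gibbs sampling
#'
#' @description
#' Partially observed binary covariates at the patient level (sex) and the
#' clinician level (sex, cadre) are imputed jointly under a two-level
#' latent-normal model: each binary variable is represented by an underlying
#' normal variable thresholded at zero (probit-style, level-1 residual
#' variance fixed at 1 for identifiability). Patient-level latents carry a
#' clinician random intercept; clinician-level latents have no separate
#' residual, their variability being carried entirely by the clinician
#' effect. The clinician effects of all targets are jointly normal with an
#' unstructured covariance Sigma_b, which is what lets observed outcomes and
#' covariates at either level inform the imputations at both. A Gibbs
#' sampler alternates truncated-normal draws of the latents with conjugate
#' updates of the regression coefficients, the random effects and Sigma_b
#' (inverse-Wishart with identity scale and minimal degrees of freedom);
#' completed datasets are taken at spaced iterations after burn-in.
#' Fully observed cells are never altered; all nine outcomes enter the
#' level-1 predictor set directly and the level-2 set as cluster means.
NULL

#' Imputation specification
#'
#' @param level1_targets patient-level binary variables to impute
#' @param level2_targets clinician-level binary variables to impute
#' @param M number of imputations (>= 2)
#' @param burn_in Gibbs iterations before the first draw (>= 1)
#' @param between iterations between consecutive draws (>= 1)
#' @param seed RNG seed
#' @return validated list of class `impute_spec`
#' @export
impute_spec <- function(level1_targets = "pat_sex",
                        level2_targets = c("clin_sex", "cadre"),
                        M = 20, burn_in = 500, between = 500, seed = 1L) {
  stopifnot(M >= 2, burn_in >= 1, between >= 1)
  structure(list(level1_targets = level1_targets,
                 level2_targets = level2_targets,
                 M = as.integer(M), burn_in = as.integer(burn_in),
                 between = as.integer(between), seed = as.integer(seed)),
            class = "impute_spec")
}

# truncated-normal draws N(mu, 1) restricted by sign; side = +1 (>= 0),
# -1 (< 0), 0 (untruncated)
rtnorm_sign <- function(mu, side) {
  n <- length(mu)
  u <- runif(n)
  out <- numeric(n)
  free <- side == 0
  out[free] <- mu[free] + qnorm(u[free])
  lo <- side > 0
  if (any(lo)) {
    p0 <- pnorm(-mu[lo])
    out[lo] <- mu[lo] + qnorm(pmin(p0 + u[lo] * (1 - p0), 1 - 1e-13))
  }
  hi <- side < 0
  if (any(hi)) {
    p0 <- pnorm(-mu[hi])
    out[hi] <- mu[hi] + qnorm(pmax(u[hi] * p0, 1e-13))
  }
  out
}

mi_designs <- function(data, spec) {
  if (anyNA(data$clinician_id)) {
    stop("records without a clinician id must be excluded before imputation ",
         "(see exclude_missing_cluster())")
  }
  ycols <- grep("^y[0-9]+$", names(data), value = TRUE)
  cl <- factor(data$clinician_id)
  J <- nlevels(cl)
  idx <- as.integer(cl)

  X1 <- cbind(1, data$time_months, data$arm, data$time_months * data$arm,
              data$workload, data$malaria, data$age_group,
              as.numeric(data$comorbid == 0), as.numeric(data$comorbid == 1),
              as.numeric(data$comorbid == 2),
              as.matrix(data[, ycols, drop = FALSE]))
  colnames(X1) <- c("(Intercept)", "time", "arm", "time_arm", "workload",
                    "malaria", "age_grp", "comorb0", "comorb1", "comorb2",
                    ycols)
  if (anyNA(X1)) stop("level-1 predictors contain missing values")

  agg <- function(v) as.vector(tapply(v, idx, mean))
  mt <- agg(data$time_months)
  arm2 <- agg(data$arm)
  X2 <- cbind(1, arm2, mt, arm2 * mt, agg(data$workload), agg(data$malaria),
              vapply(ycols, function(yc) agg(data[[yc]]), numeric(J)))
  colnames(X2) <- c("(Intercept)", "arm", "mean_time", "arm_mean_time",
                    "workload", "malaria", paste0("mean_", ycols))
  if (anyNA(X2)) stop("level-2 predictors contain missing values")

  t1 <- spec$level1_targets
  t2 <- spec$level2_targets
  for (v in c(t1, t2)) {
    x <- data[[v]]
    if (is.null(x)) stop("target variable not found: ", v)
    obs <- x[!is.na(x)]
    if (!length(obs)) stop("target has no observed values: ", v)
    if (!all(obs %in% c(0, 1))) stop("target must be binary 0/1: ", v)
  }
  Y1 <- as.matrix(data[, t1, drop = FALSE])
  # clinician-level targets: one value per clinician (take the first row)
  first <- match(levels(cl), cl)
  Y2 <- as.matrix(data[first, t2, drop = FALSE])

  list(X1 = X1, X2 = X2, Y1 = Y1, Y2 = Y2, idx = idx, J = J, N = nrow(data),
       nj = tabulate(idx, J), first = first, t1 = t1, t2 = t2,
       cl_levels = levels(cl))
}

mi_init <- function(des) {
  T1 <- length(des$t1); T2 <- length(des$t2); d <- T1 + T2
  k1 <- ncol(des$X1); k2 <- ncol(des$X2)
  lat1 <- matrix(0, des$N, T1)
  for (t in seq_len(T1)) {
    lat1[, t] <- ifelse(is.na(des$Y1[, t]), 0, ifelse(des$Y1[, t] == 1, 0.5, -0.5))
  }
  lat2 <- matrix(0, des$J, T2)
  for (t in seq_len(T2)) {
    lat2[, t] <- ifelse(is.na(des$Y2[, t]), 0, ifelse(des$Y2[, t] == 1, 0.5, -0.5))
  }
  list(lat1 = lat1, lat2 = lat2,
       b1 = matrix(0, des$J, T1),
       beta1 = matrix(0, k1, T1), beta2 = matrix(0, k2, T2),
       Sigma_b = diag(d), sigma_e2 = 1)
}

#' One sweep of the imputation Gibbs sampler
#'
#' Full-conditional updates in order: level-1 latents (truncated to the
#' half-line of the observed category, free where missing), level-1 random
#' effects, level-2 latents (their clinician effects drawn from the
#' Sigma_b-conditional, truncated by the observed category), level-1 and
#' level-2 regression coefficients (flat-prior conjugate normal / matrix
#' normal), and Sigma_b (inverse-Wishart, identity scale, d+1 prior df;
#' non-PSD draws are retried with jitter).
#'
#' @param state sampler state from [mi_init()] or a previous sweep
#' @param des design list from [mi_designs()]
#' @return updated state
#' @keywords internal
#' @export
gibbs_sweep <- function(state, des) {
  T1 <- length(des$t1); T2 <- length(des$t2); d <- T1 + T2
  i1 <- seq_len(T1); i2 <- T1 + seq_len(T2)
  S <- state$Sigma_b

  # 1) level-1 latents
  for (t in seq_len(T1)) {
    mu <- as.vector(des$X1 %*% state$beta1[, t]) + state$b1[des$idx, t]
    side <- ifelse(is.na(des$Y1[, t]), 0, ifelse(des$Y1[, t] == 1, 1, -1))
    state$lat1[, t] <- rtnorm_sign(mu, side)
  }

  # 2) level-1 random effects given level-2 effects (conditional prior)
  b2 <- state$lat2 - des$X2 %*% state$beta2   # J x T2
  if (T2 > 0) {
    S22i <- solve(S[i2, i2, drop = FALSE])
    pm <- b2 %*% t(S[i1, i2, drop = FALSE] %*% S22i)   # J x T1 prior means
    P <- S[i1, i1, drop = FALSE] -
      S[i1, i2, drop = FALSE] %*% S22i %*% S[i2, i1, drop = FALSE]
  } else {
    pm <- matrix(0, des$J, T1)
    P <- S[i1, i1, drop = FALSE]
  }
  res1 <- state$lat1 - des$X1 %*% state$beta1  # N x T1
  if (T1 == 1) {
    rsum <- as.vector(rowsum(res1[, 1], des$idx))
    prec <- 1 / P[1, 1] + des$nj
    mean_post <- (pm[, 1] / P[1, 1] + rsum) / prec
    state$b1[, 1] <- rnorm(des$J, mean_post, sqrt(1 / prec))
  } else if (T1 > 1) {
    Pinv <- solve(P)
    rsum <- rowsum(res1, des$idx)
    for (j in seq_len(des$J)) {
      Prec <- Pinv + diag(des$nj[j], T1)
      V <- solve(Prec)
      m <- V %*% (Pinv %*% pm[j, ] + rsum[j, ])
      state$b1[j, ] <- m + t(chol(V)) %*% rnorm(T1)
    }
  }

  # 3) level-2 latents: clinician effect of each target from its
  # Sigma_b-conditional given the other effects, truncated by the category
  for (t in seq_len(T2)) {
    g <- i2[t]
    oth <- setdiff(seq_len(d), g)
    U <- cbind(state$b1, state$lat2 - des$X2 %*% state$beta2)
    Soo <- solve(S[oth, oth, drop = FALSE])
    w <- as.vector(S[g, oth, drop = FALSE] %*% Soo)
    cm <- as.vector(U[, oth, drop = FALSE] %*% w)
    cv <- S[g, g] - sum(w * S[oth, g])
    cv <- max(cv, 1e-10)
    xb <- as.vector(des$X2 %*% state$beta2[, t])
    side <- ifelse(is.na(des$Y2[, t]), 0, ifelse(des$Y2[, t] == 1, 1, -1))
    # latent = xb + b2t; truncation at 0 on the latent scale
    z <- rtnorm_sign((xb + cm) / sqrt(cv), side * 1) # standardized about mean
    state$lat2[, t] <- (xb + cm) + sqrt(cv) * (z - (xb + cm) / sqrt(cv))
  }

  # 4) level-1 coefficients
  X1tX1 <- crossprod(des$X1)
  R1 <- chol(X1tX1)
  for (t in seq_len(T1)) {
    r <- state$lat1[, t] - state$b1[des$idx, t]
    bhat <- backsolve(R1, forwardsolve(t(R1), crossprod(des$X1, r)))
    state$beta1[, t] <- bhat + backsolve(R1, rnorm(ncol(des$X1)))
  }

  # 5) level-2 coefficients: matrix-normal conjugate with row covariance
  # equal to the conditional covariance of the level-2 effects given b1
  if (T2 > 0) {
    S11i <- solve(S[i1, i1, drop = FALSE])
    m2 <- state$b1 %*% t(S[i2, i1, drop = FALSE] %*% S11i)  # J x T2
    Sc <- S[i2, i2, drop = FALSE] -
      S[i2, i1, drop = FALSE] %*% S11i %*% S[i1, i2, drop = FALSE]
    Sc <- (Sc + t(Sc)) / 2 + diag(1e-10, T2)
    Z <- state$lat2 - m2
    X2tX2 <- crossprod(des$X2)
    R2 <- chol(X2tX2)
    Bhat <- backsolve(R2, forwardsolve(t(R2), crossprod(des$X2, Z)))
    G <- matrix(rnorm(ncol(des$X2) * T2), ncol(des$X2), T2)
    state$beta2 <- Bhat + backsolve(R2, G) %*% chol(Sc)
  }

  # 6) Sigma_b
  U <- cbind(state$b1, state$lat2 - des$X2 %*% state$beta2)
  scale_post <- diag(d) + crossprod(U)
  df_post <- (d + 1) + des$J
  for (try in 1:5) {
    W <- rWishart(1, df_post, solve(scale_post))[, , 1]
    Sig <- tryCatch(solve(W), error = function(e) NULL)
    if (!is.null(Sig) && all(is.finite(Sig)) &&
        min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) > 0) {
      state$Sigma_b <- (Sig + t(Sig)) / 2
      break
    }
    scale_post <- scale_post + diag(1e-6, d)  # jitter and retry
  }
  state
}

mi_trace_row <- function(state) {
  S <- state$Sigma_b
  c(as.vector(state$beta1), as.vector(state$beta2),
    S[lower.tri(S, diag = TRUE)])
}

mi_trace_names <- function(des, state) {
  d <- nrow(state$Sigma_b)
  sn <- outer(seq_len(d), seq_len(d), function(r, cc) paste0("Sigma_b.", r, ".", cc))
  c(paste0("beta1.", rep(des$t1, each = ncol(des$X1)), ".",
           rep(colnames(des$X1), length(des$t1))),
    paste0("beta2.", rep(des$t2, each = ncol(des$X2)), ".",
           rep(colnames(des$X2), length(des$t2))),
    sn[lower.tri(sn, diag = TRUE)])
}

#' Multiply impute missing covariates
#'
#' Runs the two-level latent-normal Gibbs sampler and returns M completed
#' datasets drawn at iterations burn_in, burn_in + between, ...,
#' burn_in + (M-1) * between, together with the full parameter trace.
#' Observed cells are identical across the stack; only originally missing
#' cells vary. Deterministic given the spec's seed, and the first M' draws
#' do not depend on whether M > M' further draws are requested.
#'
#' @param data trial data frame (no missing clinician ids; outcomes complete)
#' @param spec an [impute_spec()]
#' @return list of class `imputed_stack`: `datasets` (list of M completed
#'   data frames), `trace` (iterations x parameters matrix), `spec`,
#'   `draw_iters`
#' @export
run_imputation <- function(data, spec) {
  stopifnot(inherits(spec, "impute_spec"))
  des <- mi_designs(data, spec)
  state <- mi_init(des)
  n_iter <- spec$burn_in + (spec$M - 1L) * spec$between
  draw_iters <- spec$burn_in + (seq_len(spec$M) - 1L) * spec$between
  trace <- matrix(NA_real_, n_iter, length(mi_trace_row(state)))
  colnames(trace) <- mi_trace_names(des, state)
  datasets <- vector("list", spec$M)
  m <- 0L
  with_seed(spec$seed, {
    for (it in seq_len(n_iter)) {
      state <- gibbs_sweep(state, des)
      trace[it, ] <- mi_trace_row(state)
      if (it %in% draw_iters) {
        m <- m + 1L
        datasets[[m]] <- mi_complete(data, des, state)
      }
    }
  })
  structure(list(datasets = datasets, trace = trace, spec = spec,
                 draw_iters = draw_iters), class = "imputed_stack")
}

# fill originally missing cells from the current latent state
mi_complete <- function(data, des, state) {
  out <- data
  for (t in seq_along(des$t1)) {
    v <- des$t1[t]
    miss <- is.na(data[[v]])
    out[[v]][miss] <- as.integer(state$lat1[miss, t] >= 0)
  }
  for (t in seq_along(des$t2)) {
    v <- des$t2[t]
    imp_cl <- as.integer(state$lat2[, t] >= 0)     # per clinician
    miss <- is.na(data[[v]])
    out[[v]][miss] <- imp_cl[des$idx[miss]]
  }
  out
}

#' Convergence diagnostics for an imputation run
#'
#' Per-parameter summary of the Gibbs trace: mean, standard deviation,
#' lag-1 autocorrelation (flagged undefined for constant traces), and a
#' drift flag comparing the first and last thirds of the chain. Summaries
#' are computed on the post-burn-in segment (the initial transient would
#' otherwise flag every parameter); the full series, including burn-in, is
#' what `series_path` writes. No pass or fail verdict is issued; this
#' supports the usual visual assessment.
#'
#' @param stack an `imputed_stack`
#' @param path optional CSV path for the summary; the raw series can be
#'   written with `series_path`
#' @param series_path optional CSV path for the full trace series
#' @return data frame with one row per traced parameter
#' @export
convergence_report <- function(stack, path = NULL, series_path = NULL) {
  tr_full <- stack$trace
  stopifnot(nrow(tr_full) > 0)
  bi <- stack$spec$burn_in
  tr <- if (!is.null(bi) && nrow(tr_full) - bi >= 10) {
    tr_full[-seq_len(bi), , drop = FALSE]
  } else tr_full
  res <- do.call(rbind, lapply(colnames(tr), function(pn) {
    x <- tr[, pn]
    Tn <- length(x)
    constant <- sd(x) < 1e-12
    l1 <- if (constant || Tn < 3) NA_real_ else {
      cor(x[-1], x[-Tn])
    }
    third <- max(1, floor(Tn / 3))
    drift <- if (constant) FALSE else {
      abs(mean(x[seq_len(third)]) - mean(x[seq(Tn - third + 1, Tn)])) >
        2 * sd(x) / sqrt(third)
    }
    data.frame(param = pn, mean = mean(x), sd = sd(x),
               running_mean_final = mean(x), lag1_autocorr = l1,
               flag_constant = constant, flag_drift = drift)
  }))
  if (!is.null(path)) write.csv(res, path, row.names = FALSE)
  if (!is.null(series_path)) {
    write.csv(data.frame(iter = seq_len(nrow(tr_full)), tr_full), series_path,
              row.names = FALSE)
  }
  res
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("imputed stack: M = %d datasets, draws at iterations %s\n",
              x$spec$M, paste(head(x$draw_iters, 5), collapse = ", ")))
  invisible(x)
}
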