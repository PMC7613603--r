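#' @name pairwise_pseudolik
#' @title From bivariate fits to full-joint inference
#'
#' @description
#' Fitting all Q = p(p-1)/2 bivariate models instead of one p-variate model
#' yields a pseudo-likelihood whose maximizer stacks the per-pair parameter
#' vectors. Because every outcome occurs in p-1 pairs, each fixed effect has
#' p-1 duplicate estimates; an averaging weight matrix A (entries 1/(p-1))
#' maps the stacked vector to one estimate per (outcome, term). The
#' asymptotic covariance of the stacked vector is the sandwich H^-1 G H^-1
#' built from cluster-wise Hessians and score cross-products, with the
#' cross-pair blocks of G carrying the dependence between pairs sharing
#' outcomes or clusters; A transports it to the combined scale. Per-imputation
#' combined estimates are pooled by Rubin's rules, and joint Wald tests of
#' one term across all outcomes use selector contrasts against chi-squared.
NULL

#' Enumerate outcome pairs
#'
#' @param p number of outcomes (>= 2)
#' @return list of class `pair_index`: `p`, `pairs` (Q x 2 matrix, r < s,
#'   lexicographic), `Q`
#' @export
enumerate_pairs <- function(p) {
  if (!is.numeric(p) || p < 2) stop("p must be >= 2")
  p <- as.integer(p)
  prs <- do.call(rbind, lapply(seq_len(p - 1), function(r) {
    cbind(r, seq.int(r + 1L, p))
  }))
  dimnames(prs) <- list(NULL, c("r", "s"))
  structure(list(p = p, pairs = prs, Q = nrow(prs)), class = "pair_index")
}

#' Stack bivariate fits into the pseudo-likelihood estimate vector
#'
#' Orders the fits by the pair index (input order is irrelevant) and stacks
#' their coefficient vectors: pairs lexicographic, within each pair outcome
#' r's k coefficients then outcome s's. The per-pair derivative machinery
#' (per-cluster scores, total Hessians, D blocks) travels along for the
#' sandwich step.
#'
#' @param fits list of bivariate `pjmm_fit`s, each carrying `pair = c(r, s)`
#' @param index a [enumerate_pairs()] result
#' @param k coefficients per outcome (checked against the fits)
#' @return list of class `stacked_estimates`: `beta` (length 2kQ), `fits`
#'   (pair order), `index`, `k`
#' @export
stack_fits <- function(fits, index, k) {
  stopifnot(inherits(index, "pair_index"))
  keys <- vapply(fits, function(f) {
    if (is.null(f$pair)) stop("every fit must carry a pair label")
    paste(f$pair, collapse = ",")
  }, character(1))
  want <- apply(index$pairs, 1, paste, collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate pair fit: ", keys[duplicated(keys)][1])
  missing <- setdiff(want, keys)
  if (length(missing)) stop("missing pair fit(s): ", paste(missing, collapse = "; "))
  fits <- fits[match(want, keys)]
  for (f in fits) {
    if (f$p != 2 || f$k != k) stop("fits must be bivariate with k = ", k)
  }
  beta <- unlist(lapply(fits, function(f) as.vector(t(f$beta))))
  names(beta) <- unlist(lapply(fits, function(f) {
    paste0("y", rep(f$pair, each = k), ":", rep(trial_seq_terms(k), 2))
  }))
  structure(list(beta = beta, fits = fits, index = index, k = k),
            class = "stacked_estimates")
}

trial_seq_terms <- function(k) {
  if (k == 13) trial_terms() else paste0("t", seq_len(k))
}

#' Build the averaging weight matrix A
#'
#' pk rows (outcome-major coefficient order) by 2kQ columns; the row of
#' coefficient c of outcome r has entries 1/(p-1) at the p-1 stacked
#' positions holding that coefficient, so every row sums to one and a stack
#' whose duplicates agree is reproduced exactly.
#'
#' @param p number of outcomes
#' @param k coefficients per outcome
#' @return pk x 2kQ matrix
#' @export
build_weight_matrix <- function(p, k) {
  stopifnot(p >= 2, k >= 1)
  idx <- enumerate_pairs(p)
  A <- matrix(0, p * k, 2 * k * idx$Q)
  w <- 1 / (p - 1)
  for (q in seq_len(idx$Q)) {
    rs <- idx$pairs[q, ]
    off <- (q - 1) * 2 * k
    for (pos in 1:2) {
      r <- rs[pos]
      rows <- (r - 1) * k + seq_len(k)
      cols <- off + (pos - 1) * k + seq_len(k)
      A[cbind(rows, cols)] <- w
    }
  }
  A
}

# positions of the fixed-effect entries inside the stacked full parameter
# vector (each pair contributes 2k beta entries then 3 covariance entries)
beta_positions <- function(Q, k, nt_pair) {
  unlist(lapply(seq_len(Q), function(q) (q - 1) * nt_pair + seq_len(2 * k)))
}

#' Empirical cluster-robust sandwich for the stacked estimates
#'
#' The default covariance engine. H is block-diagonal in the per-pair
#' observed-information matrices (finite-difference Hessians of each pair's
#' log-likelihood); G is the cross-product of per-cluster score vectors
#' concatenated across pairs, aligned on cluster id, with zero blocks where a
#' cluster contributes no data to a pair. The cross-pair blocks of G are what
#' carry the dependence between pairs sharing an outcome. Returned are the
#' normalized H, G, Omega = H^-1 G H^-1 of pseudo-likelihood theory and the
#' finite-sample covariance of the stacked coefficient vector
#' (the beta rows/columns of (sum H_j)^-1 (sum g_j g_j') (sum H_j)^-1).
#'
#' A boundary pairwise fit (a random-intercept variance collapsed to zero)
#' makes its information matrix singular in the collapsed direction while the
#' fixed effects remain regular; `singular = "pseudo"` then inverts each
#' pair's information on its non-degenerate eigenspace instead of aborting,
#' which is what the pipeline uses so one degenerate pair cannot sink a
#' multi-dataset analysis. The default refuses singular input with the
#' condition number.
#'
#' @param stacked a [stack_fits()] result
#' @param singular `"error"` (default) or `"pseudo"`
#' @return list of class `sandwich_fit`: `H`, `G`, `Omega` (normalized, full
#'   parameter block), `var_beta` (2kQ x 2kQ), `n_clusters`, `clusters`
#' @export
sandwich_empirical <- function(stacked, singular = c("error", "pseudo")) {
  stopifnot(inherits(stacked, "stacked_estimates"))
  singular <- match.arg(singular)
  fits <- stacked$fits
  Q <- stacked$index$Q
  k <- stacked$k
  nt <- length(fits[[1]]$theta)
  clusters <- sort(unique(unlist(lapply(fits, `[[`, "cluster_levels"))))
  N <- length(clusters)

  Gmat <- matrix(0, N, Q * nt)  # per-cluster concatenated scores
  Abd <- matrix(0, Q * nt, Q * nt)
  Abd_inv <- matrix(0, Q * nt, Q * nt)
  for (q in seq_len(Q)) {
    f <- fits[[q]]
    cols <- (q - 1) * nt + seq_len(nt)
    rows <- match(f$cluster_levels, clusters)
    Gmat[rows, cols] <- f$cluster_scores
    Aq <- -f$hessian
    Abd[cols, cols] <- Aq
    Aq_inv <- tryCatch(solve(Aq), error = function(e) NULL)
    if (is.null(Aq_inv) || kappa(Aq) > 1e12) {
      if (singular == "error") {
        stop(sprintf("singular H (condition number %.3g)", kappa(Aq)))
      }
      e <- eigen((Aq + t(Aq)) / 2, symmetric = TRUE)
      keep <- e$values > max(e$values) * 1e-10
      Aq_inv <- e$vectors[, keep, drop = FALSE] %*%
        diag(1 / e$values[keep], sum(keep)) %*%
        t(e$vectors[, keep, drop = FALSE])
    }
    Abd_inv[cols, cols] <- Aq_inv
  }
  B <- crossprod(Gmat)
  var_full <- Abd_inv %*% B %*% Abd_inv
  bp <- beta_positions(Q, k, nt)
  structure(list(
    H = Abd / N, G = B / N,
    Omega = N * var_full,            # H^-1 G H^-1 on the normalized scale
    var_beta = var_full[bp, bp, drop = FALSE],
    n_clusters = N, clusters = clusters
  ), class = "sandwich_fit")
}

#' Literal printed-recipe sandwich (comparison engine)
#'
#' Implements, exactly as the emulated study prints it, the four-step
#' recipe J_q = sum_i X_i' T_i X_i with T_i = Z_i D_q Z_i' (no inverse and no
#' residual-variance term), K blocks X_i' T_i, H = J/N, G = K K'/N,
#' Omega = H^-1 G H^-1, with i running over patients (each contributing a
#' 2-row block per pair, Z_i the 2 x 2 identity). As written T omits the
#' Bernoulli variance / inverse weighting, so J is not an information-matrix
#' analogue; the engine is provided for comparability and warns on use.
#' With D = 0 (no random effects) J is exactly singular and the error
#' surfaces, matching the formula's literal content.
#'
#' @param stacked a [stack_fits()] result (fits must share the design rows)
#' @return list of class `sandwich_fit` with `H`, `G`, `Omega`, `var_beta`
#'   on the fixed-effects block (2kQ x 2kQ), `n_subjects`
#' @export
sandwich_printed_recipe <- function(stacked) {
  stopifnot(inherits(stacked, "stacked_estimates"))
  warning("printed-recipe sandwich: the printed T = Z D Z' omits an inverse/",
          "residual term; use sandwich_empirical() for inference",
          call. = FALSE)
  fits <- stacked$fits
  Q <- stacked$index$Q
  k <- stacked$k
  n_obs <- unique(vapply(fits, `[[`, numeric(1), "n_obs"))
  if (length(n_obs) != 1) {
    stop("dimension mismatch: the printed recipe needs a common design across pairs")
  }
  N <- n_obs
  f1 <- fits[[1]]
  XtX <- if (!is.null(f1$model)) crossprod(f1$model$X) else f1$xtx
  if (!all(dim(XtX) == c(k, k))) stop("dimension mismatch between X and k")
  Jm <- matrix(0, 2 * k * Q, 2 * k * Q)
  Gm <- matrix(0, 2 * k * Q, 2 * k * Q)
  for (q in seq_len(Q)) {
    Dq <- fits[[q]]$D
    iq <- (q - 1) * 2 * k + seq_len(2 * k)
    Jm[iq, iq] <- kronecker(Dq, XtX)
    for (q2 in seq_len(Q)) {
      iq2 <- (q2 - 1) * 2 * k + seq_len(2 * k)
      # K_q K_q2' = sum_i (X_i' D_q)(X_i' D_q2)' = (D_q D_q2) ox (X'X)
      Gm[iq, iq2] <- kronecker(Dq %*% fits[[q2]]$D, XtX)
    }
  }
  H <- Jm / N
  G <- Gm / N
  Hi <- tryCatch(solve(H), error = function(e) {
    stop(sprintf("singular H in printed recipe (condition number %.3g)", kappa(H)))
  })
  Omega <- Hi %*% G %*% Hi
  structure(list(H = H, G = G, Omega = Omega, var_beta = Omega / N,
                 n_subjects = N), class = "sandwich_fit")
}

#' Average duplicates: combined estimates and covariance
#'
#' beta* = A beta_stacked and Sigma* = A Var(beta_stacked) A'; standard
#' errors are the square roots of the diagonal.
#'
#' @param A weight matrix from [build_weight_matrix()]
#' @param stacked a [stack_fits()] result
#' @param sandwich a `sandwich_fit` (engine output) supplying `var_beta`
#' @param m imputation label (integer or "CC")
#' @return list of class `combined_estimates`: `beta_star` (pk), `sigma_star`
#'   (pk x pk), `se`, `p`, `k`, `m`
#' @export
combine_estimates <- function(A, stacked, sandwich, m = "CC") {
  stopifnot(inherits(stacked, "stacked_estimates"))
  if (ncol(A) != length(stacked$beta)) stop("shape mismatch: A vs stacked vector")
  if (!all(dim(sandwich$var_beta) == length(stacked$beta))) {
    stop("shape mismatch: sandwich vs stacked vector")
  }
  p <- stacked$index$p
  k <- stacked$k
  beta_star <- as.vector(A %*% stacked$beta)
  sigma_star <- A %*% sandwich$var_beta %*% t(A)
  sigma_star <- (sigma_star + t(sigma_star)) / 2
  names(beta_star) <- paste0("y", rep(seq_len(p), each = k), ":",
                             rep(trial_seq_terms(k), p))
  structure(list(beta_star = beta_star, sigma_star = sigma_star,
                 se = sqrt(pmax(diag(sigma_star), 0)), p = p, k = k, m = m),
            class = "combined_estimates")
}

#' Pool combined estimates across imputations by Rubin's rules
#'
#' beta_bar is the mean of the per-imputation combined vectors; W the mean
#' of their covariance matrices; B the between-imputation covariance
#' (divisor M-1, full matrix retained for joint Wald tests); total
#' V = W + (1 + 1/M) B.
#'
#' @param combined list of `combined_estimates` (M >= 2, equal shapes)
#' @return list of class `pooled_estimates`: `beta_bar`, `W`, `B`, `V`,
#'   `se`, `M`
#' @export
rubin_pool <- function(combined) {
  M <- length(combined)
  if (M < 2) stop("Rubin pooling needs M >= 2 (between-imputation variance undefined)")
  pk <- length(combined[[1]]$beta_star)
  for (cm in combined) stopifnot(length(cm$beta_star) == pk)
  Bmat <- do.call(rbind, lapply(combined, `[[`, "beta_star"))
  beta_bar <- colMeans(Bmat)
  W <- Reduce(`+`, lapply(combined, `[[`, "sigma_star")) / M
  Bc <- crossprod(sweep(Bmat, 2, beta_bar)) / (M - 1)
  V <- W + (1 + 1 / M) * Bc
  structure(list(beta_bar = beta_bar, W = W, B = Bc, V = V,
                 se = sqrt(pmax(diag(V), 0)), M = M),
            class = "pooled_estimates")
}

#' Selector contrast for one term across all outcomes
#'
#' Builds the p x pk matrix whose row r has a single 1 at term `label` of
#' outcome r, for the joint null that the term is zero in every outcome.
#'
#' @param label one of the k term labels ([trial_terms()] for the trial
#'   model, `t1..tk` otherwise)
#' @param p number of outcomes
#' @param k coefficients per outcome
#' @return list of class `wald_spec`: `L` (p x pk), `df`, `label`
#' @export
build_L <- function(label, p, k) {
  terms <- trial_seq_terms(k)
  j <- match(label, terms)
  if (is.na(j)) stop("unknown coefficient label: ", label)
  L <- matrix(0, p, p * k)
  L[cbind(seq_len(p), (seq_len(p) - 1) * k + j)] <- 1
  structure(list(L = L, df = as.integer(p), label = label),
            class = "wald_spec")
}

#' Joint Wald test of a linear hypothesis
#'
#' statistic = (L beta)' (L V L')^-1 (L beta), referred to chi-squared with
#' df = rows(L). For the trial configuration (nine outcomes) the per-term
#' joint tests have nine degrees of freedom.
#'
#' @param spec a `wald_spec` (or any list with `L` and optionally `label`)
#' @param beta coefficient vector (combined or pooled)
#' @param V its covariance matrix
#' @return list: `statistic`, `df`, `p_value`, `label`
#' @export
wald_joint_test <- function(spec, beta, V) {
  L <- spec$L
  stopifnot(ncol(L) == length(beta), all(dim(V) == length(beta)))
  Lb <- as.vector(L %*% beta)
  LVL <- L %*% V %*% t(L)
  qf <- tryCatch(solve(LVL, Lb), error = function(e) {
    stop(sprintf("singular L V L' (condition number %.3g)", kappa(LVL)))
  })
  stat <- sum(Lb * qf)
  df <- nrow(L)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
       label = if (is.null(spec$label)) NA_character_ else spec$label)
}
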