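#' @name association
#' @title Between-outcome association from the pairwise random-intercept blocks
#'
#' @description
#' The full p x p random-intercept covariance D is never estimated directly;
#' it is assembled from the 2 x 2 blocks of the pairwise fits. Each outcome's
#' variance appears in its p-1 pairs and is averaged; each covariance comes
#' from its unique pair. Scaled covariances give the between-outcome
#' correlations (the strength-of-association measure), and a principal
#' component summary of the correlation matrix describes the dominant
#' directions of clinician-level heterogeneity.
NULL

#' Assemble the p x p random-intercept covariance from pairwise fits
#'
#' Diagonal entry r is the mean of the p-1 variance estimates of outcome r
#' over the pairs containing it; off-diagonal (r, s) is the covariance from
#' the unique pair (r, s). Assembly does not guarantee positive
#' semidefiniteness; implied correlations outside \[-1, 1\] are flagged.
#'
#' @param fits list of bivariate `pjmm_fit`s with `pair` labels
#' @param index a [enumerate_pairs()] result
#' @return list of class `d_matrix`: `D` (symmetric), `provenance`
#'   (per-cell contributing pairs), `flags`
#' @export
assemble_D <- function(fits, index) {
  stopifnot(inherits(index, "pair_index"))
  p <- index$p
  keys <- vapply(fits, function(f) paste(f$pair, collapse = ","), character(1))
  want <- apply(index$pairs, 1, paste, collapse = ",")
  missing <- setdiff(want, keys)
  if (length(missing)) stop("missing pair fit(s): ", paste(missing, collapse = "; "))
  fits <- fits[match(want, keys)]

  D <- matrix(0, p, p)
  nvar <- integer(p)
  prov <- matrix("", p, p)
  for (q in seq_len(index$Q)) {
    rs <- index$pairs[q, ]
    Dq <- fits[[q]]$D
    lab <- paste0("(", rs[1], ",", rs[2], ")")
    for (pos in 1:2) {
      r <- rs[pos]
      D[r, r] <- D[r, r] + Dq[pos, pos]
      nvar[r] <- nvar[r] + 1L
      prov[r, r] <- paste0(prov[r, r], lab)
    }
    D[rs[1], rs[2]] <- D[rs[2], rs[1]] <- Dq[1, 2]
    prov[rs[1], rs[2]] <- prov[rs[2], rs[1]] <- lab
  }
  diag(D) <- diag(D) / nvar
  corr_ok <- TRUE
  for (r in seq_len(p - 1)) {
    for (s in (r + 1):p) {
      if (abs(D[r, s]) > sqrt(D[r, r] * D[s, s]) + 1e-12) corr_ok <- FALSE
    }
  }
  structure(list(D = D, provenance = prov,
                 flags = list(correlation_in_range = corr_ok)),
            class = "d_matrix")
}

#' Average assembled D matrices over imputations
#'
#' Entrywise mean of the per-imputation assembled matrices (passthrough for
#' M = 1).
#'
#' @param D_list list of `d_matrix` objects (or plain matrices) of one shape
#' @return `d_matrix` with the averaged matrix
#' @export
average_over_imputations <- function(D_list) {
  stopifnot(length(D_list) >= 1)
  mats <- lapply(D_list, function(d) if (inherits(d, "d_matrix")) d$D else as.matrix(d))
  dm <- dim(mats[[1]])
  for (m in mats) stopifnot(all(dim(m) == dm))
  Dbar <- Reduce(`+`, mats) / length(mats)
  structure(list(D = Dbar, provenance = NULL,
                 flags = list(n_averaged = length(mats))),
            class = "d_matrix")
}

#' Variance-correlation table from an assembled D
#'
#' Off-diagonal (r, s) becomes cov / sqrt(var_r var_s); the emitted table has
#' variances on the diagonal and correlations below it (upper triangle
#' blank), the layout used for reporting. Cells with a zero variance are
#' reported as undefined and flagged.
#'
#' @param dmat a `d_matrix` (or plain covariance matrix)
#' @param labels optional outcome labels
#' @return list of class `varcorr`: `variances`, `corr` (symmetric matrix,
#'   NA where undefined), `table` (formatted lower-triangle data frame,
#'   2 decimals), `flags`
#' @export
corr_from_D <- function(dmat, labels = NULL) {
  D <- if (inherits(dmat, "d_matrix")) dmat$D else as.matrix(dmat)
  p <- nrow(D)
  if (is.null(labels)) {
    labels <- if (p == 9) outcome_labels() else paste0("y", seq_len(p))
  }
  v <- diag(D)
  zero <- v <= 0
  C <- diag(p)
  for (r in seq_len(p)) {
    for (s in seq_len(p)) {
      if (r != s) {
        C[r, s] <- if (zero[r] || zero[s]) NA_real_ else D[r, s] / sqrt(v[r] * v[s])
      }
    }
  }
  tab <- matrix("", p, p, dimnames = list(labels, labels))
  diag(tab) <- sprintf("%.2f", v)
  for (r in 2:p) {
    for (s in seq_len(r - 1)) {
      tab[r, s] <- if (is.na(C[r, s])) "undef" else sprintf("%.2f", C[r, s])
    }
  }
  dimnames(C) <- list(labels, labels)
  structure(list(variances = setNames(v, labels), corr = C,
                 table = as.data.frame(tab),
                 flags = list(zero_variance = labels[zero])),
            class = "varcorr")
}

#' Principal component summary of a correlation matrix
#'
#' Two conventions are provided. `"direct"` eigendecomposes the correlation
#' matrix itself: eigenvalues sum to p, and component r explains
#' lambda_r / p of the variation (loadings are eigenvectors scaled by
#' sqrt(lambda), sign-fixed so the largest-magnitude loading of each
#' component is positive). `"column"` treats the correlation matrix as a
#' data matrix whose rows are the outcomes' correlation profiles and runs a
#' column-standardized PCA on it (the convention behind the reported
#' variation percentages of the emulated study); proportions are then
#' lambda_r / sum(lambda). Negative eigenvalues of an indefinite input are
#' flagged, proportions still reported against the trace, and no
#' nearest-PSD projection is applied unless `project = TRUE`.
#'
#' @param C symmetric correlation matrix with unit diagonal
#' @param method `"direct"` (default) or `"column"`
#' @param project project an indefinite input to the nearest PSD matrix first?
#' @return list of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (p x p), `proportion` (percent), `cumulative`, `method`,
#'   `flags`
#' @export
pca_correlation <- function(C, method = c("direct", "column"), project = FALSE) {
  method <- match.arg(method)
  C <- as.matrix(C)
  p <- nrow(C)
  if (max(abs(C - t(C))) > 1e-8) stop("correlation matrix must be symmetric")
  stopifnot(max(abs(diag(C) - 1)) < 1e-8)
  if (project) C <- stats::cov2cor(psd_clip(C))
  neg <- FALSE
  if (method == "direct") {
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    lam <- e$values
    neg <- any(lam < -1e-10)
    load <- e$vectors %*% diag(sqrt(pmax(lam, 0)), p)
    prop <- 100 * lam / p
  } else {
    pr <- prcomp(C, center = TRUE, scale. = TRUE)
    lam <- pr$sdev^2
    load <- pr$rotation %*% diag(pr$sdev, length(pr$sdev))
    if (length(lam) < p) {
      lam <- c(lam, rep(0, p - length(lam)))
      load <- cbind(load, matrix(0, p, p - ncol(load)))
    }
    prop <- 100 * lam / sum(lam)
  }
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(load))) {
    mi <- which.max(abs(load[, j]))
    if (length(mi) && load[mi, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- rownames(C)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(eigenvalues = lam, loadings = load, proportion = prop,
                 cumulative = cumsum(prop), method = method,
                 flags = list(negative_eigenvalues = neg)),
            class = "pca_result")
}
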