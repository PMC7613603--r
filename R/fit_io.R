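#' Serialize a fitted model to structured text
#'
#' Writes the fit as JSON: coefficients, random-intercept covariance, full
#' parameter vector, log-likelihood, convergence flags, total Hessian,
#' per-cluster score matrix, cluster labels and the design cross-product.
#' This is everything the pairwise combination stage consumes, so fits can
#' be computed once and recombined later.
#'
#' @param fit a `pjmm_fit`
#' @param path output path (conventionally `.json`)
#' @return `path`, invisibly
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pjmm_fit"))
  obj <- list(
    p = fit$p, k = fit$k, pair = fit$pair, outcomes = fit$outcomes,
    terms = fit$terms, beta = fit$beta, D = fit$D, theta = fit$theta,
    loglik = fit$loglik, converged = fit$converged, grad_norm = fit$grad_norm,
    boundary = fit$boundary, nq = fit$nq,
    n_clusters = fit$n_clusters, n_obs = fit$n_obs,
    hessian = fit$hessian, vcov = fit$vcov,
    cluster_scores = fit$cluster_scores, cluster_levels = fit$cluster_levels,
    xtx = crossprod(fit$model$X)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized fit
#'
#' Restores the subset of a `pjmm_fit` needed by the combination,
#' association and reporting stages (the raw model frame is not stored;
#' refitting requires the data).
#'
#' @param path JSON path written by [write_fit()]
#' @return `pjmm_fit`-classed list
#' @export
read_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("beta", "D", "hessian", "vcov", "cluster_scores", "xtx")) {
    o[[nm]] <- as.matrix(o[[nm]])
  }
  o$cluster_levels <- as.character(o$cluster_levels)
  o$pair <- as.integer(o$pair)
  structure(o, class = "pjmm_fit")
}
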