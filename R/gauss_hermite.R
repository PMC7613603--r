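#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule (weight function
#' exp(-x^2)), computed by the Golub-Welsch eigenvalue method on the Jacobi
#' matrix of the Hermite recurrence. Used internally by the adaptive
#' quadrature of the random-intercept likelihoods.
#'
#' @param n number of nodes (>= 1)
#' @return list with `nodes` (ascending), `weights`, and `logw`
#' @examples
#' gh <- gauss_hermite(5)
#' sum(gh$weights * gh$nodes^2) # = sqrt(pi)/2, second moment of exp(-x^2)
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi), logw = 0.5 * log(pi)))
  }
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  w <- sqrt(pi) * e$vectors[1, ord]^2
  list(nodes = nodes, weights = w, logw = log(w))
}
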