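#' Multivariate normal log-density
#'
#' Numerically stable evaluation via the Cholesky factor of the
#' covariance; errors if the covariance is not positive-definite (any
#' non-PD covariance must have been repaired upstream with
#' [nearest_pd()]).
#'
#' @param x a d-vector, or a d x n matrix of column vectors.
#' @param mu mean d-vector.
#' @param Sigma d x d positive-definite covariance.
#' @return log-density (length-n vector for matrix input).
#' @export
mvn_logpdf <- function(x, mu, Sigma) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  d <- length(mu)
  if (nrow(x) != d || !all(dim(Sigma) == d)) {
    stop("dimension mismatch between x, mu and Sigma")
  }
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("Sigma is not positive-definite; ",
                                         "repair it with nearest_pd()"))
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

#' Nearest positive-definite repair of a covariance matrix
#'
#' Eigenvalue clipping: eigenvalues below the floor
#' `eps = 1e-8 * trace(S)/d` are raised to the floor and the matrix is
#' reconstructed. A matrix that is already positive-definite is returned
#' unchanged. Non-symmetric input is symmetrised first (with a warning).
#'
#' @param S symmetric matrix.
#' @param eps_scale relative eigenvalue floor (default `1e-8`).
#' @return positive-definite matrix; attribute `repaired` is `TRUE` when
#'   clipping was applied.
#' @export
nearest_pd <- function(S, eps_scale = 1e-8) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-10 * max(1, max(abs(S)))) {
    warning("input not symmetric; symmetrising")
  }
  S <- (S + t(S)) / 2
  d <- nrow(S)
  ev <- eigen(S, symmetric = TRUE)
  tr <- sum(diag(S))
  if (tr <= 0) tr <- sum(pmax(ev$values, 0))  # pathological trace
  eps <- eps_scale * max(tr / d, .Machine$double.xmin)
  if (min(ev$values) > 0) {
    attr(S, "repaired") <- FALSE
    return(S)
  }
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  attr(out, "repaired") <- TRUE
  out
}
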