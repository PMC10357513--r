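#' Seeded FastICA decomposition
#'
#' Symmetric fixed-point FastICA with the tanh contrast function: rows of
#' `x` are centred, whitened by eigendecomposition of the channel covariance,
#' and unmixed by orthogonal-iteration updates. The starting rotation is
#' drawn from a seeded RNG so the decomposition is reproducible.
#'
#' @param x channels x time numeric matrix.
#' @param n_comp Number of components (capped at the whitened rank).
#' @param seed Integer seed for the initial rotation.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the rotation update.
#' @param alpha Slope of the tanh contrast.
#' @return List with `S` (components x time source estimates), `A`
#'   (channels x components mixing matrix), `mean` (channel means),
#'   `W`, `K` (unmixing and whitening matrices) and `converged`.
#' @export
fast_ica <- function(x, n_comp = nrow(x), seed = 1L, max_iter = 200L,
                     tol = 1e-4, alpha = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, all(is.finite(x)))
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cov <- tcrossprod(xc) / n
  eg <- eigen(cov, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(pos))
  E <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  d <- eg$values[seq_len(n_comp)]
  K <- diag(1 / sqrt(d), n_comp) %*% t(E)       # whitening: Z = K xc
  Z <- K %*% xc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_comp^2), n_comp)))
  sym_decorrelate <- function(W) {
    sv <- eigen(tcrossprod(W), symmetric = TRUE)
    sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-12)), n_comp) %*%
      t(sv$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(alpha * U)
    gprime <- alpha * (1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(gprime), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z
  A <- E %*% diag(sqrt(d), n_comp) %*% t(W)     # xc = A S
  list(S = S, A = A, mean = mu, W = W, K = K, converged = converged)
}
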