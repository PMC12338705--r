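## Shared numerical helpers: symmetry/PSD checks and repair.

symmetrize <- function(K) (K + t(K)) / 2

## Kernels must be PSD up to round-off. Mildly negative eigenvalues
## (>= -1e-6 of the largest) are clipped to zero; anything worse is a
## genuine construction error and raises.
repairPSD <- function(K, label = "kernel") {
  K <- symmetrize(K)
  ev <- eigen(K, symmetric = TRUE)
  lmax <- max(abs(ev$values), .Machine$double.eps)
  lmin <- min(ev$values)
  if (lmin >= -1e-8 * lmax) return(K)
  if (lmin < -1e-6 * lmax)
    stop(sprintf("%s is not positive semi-definite (min eig %.3g)",
                 label, lmin))
  vals <- pmax(ev$values, 0)
  K2 <- ev$vectors %*% (vals * t(ev$vectors))
  dimnames(K2) <- dimnames(K)
  symmetrize(K2)
}

checkKernel <- function(K, label = "kernel") {
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop(sprintf("%s is not symmetric", label))
  ev <- eigen(symmetrize(K), symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(abs(ev), .Machine$double.eps)
  if (min(ev) < -1e-8 * lmax)
    stop(sprintf("%s has eigenvalue %.3g below tolerance", label, min(ev)))
  invisible(TRUE)
}

## Population-variance standardization (divide by q, not q - 1), so a
## balanced binary code maps to exactly +/-1.
standardizeCols <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (is.null(scale)) scale <- sqrt(colMeans(Xc^2))
  if (any(scale <= 0))
    stop("zero-variance covariate column: ",
         paste(colnames(X)[scale <= 0], collapse = ", "))
  list(X = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}
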