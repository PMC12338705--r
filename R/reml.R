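## REML machinery for the RKHS mixed models
##   y = mu 1 + sum_k u_k + eps,  u_k ~ N(0, sigma2_k K_k),  eps ~ N(0, sigma2_e I)
## Fixed effects are the intercept only. V = sum_k sigma2_k K_k + sigma2_e I.

#' Kernels entering each named RKHS model
#'
#' @param model "G-BLUP", "E-BLUP", "GE-BLUP" or "GxE-BLUP".
#' @return character vector of kernel names from \{"ZGZt", "E", "GxE"\}.
#' @export
modelKernelNames <- function(model) {
  switch(match.arg(model, c("G-BLUP", "E-BLUP", "GE-BLUP", "GxE-BLUP")),
         "G-BLUP" = "ZGZt",
         "E-BLUP" = "E",
         "GE-BLUP" = c("ZGZt", "E"),
         "GxE-BLUP" = c("ZGZt", "E", "GxE"))
}

## One likelihood evaluation. Returns loglik and, when derivs = TRUE, the
## score and average-information matrix over all components (kernels then
## residual). Uses V^-1 and w = V^-1 1 so the projection P = V^-1 -
## w w'/ (1'w) is never formed explicitly.
remlEval <- function(y, Klist, theta, derivs = FALSE) {
  q <- length(y)
  m <- length(Klist)
  V <- diag(theta[m + 1], q)
  for (k in seq_len(m)) V <- V + theta[k] * Klist[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  w <- rowSums(Vinv)                      # V^-1 1
  sw <- sum(w)
  Py <- drop(Vinv %*% y) - w * (sum(w * y) / sw)
  yPy <- sum(y * Py)
  ll <- -0.5 * (logdetV + log(sw) + yPy + (q - 1) * log(2 * pi))
  out <- list(loglik = ll, Vinv = Vinv, w = w, sw = sw, Py = Py)
  if (!derivs) return(out)
  nc <- m + 1
  b <- vector("list", nc)                 # b_k = K_k P y
  trPK <- numeric(nc)
  for (k in seq_len(m)) {
    b[[k]] <- drop(Klist[[k]] %*% Py)
    Kw <- drop(Klist[[k]] %*% w)
    trPK[k] <- sum(Vinv * Klist[[k]]) - sum(w * Kw) / sw
  }
  b[[nc]] <- Py
  trPK[nc] <- sum(diag(Vinv)) - sum(w * w) / sw
  score <- ai <- NULL
  score <- numeric(nc)
  ai <- matrix(0, nc, nc)
  Pb <- vector("list", nc)
  for (k in seq_len(nc)) {
    score[k] <- -0.5 * (trPK[k] - sum(Py * b[[k]]))
    Pb[[k]] <- drop(Vinv %*% b[[k]]) - w * (sum(w * b[[k]]) / sw)
  }
  for (k in seq_len(nc)) for (l in k:nc) {
    ai[k, l] <- ai[l, k] <- 0.5 * sum(b[[k]] * Pb[[l]])
  }
  out$score <- score
  out$ai <- ai
  out
}

#' Restricted log-likelihood of an intercept-only kernel mixed model
#'
#' Evaluates l_R = -1/2 [ log|V| + log(1' V^-1 1) + y' P y +
#' (q - 1) log 2 pi ] with V = sum_k sigma2_k K_k + sigma2_eps I and P the
#' REML projection removing the intercept.
#'
#' @param y numeric response vector (length q).
#' @param kernels list of symmetric q x q matrices (may be empty).
#' @param variances numeric vector, one non-negative variance per kernel.
#' @param residVar positive residual variance.
#' @return the restricted log-likelihood (scalar).
#' @export
restrictedLogLik <- function(y, kernels, variances, residVar) {
  stopifnot(length(kernels) == length(variances), residVar >= 0,
            all(variances >= 0))
  ev <- remlEval(y, kernels, c(variances, residVar))
  if (is.null(ev)) stop("V is not positive definite")
  ev$loglik
}

## Deterministic starting points: equal split, residual-dominant,
## kernel-dominant fractions of var(y).
remlStarts <- function(m, vy) {
  eq <- rep(vy / (m + 1), m + 1)
  rd <- c(rep(0.05 * vy / max(m, 1), m), 0.95 * vy)
  kd <- c(rep(0.95 * vy / max(m, 1), m), 0.05 * vy)
  list(eq, rd, kd)
}

## Average-information REML with step-halving and a non-negativity floor.
aiReml <- function(y, Klist, theta0, floorv, tol = 1e-8, maxit = 200) {
  theta <- pmax(theta0, floorv)
  ev <- remlEval(y, Klist, theta, derivs = TRUE)
  if (is.null(ev)) return(NULL)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    free <- theta > floorv * 1.5 | ev$score > 0
    if (!any(free)) { converged <- TRUE; break }
    A <- ev$ai[free, free, drop = FALSE]
    A <- A + diag(1e-8 * max(diag(A), 1), nrow(A))
    delta <- tryCatch(solve(A, ev$score[free]), error = function(e) NULL)
    if (is.null(delta)) delta <- ev$score[free] / pmax(diag(A), 1e-12)
    step <- 1
    improved <- FALSE
    for (h in seq_len(30)) {
      prop <- theta
      prop[free] <- pmax(theta[free] + step * delta, floorv)
      evNew <- remlEval(y, Klist, prop, derivs = TRUE)
      if (!is.null(evNew) && evNew$loglik >= ev$loglik - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    dl <- abs(evNew$loglik - ev$loglik) / (abs(ev$loglik) + 1)
    theta <- prop
    ev <- evNew
    if (dl < tol) { converged <- TRUE; break }
  }
  list(theta = theta, loglik = ev$loglik, converged = converged)
}

## L-BFGS-B fallback on log-variances; the lower bound plays the role of
## a variance pinned to (numerical) zero.
lbfgsReml <- function(y, Klist, theta0, floorv, maxit = 500) {
  nll <- function(phi) {
    ev <- remlEval(y, Klist, exp(phi))
    if (is.null(ev)) return(1e10)
    -ev$loglik
  }
  ngr <- function(phi) {
    th <- exp(phi)
    ev <- remlEval(y, Klist, th, derivs = TRUE)
    if (is.null(ev)) return(rep(0, length(phi)))
    -(ev$score * th)
  }
  lower <- log(floorv)
  opt <- tryCatch(
    optim(log(pmax(theta0, floorv)), nll, ngr, method = "L-BFGS-B",
          lower = lower, upper = log(1e6 * sum(theta0) + 1),
          control = list(maxit = maxit, factr = 1e3)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  list(theta = exp(opt$par), loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' Fit an RKHS mixed model by REML
#'
#' Maximizes the restricted log-likelihood over the non-negative variance
#' components of an intercept-only kernel mixed model. The primary
#' optimizer is the average-information (AI) algorithm with step-halving
#' and a non-negativity floor — the workhorse of REML software in animal
#' and plant breeding; if it fails to converge, bounded quasi-Newton
#' (L-BFGS-B on log-variances) restarts from three deterministic points
#' (equal split, residual-dominant, kernel-dominant) take over. Variances
#' estimated at the boundary are snapped to exactly 0 when below 1e-10 of
#' the total, so variance-partition tables are clean.
#'
#' @param y numeric response vector for the training records (names are
#'   kept as record ids).
#' @param kernels named list of symmetric q x q covariance kernels,
#'   already restricted to the training records.
#' @param model optional model label stored in the result.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum AI iterations.
#' @return a [RemlFit-class].
#' @export
fitREML <- function(y, kernels, model = "custom", tol = 1e-8, maxit = 200) {
  stopifnot(is.list(kernels), length(y) >= 2)
  if (is.null(names(kernels)) && length(kernels))
    names(kernels) <- paste0("K", seq_along(kernels))
  q <- length(y)
  for (K in kernels) stopifnot(nrow(K) == q, ncol(K) == q)
  vy <- var(y)
  if (vy <= 0) vy <- 1
  m <- length(kernels)
  floorv <- 1e-10 * vy
  best <- NULL
  for (th0 in remlStarts(m, vy)) {
    res <- aiReml(y, kernels, th0, floorv, tol = tol, maxit = maxit)
    if (!is.null(res) && (is.null(best) || res$loglik > best$loglik +
                          1e-9 * (abs(best$loglik) + 1)))
      best <- res
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best) || !best$converged) {
    for (th0 in remlStarts(m, vy)) {
      res <- lbfgsReml(y, kernels, th0, floorv)
      if (!is.null(res) && (is.null(best) || res$loglik > best$loglik))
        best <- res
    }
  }
  if (is.null(best)) stop("REML optimization failed on every start")
  if (!best$converged)
    warning("REML did not converge; returning the best point found")
  theta <- best$theta
  theta[seq_len(m)][theta[seq_len(m)] < 1e-10 * sum(theta)] <- 0
  theta[m + 1] <- max(theta[m + 1], floorv)
  ev <- remlEval(y, kernels, theta)
  mu <- sum(ev$w * y) / ev$sw
  alpha <- drop(ev$Vinv %*% (y - mu))
  blups <- matrix(0, q, m, dimnames = list(names(y), names(kernels)))
  for (k in seq_len(m)) blups[, k] <- theta[k] * drop(kernels[[k]] %*% alpha)
  vc <- setNames(theta, c(names(kernels), "residual"))
  kd <- c(vapply(kernels, function(K) mean(diag(K)), numeric(1)), 1)
  names(kd) <- names(vc)
  new("RemlFit", model = model, mu = mu, varComponents = vc, blups = blups,
      alpha = alpha, loglik = ev$loglik, converged = best$converged,
      trainIds = if (is.null(names(y))) character(0) else names(y),
      kernelDiag = kd)
}

#' Fit one of the named RKHS models on a subset of records
#'
#' Subsets the kernels of a [KernelSet-class] to the training records and
#' calls [fitREML()] with the kernels that define the model (G-BLUP uses
#' ZGZ'; E-BLUP uses E; GE-BLUP both; GxE-BLUP both plus the Hadamard
#' interaction kernel).
#'
#' @param y full-length record response vector.
#' @param ks a [KernelSet-class] over all q records.
#' @param model model name.
#' @param trainIdx integer indices of the training records (default all).
#' @param ... passed to [fitREML()].
#' @return a [RemlFit-class].
#' @export
fitModel <- function(y, ks, model, trainIdx = seq_along(y), ...) {
  stopifnot(is(ks, "KernelSet"))
  kn <- modelKernelNames(model)
  kernels <- lapply(kn, function(nm)
    slot(ks, nm)[trainIdx, trainIdx, drop = FALSE])
  names(kernels) <- kn
  yt <- y[trainIdx]
  if (is.null(names(yt))) names(yt) <- rownames(ks@Z)[trainIdx]
  fitREML(yt, kernels, model = model, ...)
}

#' Extend BLUPs to unobserved records and predict phenotypes
#'
#' For each kernel k, u_k(all) = sigma2_k K_k[, train] V^-1 (y - mu 1);
#' predictions for the test records are mu plus the sum of the extended
#' random effects. This is the standard BLUP extension of a kernel mixed
#' model to records not used in fitting.
#'
#' @param fit a [RemlFit-class] obtained on the training records.
#' @param ks the [KernelSet-class] over all records (train and test).
#' @param trainIdx,testIdx disjoint record index sets; `trainIdx` must be
#'   the records the fit was obtained on, in the same order.
#' @return named numeric vector of predicted phenotypes for `testIdx`.
#' @export
blupPredict <- function(fit, ks, trainIdx, testIdx) {
  stopifnot(is(fit, "RemlFit"), is(ks, "KernelSet"))
  if (length(intersect(trainIdx, testIdx)))
    stop("test indices overlap the training set")
  kn <- setdiff(names(fit@varComponents), "residual")
  yhat <- rep(fit@mu, length(testIdx))
  for (nm in kn) {
    s2 <- fit@varComponents[nm]
    if (s2 <= 0) next
    Kct <- slot(ks, nm)[testIdx, trainIdx, drop = FALSE]
    yhat <- yhat + s2 * drop(Kct %*% fit@alpha)
  }
  names(yhat) <- rownames(ks@Z)[testIdx]
  yhat
}

#' Proportion of variance explained by each component
#'
#' The phenotypic variance a component contributes is its variance
#' parameter times the mean diagonal of its kernel (the VanRaden GRM of
#' fully inbred lines has mean diagonal near 2, so sigma2_a alone would
#' understate the genetic share by half); the residual kernel is the
#' identity. pve_k = sigma2_k d_k / sum_j sigma2_j d_j, residual
#' included; entries are non-negative and sum to one. For kernels with
#' unit mean diagonal this reduces to the plain ratio of variance
#' components.
#'
#' @param fit a [RemlFit-class].
#' @return named numeric vector of variance proportions.
#' @export
partitionVariance <- function(fit) {
  stopifnot(is(fit, "RemlFit"))
  if (!fit@converged)
    warning("variance partition from a non-converged fit")
  vc <- fit@varComponents * fit@kernelDiag
  tot <- sum(vc)
  if (tot <= 0) stop("all variance components are zero")
  vc / tot
}
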