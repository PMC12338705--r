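#' Legendre polynomial basis
#'
#' Plain (unnormalized) Legendre polynomials on [-1, 1] via the
#' three-term recurrence (t+1) P_{t+1} = (2t+1) x P_t - t P_{t-1}, with
#' P_0 = 1 and P_1(x) = x.
#'
#' @param x numeric values in [-1, 1] (tolerance 1e-9).
#' @param order highest polynomial order T (>= 0).
#' @return length(x) x (order+1) matrix; columns are P_0 .. P_T.
#' @export
legendreBasis <- function(x, order = 1) {
  stopifnot(order >= 0)
  if (any(abs(x) > 1 + 1e-9))
    stop("environmental value outside [-1, 1]")
  x <- pmin(pmax(x, -1), 1)
  P <- matrix(0, length(x), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) for (t in 1:(order - 1))
    P[, t + 2] <- ((2 * t + 1) * x * P[, t + 1] - t * P[, t]) / (t + 1)
  colnames(P) <- paste0("P", 0:order)
  P
}

envLabel <- function(sex, temperature) paste(sex, temperature, sep = "_")

#' Environmental values from training phenotypes
#'
#' The environmental gradient of the reaction-norm model: the raw value of
#' an environment is the mean phenotype over the training records measured
#' in it, min-max mapped to [-1, 1] across the training environments
#' (x = 2 (m - m_min)/(m_max - m_min) - 1). Adding a constant to all
#' phenotypes leaves x unchanged.
#'
#' @param pheno phenotype data.frame with columns line, sex, temperature,
#'   lifespan (training records only).
#' @return list with `values` (named standardized x per environment),
#'   `means` (named raw environment means) and `bounds` (c(min, max)).
#' @export
envValues <- function(pheno) {
  stopifnot(all(c("sex", "temperature", "lifespan") %in% names(pheno)))
  env <- envLabel(pheno$sex, pheno$temperature)
  m <- tapply(pheno$lifespan, env, mean)
  lo <- min(m); hi <- max(m)
  if (hi <= lo) stop("degenerate environmental gradient: all means equal")
  x <- 2 * (m - lo) / (hi - lo) - 1
  list(values = setNames(as.numeric(x), names(m)),
       means = setNames(as.numeric(m), names(m)),
       bounds = c(min = lo, max = hi))
}

#' Environmental value for an unseen environment
#'
#' Leakage-free extrapolation: the unseen environment's raw mean is
#' predicted by ordinary least squares of the training environment means
#' on the standardized sex/temperature covariates, then min-max mapped
#' with the training bounds and clipped to [-1, 1]. Using the test
#' environment's own observed mean would leak test information; pass
#' `observedMean` explicitly only for replication studies.
#'
#' @param ev result of [envValues()] on the training records.
#' @param design an [EnvDesign-class] whose covariates cover the new
#'   environment.
#' @param newEnv environment label to map.
#' @param observedMean optional observed mean that overrides the OLS
#'   extrapolation (off by default; leaks test information).
#' @return standardized value in [-1, 1].
#' @export
extrapolateEnvValue <- function(ev, design, newEnv, observedMean = NULL) {
  if (newEnv %in% names(ev$values) ) return(ev$values[[newEnv]])
  if (is.null(observedMean)) {
    X <- design@covariates
    trainEnvs <- intersect(rownames(X), names(ev$means))
    if (!newEnv %in% rownames(X))
      stop("environment ", newEnv, " has no covariates in the design")
    df <- data.frame(m = ev$means[trainEnvs],
                     X[trainEnvs, , drop = FALSE])
    fitlm <- lm(m ~ ., data = df)
    observedMean <- predict(fitlm,
                            as.data.frame(X[newEnv, , drop = FALSE]))
  }
  lo <- ev$bounds["min"]; hi <- ev$bounds["max"]
  x <- 2 * (observedMean - lo) / (hi - lo) - 1
  unname(pmin(pmax(x, -1), 1))
}

## Build Sigma_a from its log-Cholesky parameters (diagonal on log scale).
cholFromPars <- function(pars, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- pars
  diag(L) <- exp(diag(L))
  L
}

#' Fit the random-regression (reaction norm) model by REML
#'
#' y_ijk = sum_t beta_t phi_t(x_j) + sum_t a_it phi_t(x_j) + eps_ijk with
#' random coefficients a ~ N(0, G (x) Sigma_a) and a separate residual
#' variance per environment. The covariance of the records is
#' V = ZGZ' * (Phi Sigma_a Phi') + diag(sigma2_eps(env)), optimized over
#' the log-Cholesky factor of Sigma_a and the log residual variances by
#' L-BFGS-B with analytic gradients of the restricted log-likelihood
#' (fixed-effect design Phi).
#'
#' @param pheno training phenotype data.frame (line, sex, temperature,
#'   lifespan).
#' @param G n x n GRM with line ids as dimnames, covering the training
#'   lines.
#' @param order Legendre order T (default 1: intercept and slope).
#' @param envX optional named environmental values overriding
#'   [envValues()] (used internally for held-out-environment prediction).
#' @param fixedPars optional list with `SigmaA` ((T+1) x (T+1) PSD) and
#'   `residVars` (length-r, ordered by sorted environment label, or a
#'   single shared value): skip estimation and evaluate the model —
#'   restricted likelihood, fixed coefficients, BLUPs — at these variance
#'   parameters.
#' @return an [RRMFit-class].
#' @export
fitRRM <- function(pheno, G, order = 1, envX = NULL, fixedPars = NULL) {
  env <- envLabel(pheno$sex, pheno$temperature)
  ev <- envValues(pheno)
  if (is.null(envX)) envX <- ev$values
  if (length(unique(env)) < 2) stop("need >= 2 training environments")
  y <- pheno$lifespan
  q <- length(y)
  lines <- unique(as.character(pheno$line))
  n <- length(lines)
  if (!all(lines %in% rownames(G)))
    stop("G does not cover all training lines")
  Gt <- G[lines, lines, drop = FALSE]
  li <- match(as.character(pheno$line), lines)
  ZGZt <- Gt[li, li, drop = FALSE]
  x <- envX[env]
  Phi <- legendreBasis(as.numeric(x), order)
  k <- order + 1
  envsU <- sort(unique(env))
  r <- length(envsU)
  ei <- match(env, envsU)
  vy <- var(y); if (vy <= 0) vy <- 1
  nL <- k * (k + 1) / 2
  lowTri <- lower.tri(matrix(0, k, k), diag = TRUE)
  diagIdx <- which(diag(k)[lowTri] == 1)

  evalFn <- function(pars, derivs = FALSE) {
    L <- cholFromPars(pars[seq_len(nL)], k)
    Sa <- L %*% t(L)
    s2e <- exp(pars[nL + seq_len(r)])
    V <- ZGZt * (Phi %*% Sa %*% t(Phi))
    diag(V) <- diag(V) + s2e[ei]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% Phi
    XtVX <- crossprod(Phi, VX)
    XtVXinv <- solve(XtVX)
    P <- Vinv - VX %*% XtVXinv %*% t(VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus +
                  sum(y * Py) + (q - k) * log(2 * pi))
    out <- list(loglik = as.numeric(ll), Vinv = Vinv, P = P, Py = Py,
                XtVXinv = XtVXinv, VX = VX, Sa = Sa, s2e = s2e, L = L)
    if (!derivs) return(out)
    gr <- numeric(length(pars))
    idxMat <- which(lowTri, arr.ind = TRUE)
    for (p in seq_len(nL)) {
      dL <- matrix(0, k, k)
      dL[idxMat[p, 1], idxMat[p, 2]] <-
        if (p %in% diagIdx) L[idxMat[p, 1], idxMat[p, 2]] else 1
      dSa <- dL %*% t(L) + L %*% t(dL)
      dV <- ZGZt * (Phi %*% dSa %*% t(Phi))
      gr[p] <- -0.5 * (sum(P * dV) - sum(Py * (dV %*% Py)))
    }
    for (j in seq_len(r)) {
      sel <- ei == j
      # dV/dlog s2e_j = s2e_j on the diagonal of environment j
      gr[nL + j] <- -0.5 * s2e[j] * (sum(diag(P)[sel]) - sum(Py[sel]^2))
    }
    out$grad <- gr
    out
  }

  if (!is.null(fixedPars)) {
    Sa <- fixedPars$SigmaA
    s2e <- rep(fixedPars$residVars, length.out = r)
    # evaluate directly at the supplied parameters (ridge the Cholesky of
    # a singular SigmaA so the log-Cholesky map stays defined)
    Lf <- t(chol(Sa + diag(1e-12 * (sum(diag(Sa)) + 1), k)))
    pars <- numeric(nL + r)
    pars[seq_len(nL)] <- Lf[lowTri]
    pars[seq_len(nL)][diagIdx] <- log(pmax(diag(Lf), 1e-300))
    pars[nL + seq_len(r)] <- log(s2e)
    e <- evalFn(pars)
    if (is.null(e)) stop("V not positive definite at the fixed parameters")
    converged <- TRUE
  } else {
    pars0 <- numeric(nL + r)
    L0 <- t(chol(diag(rep(0.2 * vy, k))))
    pars0[seq_len(nL)] <- L0[lowTri]
    pars0[seq_len(nL)][diagIdx] <- log(diag(L0))
    pars0[nL + seq_len(r)] <- log(0.5 * vy)
    lower <- rep(-Inf, nL + r)
    lower[diagIdx] <- 0.5 * log(1e-10 * vy)
    lower[nL + seq_len(r)] <- log(1e-8 * vy)
    opt <- optim(pars0,
                 fn = function(p) { e <- evalFn(p); if (is.null(e)) 1e10 else -e$loglik },
                 gr = function(p) { e <- evalFn(p, derivs = TRUE)
                   if (is.null(e)) rep(0, length(p)) else -e$grad },
                 method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500, factr = 1e4))
    converged <- opt$convergence == 0
    if (!converged) warning("RRM REML did not converge (code ",
                            opt$convergence, ")")
    e <- evalFn(opt$par)
  }
  beta <- drop(e$XtVXinv %*% crossprod(e$VX, y))
  resid <- drop(e$Vinv %*% (y - Phi %*% beta))
  # coefficient BLUPs: u = (G (x) Sigma_a) Z' V^-1 (y - Phi beta)
  Zl <- matrix(0, q, n); Zl[cbind(seq_len(q), li)] <- 1
  coefB <- (Gt %*% crossprod(Zl, Phi * resid)) %*% e$Sa
  dimnames(coefB) <- list(lines, paste0("P", 0:order))
  new("RRMFit", beta = setNames(beta, paste0("P", 0:order)),
      SigmaA = symmetrize(e$Sa),
      residVars = setNames(e$s2e, envsU),
      coefBlups = coefB,
      envValues = envX[envsU][!is.na(envX[envsU])],
      envMeans = ev$means,
      loglik = e$loglik, converged = converged)
}

#' Predict phenotypes from a reaction-norm fit
#'
#' y_hat = sum_t (beta_t + a_it) phi_t(x_j). Lines absent from the fit get
#' coefficient BLUPs extended by G[new, old] G[old, old]^-1; environments
#' absent from the fit need a value in `newEnvValues` (see
#' [extrapolateEnvValue()]).
#'
#' @param fit an [RRMFit-class].
#' @param targets data.frame with columns `line` and `env`.
#' @param G full GRM with dimnames covering fitted and new lines.
#' @param newEnvValues named standardized values for environments not in
#'   the fit.
#' @return named numeric vector of predictions.
#' @export
predictRRM <- function(fit, targets, G, newEnvValues = NULL) {
  stopifnot(is(fit, "RRMFit"), all(c("line", "env") %in% names(targets)))
  xmap <- c(fit@envValues, newEnvValues)
  miss <- setdiff(unique(targets$env), names(xmap))
  if (length(miss))
    stop("no environmental value for: ", paste(miss, collapse = ", "),
         " (supply newEnvValues, e.g. via extrapolateEnvValue)")
  lines <- as.character(targets$line)
  fitted <- rownames(fit@coefBlups)
  A <- fit@coefBlups
  newLines <- setdiff(unique(lines), fitted)
  if (length(newLines)) {
    if (is.null(rownames(G)) || !all(c(newLines, fitted) %in% rownames(G)))
      stop("G must carry dimnames covering fitted and new lines")
    Goo <- G[fitted, fitted, drop = FALSE]
    dmin <- 1e-8 * mean(diag(Goo))
    Anew <- G[newLines, fitted, drop = FALSE] %*%
      solve(Goo + diag(dmin, nrow(Goo)), A)
    rownames(Anew) <- newLines
    A <- rbind(A, Anew)
  }
  Phi <- legendreBasis(as.numeric(xmap[targets$env]),
                       length(fit@beta) - 1)
  coefs <- sweep(A[match(lines, rownames(A)), , drop = FALSE], 2,
                 fit@beta, "+")
  pred <- rowSums(coefs * Phi)
  names(pred) <- paste(lines, targets$env, sep = ":")
  pred
}
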