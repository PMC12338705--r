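#' Fit the Bayesian multi-trait genomic model by Gibbs sampling
#'
#' Treats the phenotype in each of the r environments as a separate trait:
#' Y = 1 M' + A + R with A matrix-normal (row covariance G, column
#' covariance Sigma_A) and a diagonal residual covariance. Conjugate
#' priors: Sigma_A is inverse-Wishart with nu0 = r + 2 degrees of freedom
#' and a scale putting the prior mode of each genetic variance at half the
#' trait's phenotypic variance; each residual variance is scaled-inverse-
#' chi-squared with 5 df and mode half the phenotypic variance. Missing
#' cells are handled by data augmentation. The chain is driven entirely by
#' R's RNG: the same `seed` and chain settings give bit-identical draws.
#'
#' @param Y n x r phenotype matrix (NA for missing cells), rownames = line
#'   ids, colnames = trait/environment ids.
#' @param G n x n genomic relationship matrix over the same lines. A
#'   numerically singular G is ridged by 1e-8 tr(G)/n with a warning.
#' @param iterations,burnin,thin chain settings. The defaults are a
#'   desk-scale chain; the study-scale chain (300000 / 200000 / 50) is
#'   available by passing those values.
#' @param seed integer seed.
#' @return an [MTMFit-class].
#' @export
fitMTM <- function(Y, G, iterations = 6000, burnin = 1000, thin = 5,
                   seed = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y); r <- ncol(Y)
  stopifnot(nrow(G) == n, ncol(G) == n, iterations > burnin, thin >= 1)
  obs <- !is.na(Y)
  if (any(colSums(obs) < 2))
    stop("each trait needs at least 2 observed cells")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("L", seq_len(n))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("T", seq_len(r))
  eg <- eigen(symmetrize(G), symmetric = TRUE)
  dmin <- 1e-8 * sum(diag(G)) / n
  if (min(eg$values) < dmin) {
    warning("G is numerically singular; adding ridge 1e-8 tr(G)/n")
    eg$values <- eg$values + dmin
  }
  phenVar <- apply(Y, 2, var, na.rm = TRUE)
  phenVar[!is.finite(phenVar) | phenVar <= 0] <- 1
  nu0 <- r + 2
  # inverse-Wishart mode = S0 / (nu0 + r + 1); the genetic variance a
  # trait receives is SigmaA[j, j] * mean(diag(G)), so the prior scale is
  # divided by the mean kernel diagonal (as BGLR scales its default
  # priors by the kernel) to put the mode of the *contributed* variance
  # at half the phenotypic variance.
  S0 <- diag(0.5 * phenVar * (nu0 + r + 1) / mean(diag(G)), r)
  # scaled-inverse-chi2 mode = df * s / (df + 2)
  df0 <- 5
  s0R <- 0.5 * phenVar * (df0 + 2) / df0
  Yin <- Y
  Yin[!obs] <- 0
  set.seed(seed)
  res <- .mtm_gibbs(Yin, obs * 1L, eg$vectors, eg$values, S0, nu0, s0R,
                    df0, as.integer(iterations), as.integer(burnin),
                    as.integer(thin))
  dimnames(res$SigmaA) <- list(colnames(Y), colnames(Y))
  dimnames(res$Ahat) <- dimnames(Y)
  new("MTMFit",
      intercepts = setNames(drop(res$M), colnames(Y)),
      SigmaA = symmetrize(res$SigmaA),
      sigmaR = setNames(drop(res$sigmaR), colnames(Y)),
      Ahat = res$Ahat,
      samples = list(SigmaA = res$sampSigmaA, sigmaR = res$sampSigmaR),
      chain = list(iterations = iterations, burnin = burnin, thin = thin,
                   seed = seed),
      lineIds = rownames(Y), traitIds = colnames(Y))
}

#' Cross-environment genetic correlations
#'
#' r_A[i, j] = Sigma_A[i, j] / sqrt(Sigma_A[i, i] Sigma_A[j, j]). Values
#' below 1 off the diagonal indicate genetic effects that differ between
#' environments, i.e. gene-environment interaction.
#'
#' @param SigmaA symmetric PSD genetic covariance matrix with positive
#'   diagonal (e.g. `fit@SigmaA`).
#' @return correlation matrix with unit diagonal.
#' @export
geneticCorrelations <- function(SigmaA) {
  if (is(SigmaA, "MTMFit")) SigmaA <- SigmaA@SigmaA
  dg <- diag(SigmaA)
  if (any(dg <= 0)) stop("Sigma_A has non-positive diagonal entries")
  R <- SigmaA / sqrt(outer(dg, dg))
  diag(R) <- 1
  R
}

#' Predict phenotype cells from a multi-trait fit
#'
#' For fitted lines the prediction is the posterior mean M[trait] +
#' A_hat[line, trait]; for lines absent from the fit the genetic values
#' are extended by the conditional expectation
#' G[new, old] G[old, old]^-1 A_hat.
#'
#' @param fit an [MTMFit-class].
#' @param targets data.frame with columns `line` and `trait`.
#' @param G full GRM whose dimnames cover both the fitted and any new
#'   lines.
#' @return named numeric vector of predictions, one per target row.
#' @export
predictMTM <- function(fit, targets, G) {
  stopifnot(is(fit, "MTMFit"),
            all(c("line", "trait") %in% names(targets)))
  if (!all(targets$trait %in% fit@traitIds))
    stop("unknown trait(s): ",
         paste(setdiff(unique(targets$trait), fit@traitIds), collapse = ", "))
  lines <- as.character(targets$line)
  newLines <- setdiff(unique(lines), fit@lineIds)
  A <- fit@Ahat
  if (length(newLines)) {
    if (is.null(rownames(G)) ||
        !all(c(newLines, fit@lineIds) %in% rownames(G)))
      stop("G must carry dimnames covering fitted and new lines")
    Goo <- G[fit@lineIds, fit@lineIds, drop = FALSE]
    Gno <- G[newLines, fit@lineIds, drop = FALSE]
    dmin <- 1e-8 * mean(diag(Goo))
    Anew <- Gno %*% solve(Goo + diag(dmin, nrow(Goo)), fit@Ahat)
    rownames(Anew) <- newLines
    A <- rbind(A, Anew)
  }
  jt <- match(targets$trait, fit@traitIds)
  pred <- fit@intercepts[jt] + A[cbind(match(lines, rownames(A)), jt)]
  names(pred) <- paste(lines, targets$trait, sep = ":")
  pred
}
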