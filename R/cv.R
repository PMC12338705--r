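## Cross-validation schemes, the accuracy metric and the orchestration.

roundHalfUp <- function(x) floor(x + 0.5)

#' Build cross-validation folds
#'
#' Three schemes mirror how information can transfer from training to
#' test data. RandomLines: a random 17% of the lines go to test with all
#' their records, so test genotypes are unseen. RandomObservations: a
#' random 17% of the records go to test, so every line and environment
#' stays represented in training. NewEnvironment: all records of one
#' sex/temperature combination are held out (one deterministic fold per
#' environment). Fractions are rounded half-up to counts; replicate k of
#' the random schemes is drawn with seed `seed + k`.
#'
#' @param pheno phenotype data.frame (line, sex, temperature, lifespan).
#' @param scheme "RandomLines", "RandomObservations" or "NewEnvironment".
#' @param fraction test fraction for the random schemes (default 0.17).
#' @param nReplicates number of replicates (default 6; for NewEnvironment
#'   it must equal the number of environments).
#' @param seed base seed.
#' @return list of [CVFold-class] objects.
#' @export
makeFolds <- function(pheno, scheme = c("RandomLines", "RandomObservations",
                                        "NewEnvironment"),
                      fraction = 0.17, nReplicates = 6, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(fraction > 0, fraction < 1)
  q <- nrow(pheno)
  all <- seq_len(q)
  env <- envLabel(pheno$sex, pheno$temperature)
  folds <- list()
  if (scheme == "NewEnvironment") {
    envsU <- unique(env)
    if (length(envsU) != nReplicates)
      stop("NewEnvironment requires nReplicates == number of environments")
    for (k in seq_along(envsU)) {
      test <- which(env == envsU[k])
      folds[[k]] <- new("CVFold", scheme = scheme,
                        train = setdiff(all, test), test = test,
                        replicate = k, seed = NA_integer_)
    }
    return(folds)
  }
  lines <- unique(as.character(pheno$line))
  for (k in seq_len(nReplicates)) {
    sk <- as.integer(seed + k)
    set.seed(sk)
    if (scheme == "RandomLines") {
      nTest <- roundHalfUp(fraction * length(lines))
      testLines <- sample(lines, nTest)
      test <- which(as.character(pheno$line) %in% testLines)
    } else {
      test <- sort(sample(all, roundHalfUp(fraction * q)))
    }
    if (!length(test) || length(test) == q)
      stop("degenerate fold: empty test or empty training set")
    folds[[k]] <- new("CVFold", scheme = scheme,
                      train = setdiff(all, test), test = test,
                      replicate = k, seed = sk)
  }
  folds
}

#' Prediction accuracy
#'
#' R^2 of the ordinary least-squares regression of the true phenotypes on
#' the predicted phenotypes (with intercept), which equals the squared
#' Pearson correlation of the two vectors and is therefore invariant to
#' affine maps of the predictions. A constant prediction vector is scored
#' 0 with a warning, so a degenerate model does not abort a sweep.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 3.
#' @return scalar R^2 in [0, 1].
#' @export
accuracyR2 <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 3)
  if (sd(yPred) <= .Machine$double.eps * (abs(mean(yPred)) + 1)) {
    warning("constant predictions; R^2 defined as 0")
    return(0)
  }
  cor(yTrue, yPred)^2
}

cvModels <- c("G-BLUP", "E-BLUP", "GE-BLUP", "GxE-BLUP", "mvG-BLUP", "RRM")

## Phenotype matrix (lines x environments) from the training records only.
trainTraitMatrix <- function(pheno, trainIdx, envsU) {
  tr <- pheno[trainIdx, ]
  env <- envLabel(tr$sex, tr$temperature)
  lines <- unique(as.character(tr$line))
  Y <- matrix(NA_real_, length(lines), length(envsU),
              dimnames = list(lines, envsU))
  Y[cbind(match(as.character(tr$line), lines), match(env, envsU))] <-
    tr$lifespan
  Y
}

#' Run models through a cross-validation scheme
#'
#' For each fold, kernels are built over all records (covariates of test
#' records are design information, not phenotypes) but every estimated
#' quantity — variance components, environmental standardization,
#' environment means, chain states — comes from training records only.
#' Predictions on the held-out records are scored with [accuracyR2()] per
#' replicate. Under NewEnvironment the per-fold R^2 is also reported per
#' test environment, and mvG-BLUP is rejected: a multi-trait model has no
#' intercept, genetic or residual variance estimate for a trait it never
#' observed.
#'
#' @param pheno phenotype data.frame (line, sex, temperature, lifespan).
#' @param geno filtered [GenotypeMatrix-class] covering the phenotyped
#'   lines.
#' @param models subset of G-BLUP, E-BLUP, GE-BLUP, GxE-BLUP, mvG-BLUP,
#'   RRM.
#' @param scheme cross-validation scheme (see [makeFolds()]).
#' @param fraction,nReplicates,seed passed to [makeFolds()]; `seed` also
#'   drives the mvG-BLUP chains.
#' @param mtmIterations,mtmBurnin,mtmThin chain settings for mvG-BLUP.
#' @return named list of [CVResult-class], one per model.
#' @export
runCV <- function(pheno, geno, models = c("E-BLUP", "GE-BLUP", "GxE-BLUP"),
                  scheme = c("RandomLines", "RandomObservations",
                             "NewEnvironment"),
                  fraction = 0.17, nReplicates = 6, seed = 1,
                  mtmIterations = 6000, mtmBurnin = 1000, mtmThin = 5) {
  scheme <- match.arg(scheme)
  models <- match.arg(models, cvModels, several.ok = TRUE)
  if (scheme == "NewEnvironment" && "mvG-BLUP" %in% models)
    stop("mvG-BLUP cannot be fitted under the NewEnvironment scheme: ",
         "it has no parameter estimates for an unobserved environment")
  env <- envLabel(pheno$sex, pheno$temperature)
  if (scheme == "NewEnvironment") nReplicates <- length(unique(env))
  folds <- makeFolds(pheno, scheme, fraction, nReplicates, seed)
  G <- computeGRM(geno)
  y <- pheno$lifespan
  r2 <- matrix(NA_real_, length(models), length(folds),
               dimnames = list(models, NULL))
  envOfFold <- character(length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    design <- buildEnvDesign(pheno[, c("line", "sex", "temperature")],
                             standardizeOn = fold@train)
    ks <- makeKernels(geno, design, G = G)
    envsU <- unique(env[fold@train])
    envOfFold[f] <- if (scheme == "NewEnvironment")
      unique(env[fold@test]) else NA_character_
    for (m in models) {
      pred <- switch(m,
        "mvG-BLUP" = {
          Y <- trainTraitMatrix(pheno, fold@train, envsU)
          fit <- fitMTM(Y, G[rownames(Y), rownames(Y)],
                        iterations = mtmIterations, burnin = mtmBurnin,
                        thin = mtmThin,
                        seed = as.integer(seed + 1000L + fold@replicate))
          predictMTM(fit, data.frame(line = pheno$line[fold@test],
                                     trait = env[fold@test]), G)
        },
        "RRM" = {
          fit <- fitRRM(pheno[fold@train, ], G)
          newVals <- NULL
          missEnv <- setdiff(unique(env[fold@test]), names(fit@envValues))
          if (length(missEnv)) {
            ev <- envValues(pheno[fold@train, ])
            newVals <- setNames(
              vapply(missEnv, function(e2)
                extrapolateEnvValue(ev, design, e2), numeric(1)),
              missEnv)
          }
          predictRRM(fit, data.frame(line = pheno$line[fold@test],
                                     env = env[fold@test]), G,
                     newEnvValues = newVals)
        },
        { # the four RKHS mixed models
          fit <- fitModel(y, ks, m, fold@train)
          blupPredict(fit, ks, fold@train, fold@test)
        })
      r2[m, f] <- suppressWarnings(accuracyR2(y[fold@test], pred))
    }
  }
  out <- lapply(models, function(m) {
    perEnv <- if (scheme == "NewEnvironment")
      setNames(r2[m, ], envOfFold) else setNames(numeric(0), character(0))
    new("CVResult", scheme = scheme, model = m,
        perReplicateR2 = unname(r2[m, ]), meanR2 = mean(r2[m, ]),
        perEnvironmentR2 = perEnv)
  })
  names(out) <- models
  out
}

#' Tidy table of cross-validation results
#'
#' @param results list of [CVResult-class] (possibly concatenated across
#'   schemes).
#' @return data.frame with columns scheme, model, replicate, environment,
#'   r2.
#' @export
cvTable <- function(results) {
  do.call(rbind, lapply(results, function(res) {
    envs <- if (length(res@perEnvironmentR2))
      names(res@perEnvironmentR2) else NA_character_
    data.frame(scheme = res@scheme, model = res@model,
               replicate = seq_along(res@perReplicateR2),
               environment = envs, r2 = res@perReplicateR2,
               row.names = NULL)
  }))
}

#' Variance partition and genetic correlations on the full data
#'
#' Fits the four RKHS models on all records and reports each model's
#' proportion of variance explained, plus the cross-environment genetic
#' correlation matrix from the multi-trait model.
#'
#' @param pheno,geno as in [runCV()].
#' @param models RKHS models to partition.
#' @param seed seed for the multi-trait chain.
#' @param mtm logical: also fit the multi-trait model?
#' @param ... chain settings passed to [fitMTM()].
#' @return list with `fits`, `pve` (data.frame model x component) and,
#'   when `mtm`, `rA` and `mtmFit`.
#' @export
runPartition <- function(pheno, geno,
                         models = c("G-BLUP", "E-BLUP", "GE-BLUP",
                                    "GxE-BLUP"),
                         seed = 1, mtm = TRUE, ...) {
  design <- buildEnvDesign(pheno[, c("line", "sex", "temperature")])
  ks <- makeKernels(geno, design)
  y <- pheno$lifespan
  fits <- lapply(models, function(m) fitModel(y, ks, m))
  names(fits) <- models
  comps <- c("ZGZt", "E", "GxE", "residual")
  pve <- as.data.frame(t(vapply(fits, function(f) {
    p <- partitionVariance(f)
    setNames(p[comps], comps)
  }, numeric(length(comps)))))
  pve$model <- models
  out <- list(fits = fits, pve = pve)
  if (mtm) {
    env <- envLabel(pheno$sex, pheno$temperature)
    Y <- trainTraitMatrix(pheno, seq_len(nrow(pheno)), unique(env))
    G <- computeGRM(geno)
    fitM <- fitMTM(Y, G[rownames(Y), rownames(Y)], seed = seed, ...)
    out$mtmFit <- fitM
    out$rA <- geneticCorrelations(fitM)
  }
  out
}
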