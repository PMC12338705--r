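#' Simulation settings for a DGRP-like panel
#'
#' Defaults emulate the study design: fully inbred lines (dosages in
#' \{0, 2\}), six environments from two sexes crossed with three rearing
#' temperatures, one record per line x environment, and a phenotype built
#' from additive + environment + GxE + residual components whose variance
#' fractions default to the estimates from the lifespan panel
#' (0.12 / 0.72 / 0.08 / 0.08).
#'
#' @param nLines,nVariants panel size (defaults 176 lines, 3000 variants —
#'   the study's line count at a desk-scale variant count).
#' @param mafRange range the per-variant minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param sexes,temperatures the environment grid.
#' @param pve variance fractions (genetic, environment, gxe, residual);
#'   non-negative, summing to 1.
#' @param totalVar total phenotypic variance (days^2).
#' @param mu grand mean lifespan (days).
#' @param seed integer seed.
#' @return a validated settings list.
#' @export
simulationConfig <- function(nLines = 176, nVariants = 3000,
                             mafRange = c(0.05, 0.5),
                             sexes = c("F", "M"),
                             temperatures = c(18, 25, 28),
                             pve = c(genetic = 0.12, environment = 0.72,
                                     gxe = 0.08, residual = 0.08),
                             totalVar = 1, mu = 50, seed = 1) {
  stopifnot(length(pve) == 4, all(pve >= 0), abs(sum(pve) - 1) < 1e-9,
            mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2], nVariants >= 50, totalVar > 0)
  names(pve) <- c("genetic", "environment", "gxe", "residual")
  list(nLines = nLines, nVariants = nVariants, mafRange = mafRange,
       sexes = sexes, temperatures = temperatures, pve = pve,
       totalVar = totalVar, mu = mu, seed = seed)
}

#' Simulate genotypes of fully inbred lines
#'
#' Each variant's allele frequency is drawn uniformly from
#' `config$mafRange`; each line is homozygous, so its dosage is 2 with
#' that probability and 0 otherwise. Monomorphic variants are redrawn.
#'
#' @param config a [simulationConfig()].
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(config = simulationConfig()) {
  set.seed(config$seed)
  n <- config$nLines; p <- config$nVariants
  maf <- runif(p, config$mafRange[1], config$mafRange[2])
  d <- matrix(2L * rbinom(n * p, 1, rep(maf, each = n)), n, p)
  mono <- which(colSums(d) %in% c(0L, 2L * n))
  while (length(mono)) {
    maf[mono] <- runif(length(mono), config$mafRange[1], config$mafRange[2])
    d[, mono] <- 2L * rbinom(n * length(mono), 1, rep(maf[mono], each = n))
    mono <- which(colSums(d) %in% c(0L, 2L * n))
  }
  genotypeMatrix(d, lineIds = sprintf("line_%03d", seq_len(n)),
                 variantIds = sprintf("var_%05d", seq_len(p)))
}

## Draw z ~ N(0, K) through the eigendecomposition of the PSD kernel K.
drawFromKernel <- function(K) {
  eg <- eigen(symmetrize(K), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  drop(eg$vectors %*% (sqrt(vals) * rnorm(length(vals))))
}

## Rescale a component to an exact empirical variance (0 target -> exact 0).
scaleToVar <- function(v, target, label) {
  if (target <= 0) return(rep(0, length(v)))
  s <- var(v)
  if (s <= .Machine$double.eps)
    stop("component '", label, "' is degenerate; target variance ",
         target, " unrealizable")
  v * sqrt(target / s)
}

#' Simulate multi-environment phenotypes with exact variance composition
#'
#' Components are drawn from the GxE mixed-model decomposition
#' y = mu + a + e + ae + eps with a ~ N(0, ZGZ'), e = X_q gamma
#' (gamma ~ N(0, I_c): environments act through their covariates),
#' ae ~ N(0, ZGZ' * E) and iid residuals, then each component is rescaled
#' so its realized (sample) variance equals its target fraction of
#' `totalVar` exactly. Components are empirically near-orthogonal, not
#' exactly, so the total variance matches `totalVar` only approximately.
#'
#' @param geno a [GenotypeMatrix-class] (already filtered or simulated
#'   without missing values).
#' @param config a [simulationConfig()].
#' @return list with `pheno` (data.frame line, sex, temperature,
#'   lifespan), `truth` (component vectors and realized fractions),
#'   `kernels` (the [KernelSet-class] used) and `design` (the
#'   [EnvDesign-class]).
#' @export
simulatePhenotypes <- function(geno, config = simulationConfig()) {
  set.seed(config$seed + 1L)
  lines <- lineIds(geno)
  grid <- expand.grid(sex = config$sexes, temperature = config$temperatures,
                      stringsAsFactors = FALSE)
  records <- data.frame(
    line = rep(lines, each = nrow(grid)),
    sex = rep(grid$sex, times = length(lines)),
    temperature = rep(grid$temperature, times = length(lines)),
    stringsAsFactors = FALSE)
  design <- buildEnvDesign(records)
  ks <- makeKernels(geno, design)
  q <- nrow(records)
  tv <- config$totalVar
  pve <- config$pve
  a <- e <- ae <- eps <- rep(0, q)
  if (pve["genetic"] > 0)
    a <- scaleToVar(drop(ks@Z %*% drawFromKernel(ks@G)),
                    pve["genetic"] * tv, "genetic")
  if (pve["environment"] > 0) {
    Xq <- recordCovariates(design)
    e <- scaleToVar(drop(Xq %*% rnorm(ncol(Xq))),
                    pve["environment"] * tv, "environment")
  }
  if (pve["gxe"] > 0)
    ae <- scaleToVar(drawFromKernel(ks@GxE), pve["gxe"] * tv, "gxe")
  if (pve["residual"] > 0)
    eps <- scaleToVar(rnorm(q), pve["residual"] * tv, "residual")
  y <- config$mu + a + e + ae + eps
  pheno <- data.frame(records, lifespan = y, stringsAsFactors = FALSE)
  truth <- list(
    components = data.frame(a = a, e = e, ae = ae, eps = eps),
    realizedPve = c(genetic = var(a), environment = var(e),
                    gxe = var(ae), residual = var(eps)) / tv,
    config = config)
  list(pheno = pheno, truth = truth, kernels = ks, design = design)
}
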