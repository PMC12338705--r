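test_that("Legendre basis matches closed forms and the recurrence", {
  expect_equal(drop(legendreBasis(-1, 1)), c(P0 = 1, P1 = -1))
  expect_equal(drop(legendreBasis(0, 2)), c(P0 = 1, P1 = 0, P2 = -0.5))
  xs <- seq(-1, 1, length.out = 101)
  B <- legendreBasis(xs, 3)
  expect_equal(B[, "P2"], (3 * xs^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(B[, "P3"], (5 * xs^3 - 3 * xs) / 2, tolerance = 1e-12)
  # orthogonality of P0 and P1 on [-1, 1]
  expect_lt(abs(integrate(function(x) legendreBasis(x, 1)[, "P1"],
                          -1, 1)$value), 1e-12)
  expect_error(legendreBasis(1.1, 1), "outside")
})

test_that("environmental values are min-max standardized training means", {
  pheno <- data.frame(line = rep(c("a", "b"), 3),
                      sex = rep("F", 6),
                      temperature = rep(c(18, 25, 28), each = 2),
                      lifespan = c(9, 11, 19, 21, 29, 31))
  ev <- envValues(pheno)
  expect_equal(unname(ev$values[c("F_18", "F_25", "F_28")]), c(-1, 0, 1))
  expect_equal(unname(ev$means[c("F_18", "F_25", "F_28")]), c(10, 20, 30))
  # location invariance
  pheno2 <- pheno; pheno2$lifespan <- pheno$lifespan + 7
  expect_equal(envValues(pheno2)$values, ev$values)
  pheno$lifespan <- 5
  expect_error(envValues(pheno), "degenerate")
})

test_that("unseen environments get leakage-free extrapolated values", {
  sim <- smallPanel()
  keep <- sim$pheno$temperature != 28 | sim$pheno$sex != "M"
  ev <- envValues(sim$pheno[keep, ])
  x <- extrapolateEnvValue(ev, sim$design, "M_28")
  expect_gte(x, -1); expect_lte(x, 1)
  # a training environment returns its own value untouched
  expect_equal(extrapolateEnvValue(ev, sim$design, "F_18"),
               ev$values[["F_18"]])
  # an explicit observed mean overrides the regression
  xo <- extrapolateEnvValue(ev, sim$design, "M_28",
                            observedMean = max(ev$means))
  expect_equal(xo, 2 * (max(ev$means) - ev$bounds["min"]) /
                 diff(range(ev$means)) - 1, ignore_attr = TRUE)
})

test_that("intercept-only genetics reduce RRM to G-BLUP with environment
           intercepts", {
  # fixed-parameter equivalence: Sigma_a with zero slope variance and a
  # shared residual variance must reproduce the kernel mixed model
  # y = Phi beta + u_line + eps, u ~ N(0, s2a G), via an independent GLS
  # implementation
  set.seed(211)
  n <- 20
  cfg <- simulationConfig(nLines = n, nVariants = 400, seed = 212)
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  G <- computeGRM(geno)
  s2a <- 0.3; s2e <- 0.5
  fit <- fitRRM(sim$pheno, G,
                fixedPars = list(SigmaA = diag(c(s2a, 0)),
                                 residVars = s2e))
  env <- paste(sim$pheno$sex, sim$pheno$temperature, sep = "_")
  targets <- data.frame(line = sim$pheno$line, env = env)
  pred <- predictRRM(fit, targets, G)
  # oracle: GLS with X = Legendre design, V = s2a ZGZ' + s2e I
  ev <- envValues(sim$pheno)
  x <- ev$values[env]
  X <- cbind(1, x)
  li <- match(sim$pheno$line, rownames(G))
  ZGZt <- G[li, li]
  V <- s2a * ZGZt + diag(s2e, nrow(X))
  Vi <- solve(V)
  y <- sim$pheno$lifespan
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * ZGZt %*% Vi %*% (y - X %*% beta)
  expect_equal(unname(pred), unname(drop(X %*% beta + u)),
               tolerance = 1e-6)
})

test_that("RRM recovers intercept-dominant genetics and homogeneous
           residuals", {
  # truth: genetic intercept variance only, equal residual variances
  okSlope <- 0
  for (s in 1:6) {
    cfg <- simulationConfig(nLines = 50, nVariants = 500, seed = 2200 + s,
                            pve = c(genetic = 0.5, environment = 0.3,
                                    gxe = 0, residual = 0.2))
    geno <- simulateGenotypes(cfg)
    sim <- simulatePhenotypes(geno, cfg)
    G <- computeGRM(geno)
    fit <- suppressWarnings(fitRRM(sim$pheno, G))
    if (fit@SigmaA[2, 2] < 0.1 * fit@SigmaA[1, 1]) okSlope <- okSlope + 1
  }
  expect_gte(okSlope, 4)
  # single larger fit: residual variances within 2x of each other
  cfg <- simulationConfig(nLines = 100, nVariants = 1000, seed = 231,
                          pve = c(genetic = 0.4, environment = 0.3,
                                  gxe = 0, residual = 0.3))
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  fit <- suppressWarnings(fitRRM(sim$pheno, computeGRM(geno)))
  expect_lt(max(fit@residVars) / min(fit@residVars), 2)
})

test_that("the RRM optimum dominates a random parameter sweep on a tiny
           instance", {
  cfg <- simulationConfig(nLines = 6, nVariants = 200, seed = 241,
                          temperatures = c(18, 25, 28))
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  # one sex so r = 3 environments over 6 lines
  pheno <- sim$pheno[sim$pheno$sex == "F", ]
  G <- computeGRM(geno)
  fit <- suppressWarnings(fitRRM(pheno, G))
  vy <- var(pheno$lifespan)
  set.seed(242)
  worse <- TRUE
  for (i in 1:2000) {
    A <- matrix(rnorm(4), 2); Sa <- crossprod(A) * runif(1, 0.01, 1) * vy
    rv <- runif(3, 0.05, 2) * vy
    ll <- suppressWarnings(
      fitRRM(pheno, G, fixedPars = list(SigmaA = Sa, residVars = rv))@loglik)
    if (ll > fit@loglik + 1e-6) worse <- FALSE
  }
  expect_true(worse)
})

test_that("RRM predictions respect the model geometry", {
  sim <- smallPanel()
  G <- computeGRM(sim$geno)
  fit <- suppressWarnings(fitRRM(sim$pheno, G))
  # per line, predictions are affine in x at T = 1
  xs <- fit@envValues
  lines <- rownames(fit@coefBlups)[1:5]
  for (ln in lines) {
    pr <- predictRRM(fit, data.frame(line = ln, env = names(xs)), G)
    co <- coef(lm(pr ~ xs))
    expect_equal(unname(pr), unname(co[1] + co[2] * xs), tolerance = 1e-8)
  }
  # environments sharing x give identical predictions
  fit2 <- fit
  fit2@envValues <- c(fit@envValues, dupEnv = unname(fit@envValues[2]))
  p2 <- predictRRM(fit2, data.frame(line = lines[1],
                                    env = c(names(xs)[2], "dupEnv")), G)
  expect_equal(unname(p2[1]), unname(p2[2]))
  # a line with no genomic relationship predicts at the fixed curve
  G2 <- rbind(cbind(G, new = 0), new = 0); G2["new", "new"] <- 2
  dimnames(G2) <- list(c(rownames(G), "new"), c(rownames(G), "new"))
  p0 <- predictRRM(fit, data.frame(line = "new", env = names(xs)[1]), G2)
  phi <- drop(legendreBasis(xs[1], 1))
  expect_equal(unname(p0), sum(fit@beta * phi), tolerance = 1e-8)
  expect_error(predictRRM(fit, data.frame(line = lines[1], env = "zz"), G),
               "no environmental value")
})
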