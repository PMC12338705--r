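makeGRM <- function(n, p, seed) {
  computeGRM(simulateGenotypes(simulationConfig(
    nLines = n, nVariants = p, seed = seed)))
}

test_that("duplicated traits yield a genetic correlation near one", {
  set.seed(61)
  n <- 100
  G <- makeGRM(n, 800, 62)
  eg <- eigen(G, symmetric = TRUE)
  a <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
  y <- 5 + a + rnorm(n, sd = 0.5)
  Y <- cbind(t1 = y, t2 = y)
  rownames(Y) <- rownames(G)
  fit <- suppressWarnings(fitMTM(Y, G, iterations = 3000, burnin = 500,
                                 thin = 5, seed = 63))
  expect_gte(geneticCorrelations(fit)[1, 2], 0.9)
})

test_that("chains are bit-identical for the same seed and settings", {
  set.seed(71)
  n <- 40
  G <- makeGRM(n, 300, 72)
  Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(G), c("a", "b")))
  f1 <- suppressWarnings(fitMTM(Y, G, iterations = 600, burnin = 100,
                                thin = 2, seed = 9))
  f2 <- suppressWarnings(fitMTM(Y, G, iterations = 600, burnin = 100,
                                thin = 2, seed = 9))
  expect_identical(f1@samples, f2@samples)
  expect_identical(f1@Ahat, f2@Ahat)
  expect_equal(nrow(f1@samples$sigmaR), (600 - 100) / 2)
})

test_that("a nearly empty trait is handled by data augmentation", {
  set.seed(81)
  n <- 50
  G <- makeGRM(n, 300, 82)
  Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(G), c("a", "b")))
  Y[seq_len(n - 2), 2] <- NA
  fit <- suppressWarnings(fitMTM(Y, G, iterations = 800, burnin = 200,
                                 thin = 2, seed = 83))
  expect_true(all(is.finite(fit@SigmaA)))
  expect_true(all(fit@sigmaR > 0))
  Y[, 2] <- NA
  expect_error(fitMTM(Y, G), "at least 2 observed")
})

test_that("genetic correlations follow the covariance-to-correlation map", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(geneticCorrelations(S)[1, 2], 0.5)
  expect_equal(geneticCorrelations(diag(c(2, 3, 4))), diag(3))
  expect_equal(geneticCorrelations(7.3 * S), geneticCorrelations(S))
  expect_error(geneticCorrelations(matrix(c(0, 0, 0, 1), 2)),
               "non-positive")
})

test_that("predictions cover fitted lines, new lines and duplicates", {
  set.seed(91)
  n <- 60
  G <- makeGRM(n, 400, 92)
  eg <- eigen(G, symmetric = TRUE)
  A <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * matrix(rnorm(n * 2), n))
  Y <- 3 + A + 0.3 * matrix(rnorm(n * 2), n)
  dimnames(Y) <- list(rownames(G), c("e1", "e2"))
  fit <- suppressWarnings(fitMTM(Y, G, iterations = 1500, burnin = 300,
                                 thin = 3, seed = 93))
  expect_error(predictMTM(fit, data.frame(line = rownames(G)[1],
                                          trait = "nope"), G), "unknown")
  # a new line with zero relationship predicts at the trait intercept
  G2 <- rbind(cbind(G, new = 0), new = 0)
  G2["new", "new"] <- 2
  dimnames(G2) <- list(c(rownames(G), "new"), c(rownames(G), "new"))
  p0 <- predictMTM(fit, data.frame(line = "new", trait = "e1"), G2)
  expect_equal(unname(p0), unname(fit@intercepts["e1"]), tolerance = 1e-8)
  # a duplicate of a fitted line predicts like that line
  G3 <- G[c(seq_len(n), 1), c(seq_len(n), 1)]
  dimnames(G3) <- list(c(rownames(G), "dup"), c(rownames(G), "dup"))
  pd <- predictMTM(fit, data.frame(line = c(rownames(G)[1], "dup"),
                                   trait = "e2"), G3)
  expect_equal(unname(pd[1]), unname(pd[2]), tolerance = 1e-6)
  # observed cells are tracked roughly at the within-trait signal level
  pobs <- predictMTM(fit, data.frame(line = rownames(G), trait = "e1"), G)
  expect_gt(cor(pobs, Y[, "e1"])^2, 0.5)
})

test_that("no-genetic-signal data keep the genetic variances at or below
           the prior scale", {
  # with nearly unrelated lines the genetic variance is weakly identified
  # and its posterior cannot fall far below the prior mode (half the
  # phenotypic variance); the check is that pure-noise data never push it
  # above that scale
  ok <- 0
  for (s in 1:6) {
    set.seed(1100 + s)
    n <- 120
    G <- makeGRM(n, 600, 1200 + s)
    Y <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(rownames(G), c("a", "b")))
    fit <- suppressWarnings(fitMTM(Y, G, iterations = 2000, burnin = 400,
                                   thin = 4, seed = 1300 + s))
    gshare <- diag(fit@SigmaA) * mean(diag(G)) / apply(Y, 2, var)
    if (all(gshare < 0.6)) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("the residual-variance posterior matches an exact grid posterior", {
  # single trait: the sampler's marginal for sigma2_e is compared with a
  # dense 2-D grid integration of the exact posterior (independent code
  # path), by Kolmogorov-Smirnov distance
  set.seed(131)
  n <- 80
  G <- makeGRM(n, 500, 132)
  eg <- eigen(G, symmetric = TRUE)
  a <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
  y <- 10 + a + rnorm(n)
  Y <- matrix(y, ncol = 1, dimnames = list(rownames(G), "t"))
  fit <- suppressWarnings(fitMTM(Y, G, iterations = 42000, burnin = 2000,
                                 thin = 20, seed = 133))
  draws <- drop(fit@samples$sigmaR)
  # exact posterior on a grid, eigenbasis marginal likelihood
  d <- eg$values + 1e-8 * mean(diag(G))
  U <- eg$vectors
  yt <- drop(t(U) %*% y)
  u1 <- drop(t(U) %*% rep(1, n))
  pv <- var(y)
  nu0 <- 3; S0 <- 0.5 * pv * (nu0 + 2) / mean(diag(G))
  df0 <- 5; s0 <- 0.5 * pv * (df0 + 2) / df0
  logpost <- function(sa, se) {
    V <- sa * d + se
    Vi <- 1 / V
    sw <- sum(u1^2 * Vi)
    mhat <- sum(u1 * yt * Vi) / sw
    r <- yt - mhat * u1
    -0.5 * (sum(log(V)) + log(sw) + sum(r^2 * Vi)) +
      (-(nu0 / 2 + 1)) * log(sa) - S0 / (2 * sa) +
      (-(df0 / 2 + 1)) * log(se) - df0 * s0 / (2 * se)
  }
  sas <- seq(0.02, 6, length.out = 160)
  ses <- seq(0.02, 6, length.out = 160)
  LP <- outer(sas, ses, Vectorize(logpost))
  P <- exp(LP - max(LP)); P <- P / sum(P)
  margE <- colSums(P)
  cdf <- cumsum(margE)
  ecdfDraws <- ecdf(draws)
  ks <- max(abs(ecdfDraws(ses) - cdf))
  expect_lt(ks, 0.05)
})
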