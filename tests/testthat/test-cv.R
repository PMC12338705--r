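test_that("folds partition the records under every scheme", {
  pheno <- recordGrid(sprintf("L%03d", 1:176))
  pheno$lifespan <- rnorm(nrow(pheno))
  q <- nrow(pheno)
  expect_equal(q, 1056L)
  for (sc in c("RandomLines", "RandomObservations", "NewEnvironment")) {
    folds <- makeFolds(pheno, sc, seed = 5)
    for (f in folds) {
      expect_length(intersect(f@train, f@test), 0)
      expect_setequal(c(f@train, f@test), seq_len(q))
      expect_gt(length(f@test), 0)
    }
  }
  # 17% of 176 lines -> 30 lines -> 180 test records
  rl <- makeFolds(pheno, "RandomLines", seed = 5)
  expect_equal(unique(vapply(rl, function(f) length(f@test), integer(1))),
               180L)
  ro <- makeFolds(pheno, "RandomObservations", seed = 5)
  expect_equal(length(ro[[1]]@test), round(0.17 * q))
  # NewEnvironment: one fold per environment with n records each
  ne <- makeFolds(pheno, "NewEnvironment", seed = 5)
  expect_length(ne, 6)
  expect_equal(unique(vapply(ne, function(f) length(f@test), integer(1))),
               176L)
  # determinism
  expect_identical(lapply(makeFolds(pheno, "RandomLines", seed = 5),
                          function(f) f@test),
                   lapply(rl, function(f) f@test))
  expect_error(makeFolds(pheno, "NewEnvironment", nReplicates = 4),
               "number of environments")
})

test_that("accuracy is the squared correlation of truth with prediction", {
  y <- c(5.0, 6.1, 7.2, 8.0)
  expect_equal(accuracyR2(y, y), 1)
  expect_equal(accuracyR2(c(1, 2, 3), c(1, 1, 2)), 0.75)
  set.seed(3)
  yt <- rnorm(30); yp <- rnorm(30)
  expect_equal(accuracyR2(yt, 3 * yp - 2), accuracyR2(yt, yp))
  expect_warning(r0 <- accuracyR2(yt, rep(1, 30)), "constant")
  expect_equal(r0, 0)
})

test_that("no test phenotype leaks into fitting or prediction", {
  sim <- smallPanel()
  y <- sim$pheno$lifespan
  folds <- makeFolds(sim$pheno, "RandomObservations", nReplicates = 1,
                     seed = 77)
  fold <- folds[[1]]
  yZero <- y; yZero[fold@test] <- 0
  for (m in c("GE-BLUP", "GxE-BLUP")) {
    f1 <- fitModel(y, sim$kernels, m, fold@train)
    f2 <- fitModel(yZero, sim$kernels, m, fold@train)
    expect_identical(f1@varComponents, f2@varComponents)
    expect_identical(blupPredict(f1, sim$kernels, fold@train, fold@test),
                     blupPredict(f2, sim$kernels, fold@train, fold@test))
  }
  # the reaction-norm environmental values come from training data only
  G <- computeGRM(sim$geno)
  p1 <- sim$pheno; p2 <- sim$pheno; p2$lifespan[fold@test] <- 0
  r1 <- suppressWarnings(fitRRM(p1[fold@train, ], G))
  r2 <- suppressWarnings(fitRRM(p2[fold@train, ], G))
  expect_identical(r1@envValues, r2@envValues)
  expect_identical(r1@beta, r2@beta)
})

test_that("cross-validation results are coherent and reproducible", {
  sim <- smallPanel()
  res <- suppressWarnings(
    runCV(sim$pheno, sim$geno, models = c("E-BLUP", "GE-BLUP"),
          scheme = "RandomObservations", nReplicates = 3, seed = 4))
  for (r in res) {
    expect_equal(r@meanR2, mean(r@perReplicateR2), tolerance = 1e-12)
    expect_true(all(r@perReplicateR2 >= 0 & r@perReplicateR2 <= 1))
  }
  tab <- cvTable(res)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$model), c("E-BLUP", "GE-BLUP"))
  res2 <- suppressWarnings(
    runCV(sim$pheno, sim$geno, models = c("E-BLUP", "GE-BLUP"),
          scheme = "RandomObservations", nReplicates = 3, seed = 4))
  expect_equal(sapply(res, function(r) r@perReplicateR2),
               sapply(res2, function(r) r@perReplicateR2))
})

test_that("the multi-trait model is rejected for unseen environments", {
  sim <- smallPanel()
  expect_error(runCV(sim$pheno, sim$geno, models = "mvG-BLUP",
                     scheme = "NewEnvironment"),
               "cannot be fitted")
})

test_that("zero-interaction data make GxE-BLUP and GE-BLUP agree", {
  cfg <- simulationConfig(nLines = 60, nVariants = 600, seed = 303,
                          pve = c(genetic = 0.15, environment = 0.65,
                                  gxe = 0, residual = 0.2))
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  res <- suppressWarnings(
    runCV(sim$pheno, geno, models = c("GE-BLUP", "GxE-BLUP"),
          scheme = "RandomObservations", nReplicates = 3, seed = 7))
  expect_lt(abs(res[["GxE-BLUP"]]@meanR2 - res[["GE-BLUP"]]@meanR2), 0.03)
})

test_that("genetics-aware models improve when lines stay in training", {
  # RandomObservations keeps every line in the training set, so models
  # that use the genomic kernels gain accuracy relative to RandomLines
  gains <- matrix(NA, 3, 2, dimnames = list(NULL, c("GE", "GxE")))
  for (s in 1:3) {
    cfg <- simulationConfig(nLines = 80, nVariants = 800, seed = 310 + s)
    geno <- simulateGenotypes(cfg)
    sim <- simulatePhenotypes(geno, cfg)
    rl <- suppressWarnings(
      runCV(sim$pheno, geno, models = c("GE-BLUP", "GxE-BLUP"),
            scheme = "RandomLines", nReplicates = 3, seed = 320 + s))
    ro <- suppressWarnings(
      runCV(sim$pheno, geno, models = c("GE-BLUP", "GxE-BLUP"),
            scheme = "RandomObservations", nReplicates = 3, seed = 320 + s))
    gains[s, ] <- c(ro[["GE-BLUP"]]@meanR2 - rl[["GE-BLUP"]]@meanR2,
                    ro[["GxE-BLUP"]]@meanR2 - rl[["GxE-BLUP"]]@meanR2)
  }
  expect_true(all(gains > 0))
})

test_that("full-data partition reports all components and correlations", {
  sim <- smallPanel()
  part <- suppressWarnings(
    runPartition(sim$pheno, sim$geno, models = c("E-BLUP", "GxE-BLUP"),
                 seed = 2, iterations = 1500, burnin = 300, thin = 3))
  expect_equal(part$pve$model, c("E-BLUP", "GxE-BLUP"))
  sums <- rowSums(part$pve[, c("ZGZt", "E", "GxE", "residual")],
                  na.rm = TRUE)
  expect_equal(unname(sums), c(1, 1), tolerance = 1e-9)
  expect_true(all(diag(part$rA) == 1))
  expect_true(all(abs(part$rA) <= 1 + 1e-9))
})
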