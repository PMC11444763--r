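test_that("Ki/IC50 to free energy conversion follows RT ln K", {
  expect_equal(kiToDG(1, temperature = 300), 0)
  expect_equal(round(kiToDG(1e-6, temperature = 300), 2), -8.24)
  # RT at 298 K with R = 1.987e-3: ln(e) leaves exactly RT
  expect_equal(kiToDG(exp(1), temperature = 298), 0.59213, tolerance = 1e-5)
  expect_equal(round(ic50ToDG(100e-9, temperature = 300), 2), -9.61)
  expect_equal(round(ic50ToDG(8.6e-10, temperature = 300), 2), -12.44)
  expect_equal(ic50ToDG(1, temperature = 300), 0)
  expect_error(kiToDG(0), "> 0")
  expect_error(kiToDG(-1e-9), "> 0")
  # strictly increasing in the constant
  k <- sort(10^runif(20, -12, 0))
  expect_true(all(diff(kiToDG(k)) > 0))
})

test_that("metrics match hand-computed closed forms on 3-point vectors", {
  m <- evaluateMetrics(c(1, 2, 3), c(1, 2, 3), nBoot = 50, seed = 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$spearman_rho, 1)
  m2 <- evaluateMetrics(c(-1, -2, -3), c(1, 2, 3), nBoot = 50, seed = 1)
  expect_equal(m2$pearson_r, -1)
  # pred (1,2,4) vs truth (1,2,3): rmse sqrt(1/3), pearson 4.5/sqrt(21)
  m3 <- evaluateMetrics(c(1, 2, 4), c(1, 2, 3), nBoot = 50, seed = 1)
  expect_equal(m3$rmse, sqrt(1 / 3))
  expect_equal(m3$pearson_r, 4.5 / sqrt(21))
  expect_equal(m3$spearman_rho, 1)
})

test_that("metrics guard degenerate input but keep the RMSE", {
  expect_error(evaluateMetrics(1:2, 1:2), "at least 3")
  expect_error(evaluateMetrics(1:4, 1:3), "equal length")
  expect_warning(m <- evaluateMetrics(c(2, 2, 2), c(1, 2, 3), nBoot = 20),
                 "zero variance")
  expect_true(is.na(m$pearson_r))
  expect_equal(m$rmse, sqrt(mean(c(1, 0, 1))))
})

test_that("metrics are permutation-invariant and affine-stable", {
  set.seed(7)
  p <- rnorm(30); t <- p + rnorm(30, 0, 0.5)
  m <- evaluateMetrics(p, t, nBoot = 20, seed = 2)
  i <- sample(30)
  mp <- evaluateMetrics(p[i], t[i], nBoot = 20, seed = 2)
  expect_equal(mp$rmse, m$rmse)
  expect_equal(mp$pearson_r, m$pearson_r)
  ma <- evaluateMetrics(2.5 * p + 1, t, nBoot = 20, seed = 2)
  expect_equal(ma$pearson_r, m$pearson_r)
})

test_that("a linear model recovers a noiseless linear world", {
  gen <- noiselessLibrary()
  model <- trainAffinityModel(gen$library, family = "linear", nTrain = 90,
                              nBoot = 50)
  expect_lt(modelMetrics(model)$rmse, 1e-6)
  pred <- dgPred(predictAffinity(model, gen$library))
  expect_equal(unname(pred), unname(dgExp(gen$library)), tolerance = 1e-6)
})

test_that("gradient boosting approaches the irreducible noise at n = 1400", {
  gen <- makeLibrary(nScaffolds = 28L, nPerScaffold = 50L,
                     labelNoiseSd = 1.0, seed = 21L)
  model <- trainAffinityModel(gen$library, family = "gbm", nTrain = 1064,
                              splitSeed = 3, modelSeed = 3, nBoot = 50)
  m <- modelMetrics(model)
  expect_equal(m$n, 1400L - 1064L)
  expect_gt(m$rmse, 0.8)
  expect_lt(m$rmse, 1.5)
})

test_that("training and prediction are deterministic given seeds", {
  gen <- makeLibrary(nScaffolds = 6L, nPerScaffold = 20L, seed = 9L)
  for (fam in c("gbm", "rf")) {
    m1 <- trainAffinityModel(gen$library, family = fam, nTrain = 80,
                             splitSeed = 4, modelSeed = 4, nBoot = 30)
    m2 <- trainAffinityModel(gen$library, family = fam, nTrain = 80,
                             splitSeed = 4, modelSeed = 4, nBoot = 30)
    expect_identical(modelMetrics(m1), modelMetrics(m2))
    expect_identical(dgPred(predictAffinity(m1, gen$library)),
                     dgPred(predictAffinity(m2, gen$library)))
  }
})

test_that("training errors name compounds without labels", {
  gen <- noiselessLibrary()
  lib <- gen$library
  lib@compounds$dg_exp[3] <- NA
  bad_id <- compoundIds(lib)[3]
  expect_error(
    trainAffinityModel(lib, family = "linear", nTrain = length(lib) - 1,
                       splitSeed = 1, nBoot = 20),
    bad_id)
})

test_that("prediction rejects mismatched descriptor spaces", {
  gen <- noiselessLibrary()
  model <- trainAffinityModel(gen$library, family = "linear", nTrain = 90,
                              nBoot = 20)
  other <- makeLibrary(nScaffolds = 2L, nPerScaffold = 5L, featureDim = 3L,
                       seed = 1L)$library
  expect_error(predictAffinity(model, other), "mismatch")
})

test_that("top-compound selection respects strictness, order and ties", {
  lib <- predictedLibrary(c("A", "B", "C"), c(-11, -10, -9.5))
  sel <- selectTop(lib, "threshold", -10)
  expect_equal(compoundIds(sel), "A")  # strictly below -10
  sel2 <- selectTop(lib, "top_k", 2)
  expect_equal(compoundIds(sel2), c("A", "B"))
  tied <- predictedLibrary(c("B", "A", "C"), c(-11, -11, -9))
  expect_equal(compoundIds(selectTop(tied, "top_k", 1)), "A")
  expect_error(selectTop(lib, "top_k", 4), "<=")
  # nesting of threshold selections
  s1 <- compoundIds(selectTop(lib, "threshold", -10.5))
  s2 <- compoundIds(selectTop(lib, "threshold", -9.9))
  expect_true(all(s1 %in% s2))
  unpred <- CompoundLibrary(data.frame(id = "X"))
  expect_error(selectTop(unpred, "threshold", -10), "dg_pred")
})
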