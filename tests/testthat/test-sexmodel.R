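# Strategy layer: fitting, the two-step decision rule, probability algebra.

test_that("two-class multinomial collapses to the binary logistic model", {
  set.seed(51)
  X <- matrix(rnorm(80), ncol = 2)
  y <- ifelse(rbinom(40, 1, plogis(X[, 1])) == 1, "MM", "FF")
  multi <- fitMultinomial(X, y, reference = "FF", lambda = 1e-4)
  bin <- fitLogistic(X, y == "MM", lambda = 1e-4)
  pMulti <- twinnipt:::.multinomProbs(multi, "FF", X)[, "MM"]
  pBin <- plogis(drop(cbind(1, X) %*% bin))
  expect_equal(pMulti, pBin, tolerance = 1e-6)
})

test_that("separable classes are fitted to 100% training accuracy", {
  feats <- separableFeatures()
  for (strat in c("one_step", "two_step")) {
    model <- suppressWarnings(fitSexModel(feats, strat))
    preds <- predict(model, feats)
    expect_equal(preds$predicted, feats$label)
  }
  # and the two strategies agree on noise-free separable data
  p1 <- predict(suppressWarnings(fitSexModel(feats, "one_step")), feats)
  p2 <- predict(suppressWarnings(fitSexModel(feats, "two_step")), feats)
  expect_equal(p1$predicted, p2$predicted)
})

test_that("two-step probabilities compose by the stated chain rule", {
  # a model with known step probabilities: intercept-only logits
  model <- new("SexModel", strategy = "two_step",
               components = list(
                 stepA = c("(Intercept)" = qlogis(0.4), normX = 0,
                           normY = 0, ff = 0),
                 stepB = c("(Intercept)" = qlogis(0.9), normX = 0,
                           normY = 0, ff = 0)),
               covariates = c("normX", "normY", "ff"),
               referenceClass = "FF", regularization = 0,
               center = c(normX = 0, normY = 0, ff = 0),
               scale = c(normX = 1, normY = 1, ff = 1))
  row <- data.frame(sample_id = "z", normX = 0.05, normY = 1e-4, ff = 0.1)
  pr <- predict(model, row)
  expect_equal(pr$P_FF, 0.4)
  expect_equal(pr$P_FM, 0.54)
  expect_equal(pr$P_MM, 0.06)
  expect_equal(pr$predicted, "FM")     # step one says non-FF, step two FM
  expect_equal(pr$step_used, "second")
})

test_that("class probabilities always form a simplex", {
  feats <- simulateCohort(80, seed = 52)$features
  for (strat in c("one_step", "two_step")) {
    pr <- predict(fitSexModel(feats, strat), feats)
    P <- as.matrix(pr[, c("P_FF", "P_FM", "P_MM")])
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(pr$predicted %in% c("FF", "FM", "MM")))
  }
})

test_that("chrY signal monotonically favors male-male calls", {
  feats <- simulateCohort(198, seed = 53)$features
  model <- fitSexModel(feats, "one_step")
  # fitted normY coefficient of the MM component is positive (oracle: the
  # generator's normY slope has that sign by construction)
  expect_gt(model@components$MM[["normY"]], 0)
  grid <- data.frame(sample_id = paste0("g", 1:20),
                     normX = 0.048, normY = seq(5e-5, 3e-4, length.out = 20),
                     ff = 0.12)
  pr <- predict(model, grid)
  odds <- pr$P_MM / pr$P_FF
  expect_true(all(diff(odds) > 0))
})

test_that("monochorionic constraints are enforced", {
  feats <- separableFeatures()
  mcOnly <- feats[feats$label != "FM", ]
  mcOnly$chorionicity <- "MCDA"
  model <- suppressWarnings(fitSexModel(mcOnly, "mc_binary"))
  pr <- predict(model, simulateCohort(50, seed = 54)$features)
  expect_false(any(pr$predicted == "FM"))
  expect_true(all(pr$P_FM == 0))

  badMC <- feats
  badMC$chorionicity <- "MCMA"
  expect_error(fitSexModel(badMC, "two_step"), "monochorionic")
  expect_error(fitSexModel(feats, "mc_binary"), "FM rows")
})

test_that("training must cover the classes a strategy can emit", {
  feats <- separableFeatures()
  noMM <- feats[feats$label != "MM", ]
  expect_error(fitSexModel(noMM, "one_step"), "cover classes")
})

test_that("fitted models round-trip through JSON unchanged", {
  feats <- simulateCohort(60, seed = 55)$features
  model <- fitSexModel(feats, "two_step")
  path <- tempfile(fileext = ".json")
  writeSexModel(model, path)
  back <- readSexModel(path)
  expect_equal(back@components, model@components)
  pr1 <- predict(model, feats)
  pr2 <- predict(back, feats)
  expect_equal(pr1, pr2)
})

test_that("dropping the fetal-fraction covariate does not help", {
  # averaged over 10 seeds, LOOCV accuracy without ff must not exceed the
  # full model's (the covariate carries real FM/MM information)
  accWith <- accWithout <- numeric(10)
  for (s in 1:10) {
    feats <- simulateCohort(198, seed = 5600 + s)$features
    pW <- loocvPredict(feats, "two_step", "aware")
    pWo <- loocvPredict(feats, "two_step", "aware",
                        covariates = c("normX", "normY"))
    accWith[s] <- mean(pW$predicted == pW$truth)
    accWithout[s] <- mean(pWo$predicted == pWo$truth)
  }
  expect_lte(mean(accWithout), mean(accWith))
})
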