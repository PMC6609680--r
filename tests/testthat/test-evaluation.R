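# LOOCV, confusion arithmetic, Wilson intervals, rank-sum comparison.

test_that("LOOCV equals explicit per-fold refits on a toy cohort", {
  feats <- toyBinaryFeatures()
  preds <- loocvPredict(feats, "two_step", "aware")   # MC stratum -> binary
  manual <- lapply(seq_len(nrow(feats)), function(i) {
    m <- fitSexModel(feats[-i, ], "mc_binary")
    predict(m, feats[i, , drop = FALSE])
  })
  manual <- do.call(rbind, manual)
  expect_equal(preds$predicted, manual$predicted)
  expect_equal(preds$P_MM, manual$P_MM)
  expect_equal(nrow(preds), nrow(feats))
})

test_that("LOOCV on separable cohorts makes zero errors and is deterministic", {
  feats <- separableFeatures(8)
  p1 <- suppressWarnings(loocvPredict(feats, "two_step", "pooled"))
  expect_equal(p1$predicted, feats$label)
  p2 <- suppressWarnings(loocvPredict(feats, "two_step", "pooled"))
  expect_identical(p1, p2)
})

test_that("duplicating every sample cannot worsen LOOCV", {
  feats <- simulateCohort(60, seed = 71)$features
  base <- loocvPredict(feats, "two_step", "aware")
  dup <- feats[rep(seq_len(nrow(feats)), 2), ]
  dup$sample_id <- paste0(dup$sample_id, rep(c("a", "b"), each = nrow(feats)))
  dupPred <- loocvPredict(dup, "two_step", "aware")
  expect_lte(mean(dupPred$predicted != dupPred$truth),
             mean(base$predicted != base$truth) + 1e-12)
})

test_that("confusion matrices cross-tabulate exactly", {
  expect_equal(diag(confusionCounts(c("FF", "FM", "MM"),
                                    c("FF", "FM", "MM"))), c(FF = 1, FM = 1,
                                                             MM = 1))
  empty <- confusionCounts(character(), character())
  expect_true(all(empty == 0))
  expect_error(confusionCounts(c("FF", "FM"), "FF"), "mismatch")

  # the dichorionic stratum of the reference study: 29/46/37 with one
  # FM->MM and three MM->FM discordances
  truth <- rep(c("FF", "FM", "MM"), c(29, 46, 37))
  pred <- truth
  pred[truth == "FM"][1] <- "MM"
  pred[truth == "MM"][1:3] <- "FM"
  cm <- confusionCounts(pred, truth)
  expect_equal(cm["FM", "MM"], 1)
  expect_equal(cm["MM", "FM"], 3)
  expect_equal(unname(rowSums(cm)), c(29, 46, 37))
})

test_that("sensitivity and specificity are plain ratios of matrix entries", {
  set.seed(72)
  for (rep in 1:25) {
    cm <- matrix(rpois(9, 15) + 1, 3, 3,
                 dimnames = list(c("FF", "FM", "MM"), c("FF", "FM", "MM")))
    for (cl in rownames(cm)) {
      ss <- sensSpec(cm, cl)
      pos <- sum(cm[cl, ]); neg <- sum(cm) - pos
      expect_equal(ss[["sensitivity"]], cm[cl, cl] / pos)
      expect_equal(ss[["specificity"]],
                   (neg - sum(cm[setdiff(rownames(cm), cl), cl])) / neg)
    }
  }
  oneClass <- matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3,
                     dimnames = list(c("FF", "FM", "MM"),
                                     c("FF", "FM", "MM")))
  expect_true(is.na(sensSpec(oneClass, "FF")[["specificity"]]))
  expect_error(sensSpec(oneClass, "FM"), "no samples")
})

test_that("Wilson intervals reproduce the published bounds after rounding", {
  expect_equal(round(wilsonCI(50, 50), 2), c(lower = 0.93, upper = 1.00))
  expect_equal(round(wilsonCI(36, 36), 2), c(lower = 0.90, upper = 1.00))
  expect_equal(round(wilsonCI(45, 46), 2), c(lower = 0.89, upper = 1.00))
  expect_equal(round(wilsonCI(34, 37), 2), c(lower = 0.79, upper = 0.97))
  expect_equal(round(wilsonCI(63, 66), 2), c(lower = 0.87, upper = 0.98))
  expect_equal(round(wilsonCI(74, 75), 2), c(lower = 0.93, upper = 1.00))
})

test_that("Wilson bounds are mirror-symmetric and validated", {
  for (n in c(1, 7, 36, 50)) {
    expect_equal(wilsonCI(n, n)[["lower"]], 1 - wilsonCI(0, n)[["upper"]])
  }
  expect_error(wilsonCI(5, 0), "n must be")
  expect_error(wilsonCI(7, 5), "successes")
})

test_that("Wilson bounds agree with numeric score-test inversion", {
  # oracle: root-find the score equation directly, independent of the
  # closed-form quadratic
  z <- qnorm(0.975)
  scoreRoot <- function(x, n, side) {
    phat <- x / n
    f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
    if (side == "lower") {
      if (x == 0) return(0)
      # at x = n the root interior to (0, 1) is the lower bound
      hi <- if (x == n) 1 - 1e-9 else phat
      uniroot(f, c(1e-9, hi), tol = 1e-12)$root
    } else {
      if (x == n) return(1)
      lo <- if (x == 0) 1e-9 else phat
      uniroot(f, c(lo, 1 - 1e-9), tol = 1e-12)$root
    }
  }
  worst <- 0
  for (n in 1:60) for (x in 0:n) {
    ci <- wilsonCI(x, n)
    worst <- max(worst,
                 abs(ci[["lower"]] - scoreRoot(x, n, "lower")),
                 abs(ci[["upper"]] - scoreRoot(x, n, "upper")))
  }
  expect_lt(worst, 1e-5)
})

test_that("metric reports keep bounds ordered and rounded", {
  feats <- simulateCohort(120, seed = 73)$features
  preds <- loocvPredict(feats)
  rep <- metricsReport(confusionCounts(preds), stratum = "combined")
  expect_true(all(rep$sens_ci_lower <= rep$sensitivity + 0.005))
  expect_true(all(rep$sensitivity <= rep$sens_ci_upper + 0.005))
  expect_true(all(rep$sens_ci_lower >= 0 & rep$sens_ci_upper <= 1))
  # percent rounding: half away from zero
  expect_equal(twinnipt:::.percentRound(0.975), 98)
  expect_equal(twinnipt:::.percentRound(0.9783), 98)
  expect_equal(twinnipt:::.percentRound(0.9545), 95)
})

test_that("rank-sum comparison matches brute-force enumeration", {
  # identical samples: statistic at the null mean, p = 1
  same <- compareFFDistributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  out <- compareFFDistributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)
  # oracle: enumerate all 20 ways to assign ranks 1..6 to the first sample
  combos <- combn(6, 3)
  U <- apply(combos, 2, function(idx) sum(idx) - 6)   # U = ranksum - m(m+1)/2
  obs <- 0
  pExact <- mean(abs(U - 4.5) >= abs(obs - 4.5))      # two-sided around E[U]
  expect_equal(out$p_value, pExact)
  expect_equal(pExact, 0.1)
})

test_that("twin and singleton fetal fractions differ decisively at scale", {
  set.seed(74)
  twins <- twinnipt:::.rtruncnorm(5000, 12.08, 3.50, 3.5, 25)
  singletons <- twinnipt:::.rtruncnorm(5000, 9.64, 3.52, 1, 25)
  out <- compareFFDistributions(twins, singletons)
  expect_lt(out$p_value, 1e-10)
})
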