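# The synthetic cohort generator: composition, fetal-fraction distribution,
# the linear frequency model, and count realization.

test_that("class-mix allocation reproduces the reference composition exactly", {
  truth <- sampleTruth(198, seed = 1)
  tab <- table(truth$chorionicity, truth$sex_pair)
  expect_equal(unname(tab["DCDA", c("FF", "FM", "MM")]), c(29, 46, 37))
  expect_equal(unname(tab["MCDA", c("FF", "MM")]), c(50, 36))
  # monochorionic pairs are monozygotic, never mixed-sex
  mc <- truth$chorionicity %in% c("MCDA", "MCMA")
  expect_false(any(truth$sex_pair[mc] == "FM"))
})

test_that("per-fetus fractions are a valid split of the total", {
  cfg <- generatorConfig(sheddingRatioBounds = c(1, 1))
  truth <- sampleTruth(50, config = cfg, seed = 2)
  expect_equal(truth$ff1, truth$ff2, tolerance = 1e-15)
  expect_lt(max(abs(truth$ff1 + truth$ff2 - truth$ff_total)), 1e-12)

  truth2 <- sampleTruth(400, seed = 3)
  expect_lt(max(abs(truth2$ff1 + truth2$ff2 - truth2$ff_total)), 1e-12)
  ratio <- truth2$ff1 / truth2$ff2
  b <- generatorConfig()@sheddingRatioBounds
  expect_true(all(ratio >= b[1] - 1e-12 & ratio <= b[2] + 1e-12))
  expect_true(all(truth2$ff1 > 0 & truth2$ff2 > 0))
})

test_that("fetal-fraction distribution matches the truncated normal", {
  truth <- sampleTruth(10000, seed = 4)
  ffPct <- 100 * truth$ff_total
  # law of large numbers against the stated truncated Normal(12.08, 3.50)
  expect_lt(abs(mean(ffPct) - 12.08), 0.2)
  expect_lt(abs(sd(ffPct) - 3.50), 0.2)
  cfg <- generatorConfig()
  expect_true(all(ffPct >= cfg@ffMin & ffPct <= cfg@ffMax))
  # and the truncated-normal mean itself (closed form)
  expect_lt(abs(mean(ffPct) - expectedTruncNormMean(12.08, 3.5, 3.5, 25)),
            0.15)
})

test_that("a fixed seed reproduces the full cohort byte-for-byte", {
  a <- simulateCohort(60, seed = 5)
  b <- simulateCohort(60, seed = 5)
  expect_identical(a, b)
  cfg <- smallConfig()
  t1 <- sampleTruth(2, config = cfg, seed = 6)
  g1 <- emitBinCounts(t1[1, ], cfg, seed = 7)
  g2 <- emitBinCounts(t1[1, ], cfg, seed = 7)
  expect_identical(g1, g2)
})

test_that("expected frequencies follow the linear placental model", {
  cfg <- generatorConfig()
  ffAny <- c(0.05, 0.12, 0.20)
  ffTruth <- data.frame(sex_pair = "FF", ff_total = ffAny, ff2 = ffAny / 2)
  ex <- expectedFrequencies(ffTruth, cfg)
  expect_equal(ex$normY, rep(4.894e-5, 3))
  expect_equal(ex$normX, rep(4.973e-2, 3))

  mm <- data.frame(sex_pair = "MM", ff_total = 0.1208, ff2 = 0.0604)
  expect_equal(expectedFrequencies(mm, cfg)$normY, 2.431e-4,
               tolerance = 1e-6 / 2.431e-4)

  # implied mixed-pair mean is a consistency bound, not an equality
  fm <- data.frame(sex_pair = "FM", ff_total = 0.1208, ff2 = 0.0604)
  expect_lt(abs(expectedFrequencies(fm, cfg)$normY - 1.428e-4) / 1.428e-4,
            0.05)
})

test_that("noise-free bin counts aggregate to the expected frequencies", {
  cfg <- smallConfig(gcBiasAmplitude = 0)
  truth <- sampleTruth(3, config = cfg, seed = 8)
  for (i in seq_len(3)) {
    gr <- emitBinCounts(truth[i, ], cfg, seed = 9, countNoise = "expected",
                        residualNoise = FALSE)
    prof <- aggregateChromosomes(gr)
    ex <- expectedFrequencies(truth[i, ], cfg)
    # integer allocation leaves at most ~1 read per chromosome of error
    expect_lt(abs(prof$normY - ex$normY), 1e-7)
    expect_lt(abs(prof$normX - ex$normX), 1e-6)
    expect_equal(prof$total, truth$total_reads[i])
  }
})

test_that("Poisson counts land within counting fluctuation of the depth", {
  cfg <- smallConfig()
  truth <- sampleTruth(1, config = cfg, seed = 10)
  gr <- emitBinCounts(truth, cfg, seed = 11)
  expect_lt(abs(sum(gr$count) - truth$total_reads),
            6 * sqrt(truth$total_reads))
})

test_that("realized group means and spreads match the cohort calibration", {
  feats <- simulateCohort(2000, seed = 12)$features
  cfg <- generatorConfig()
  meanFF <- expectedTruncNormMean(cfg@ffMean, cfg@ffSD, cfg@ffMin,
                                  cfg@ffMax) / 100
  modelMean <- c(FF = cfg@baselineNormY,
                 FM = cfg@baselineNormY + cfg@slopeNormY * meanFF / 4,
                 MM = cfg@baselineNormY + cfg@slopeNormY * meanFF / 2)
  refMean <- c(FF = 4.894e-5, FM = 1.428e-4, MM = 2.431e-4)
  for (cl in c("FF", "FM", "MM")) {
    x <- feats$normY[feats$label == cl]
    se <- sd(x) / sqrt(length(x))
    # realized means sit within 3 SE of the generator's model means ...
    expect_lt(abs(mean(x) - modelMean[[cl]]), 3 * se)
    # ... which are themselves within 5% of the reference group means
    expect_lt(abs(modelMean[[cl]] - refMean[[cl]]) / refMean[[cl]], 0.05)
  }
  # male-male spread reproduces the reference SD within calibration slack
  sdMM <- sd(feats$normY[feats$label == "MM"])
  expect_lt(abs(sdMM - 7.137e-5) / 7.137e-5, 0.25)
})

test_that("invalid mixes and configs are rejected", {
  expect_error(sampleTruth(10, classMix = c(DCDA_FF = 0.7, DCDA_MM = 0.7)),
               "sum to 1")
  expect_error(sampleTruth(10, classMix = c(bogus = 1)), "classMix")
  expect_error(generatorConfig(sheddingRatioBounds = c(1.5, 2)),
               "straddle 1")
  expect_error(generatorConfig(ffMin = 15, ffMax = 10), "ffMin")
  expect_error(generatorConfig(genomeScale = 0), "genomeScale")
})

test_that("bin tables and truth sheets round-trip through TSV", {
  cfg <- smallConfig()
  truth <- sampleTruth(2, config = cfg, seed = 13)
  gr <- emitBinCounts(truth[1, ], cfg, seed = 14)

  plain <- file.path(withr::local_tempdir(), "s1.bins.tsv")
  writeBinCounts(gr, plain)
  back <- readBinCounts(plain)
  expect_equal(back$count, gr$count)
  expect_equal(back$gc, gr$gc)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))

  gz <- paste0(plain, ".gz")
  writeBinCounts(gr, gz)
  expect_equal(readBinCounts(gz)$count, gr$count)

  sheet <- file.path(dirname(plain), "truth.tsv")
  writeTruthSheet(truth, sheet)
  df <- read.table(sheet, header = TRUE, sep = "\t")
  expect_equal(df$ff_total_percent, 100 * truth$ff_total)
  expect_equal(df$sex_pair, truth$sex_pair)
})
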