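#' Build a generator configuration with cohort-calibrated defaults
#'
#' Defaults reproduce the group-level statistics of a real 198-pregnancy
#' shallow-WGS NIPT twin cohort:
#' \itemize{
#'   \item total fetal fraction ~ truncated Normal(12.08, 3.50)\% on
#'     \[3.5, 25\]\%, bracketing the observed 5.4–23.5\% range with margin;
#'   \item normalized chrY frequency rises linearly with half the summed
#'     male-fetus fetal fraction from an all-female baseline of 4.894e-5
#'     (X–Y homologous mismapping floor); the slope 3.2146e-3 is calibrated
#'     from the male-male group mean 2.431e-4 at the mean ff of 12.08\%
#'     (`(2.431e-4 - 4.894e-5) / (0.1208 / 2)`); the implied mixed-pair mean
#'     1.460e-4 then sits within 2.3\% of the observed 1.428e-4;
#'   \item normalized chrX frequency falls from 4.973e-2 with slope
#'     6.0596e-2 (`(4.973e-2 - 4.607e-2) / (0.1208 / 2)`);
#'   \item per-class residual noise is multiplicative (SD proportional to
#'     the expected frequency): cfDNA fractional signals get quieter, not
#'     noisier, as the fetal signal shrinks, which keeps the class strata
#'     separable at low fetal fraction as observed. The coefficients of
#'     variation are quadrature remainders of the observed group SDs after
#'     removing the fetal-fraction-driven variance, divided by the class
#'     mean: for male-male normY,
#'     `sqrt(7.137e-5^2 - (3.2146e-3 * 0.035 / 2)^2) / 2.431e-4` = 0.181,
#'     and analogously FF 0.066 (the Poisson counting part of the observed
#'     3.668e-6 is removed first) and for chrX (FF 0.0096, FM 0.0074,
#'     MM 0.0236). For mixed pairs the shedding split plus ff spread
#'     already induce a normY SD of 3.44e-5, slightly above the observed
#'     2.926e-5, so the FM normY residual is 0;
#'   \item mean depth 16,198,687 binned reads; co-twin placental shedding
#'     ratio log-uniform in \[0.5, 2\] (up to ~2-fold unequal contributions).
#' }
#'
#' @param ffMean,ffSD,ffMin,ffMax fetal-fraction distribution in percent.
#' @param baselineNormY,baselineNormX,slopeNormY,slopeNormX linear
#'   frequency-vs-ff model constants (fractions; slopes per unit ff).
#' @param residualCVNormY,residualCVNormX named per-class residual
#'   coefficients of variation.
#' @param totalReadsMean,totalReadsCV per-sample depth distribution
#'   (log-normal with this mean and coefficient of variation).
#' @param sheddingRatioBounds bounds for the co-twin shedding ratio.
#' @param binSize bin width in bp.
#' @param gcBiasAmplitude maximal per-sample GC-bias amplitude.
#' @param genomeScale fraction of each chromosome length kept in the bin
#'   map (reduce for fast small-genome simulations).
#' @param seed fallback RNG seed.
#' @return a validated [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig()
#' cfg
#' @export
generatorConfig <- function(ffMean = 12.08, ffSD = 3.50,
                            ffMin = 3.5, ffMax = 25.0,
                            baselineNormY = 4.894e-5,
                            baselineNormX = 4.973e-2,
                            slopeNormY = 3.2146e-3,
                            slopeNormX = 6.0596e-2,
                            residualCVNormY = c(FF = 0.066, FM = 0,
                                                MM = 0.181),
                            residualCVNormX = c(FF = 0.0096, FM = 0.0074,
                                                MM = 0.0236),
                            totalReadsMean = 16198687, totalReadsCV = 0.10,
                            sheddingRatioBounds = c(0.5, 2.0),
                            binSize = 50000, gcBiasAmplitude = 0.15,
                            genomeScale = 1, seed = 1L) {
  new("GeneratorConfig", ffMean = ffMean, ffSD = ffSD, ffMin = ffMin,
      ffMax = ffMax, baselineNormY = baselineNormY,
      baselineNormX = baselineNormX, slopeNormY = slopeNormY,
      slopeNormX = slopeNormX,
      residualCVNormY = residualCVNormY[.SEX_CLASSES],
      residualCVNormX = residualCVNormX[.SEX_CLASSES],
      totalReadsMean = totalReadsMean, totalReadsCV = totalReadsCV,
      sheddingRatioBounds = sheddingRatioBounds, binSize = binSize,
      gcBiasAmplitude = gcBiasAmplitude, genomeScale = genomeScale,
      seed = as.integer(seed))
}

#' Default cohort composition
#'
#' Stratum proportions of the reference cohort: 112 dichorionic pregnancies
#' (37 MM / 46 FM / 29 FF) and 86 monochorionic ones (36 MM / 50 FF), n=198.
#' Monochorionic (monozygotic) pairs are always same-sex, so no MC_FM
#' stratum exists.
#'
#' @return named numeric proportions over the five chorionicity-by-sex
#'   strata, summing to 1.
#' @export
defaultClassMix <- function() {
  c(DCDA_FF = 29, DCDA_FM = 46, DCDA_MM = 37, MC_FF = 50, MC_MM = 36) / 198
}

# seed = NULL continues the current RNG stream (so composed calls under one
# outer seed stay reproducible); an explicit seed restarts it.
.setSeed <- function(seed, config = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(seed)
}

# Largest-remainder allocation of n among proportions p (exact when n*p is
# integral, as for the reference cohort mix at n = 198).
.allocateCounts <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw + 1e-9)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

# Inverse-CDF draw from Normal(mean, sd) truncated to [lo, hi].
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Sample ground-truth twin pregnancies
#'
#' Draws a cohort of twin pregnancies with known chorionicity, sex pair,
#' total and per-fetus fetal fractions, and sequencing depth. Class counts
#' follow `classMix` by largest-remainder allocation, so a mix whose
#' products with `n` are integral yields those exact counts. Total fetal
#' fraction is a truncated normal; the per-fetus split uses a shedding
#' ratio `r` drawn log-uniformly within `sheddingRatioBounds`, giving
#' `ffA = ff * r / (1 + r)`. For mixed pairs twin A is by convention the
#' female, so `ff2` is the male contribution.
#'
#' @param n number of pregnancies (>= 1).
#' @param classMix named proportions over strata `DCDA_FF`, `DCDA_FM`,
#'   `DCDA_MM`, `MC_FF`, `MC_MM` (must sum to 1; monochorionic strata are
#'   emitted with chorionicity `MCDA`).
#' @param config a [GeneratorConfig-class].
#' @param seed RNG seed (falls back to `config@seed`).
#' @return data.frame with columns `sample_id`, `chorionicity`, `sex_pair`,
#'   `ff_total`, `ff1`, `ff2` (fractions), `total_reads`.
#' @examples
#' truth <- sampleTruth(20, seed = 7)
#' table(truth$chorionicity, truth$sex_pair)
#' @export
sampleTruth <- function(n, classMix = defaultClassMix(),
                        config = generatorConfig(), seed = NULL) {
  stopifnot(n >= 1)
  want <- c("DCDA_FF", "DCDA_FM", "DCDA_MM", "MC_FF", "MC_MM")
  if (is.null(names(classMix)) || !all(names(classMix) %in% want))
    stop("classMix must be named with a subset of {",
         paste(want, collapse = ", "), "}")
  mix <- setNames(numeric(length(want)), want)
  mix[names(classMix)] <- classMix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("classMix proportions must be non-negative and sum to 1")
  .setSeed(seed, config)

  counts <- .allocateCounts(n, mix)
  stratum <- rep(want, counts)
  chor <- ifelse(startsWith(stratum, "MC"), "MCDA", "DCDA")
  sexp <- sub("^(DCDA|MC)_", "", stratum)

  ff <- .rtruncnorm(n, config@ffMean, config@ffSD,
                    config@ffMin, config@ffMax) / 100
  b <- config@sheddingRatioBounds
  r <- exp(runif(n, log(b[1]), log(b[2])))
  u <- r / (1 + r)                       # twin A share of the fetal cfDNA
  sdl <- sqrt(log(1 + config@totalReadsCV^2))
  reads <- round(rlnorm(n, log(config@totalReadsMean) - sdl^2 / 2, sdl))

  data.frame(
    sample_id = sprintf("twin%03d", seq_len(n)),
    chorionicity = chor, sex_pair = sexp,
    ff_total = ff, ff1 = ff * u, ff2 = ff * (1 - u),
    total_reads = reads, stringsAsFactors = FALSE)
}

#' Expected normalized sex-chromosome frequencies
#'
#' Deterministic linear placental-contribution model: each male fetus adds
#' chrY reads (and removes chrX reads) in proportion to half its fetal
#' fraction, on top of the all-female baselines. Female fetuses contribute
#' no chrY signal; the nonzero baseline models constant X–Y
#' homologous-region mismapping.
#'
#' @param truth data.frame as from [sampleTruth()] (columns `sex_pair`,
#'   `ff_total`, `ff2`; for mixed pairs `ff2` is the male twin's fraction).
#' @param config a [GeneratorConfig-class].
#' @return data.frame with columns `normX`, `normY`.
#' @examples
#' cfg <- generatorConfig()
#' t1 <- data.frame(sex_pair = c("FF", "FM", "MM"), ff_total = 0.12,
#'                  ff2 = 0.06)
#' expectedFrequencies(t1, cfg)
#' @export
expectedFrequencies <- function(truth, config = generatorConfig()) {
  maleFF <- ifelse(truth$sex_pair == "MM", truth$ff_total,
                   ifelse(truth$sex_pair == "FM", truth$ff2, 0))
  data.frame(
    normX = config@baselineNormX - config@slopeNormX * maleFF / 2,
    normY = config@baselineNormY + config@slopeNormY * maleFF / 2)
}

# Per-class multiplicative residual draw applied to the expected
# frequencies; the multiplier is floored at 0.05 against extreme tails.
.realizedFrequencies <- function(truth, config) {
  ex <- expectedFrequencies(truth, config)
  cy <- config@residualCVNormY[truth$sex_pair]
  cx <- config@residualCVNormX[truth$sex_pair]
  n <- nrow(truth)
  data.frame(normX = ex$normX * pmax(1 + rnorm(n, 0, cx), 0.05),
             normY = ex$normY * pmax(1 + rnorm(n, 0, cy), 0.05))
}

#' Synthetic bin map
#'
#' Deterministic genome partition into fixed-width bins with synthetic but
#' realistic per-bin GC fractions: a chromosome-specific base GC plus smooth
#' within-chromosome waves. Pure function of the configuration (no RNG), so
#' all samples of a cohort share one map.
#'
#' @param config a [GeneratorConfig-class]; `binSize` and `genomeScale`
#'   control resolution and genome size.
#' @return a [GenomicRanges::GRanges] with metadata column `gc`.
#' @export
binMap <- function(config = generatorConfig()) {
  lens <- pmax(round(.CHROM_LENGTHS * config@genomeScale), config@binSize)
  grl <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    starts <- seq(0, len - 1, by = config@binSize)
    ends <- pmin(starts + config@binSize, len)
    mid <- (starts + ends) / 2 / len
    gc <- .CHROM_GC[[chrom]] +
      0.040 * sin(2 * pi * 3.7 * mid) +
      0.018 * sin(2 * pi * 11.3 * mid + 1.0) +
      0.010 * cos(2 * pi * 23.1 * mid + 2.0)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts + 1,
                                                   end = ends),
                           gc = round(gc, 4))
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

# Smooth unimodal multiplicative GC response; amp = 0 is flat.
.gcBiasCurve <- function(gc, amp) 1 + amp * exp(-((gc - 0.50)^2) / (2 * 0.08^2))

# Integer allocation of `total` reads over expected weights w, preserving
# marginal sums by largest remainder.
.roundAllocate <- function(total, w) {
  .allocateCounts(round(total), w)
}

#' Realize per-bin read counts for one pregnancy
#'
#' Turns one truth row into a binned read-count profile. Chromosome-level
#' expected frequencies come from [expectedFrequencies()] plus per-class
#' residual noise (disable with `residualNoise = FALSE`); autosomes share
#' the remaining read mass in proportion to length. Within the genome,
#' per-bin expectations are length weights modulated by a per-sample
#' multiplicative GC bias (amplitude drawn uniformly in
#' `+/- gcBiasAmplitude`), globally rescaled to the sample's total depth.
#' Counts are Poisson draws, or the rounded expectations themselves when
#' `countNoise = "expected"` (largest-remainder rounding, preserving
#' chromosome totals to ~1 read).
#'
#' @param truth a single-row data.frame as from [sampleTruth()].
#' @param config a [GeneratorConfig-class].
#' @param seed RNG seed.
#' @param countNoise `"poisson"` or `"expected"`.
#' @param residualNoise add per-class biological residual noise to the
#'   chromosome frequencies?
#' @param bins optional precomputed [binMap()] (shared across a cohort).
#' @return a [GenomicRanges::GRanges] with metadata columns `gc`, `count`.
#' @examples
#' cfg <- generatorConfig(genomeScale = 0.01)
#' tr <- sampleTruth(1, config = cfg, seed = 3)
#' gr <- emitBinCounts(tr, cfg, seed = 3)
#' sum(gr$count)
#' @export
emitBinCounts <- function(truth, config = generatorConfig(), seed = NULL,
                          countNoise = c("poisson", "expected"),
                          residualNoise = TRUE, bins = NULL) {
  countNoise <- match.arg(countNoise)
  stopifnot(nrow(truth) == 1)
  .setSeed(seed, config)
  if (is.null(bins)) bins <- binMap(config)

  fr <- if (residualNoise) .realizedFrequencies(truth, config)
        else expectedFrequencies(truth, config)
  autoLen <- .CHROM_LENGTHS[.AUTOSOMES]
  chromFreq <- c(autoLen / sum(autoLen) * (1 - fr$normX - fr$normY),
                 chrX = fr$normX, chrY = fr$normY)

  chrom <- as.character(GenomicRanges::seqnames(bins))
  w <- GenomicRanges::width(bins)
  amp <- runif(1, -config@gcBiasAmplitude, config@gcBiasAmplitude)
  bias <- .gcBiasCurve(bins$gc, amp)
  # bin weight within its chromosome, then chromosome frequency, then global
  # GC distortion renormalized to preserve total depth
  wc <- tapply(w, chrom, sum)[chrom]
  mu <- chromFreq[chrom] * (w / wc) * bias
  mu <- mu / sum(mu) * truth$total_reads

  count <- if (countNoise == "poisson") {
    rpois(length(mu), mu)
  } else {
    out <- integer(length(mu))
    chromTotals <- .roundAllocate(truth$total_reads,
                                  tapply(mu, chrom, sum)[unique(chrom)])
    names(chromTotals) <- unique(chrom)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      out[i] <- .allocateCounts(chromTotals[[ch]], mu[i])
    }
    out
  }
  bins$count <- as.numeric(count)
  bins
}

#' Simulate classifier-ready features for a cohort
#'
#' Fast chromosome-level path: realizes GC-free chromosome read counts
#' (Poisson around the expected frequencies plus per-class residual noise)
#' without materializing bins, and attaches a fetal-fraction estimate via
#' [getFetalFraction()]. Statistically equivalent, at the chromosome
#' aggregate, to [emitBinCounts()] followed by [aggregateChromosomes()]
#' with zero GC bias.
#'
#' @param truth data.frame from [sampleTruth()].
#' @param config a [GeneratorConfig-class].
#' @param seed RNG seed.
#' @param ffNoiseSD SD (percentage points) of the fetal-fraction estimator
#'   error; 0 passes truth through.
#' @param countNoise draw Poisson counting noise?
#' @param residualNoise add per-class residual noise?
#' @return data.frame of [SampleFeatures][fitSexModel]: `sample_id`,
#'   `normX`, `normY`, `ff`, `chorionicity`, `label`.
#' @examples
#' truth <- sampleTruth(50, seed = 11)
#' feats <- simulateFeatures(truth, seed = 11)
#' head(feats)
#' @export
simulateFeatures <- function(truth, config = generatorConfig(), seed = NULL,
                             ffNoiseSD = 1, countNoise = TRUE,
                             residualNoise = TRUE) {
  .setSeed(seed, config)
  fr <- if (residualNoise) .realizedFrequencies(truth, config)
        else expectedFrequencies(truth, config)
  n <- nrow(truth)
  if (countNoise) {
    yc <- rpois(n, truth$total_reads * fr$normY)
    xc <- rpois(n, truth$total_reads * fr$normX)
    normY <- yc / truth$total_reads
    normX <- xc / truth$total_reads
  } else {
    normY <- fr$normY; normX <- fr$normX
  }
  ff <- getFetalFraction(truth = truth, noiseSD = ffNoiseSD, seed = NULL)
  data.frame(sample_id = truth$sample_id, normX = normX, normY = normY,
             ff = ff$value, chorionicity = truth$chorionicity,
             label = truth$sex_pair, stringsAsFactors = FALSE)
}

#' One-call cohort simulation
#'
#' Convenience wrapper: [sampleTruth()] then [simulateFeatures()].
#'
#' @inheritParams sampleTruth
#' @inheritParams simulateFeatures
#' @return list with elements `truth` and `features`.
#' @export
simulateCohort <- function(n, classMix = defaultClassMix(),
                           config = generatorConfig(), seed = NULL,
                           ffNoiseSD = 1) {
  .setSeed(seed, config)
  truth <- sampleTruth(n, classMix, config, seed = NULL)
  features <- simulateFeatures(truth, config, seed = NULL,
                               ffNoiseSD = ffNoiseSD)
  list(truth = truth, features = features)
}

#' Write / read binned counts and truth sheets
#'
#' TSV dialect: columns `chrom`, `start`, `end`, `gc`, `count` with 0-based
#' half-open coordinates, chromosomes `chr1`..`chr22`, `chrX`, `chrY`.
#' Gzipped files (by `.gz` suffix) are handled transparently.
#'
#' @param gr a `GRanges` with `gc` and `count` metadata columns.
#' @param path file path (`.gz` for compression).
#' @return `readBinCounts` returns the `GRanges`; writers return the path
#'   invisibly.
#' @export
writeBinCounts <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   gc = gr$gc, count = gr$count)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinCounts
#' @export
readBinCounts <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- read.table(con, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "count")
  if (!all(need %in% names(df)))
    stop("bin-count table must have columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("negative counts in ", path)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end),
                         gc = df$gc, count = df$count)
}

#' @rdname writeBinCounts
#' @param truth truth data.frame from [sampleTruth()].
#' @export
writeTruthSheet <- function(truth, path) {
  df <- data.frame(sample_id = truth$sample_id,
                   chorionicity = truth$chorionicity,
                   sex_pair = truth$sex_pair,
                   ff_total_percent = 100 * truth$ff_total,
                   ff1_percent = 100 * truth$ff1,
                   ff2_percent = 100 * truth$ff2)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
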