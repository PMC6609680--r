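#' @import methods
#' @importFrom stats coef dnorm lm loess median pnorm predict qnorm quantile
#'   rlnorm rnorm rpois runif sd setNames uniroot wilcox.test mad plogis
#'   qlogis loess.control residuals complete.cases
#' @importFrom utils read.table write.table modifyList
NULL

#' Generator configuration for synthetic twin cohorts
#'
#' Holds every tunable of the synthetic twin-pregnancy cfDNA simulator. The
#' defaults (see [generatorConfig()]) are calibrated so that group-level
#' summary statistics of the generated cohorts — per-class means and spreads
#' of the normalized chromosome X/Y read frequencies, the fetal-fraction
#' distribution, and the sequencing depth — match a real shallow-WGS NIPT
#' twin cohort of 198 pregnancies.
#'
#' Fetal-fraction fields (`ffMean`, `ffSD`, `ffMin`, `ffMax`, residual noise)
#' are expressed in percent; normalized frequencies and their slopes are
#' fractions of total reads (slopes per unit fetal fraction, i.e. per 1.0 of
#' ff expressed as a fraction).
#'
#' @slot ffMean,ffSD mean and SD (percent) of the truncated-normal total
#'   fetal-fraction distribution.
#' @slot ffMin,ffMax truncation bounds (percent).
#' @slot baselineNormY chrY read fraction of an all-female pregnancy: the
#'   X–Y homologous-region mismapping floor.
#' @slot baselineNormX chrX read fraction at zero male fetal contribution.
#' @slot slopeNormY,slopeNormX change of normY (resp. -normX) per unit of
#'   summed male-fetus fetal fraction divided by two.
#' @slot residualCVNormY,residualCVNormX named numeric (FF/FM/MM): per-class
#'   biological residual noise of the realized frequencies beyond the linear
#'   fetal-fraction model, as a coefficient of variation — the noise SD
#'   scales with the expected frequency, so low-fetal-fraction samples are
#'   proportionally quieter. Calibrated to reproduce the observed group SDs
#'   at the class mean frequencies.
#' @slot totalReadsMean mean sequencing depth (read pairs counted into bins).
#' @slot totalReadsCV coefficient of variation of per-sample depth.
#' @slot sheddingRatioBounds bounds of the between-co-twin placental
#'   shedding ratio; the ratio is drawn log-uniformly within them.
#' @slot binSize bin width in bp.
#' @slot gcBiasAmplitude maximal per-sample multiplicative GC-bias amplitude
#'   (each sample draws its own amplitude uniformly in +/- this value).
#' @slot genomeScale fraction of each chromosome length retained in the
#'   synthetic bin map; 1 is the full genome (~61k bins), smaller values give
#'   proportionally fewer bins at identical chromosome frequencies.
#' @slot seed seed recorded with the configuration (for manifests); the
#'   sampling functions take their own `seed` argument, and `seed = NULL`
#'   there continues the current RNG stream.
#'
#' @seealso [generatorConfig()] for construction with calibrated defaults.
#' @export
setClass("GeneratorConfig", representation(
  ffMean = "numeric", ffSD = "numeric", ffMin = "numeric", ffMax = "numeric",
  baselineNormY = "numeric", baselineNormX = "numeric",
  slopeNormY = "numeric", slopeNormX = "numeric",
  residualCVNormY = "numeric", residualCVNormX = "numeric",
  totalReadsMean = "numeric", totalReadsCV = "numeric",
  sheddingRatioBounds = "numeric", binSize = "numeric",
  gcBiasAmplitude = "numeric", genomeScale = "numeric", seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  frac <- c(baselineNormY = object@baselineNormY,
            baselineNormX = object@baselineNormX)
  if (any(frac <= 0 | frac >= 1))
    msg <- c(msg, "baseline frequencies must lie in (0, 1)")
  if (object@ffSD <= 0) msg <- c(msg, "ffSD must be positive")
  if (!(object@ffMin < object@ffMean && object@ffMean < object@ffMax))
    msg <- c(msg, "need ffMin < ffMean < ffMax")
  if (object@ffMin <= 0 || object@ffMax >= 100)
    msg <- c(msg, "ff truncation bounds must lie in (0, 100) percent")
  b <- object@sheddingRatioBounds
  if (length(b) != 2 || !(b[1] <= 1 && 1 <= b[2]) || b[1] <= 0)
    msg <- c(msg, "sheddingRatioBounds must be positive and straddle 1")
  for (nm in c("residualCVNormY", "residualCVNormX")) {
    v <- slot(object, nm)
    if (!all(.SEX_CLASSES %in% names(v)) || any(v < 0))
      msg <- c(msg, sprintf("%s needs non-negative entries named FF, FM, MM", nm))
  }
  if (object@genomeScale <= 0 || object@genomeScale > 1)
    msg <- c(msg, "genomeScale must lie in (0, 1]")
  if (object@binSize < 1000) msg <- c(msg, "binSize must be >= 1000 bp")
  if (object@totalReadsMean < 1e4) msg <- c(msg, "totalReadsMean too small")
  if (object@gcBiasAmplitude < 0 || object@gcBiasAmplitude >= 1)
    msg <- c(msg, "gcBiasAmplitude must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Fitted twin fetal-sex classifier
#'
#' Container for a fitted sex-pair classifier. `strategy` selects the
#' decision rule:
#' \describe{
#'   \item{`one_step`}{a single 3-class multinomial ridge-logistic model over
#'     FF/FM/MM (reference class FF); prediction is the probability argmax.}
#'   \item{`two_step`}{step one, a binomial model of FF vs non-FF fitted on
#'     all samples; step two, a binomial FM-vs-MM model fitted on the truly
#'     non-FF samples, consulted only when step one calls non-FF.}
#'   \item{`mc_binary`}{a single FF-vs-MM binomial model for monochorionic
#'     (necessarily same-sex) pregnancies; it can never emit FM.}
#' }
#' Covariates are standardized internally during fitting; the stored
#' coefficient vectors are back-transformed to the original covariate scale
#' (an intercept plus one coefficient per covariate).
#'
#' @slot strategy one of `"one_step"`, `"two_step"`, `"mc_binary"`.
#' @slot components named list of numeric coefficient vectors; names depend
#'   on the strategy (`FM`/`MM` log-odds vs FF for `one_step`; `stepA`
#'   (logit of FF) and `stepB` (logit of FM among non-FF) for `two_step`;
#'   `MM` (logit of MM vs FF) for `mc_binary`).
#' @slot covariates covariate column names used at fit time.
#' @slot referenceClass the multinomial reference class.
#' @slot regularization ridge penalty applied to non-intercept coefficients
#'   on the standardized scale.
#' @slot center,scale standardization constants of the covariates.
#' @export
setClass("SexModel", representation(
  strategy = "character", components = "list", covariates = "character",
  referenceClass = "character", regularization = "numeric",
  center = "numeric", scale = "numeric"
))

setValidity("SexModel", function(object) {
  msg <- character()
  if (!object@strategy %in% c("one_step", "two_step", "mc_binary"))
    msg <- c(msg, "unknown strategy")
  want <- switch(object@strategy,
    one_step = c("FM", "MM"), two_step = c("stepA", "stepB"), mc_binary = "MM")
  if (!setequal(names(object@components), want))
    msg <- c(msg, sprintf("components must be named {%s}",
                          paste(want, collapse = ", ")))
  k <- length(object@covariates) + 1L
  if (!all(vapply(object@components, length, 1L) == k))
    msg <- c(msg, sprintf("coefficient vectors must have length %d", k))
  if (object@regularization < 0) msg <- c(msg, "regularization must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SexModel-class compact display of strategy and coefficients.
#' @param object a `SexModel`.
#' @export
setMethod("show", "SexModel", function(object) {
  cat(sprintf("SexModel (strategy = %s, ridge = %g)\n",
              object@strategy, object@regularization))
  cat("covariates:", paste(object@covariates, collapse = ", "), "\n")
  for (nm in names(object@components)) {
    b <- object@components[[nm]]
    cat(sprintf("  %-5s %s\n", nm,
                paste(sprintf("%s=%.4g", names(b), b), collapse = "  ")))
  }
  invisible(object)
})

#' @describeIn GeneratorConfig-class display key calibration values.
#' @param object a `GeneratorConfig`.
#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  fetal fraction: %.2f +/- %.2f%%, truncated to [%.1f, %.1f]\n",
              object@ffMean, object@ffSD, object@ffMin, object@ffMax))
  cat(sprintf("  normY: baseline %.4g, slope %.4g; normX: baseline %.4g, slope %.4g\n",
              object@baselineNormY, object@slopeNormY,
              object@baselineNormX, object@slopeNormX))
  cat(sprintf("  depth: %.3g reads (CV %.2g), %g kb bins, genomeScale %g\n",
              object@totalReadsMean, object@totalReadsCV,
              object@binSize / 1000, object@genomeScale))
  cat(sprintf("  shedding ratio in [%g, %g], GC bias amplitude %g\n",
              object@sheddingRatioBounds[1], object@sheddingRatioBounds[2],
              object@gcBiasAmplitude))
  invisible(object)
})
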