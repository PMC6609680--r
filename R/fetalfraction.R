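#' Fetal-fraction covariate (pluggable interface)
#'
#' The classifier's third covariate. Real cohorts must supply an externally
#' estimated fetal fraction (e.g. from SeqFF-style autosomal models, whose
#' pretrained coefficients are outside this package); synthetic cohorts take
#' the simulator's ground truth perturbed by Gaussian estimator noise. A
#' provided value always wins and passes through unchanged. Values are
#' clipped to \[0, 1\]. No sample is ever filtered on its fetal fraction;
#' samples with neither source yield `NA` with a warning and are flagged
#' for the caller to handle.
#'
#' @param providedPercent numeric vector of externally estimated fetal
#'   fractions in percent (NA where absent), e.g. the sample sheet's
#'   `fetal_fraction_percent` column.
#' @param truth optional truth data.frame (column `ff_total`, fraction).
#' @param noiseSD estimator-noise SD in percentage points added to truth.
#' @param seed optional RNG seed.
#' @return data.frame with columns `value` (fraction in \[0,1\]) and
#'   `method` (`"provided"` or `"oracle_noisy"`).
#' @examples
#' getFetalFraction(providedPercent = 12.1)
#' getFetalFraction(truth = data.frame(ff_total = 0.12), noiseSD = 0)
#' @export
getFetalFraction <- function(providedPercent = NULL, truth = NULL,
                             noiseSD = 1, seed = NULL) {
  .setSeed(seed)
  n <- if (!is.null(providedPercent)) length(providedPercent)
       else if (!is.null(truth)) nrow(truth)
       else stop("missing covariate: supply providedPercent or truth")
  value <- rep(NA_real_, n)
  method <- rep(NA_character_, n)

  if (!is.null(providedPercent)) {
    has <- !is.na(providedPercent)
    value[has] <- providedPercent[has] / 100
    method[has] <- "provided"
  }
  todo <- is.na(value)
  if (any(todo) && !is.null(truth)) {
    if (nrow(truth) != n) stop("truth and providedPercent lengths differ")
    value[todo] <- truth$ff_total[todo] +
      rnorm(sum(todo), 0, noiseSD / 100)
    method[todo] <- "oracle_noisy"
  }
  if (anyNA(value))
    warning(sum(is.na(value)),
            " sample(s) lack both a provided fetal fraction and truth; ",
            "returned NA")
  data.frame(value = pmin(pmax(value, 0), 1), method = method,
             stringsAsFactors = FALSE)
}
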