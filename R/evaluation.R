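# Leave-one-out cross-validation and the performance metrics used to report
# classifier quality: per-class sensitivity/specificity with Wilson score
# intervals, plus the fetal-fraction distribution comparison.

#' Leave-one-out cross-validation predictions
#'
#' Each sample is predicted by a model trained on every other sample, so no
#' prediction ever sees its own row. With `chorionicityMode = "aware"`,
#' monochorionic samples are evaluated within the monochorionic stratum
#' using the FF-vs-MM binary model and dichorionic samples within the DCDA
#' stratum using `strategy`; with `"pooled"` all samples are evaluated
#' together under `strategy`, ignoring chorionicity. A fold whose training
#' remainder loses an entire class falls back to the classes present, with
#' a warning. Deterministic given the features.
#'
#' @param features labelled feature data.frame (see [fitSexModel()]).
#' @param strategy classifier strategy for (pooled or DCDA) fitting.
#' @param chorionicityMode `"aware"` or `"pooled"`.
#' @param regularization ridge penalty.
#' @param covariates covariate columns.
#' @return data.frame of per-sample predictions (as [predict][SexModel-class])
#'   plus `truth` and `chorionicity`.
#' @examples
#' cohort <- simulateCohort(40, seed = 9)
#' preds <- loocvPredict(cohort$features)
#' mean(preds$predicted == preds$truth)
#' @export
loocvPredict <- function(features, strategy = c("two_step", "one_step"),
                         chorionicityMode = c("aware", "pooled"),
                         regularization = 1e-6,
                         covariates = c("normX", "normY", "ff")) {
  strategy <- match.arg(strategy)
  chorionicityMode <- match.arg(chorionicityMode)
  .checkFeatures(features, covariates)

  strata <- if (chorionicityMode == "aware") {
    mc <- features$chorionicity %in% .MONOCHORIONIC
    list(list(rows = which(!mc), strategy = strategy),
         list(rows = which(mc), strategy = "mc_binary"))
  } else {
    list(list(rows = seq_len(nrow(features)), strategy = strategy))
  }

  out <- vector("list", nrow(features))
  for (s in strata) {
    rows <- s$rows
    if (!length(rows)) next
    sub <- features[rows, , drop = FALSE]
    for (i in seq_along(rows)) {
      train <- sub[-i, , drop = FALSE]
      fold <- tryCatch(
        fitSexModel(train, s$strategy, regularization, covariates),
        error = function(e) {
          # a fold can lose a whole class; fall back to classes present
          warning("LOOCV fold for ", sub$sample_id[i],
                  " degraded: ", conditionMessage(e), call. = FALSE)
          present <- unique(train$label)
          if (setequal(present, c("FF", "MM")))
            fitSexModel(train, "mc_binary", regularization, covariates)
          else stop(e)
        })
      out[[rows[i]]] <- predict(fold, sub[i, , drop = FALSE])
    }
  }
  preds <- do.call(rbind, out)
  preds$truth <- features$label
  preds$chorionicity <- features$chorionicity
  rownames(preds) <- NULL
  preds
}

#' Cross-tabulate predictions against truth
#'
#' @param predicted,truth character vectors of FF/FM/MM calls; or a
#'   prediction data.frame from [loocvPredict()] as the first argument.
#' @param ids optional sample ids for both vectors (mismatch is an error).
#' @return 3x3 integer matrix, rows = truth, columns = prediction.
#' @examples
#' confusionCounts(c("FF", "FM", "FM"), c("FF", "FM", "MM"))
#' @export
confusionCounts <- function(predicted, truth = NULL, ids = NULL) {
  if (is.data.frame(predicted)) {
    truth <- predicted$truth
    predicted <- predicted$predicted
  }
  if (length(predicted) != length(truth))
    stop("prediction/truth length mismatch")
  if (!is.null(ids) && anyDuplicated(ids))
    stop("duplicate sample ids in confusion input")
  f <- function(x) factor(x, levels = .SEX_CLASSES)
  cm <- table(truth = f(truth), predicted = f(predicted))
  matrix(as.integer(cm), 3, 3, dimnames = dimnames(cm))
}

#' Per-class sensitivity and specificity
#'
#' Sensitivity is the fraction of the class's samples predicted as that
#' class; specificity is the fraction of all *other* samples in the
#' evaluated stratum not predicted as the class.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @param class one of FF/FM/MM.
#' @return named numeric `sensitivity`, `specificity` (the latter `NA` when
#'   the stratum contains no negatives).
#' @export
sensSpec <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  pos <- sum(cm[class, ])
  if (pos == 0) stop("class ", class, " has no samples in this stratum")
  neg <- sum(cm) - pos
  sens <- cm[class, class] / pos
  spec <- if (neg > 0) (neg - sum(cm[rownames(cm) != class, class])) / neg
          else NA_real_
  c(sensitivity = unname(sens), specificity = unname(spec))
}

#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: the interval endpoints are the two roots of
#' `(phat - p)^2 = z^2 p (1 - p) / n`. Well-behaved at proportions of 0 or
#' 1, where Wald intervals collapse. Bounds are clipped to \[0, 1\];
#' reporting rounds them to 2 decimals (see [metricsReport()]).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param confidence confidence level.
#' @return named numeric `lower`, `upper` (unrounded).
#' @examples
#' round(wilsonCI(45, 46), 2)   # 0.89, 1.00
#' @export
wilsonCI <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("need 0 <= successes <= n")
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- phat + z^2 / (2 * n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  c(lower = max(0, (centre - half) / denom),
    upper = min(1, (centre + half) / denom))
}

# percent rounding, half away from zero
.percentRound <- function(p) {
  x <- 100 * p
  sign(x) * floor(abs(x) + 0.5)
}

#' Per-class performance report with confidence intervals
#'
#' @param cm confusion matrix.
#' @param stratum label recorded in the report (`"DCDA"`, `"MC"`,
#'   `"combined"`, ...).
#' @param confidence CI level.
#' @return data.frame with one row per class present: sensitivity and
#'   specificity (proportions), their Wilson CIs rounded to 2 decimals, and
#'   the rounded percent values.
#' @export
metricsReport <- function(cm, stratum = "combined", confidence = 0.95) {
  classes <- rownames(cm)[rowSums(cm) > 0]
  rows <- lapply(classes, function(cl) {
    ss <- sensSpec(cm, cl)
    pos <- sum(cm[cl, ]); neg <- sum(cm) - pos
    ciSens <- round(wilsonCI(cm[cl, cl], pos, confidence), 2)
    ciSpec <- if (neg > 0)
      round(wilsonCI(neg - sum(cm[rownames(cm) != cl, cl]), neg,
                     confidence), 2)
      else c(lower = NA_real_, upper = NA_real_)
    data.frame(stratum = stratum, class = cl,
               sensitivity = ss[["sensitivity"]],
               sensitivity_pct = .percentRound(ss[["sensitivity"]]),
               sens_ci_lower = ciSens[["lower"]],
               sens_ci_upper = ciSens[["upper"]],
               specificity = ss[["specificity"]],
               specificity_pct = .percentRound(ss[["specificity"]]),
               spec_ci_lower = ciSpec[["lower"]],
               spec_ci_upper = ciSpec[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare fetal-fraction distributions (twins vs singletons)
#'
#' Two-sided Wilcoxon/Mann–Whitney rank-sum test via [stats::wilcox.test]
#' (exact for small untied samples, otherwise normal approximation with tie
#' correction).
#'
#' @param twins,singletons numeric fetal-fraction vectors (any common unit).
#' @return list with `statistic` (Mann–Whitney U of the first sample) and
#'   `p_value`.
#' @examples
#' compareFFDistributions(c(1, 2, 3), c(4, 5, 6))
#' @export
compareFFDistributions <- function(twins, singletons) {
  if (!length(twins) || !length(singletons))
    stop("both samples must be non-empty")
  ht <- suppressWarnings(wilcox.test(twins, singletons,
                                     alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
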