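# Strategy layer over the ridge-logistic core: one-step multinomial,
# two-step binomial, and the monochorionic FF-vs-MM binary model.

.checkFeatures <- function(features, covariates, needLabel = TRUE) {
  need <- c("sample_id", covariates, if (needLabel) "label")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("features are missing column(s): ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(features[covariates]) |
    !apply(as.matrix(features[covariates]), 1, function(r) all(is.finite(r)))
  if (any(bad))
    stop("non-finite covariates for sample(s): ",
         paste(features$sample_id[bad], collapse = ", "))
  if (needLabel && !all(features$label %in% .SEX_CLASSES))
    stop("labels must be one of ", paste(.SEX_CLASSES, collapse = ", "))
  invisible(features)
}

# standardize covariates; guard constant columns (scale 1)
.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# back-transform standardized-scale coefficients to the raw covariate scale
.unstandardize <- function(beta, center, scale) {
  slopes <- beta[-1] / scale
  c("(Intercept)" = unname(beta[1] - sum(beta[-1] * center / scale)),
    slopes)
}

#' Fit a twin fetal-sex classifier
#'
#' Fits the strategy-specific logistic components on labelled sample
#' features. Covariates are standardized to training mean/SD before
#' fitting (the ridge penalty then acts on comparable scales) and the
#' returned coefficients are back-transformed to the original scale.
#'
#' Strategies: `one_step` fits a 3-class multinomial (reference FF);
#' `two_step` fits FF-vs-rest on all rows and FM-vs-MM on the rows whose
#' *true* label is non-FF (step two is therefore independent of step-one
#' errors); `mc_binary` fits FF-vs-MM and rejects FM-labelled rows, since a
#' monochorionic (monozygotic) pair cannot be mixed-sex.
#'
#' @param train data.frame of sample features: columns `sample_id`,
#'   `normX`, `normY`, `ff` (fractions), `chorionicity`, `label` (FF/FM/MM).
#' @param strategy `"one_step"`, `"two_step"` or `"mc_binary"`.
#' @param regularization ridge penalty (standardized scale).
#' @param covariates covariate columns to use; drop `"ff"` to fit the
#'   frequencies-only model.
#' @return a [SexModel-class].
#' @examples
#' cohort <- simulateCohort(60, seed = 5)
#' fitSexModel(cohort$features, "two_step")
#' @export
fitSexModel <- function(train, strategy = c("two_step", "one_step",
                                            "mc_binary"),
                        regularization = 1e-6,
                        covariates = c("normX", "normY", "ff")) {
  strategy <- match.arg(strategy)
  .checkFeatures(train, covariates)
  if ("chorionicity" %in% names(train)) {
    mcFM <- train$chorionicity %in% .MONOCHORIONIC & train$label == "FM"
    if (any(mcFM))
      stop("invalid labels: monochorionic sample(s) labelled FM: ",
           paste(train$sample_id[mcFM], collapse = ", "))
  }
  need <- switch(strategy, one_step = , two_step = c("FF", "FM", "MM"),
                 mc_binary = c("FF", "MM"))
  if (strategy == "mc_binary" && any(train$label == "FM"))
    stop("invalid labels: mc_binary cannot be trained on FM rows")
  if (!all(need %in% train$label))
    stop("training labels must cover classes: ",
         paste(need, collapse = ", "))

  X <- as.matrix(train[covariates])
  std <- .standardize(X)
  components <- switch(strategy,
    one_step = {
      fit <- fitMultinomial(std$X, train$label, reference = "FF",
                            lambda = regularization)
      lapply(fit, .unstandardize, center = std$center, scale = std$scale)
    },
    two_step = {
      a <- fitLogistic(std$X, train$label == "FF", lambda = regularization)
      nb <- train$label != "FF"
      b <- fitLogistic(std$X[nb, , drop = FALSE],
                       train$label[nb] == "FM", lambda = regularization)
      list(stepA = .unstandardize(a, std$center, std$scale),
           stepB = .unstandardize(b, std$center, std$scale))
    },
    mc_binary = {
      b <- fitLogistic(std$X, train$label == "MM", lambda = regularization)
      list(MM = .unstandardize(b, std$center, std$scale))
    })
  components <- lapply(components, function(b)
    setNames(b, c("(Intercept)", covariates)))
  new("SexModel", strategy = strategy, components = components,
      covariates = covariates, referenceClass = "FF",
      regularization = regularization, center = std$center,
      scale = std$scale)
}

#' Predict twin fetal sex
#'
#' Applies a fitted [SexModel-class] to new sample features. For
#' `two_step`, step one decides FF when `P(FF) >= 0.5` (`step_used =
#' "first"`); otherwise step two picks the larger of FM/MM (`step_used =
#' "second"`), and the reported class probabilities compose as
#' `{P(FF), (1 - P(FF)) * P(FM | non-FF), (1 - P(FF)) * P(MM | non-FF)}`.
#' `one_step` takes the softmax argmax (`step_used = "single"`).
#' `mc_binary` distributes all mass over FF and MM and never emits FM.
#'
#' @param object a fitted [SexModel-class].
#' @param newdata data.frame with the model's covariate columns (and
#'   `sample_id`).
#' @param ... unused.
#' @return data.frame: `sample_id`, `P_FF`, `P_FM`, `P_MM`, `predicted`,
#'   `step_used`.
#' @export
setMethod("predict", "SexModel", function(object, newdata, ...) {
  if (!"sample_id" %in% names(newdata))
    newdata$sample_id <- sprintf("s%03d", seq_len(nrow(newdata)))
  .checkFeatures(newdata, object@covariates, needLabel = FALSE)
  X <- as.matrix(newdata[object@covariates])
  n <- nrow(X)
  probs <- matrix(0, n, 3, dimnames = list(NULL, .SEX_CLASSES))
  step <- character(n)

  if (object@strategy == "one_step") {
    pr <- .multinomProbs(object@components, "FF", X)
    probs[, colnames(pr)] <- pr
    step[] <- "single"
  } else if (object@strategy == "two_step") {
    X1 <- cbind(1, X)
    pFF <- plogis(drop(X1 %*% object@components$stepA))
    pFMgiven <- plogis(drop(X1 %*% object@components$stepB))
    probs[, "FF"] <- pFF
    probs[, "FM"] <- (1 - pFF) * pFMgiven
    probs[, "MM"] <- (1 - pFF) * (1 - pFMgiven)
    step <- ifelse(pFF >= 0.5, "first", "second")
  } else {                                     # mc_binary
    pMM <- plogis(drop(cbind(1, X) %*% object@components$MM))
    probs[, "MM"] <- pMM
    probs[, "FF"] <- 1 - pMM
    step[] <- "single"
  }

  predicted <- .SEX_CLASSES[max.col(probs, ties.method = "first")]
  if (object@strategy == "two_step") {
    first <- step == "first"
    predicted[first] <- "FF"
    if (any(!first)) {
      amongMales <- probs[!first, c("FM", "MM"), drop = FALSE]
      predicted[!first] <- c("FM", "MM")[max.col(amongMales,
                                                 ties.method = "first")]
    }
  }
  data.frame(sample_id = newdata$sample_id, P_FF = probs[, "FF"],
             P_FM = probs[, "FM"], P_MM = probs[, "MM"],
             predicted = predicted, step_used = step,
             stringsAsFactors = FALSE)
})

#' Serialize / deserialize a fitted model as JSON
#'
#' @param model a [SexModel-class].
#' @param path output / input path.
#' @return `readSexModel` returns the model; the writer returns the path
#'   invisibly.
#' @export
writeSexModel <- function(model, path) {
  obj <- list(strategy = model@strategy,
              covariates = model@covariates,
              reference_class = model@referenceClass,
              regularization = model@regularization,
              components = lapply(model@components, as.list),
              center = as.list(model@center), scale = as.list(model@scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSexModel
#' @export
readSexModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- lapply(obj$components, unlist)
  new("SexModel", strategy = obj$strategy,
      components = comp, covariates = obj$covariates,
      referenceClass = obj$reference_class,
      regularization = obj$regularization,
      center = unlist(obj$center), scale = unlist(obj$scale))
}
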