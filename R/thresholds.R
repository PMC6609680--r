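# Minimum fetal fraction needed to tell sex-pair classes apart, from
# per-class straight-line fits of the normalized chrY frequency against
# fetal fraction and their intersections.

#' Fit a per-class normY-versus-fetal-fraction line
#'
#' Ordinary least squares of the normalized chrY frequency on fetal
#' fraction within one sex-pair class. The residual SD is the
#' root-mean-square residual (no df adjustment), the width parameter of the
#' +/- 3 s.d. accuracy bands.
#'
#' @param features labelled feature data.frame (`normY`, `ff`, `label`).
#' @param class class to fit (FF/FM/MM).
#' @return list of class `LineFit`: `class`, `intercept`, `slope`,
#'   `residual_sd`, `n`, `ff_sd` (SD of the class's fetal fractions, used
#'   by the alternative band definition).
#' @examples
#' cohort <- simulateCohort(120, seed = 21)
#' fitClassLine(cohort$features, "MM")
#' @export
fitClassLine <- function(features, class) {
  stopifnot(class %in% .SEX_CLASSES)
  rows <- features[features$label == class, , drop = FALSE]
  if (nrow(rows) < 3) stop("need >= 3 rows of class ", class)
  if (sd(rows$ff) == 0)
    stop("degenerate design: all fetal fractions identical in class ", class)
  fit <- lm(normY ~ ff, data = rows)
  res <- structure(list(class = class,
                        intercept = unname(coef(fit)[1]),
                        slope = unname(coef(fit)[2]),
                        residual_sd = sqrt(mean(residuals(fit)^2)),
                        n = nrow(rows), ff_sd = sd(rows$ff)),
                   class = "LineFit")
  res
}

#' @export
print.LineFit <- function(x, ...) {
  cat(sprintf("LineFit[%s]: normY = %.4g + %.4g * ff  (rms resid %.3g, n=%d)\n",
              x$class, x$intercept, x$slope, x$residual_sd, x$n))
  invisible(x)
}

#' Intersection of two class lines
#'
#' The fetal fraction at which the two mean lines cross:
#' `ff* = (a$intercept - b$intercept) / (b$slope - a$slope)`. Symmetric in
#' its arguments.
#'
#' @param a,b `LineFit` objects (or lists with `intercept`, `slope`).
#' @return the crossing fetal fraction (same unit as the fitted `ff`).
#' @examples
#' l1 <- list(intercept = 1, slope = 2)
#' l2 <- list(intercept = 3, slope = 1)
#' intersectLines(l1, l2)   # 2
#' @export
intersectLines <- function(a, b) {
  ds <- b$slope - a$slope
  if (abs(ds) <= 1e-12)
    stop("no intersection: lines are parallel (slope difference <= 1e-12)")
  (a$intercept - b$intercept) / ds
}

# smallest ff at which lo-line mean + 3 sd_lo stops overlapping hi-line
# mean - 3 sd_hi (bands in normY units)
.bandCrossing <- function(lo, hi, sLo, sHi) {
  ds <- hi$slope - lo$slope
  if (ds <= 1e-12)
    stop("band crossing undefined: upper line does not diverge from lower")
  (lo$intercept - hi$intercept + 3 * (sLo + sHi)) / ds
}

#' Fetal-fraction accuracy thresholds from class-line bands
#'
#' For each adjacent class pair (ordered by slope: FF < FM < MM), reports
#' the fetal fraction where the mean lines cross — above it the classes are
#' separable on average, i.e. accuracy exceeds 50% — and the smallest
#' fetal fraction at which the mean +/- 3 s.d. bands no longer overlap,
#' above which essentially every pregnancy is classified correctly.
#'
#' Band width: with `band = "residual"` (default) the s.d. is each line's
#' residual SD of normY; with `band = "ff"` the horizontal fetal-fraction
#' spread is propagated through each line's slope
#' (`3 * ff_sd * |slope|` in normY units).
#'
#' @param lines list of the three `LineFit`s (any order; matched by class).
#' @param band `"residual"` or `"ff"`.
#' @return data.frame with one row per class pair: `mean_crossing_ff`
#'   (the >50%-accuracy threshold) and `band_separation_ff` (the
#'   all-accurate threshold), in the fitted ff unit.
#' @export
accuracyBands <- function(lines, band = c("residual", "ff")) {
  band <- match.arg(band)
  names(lines) <- vapply(lines, `[[`, "", "class")
  stopifnot(all(.SEX_CLASSES %in% names(lines)))
  sdOf <- function(l) if (band == "residual") l$residual_sd
                      else l$ff_sd * abs(l$slope)
  pairs <- list(c("FF", "FM"), c("FM", "MM"))
  rows <- lapply(pairs, function(p) {
    lo <- lines[[p[1]]]; hi <- lines[[p[2]]]
    if (lo$slope > hi$slope) { tmp <- lo; lo <- hi; hi <- tmp }
    data.frame(pair = paste(p, collapse = "/"),
               mean_crossing_ff = intersectLines(lo, hi),
               band_separation_ff = .bandCrossing(lo, hi, sdOf(lo),
                                                  sdOf(hi)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full threshold report
#'
#' Fits the three class lines and derives pairwise mean-line intersections
#' and band thresholds, reported in percent fetal fraction rounded to two
#' decimals (when `ff` is in fractions).
#'
#' @inheritParams fitClassLine
#' @inheritParams accuracyBands
#' @return list: `lines` (per-class fits), `thresholds` (data.frame with
#'   percent columns).
#' @export
thresholdReport <- function(features, band = "residual") {
  lines <- lapply(.SEX_CLASSES, function(cl) fitClassLine(features, cl))
  bands <- accuracyBands(lines, band = band)
  bands$mean_crossing_pct <- round(100 * bands$mean_crossing_ff, 2)
  bands$band_separation_pct <- round(100 * bands$band_separation_ff, 2)
  list(lines = setNames(lines, .SEX_CLASSES), thresholds = bands)
}
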