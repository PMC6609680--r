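#' GC-correct binned read counts
#'
#' Removes the sample-specific relationship between bin GC fraction and read
#' count. A local-regression (loess) trend of count versus GC is fitted on
#' autosomal bins only — chrY is mismapping-dominated and chrX depends on
#' the signal being measured — with bin-length weights and one round of
#' robustness trimming (bins whose counts lie beyond 3
#' median-absolute-deviations are excluded from the fit). Every bin count is
#' divided by the trend value at its GC (nearest-boundary value for GC
#' outside the fitted support) and the table is rescaled so the total count
#' is preserved exactly.
#'
#' @param table a `GRanges` bin-count table (`gc`, `count` columns), as from
#'   [emitBinCounts()] or [readBinCounts()].
#' @param span loess span (fraction of bins in each local fit).
#' @return the corrected `GRanges`; counts become non-negative reals.
#' @examples
#' cfg <- generatorConfig(genomeScale = 0.01)
#' gr <- emitBinCounts(sampleTruth(1, config = cfg, seed = 2), cfg, seed = 2)
#' corrected <- gcCorrect(gr)
#' abs(sum(corrected$count) - sum(gr$count)) < 1e-6
#' @export
gcCorrect <- function(table, span = 0.75) {
  count <- table$count
  gc <- table$gc
  if (all(count == 0)) stop("degenerate input: all bin counts are zero")
  chrom <- as.character(GenomicRanges::seqnames(table))
  auto <- chrom %in% .AUTOSOMES & count > 0
  if (sum(auto) < 100)
    stop("need >= 100 autosomal bins with positive counts for the GC trend")

  if (sd(gc[auto]) == 0) return(table)   # constant GC: trend is flat

  m <- median(count[auto]); s <- mad(count[auto])
  keep <- auto
  if (s > 0) keep <- auto & abs(count - m) <= 3 * s
  if (sum(keep) < 100) keep <- auto

  fit <- loess(count ~ gc,
               data = data.frame(gc = gc[keep], count = count[keep]),
               weights = GenomicRanges::width(table)[keep],
               span = span, degree = 2,
               control = loess.control(surface = "direct"))
  gcClamped <- pmin(pmax(gc, min(gc[keep])), max(gc[keep]))
  trend <- predict(fit, newdata = data.frame(gc = gcClamped))
  trend <- pmax(trend, 1e-8 * max(trend))
  corrected <- count / trend
  table$count <- corrected * sum(count) / sum(corrected)
  table
}

#' Aggregate a bin table to normalized chromosome frequencies
#'
#' Sums (corrected) counts per chromosome and divides the chrX and chrY
#' totals by the grand total: the normalized sex-chromosome frequencies that
#' feed the classifier.
#'
#' @param table a `GRanges` bin-count table containing chrX and chrY rows.
#' @return object of class `ChromosomeProfile`: a list with `perChromosome`
#'   (named totals), `total`, `normX`, `normY`, and `frequencies` (all
#'   chromosomes, summing to 1).
#' @examples
#' gr <- GenomicRanges::GRanges(rep(c("chr1", "chrX", "chrY"), 2),
#'   IRanges::IRanges(start = c(1, 1, 1, 50001, 50001, 50001), width = 50000),
#'   gc = 0.4, count = c(50, 3, 1, 44, 2, 0))
#' aggregateChromosomes(gr)
#' @export
aggregateChromosomes <- function(table) {
  chrom <- as.character(GenomicRanges::seqnames(table))
  if (!all(c("chrX", "chrY") %in% chrom))
    stop("bin table must contain chrX and chrY rows")
  per <- tapply(table$count, chrom, sum)
  total <- sum(per)
  if (total <= 0) stop("degenerate input: total count is zero")
  structure(list(perChromosome = per, total = total,
                 normX = unname(per[["chrX"]] / total),
                 normY = unname(per[["chrY"]] / total),
                 frequencies = per / total),
            class = "ChromosomeProfile")
}

#' @export
print.ChromosomeProfile <- function(x, ...) {
  cat(sprintf("ChromosomeProfile: %d chromosomes, %.4g reads\n",
              length(x$perChromosome), x$total))
  cat(sprintf("  normX = %.4e   normY = %.4e\n", x$normX, x$normY))
  invisible(x)
}

#' Normalized sex-chromosome features from raw bin counts
#'
#' Convenience composition `aggregateChromosomes(gcCorrect(table))`,
#' returning the two classifier covariates for one sample.
#'
#' @inheritParams gcCorrect
#' @return named numeric: `normX`, `normY`, `total_reads`.
#' @export
normalizedFrequencies <- function(table, span = 0.75) {
  prof <- aggregateChromosomes(gcCorrect(table, span = span))
  c(normX = prof$normX, normY = prof$normY, total_reads = unname(prof$total))
}
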