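# Sample-sheet I/O and the end-to-end pipeline: simulate (or read) ->
# normalize -> features -> LOOCV evaluation -> thresholds.

#' Read and validate a sample sheet
#'
#' TSV with header; required columns `sample_id` and `chorionicity`,
#' optional `known_sex`, `fetal_fraction_percent`, `bin_counts_path`.
#' Unknown columns are preserved. Errors name the offending row.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "chorionicity") %in% names(df)))
    stop("sample sheet needs columns sample_id and chorionicity")
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop("duplicate sample_id at row ", dup[1], ": ", df$sample_id[dup[1]])
  bad <- which(!df$chorionicity %in% .CHORIONICITY_LEVELS)
  if (length(bad))
    stop("invalid chorionicity at row ", bad[1], ": '",
         df$chorionicity[bad[1]], "' (expected ",
         paste(.CHORIONICITY_LEVELS, collapse = "/"), ")")
  if ("known_sex" %in% names(df)) {
    ks <- df$known_sex
    badSex <- which(!(is.na(ks) | ks %in% .SEX_CLASSES | ks == ""))
    if (length(badSex))
      stop("invalid known_sex at row ", badSex[1], ": '", ks[badSex[1]], "'")
    impossible <- which(df$chorionicity %in% .MONOCHORIONIC &
                          !is.na(ks) & ks == "FM")
    if (length(impossible))
      stop("impossible combination at row ", impossible[1],
           ": monochorionic pregnancy with known_sex FM")
  }
  df
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' End-to-end run on a simulated cohort: ground truth, per-sample bin
#' counts, GC correction and aggregation to normalized frequencies,
#' fetal-fraction attachment, leave-one-out evaluation and fetal-fraction
#' thresholds. All artifacts are written under `outdir` together with a
#' manifest (seed, sizes, strategy, config hash); rerunning with the same
#' arguments reproduces every numeric output exactly.
#'
#' With `binLevel = FALSE` the simulator's chromosome-level fast path
#' replaces bin realization + normalization (identical at the aggregate
#' with zero GC bias); with `binLevel = TRUE` each sample's bins are
#' materialized and GC-corrected, which is the full pipeline and is
#' proportionally slower at `genomeScale = 1`.
#'
#' @param outdir output directory (created if needed).
#' @param n cohort size.
#' @param seed integer seed controlling the whole run.
#' @param strategy classifier strategy for the (pooled or DCDA) model.
#' @param chorionicityMode `"aware"` or `"pooled"`.
#' @param config a [GeneratorConfig-class].
#' @param classMix stratum proportions (see [sampleTruth()]).
#' @param span GC-correction loess span.
#' @param regularization ridge penalty.
#' @param ffNoiseSD fetal-fraction estimator noise (percentage points).
#' @param binLevel realize and normalize per-bin counts?
#' @param quiet suppress progress messages?
#' @return (invisibly) list with `truth`, `features`, `predictions`,
#'   `metrics`, `thresholds`, `paths`.
#' @export
runPipeline <- function(outdir, n = 198, seed = 1,
                        strategy = c("two_step", "one_step"),
                        chorionicityMode = c("aware", "pooled"),
                        config = generatorConfig(),
                        classMix = defaultClassMix(), span = 0.75,
                        regularization = 1e-6, ffNoiseSD = 1,
                        binLevel = FALSE, quiet = FALSE) {
  strategy <- match.arg(strategy)
  chorionicityMode <- match.arg(chorionicityMode)
  stopifnot(n >= 6)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[twinnipt] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  .setSeed(seed)
  say("simulating truth for ", n, " pregnancies (seed ", seed, ")")
  truth <- stage("simulate", sampleTruth(n, classMix, config, seed = NULL))

  features <- if (binLevel) {
    say("realizing bin counts and GC-correcting ", n, " samples")
    stage("normalize", {
      bins <- binMap(config)
      rows <- lapply(seq_len(n), function(i) {
        gr <- emitBinCounts(truth[i, , drop = FALSE], config, seed = NULL,
                            bins = bins)
        normalizedFrequencies(gr, span = span)
      })
      nf <- do.call(rbind, rows)
      ff <- getFetalFraction(truth = truth, noiseSD = ffNoiseSD)
      data.frame(sample_id = truth$sample_id, normX = nf[, "normX"],
                 normY = nf[, "normY"], ff = ff$value,
                 chorionicity = truth$chorionicity, label = truth$sex_pair,
                 stringsAsFactors = FALSE)
    })
  } else {
    say("simulating chromosome-level features")
    stage("features", simulateFeatures(truth, config, seed = NULL,
                                       ffNoiseSD = ffNoiseSD))
  }

  say("leave-one-out evaluation (", strategy, ", ", chorionicityMode, ")")
  preds <- stage("evaluate",
                 loocvPredict(features, strategy, chorionicityMode,
                              regularization))
  strataCM <- list(
    combined = confusionCounts(preds),
    DCDA = confusionCounts(preds[!preds$chorionicity %in% .MONOCHORIONIC, ]),
    MC = confusionCounts(preds[preds$chorionicity %in% .MONOCHORIONIC, ]))
  metrics <- do.call(rbind, lapply(names(strataCM), function(st)
    metricsReport(strataCM[[st]], stratum = st)))
  accuracy <- mean(preds$predicted == preds$truth)

  say("fetal-fraction thresholds")
  thr <- stage("thresholds", thresholdReport(features))

  cfgHash <- rlang::hash(list(n = n, seed = seed, strategy = strategy,
                              chorionicityMode = chorionicityMode,
                              classMix = classMix, span = span,
                              regularization = regularization,
                              ffNoiseSD = ffNoiseSD, binLevel = binLevel,
                              config = as.list(attributes(config))))
  paths <- list(
    truth = file.path(outdir, "truth.tsv"),
    features = file.path(outdir, "features.tsv"),
    predictions = file.path(outdir, "predictions.tsv"),
    metrics = file.path(outdir, "metrics.json"),
    thresholds = file.path(outdir, "thresholds.json"),
    manifest = file.path(outdir, "manifest.json"))
  writeTruthSheet(truth, paths$truth)
  .writeTSV(features, paths$features)
  .writeTSV(preds, paths$predictions)
  jsonlite::write_json(list(config_hash = cfgHash,
                            overall_accuracy = accuracy,
                            confusion = lapply(strataCM, identity),
                            metrics = metrics),
                       paths$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(list(config_hash = cfgHash,
                            lines = lapply(thr$lines, unclass),
                            thresholds = thr$thresholds),
                       paths$thresholds, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(list(package = "twinnipt",
                            version = as.character(
                              utils::packageVersion("twinnipt")),
                            seed = seed, n = n, strategy = strategy,
                            chorionicity_mode = chorionicityMode,
                            bin_level = binLevel, config_hash = cfgHash),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say(sprintf("done: overall LOOCV accuracy %.1f%%", 100 * accuracy))
  invisible(list(truth = truth, features = features, predictions = preds,
                 metrics = metrics, confusion = strataCM,
                 accuracy = accuracy, thresholds = thr, paths = paths))
}
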