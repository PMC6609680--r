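# Shared fixtures: tiny genomes and hand-built feature tables.

smallConfig <- function(...) {
  generatorConfig(genomeScale = 0.01, ...)
}

# cleanly separable three-class features (no noise): normY steps up with
# male content, normX down, ff varied but uninformative
separableFeatures <- function(nPerClass = 6) {
  cls <- rep(c("FF", "FM", "MM"), each = nPerClass)
  i <- seq_len(nPerClass)
  data.frame(
    sample_id = sprintf("s%02d", seq_along(cls)),
    normX = c(0.0497 + i * 1e-5, 0.0479 + i * 1e-5, 0.0461 + i * 1e-5),
    normY = c(4.9e-5 + i * 1e-7, 1.4e-4 + i * 1e-6, 2.4e-4 + i * 1e-6),
    ff = rep(0.08 + 0.01 * i, 3),
    chorionicity = ifelse(cls == "FM", "DCDA",
                          rep(c("DCDA", "MCDA"), length.out = length(cls))),
    label = cls, stringsAsFactors = FALSE)
}

# binary toy for exact LOOCV fold comparisons (3 FF vs 3 MM, monochorionic)
toyBinaryFeatures <- function() {
  data.frame(
    sample_id = paste0("t", 1:6),
    normX = c(0.0497, 0.0498, 0.0496, 0.0461, 0.0460, 0.0462),
    normY = c(4.8e-5, 5.0e-5, 4.9e-5, 2.4e-4, 2.5e-4, 2.3e-4),
    ff = c(0.10, 0.12, 0.11, 0.09, 0.13, 0.12),
    chorionicity = "MCDA",
    label = rep(c("FF", "MM"), each = 3), stringsAsFactors = FALSE)
}

expectedTruncNormMean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / Z
}
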