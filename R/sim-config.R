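#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: array geometry,
#' methylation-peak density and effect size, noise, dye bias, the number of
#' injected differential peaks, and the bisulfite conversion rate. One global
#' seed drives a per-stage derived seed (see [split_seed()]) so each stage is
#' independently reproducible.
#'
#' The defaults describe the study conditions the rest of the package is
#' exercised under: ~100 bp probe tiling of alternating CpG-island and
#' promoter regions, a minority (15%) of regions methylated — loess
#' normalization presumes the bulk of probes carry no enrichment, as in a
#' normal-cell methylome where most CpG islands are unmethylated — a 2.0
#' log2-unit MIRA enrichment over methylated regions, per-probe log2 noise
#' of 0.25, a mild quadratic intensity-dependent dye bias, and truth peaks
#' spanning at least 6 probes so the default peak caller (4 positives,
#' 1 gap) can recover them.
#'
#' @param n_regions Number of tiled regions on the array.
#' @param probes_per_region Integer range `c(lo, hi)` of probes per region.
#' @param probe_length Probe length in bp.
#' @param probe_spacing Start-to-start distance between adjacent probes (bp).
#' @param region_gap Distance between consecutive regions (bp).
#' @param peak_density Probability that a region carries a shared
#'   methylation peak.
#' @param effect_mean Log2-ratio elevation of probes under a peak.
#' @param noise_sd Per-probe log2 noise standard deviation.
#' @param dye_bias Coefficients `c(b0, b1, b2)` of a quadratic in centred
#'   mean log-intensity A, added to the MIRA channel (log2 scale).
#' @param n_differential Number of injected differential peaks (split
#'   between hyper- and hypomethylated).
#' @param min_peak_span Minimum truth-peak span in probes.
#' @param baseline_mean,baseline_sd Input-channel log2 intensity model.
#' @param conversion_rate Bisulfite conversion success probability per
#'   unmethylated cytosine.
#' @param seed Global integer seed.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_regions = 20, seed = 7)
#' cfg$peak_density
#' @export
sim_config <- function(n_regions = 200,
                       probes_per_region = c(8L, 14L),
                       probe_length = 50L,
                       probe_spacing = 100L,
                       region_gap = 10000L,
                       peak_density = 0.15,
                       effect_mean = 2.0,
                       noise_sd = 0.25,
                       dye_bias = c(0.2, -0.1, 0.05),
                       n_differential = 8L,
                       min_peak_span = 6L,
                       baseline_mean = 10,
                       baseline_sd = 1.5,
                       conversion_rate = 0.99,
                       seed = 1L) {
  if (length(probes_per_region) == 1L)
    probes_per_region <- rep(probes_per_region, 2L)
  cfg <- list(
    n_regions = as.integer(n_regions),
    probes_per_region = as.integer(probes_per_region),
    probe_length = as.integer(probe_length),
    probe_spacing = as.integer(probe_spacing),
    region_gap = as.integer(region_gap),
    peak_density = peak_density,
    effect_mean = effect_mean,
    noise_sd = noise_sd,
    dye_bias = as.numeric(dye_bias),
    n_differential = as.integer(n_differential),
    min_peak_span = as.integer(min_peak_span),
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    conversion_rate = conversion_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_regions) || cfg$n_regions < 1L)
    stop("configuration error: n_regions must be a positive integer")
  if (any(cfg$probes_per_region < 1L) ||
      cfg$probes_per_region[1] > cfg$probes_per_region[2])
    stop("configuration error: probes_per_region must be a positive range c(lo, hi)")
  if (cfg$probe_length < 1L || cfg$probe_spacing < 1L)
    stop("configuration error: probe_length and probe_spacing must be positive")
  if (cfg$probe_spacing < cfg$probe_length)
    stop("configuration error: probe_spacing must be >= probe_length (non-overlapping probes)")
  if (cfg$peak_density < 0 || cfg$peak_density > 1)
    stop("configuration error: peak_density must lie in [0, 1]")
  if (cfg$noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0")
  if (length(cfg$dye_bias) != 3L)
    stop("configuration error: dye_bias needs three polynomial coefficients")
  if (cfg$n_differential < 0L)
    stop("configuration error: n_differential must be >= 0")
  if (cfg$min_peak_span < 1L)
    stop("configuration error: min_peak_span must be positive")
  if (cfg$conversion_rate < 0 || cfg$conversion_rate > 1)
    stop("configuration error: conversion_rate must lie in [0, 1]")
  invisible(cfg)
}

#' Derive a stage-specific seed from the global seed
#'
#' Hashes a label into the global seed so that each generator stage has its
#' own reproducible random stream, independent of the others.
#'
#' @param seed Global integer seed.
#' @param what Stage label, e.g. `"truth"` or `"sample:UVB1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}


#' @export
print.sim_config <- function(x, ...) {
  cat("MIRA-chip simulation configuration\n")
  cat(sprintf("  regions: %d (%d-%d probes, %d bp every %d bp)\n",
              x$n_regions, x$probes_per_region[1], x$probes_per_region[2],
              x$probe_length, x$probe_spacing))
  cat(sprintf("  peaks: density %.2f, effect %.2f log2, span >= %d probes\n",
              x$peak_density, x$effect_mean, x$min_peak_span))
  cat(sprintf("  noise sd %.2f, dye bias (%s), %d differential peaks\n",
              x$noise_sd, paste(format(x$dye_bias), collapse = ", "),
              x$n_differential))
  cat(sprintf("  bisulfite conversion rate %.3f, seed %d\n",
              x$conversion_rate, x$seed))
  invisible(x)
}
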