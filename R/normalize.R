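#' M and A values of a two-channel sample
#'
#' M = log2(MIRA/input), A = half the log2 product of the two channels —
#' the usual two-colour array coordinates in which dye bias appears as an
#' intensity-dependent trend of M on A.
#'
#' @param sample An `array_sample` with raw channels.
#' @return data.frame with columns `M` and `A`.
#' @export
ma_values <- function(sample) {
  stopifnot(inherits(sample, "array_sample"))
  data.frame(M = log2(sample$mira_raw / sample$input_raw),
             A = 0.5 * log2(sample$mira_raw * sample$input_raw))
}

#' Loess-correct intensity-dependent dye bias for one array
#'
#' Fits a robust local regression of M on A (via [limma::loessFit()], the
#' standard MA-loess used for two-colour arrays) per array, independently
#' of all other arrays, and subtracts the fitted trend:
#' `log2_ratio = M - fit(A)`. The input object is not modified.
#'
#' @param sample An `array_sample` with positive raw channels.
#' @param span Loess span (fraction of probes per local window), in (0, 1].
#' @param iterations Robustifying iterations.
#' @return A new `array_sample` with `log2_ratio` populated and
#'   `normalized = TRUE`.
#' @examples
#' cfg <- sim_config(n_regions = 30, seed = 3)
#' ex <- simulate_experiment(cfg, n_control = 1, n_treated = 0)
#' s <- loess_normalize(ex$samples[[1]])
#' summary(s$log2_ratio)
#' @export
loess_normalize <- function(sample, span = 0.3, iterations = 3L) {
  stopifnot(inherits(sample, "array_sample"))
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (any(sample$mira_raw <= 0) || any(sample$input_raw <= 0))
    stop("raw intensities must be strictly positive")
  n <- length(sample$mira_raw)
  n_min <- ceiling(4 / span)
  if (n < n_min)
    stop(sprintf("loess_normalize needs at least %d probes at span %.2f (got %d)",
                 n_min, span, n))
  ma <- ma_values(sample)
  fit <- limma::loessFit(y = ma$M, x = ma$A, span = span,
                         iterations = iterations)
  out <- sample
  out$log2_ratio <- ma$M - fit$fitted
  out$normalized <- TRUE
  out
}

#' Quantile-normalize log2 ratios across samples
#'
#' Forces every sample's log2-ratio distribution onto the common reference
#' (the across-sample mean of order statistics), preserving within-sample
#' ranks; ties receive the mean of their tied reference values. Backed by
#' [limma::normalizeQuantiles()] with `ties = TRUE`. Applied to the pooled
#' set of arrays after per-array loess correction.
#'
#' @param samples List of loess-normalized `array_sample`s on one design.
#' @return List of `array_sample`s with quantile-normalized `log2_ratio`.
#' @export
quantile_normalize <- function(samples) {
  if (length(samples) == 0L) stop("empty sample list")
  stopifnot(all(vapply(samples, inherits, logical(1), "array_sample")))
  if (!all(vapply(samples, function(s) s$normalized, logical(1))))
    stop("all samples must be loess-normalized before quantile normalization")
  lens <- vapply(samples, function(s) length(s$log2_ratio), integer(1))
  if (length(unique(lens)) != 1L)
    stop("samples have mismatched probe counts; one shared design required")
  mat <- vapply(samples, function(s) s$log2_ratio, numeric(lens[1]))
  mat <- matrix(mat, nrow = lens[1])
  qn <- limma::normalizeQuantiles(mat, ties = TRUE)
  out <- samples
  for (j in seq_along(out)) out[[j]]$log2_ratio <- qn[, j]
  out
}

#' Write normalized log2 ratios as a TSV matrix (probes x samples)
#'
#' @param samples List of normalized `array_sample`s.
#' @param design A `probe_design`.
#' @param path Output TSV path.
#' @export
write_normalized <- function(samples, design, path) {
  mat <- as.data.frame(lapply(samples, function(s) s$log2_ratio))
  names(mat) <- vapply(samples, function(s) s$sample_id, character(1))
  tab <- cbind(design$probes[, c("probe_id", "chrom", "start", "end",
                                 "region_id")], mat)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one sample's normalized ratios as bedGraph
#'
#' @param sample A normalized `array_sample`.
#' @param design A `probe_design`.
#' @param path Output path.
#' @export
write_bedgraph <- function(sample, design, path) {
  stopifnot(sample$normalized)
  tab <- data.frame(design$probes$chrom, design$probes$start,
                    design$probes$end, sample$log2_ratio)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
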