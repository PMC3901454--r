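#' Construct an array sample
#'
#' One two-channel hybridization: per-probe MIRA-channel and input-channel
#' raw intensities in design order, plus the normalized log2(MIRA/input)
#' ratio once normalization has run.
#'
#' @param sample_id Sample identifier.
#' @param group Group label (e.g. `"treated"`, `"control"`).
#' @param mira_raw,input_raw Positive raw intensity vectors, equal length.
#' @param log2_ratio Optional pre-computed log2 ratio (normally filled in by
#'   [loess_normalize()]).
#' @param normalized Logical; whether `log2_ratio` is normalized.
#' @return An object of class `array_sample`.
#' @export
array_sample <- function(sample_id, group, mira_raw, input_raw,
                         log2_ratio = NULL, normalized = FALSE) {
  if (length(mira_raw) != length(input_raw))
    stop("mira_raw and input_raw must have equal length")
  if (any(!is.finite(mira_raw)) || any(!is.finite(input_raw)) ||
      any(mira_raw <= 0) || any(input_raw <= 0))
    stop("raw intensities must be finite and strictly positive")
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 mira_raw = as.numeric(mira_raw),
                 input_raw = as.numeric(input_raw),
                 log2_ratio = if (is.null(log2_ratio))
                   rep(NA_real_, length(mira_raw)) else as.numeric(log2_ratio),
                 normalized = isTRUE(normalized)),
            class = "array_sample")
}

#' @export
print.array_sample <- function(x, ...) {
  cat(sprintf("array_sample '%s' (group %s): %d probes, %s\n",
              x$sample_id, x$group, length(x$mira_raw),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Simulate raw two-channel intensities for one sample
#'
#' The input channel draws a lognormal baseline (normal on the log2 scale);
#' the MIRA channel adds the truth effect wherever the probe lies under a
#' peak carried by this sample's group, an intensity-dependent dye bias
#' (quadratic in centred mean log-intensity A, evaluated at the pre-bias A),
#' and per-probe Gaussian log2 noise.
#'
#' @param design A `probe_design`.
#' @param truth A `truth_set` from [simulate_truth_methylome()].
#' @param group Group label this hybridization belongs to.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier (also salts the stage seed, so
#'   replicates differ while sharing the truth peak structure).
#' @return An `array_sample` with raw channels populated.
#' @export
simulate_sample_intensities <- function(design, truth, group, config,
                                        sample_id = paste0(group, "_1")) {
  stopifnot(inherits(design, "probe_design"), inherits(truth, "truth_set"))
  validate_sim_config(config)
  set.seed(split_seed(config$seed, paste0("sample:", sample_id)))
  n <- nrow(design$probes)
  effect <- truth_effect_vector(design, truth, group)

  input_l2 <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  m0 <- effect + stats::rnorm(n, 0, config$noise_sd)
  a0 <- input_l2 + m0 / 2
  ac <- a0 - config$baseline_mean
  bias <- config$dye_bias[1] + config$dye_bias[2] * ac +
    config$dye_bias[3] * ac^2
  mira_l2 <- input_l2 + m0 + bias

  array_sample(sample_id, group, mira_raw = 2^mira_l2,
               input_raw = 2^input_l2)
}

#' Write / read probe intensity tables
#'
#' The TSV contract for user-supplied data: columns `probe_id`, `mira_raw`,
#' `input_raw` in design order (a `log2_ratio` column is added on write when
#' the sample is normalized, and used on read when present).
#'
#' @param sample An `array_sample`.
#' @param design A `probe_design` supplying probe ids.
#' @param path TSV path.
#' @return `write_intensities()` the path, invisibly;
#'   `read_intensities()` an `array_sample`.
#' @export
write_intensities <- function(sample, design, path) {
  stopifnot(inherits(sample, "array_sample"))
  tab <- data.frame(probe_id = design$probes$probe_id,
                    mira_raw = sample$mira_raw,
                    input_raw = sample$input_raw)
  if (sample$normalized) tab$log2_ratio <- sample$log2_ratio
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @param sample_id,group Identity of the sample being read.
#' @export
read_intensities <- function(path, sample_id, group) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "mira_raw", "input_raw")
  if (!all(need %in% names(tab)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  array_sample(sample_id, group, tab$mira_raw, tab$input_raw,
               log2_ratio = tab$log2_ratio,
               normalized = "log2_ratio" %in% names(tab))
}

#' Simulate a complete two-group MIRA-chip experiment
#'
#' Convenience wrapper: design, truth methylome, and `n_control` +
#' `n_treated` replicate hybridizations sharing the truth peak structure.
#'
#' @param config A [sim_config()].
#' @param n_control,n_treated Replicates per group (the motivating study
#'   profiled four controls and three treated samples).
#' @param groups Group names `c(control, treated)`.
#' @return List with `design`, `truth`, `samples` (list of `array_sample`).
#' @export
simulate_experiment <- function(config, n_control = 4L, n_treated = 3L,
                                groups = c("control", "treated")) {
  design <- generate_array_design(config)
  truth <- simulate_truth_methylome(design, config, groups = groups)
  ids <- c(paste0("CON", seq_len(n_control)), paste0("UVB", seq_len(n_treated)))
  grp <- c(rep(groups[1], n_control), rep(groups[2], n_treated))
  samples <- Map(function(id, g)
    simulate_sample_intensities(design, truth, g, config, sample_id = id),
    ids, grp)
  names(samples) <- ids
  list(design = design, truth = truth, samples = samples)
}
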