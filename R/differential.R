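#' Compare a treated sample with a control sample
#'
#' Candidate peaks are the union of both samples' called peaks; candidates
#' whose probe footprints overlap are merged on the union of their
#' footprints, so a peak present in only one sample still gets scored in
#' both. For each candidate the mean normalized log2 ratio over its
#' footprint is evaluated in each sample ([score_peak_in_sample()]), and a
#' differential call is emitted when the treated-minus-control difference
#' exceeds `delta_threshold` in magnitude (strictly): hypermethylated when
#' positive, hypomethylated when negative. The default threshold is
#' log2(3).
#'
#' @param treated,control Normalized `array_sample`s on one design.
#' @param treated_peaks,control_peaks Peak data.frames from [call_peaks()].
#' @param delta_threshold Strict threshold on `|delta|`, log2 units.
#' @return An object of class `comparison_summary`: list with
#'   `comparison_id`, `treated_id`, `control_id`, `n_hyper`, `n_hypo` and
#'   `calls` (data.frame `chrom, start, end, region_id, first_probe,
#'   last_probe, mean_treated, mean_control, delta, direction`).
#' @examples
#' cfg <- sim_config(n_regions = 60, effect_mean = 3, noise_sd = 0.2, seed = 5)
#' ex <- simulate_experiment(cfg, n_control = 1, n_treated = 1)
#' ns <- quantile_normalize(lapply(ex$samples, loess_normalize))
#' pk <- lapply(ns, function(s) call_peaks(ex$design, flag_positive_probes(s), s))
#' compare_sample_pair(ns$UVB1, ns$CON1, pk$UVB1, pk$CON1)
#' @export
compare_sample_pair <- function(treated, control, treated_peaks,
                                control_peaks,
                                delta_threshold = log2(3)) {
  stopifnot(inherits(treated, "array_sample"), inherits(control, "array_sample"))
  if (!treated$normalized || !control$normalized)
    stop("both samples must be normalized")
  if (length(treated$log2_ratio) != length(control$log2_ratio))
    stop("samples are on different designs (probe counts differ)")

  cand <- merge_peak_footprints(rbind(
    treated_peaks[, c("chrom", "start", "end", "region_id",
                      "first_probe", "last_probe")],
    control_peaks[, c("chrom", "start", "end", "region_id",
                      "first_probe", "last_probe")]))

  calls <- empty_calls()
  if (nrow(cand) > 0L) {
    mt <- vapply(seq_len(nrow(cand)), function(i)
      mean(treated$log2_ratio[cand$first_probe[i]:cand$last_probe[i]]),
      numeric(1))
    mc <- vapply(seq_len(nrow(cand)), function(i)
      mean(control$log2_ratio[cand$first_probe[i]:cand$last_probe[i]]),
      numeric(1))
    delta <- mt - mc
    keep <- abs(delta) > delta_threshold
    if (any(keep)) {
      calls <- cand[keep, , drop = FALSE]
      calls$mean_treated <- mt[keep]
      calls$mean_control <- mc[keep]
      calls$delta <- delta[keep]
      calls$direction <- ifelse(calls$delta > 0, "hyper", "hypo")
      rownames(calls) <- NULL
    }
  }
  structure(list(
    comparison_id = paste(treated$sample_id, "vs", control$sample_id),
    treated_id = treated$sample_id,
    control_id = control$sample_id,
    n_hyper = sum(calls$direction == "hyper"),
    n_hypo = sum(calls$direction == "hypo"),
    calls = calls
  ), class = "comparison_summary")
}

empty_calls <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             region_id = character(), first_probe = integer(),
             last_probe = integer(), mean_treated = numeric(),
             mean_control = numeric(), delta = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}

# Merge overlapping probe-footprint intervals within each region.
merge_peak_footprints <- function(peaks) {
  if (nrow(peaks) == 0L) return(peaks)
  peaks <- peaks[order(peaks$region_id, peaks$first_probe, peaks$last_probe), ,
                 drop = FALSE]
  out <- list()
  cur <- peaks[1, ]
  for (i in seq_len(nrow(peaks))[-1]) {
    row <- peaks[i, ]
    if (row$region_id == cur$region_id && row$first_probe <= cur$last_probe) {
      cur$last_probe <- max(cur$last_probe, row$last_probe)
      cur$end <- max(cur$end, row$end)
      cur$start <- min(cur$start, row$start)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("%s: %d hypermethylated, %d hypomethylated peaks\n",
              x$comparison_id, x$n_hyper, x$n_hypo))
  invisible(x)
}

#' Summarize several treated-vs-control comparisons
#'
#' Runs [compare_sample_pair()] for each declared pair and tabulates
#' hyper/hypo counts, one row per comparison — the shape of a
#' per-comparison candidate-count table.
#'
#' @param pairs List of pair specs, each a list with elements `treated`,
#'   `control` (normalized `array_sample`s), `treated_peaks`,
#'   `control_peaks`; alternatively a list of precomputed
#'   `comparison_summary` objects.
#' @param delta_threshold Passed to [compare_sample_pair()].
#' @return data.frame `comparison_id, treated_id, control_id, n_hyper,
#'   n_hypo`, ordered by `comparison_id`, with the full list of
#'   `comparison_summary` objects in attribute `"comparisons"`.
#' @export
summarize_comparisons <- function(pairs, delta_threshold = log2(3)) {
  summaries <- lapply(pairs, function(p) {
    if (inherits(p, "comparison_summary")) p
    else compare_sample_pair(p$treated, p$control, p$treated_peaks,
                             p$control_peaks, delta_threshold)
  })
  ids <- vapply(summaries, function(s) s$comparison_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate comparison_id: ", ids[duplicated(ids)][1])
  tab <- data.frame(
    comparison_id = ids,
    treated_id = vapply(summaries, function(s) s$treated_id, character(1)),
    control_id = vapply(summaries, function(s) s$control_id, character(1)),
    n_hyper = vapply(summaries, function(s) s$n_hyper, integer(1)),
    n_hypo = vapply(summaries, function(s) s$n_hypo, integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$comparison_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "comparisons") <- summaries[ord]
  tab
}

#' Write a comparison's differential calls as TSV
#' @param summary A `comparison_summary`.
#' @param path Output TSV path.
#' @export
write_differential <- function(summary, path) {
  cols <- c("chrom", "start", "end", "region_id", "mean_treated",
            "mean_control", "delta", "direction")
  utils::write.table(summary$calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
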