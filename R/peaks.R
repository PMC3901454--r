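#' Flag positive probes
#'
#' A probe is positive when its normalized log2(MIRA/input) ratio exceeds
#' 2-fold enrichment, i.e. log2 ratio strictly greater than `threshold`
#' (default 1.0, since log2 ratio > 1 is equivalent to a > 2-fold ratio).
#' Refuses unnormalized samples: positivity is defined on normalized ratios.
#'
#' @param sample A normalized `array_sample`.
#' @param threshold Log2-ratio positivity threshold; strict inequality.
#' @return Logical vector, one flag per probe.
#' @export
flag_positive_probes <- function(sample, threshold = 1.0) {
  stopifnot(inherits(sample, "array_sample"))
  if (!sample$normalized)
    stop("sample '", sample$sample_id,
         "' is not normalized; flag_positive_probes refuses raw data")
  sample$log2_ratio > threshold
}

#' Call methylation peaks from positive-probe flags
#'
#' A peak is a run of probes, scanned in design order within one tiled
#' region, that contains at least `min_positive` positive probes and at most
#' `max_gaps` gaps, where a gap is a single negative probe strictly interior
#' to the run (two adjacent negative probes always terminate a run). Runs
#' start and end on positive probes, and adjacent probes separated by more
#' than `max_spacing` bp never share a run. Peaks are emitted left to right:
#' each is the longest admissible run starting at the leftmost positive
#' probe not already consumed, so every peak is maximal and no two peaks
#' overlap. `mean_log2_ratio` averages over all member probes, gap probes
#' included.
#'
#' @param design A `probe_design`.
#' @param flags Logical vector from [flag_positive_probes()], one per probe.
#' @param sample A normalized `array_sample` (supplies ratios for
#'   `mean_log2_ratio`); optional — pass `NULL` to get peaks without means.
#' @param min_positive Minimum count of positive probes in a peak.
#' @param max_gaps Maximum number of single-probe gaps.
#' @param max_spacing Maximum bp between the end of one probe and the start
#'   of the next within a single run.
#' @return data.frame of peaks: `sample_id, chrom, start, end, region_id,
#'   first_probe, last_probe` (row indices into `design$probes`),
#'   `n_probes, n_positive, n_gaps, mean_log2_ratio`.
#' @examples
#' cfg <- sim_config(n_regions = 40, seed = 11)
#' ex <- simulate_experiment(cfg, n_control = 1, n_treated = 0)
#' s <- quantile_normalize(lapply(ex$samples, loess_normalize))[[1]]
#' peaks <- call_peaks(ex$design, flag_positive_probes(s), s)
#' nrow(peaks)
#' @export
call_peaks <- function(design, flags, sample = NULL, min_positive = 4L,
                       max_gaps = 1L, max_spacing = 500L) {
  stopifnot(inherits(design, "probe_design"))
  if (length(flags) != nrow(design$probes))
    stop("flags length (", length(flags), ") does not match probe count (",
         nrow(design$probes), ")")
  ratios <- if (is.null(sample)) rep(NA_real_, length(flags)) else {
    stopifnot(inherits(sample, "array_sample"))
    if (length(sample$log2_ratio) != length(flags))
      stop("sample and flags disagree on probe count")
    sample$log2_ratio
  }
  sid <- if (is.null(sample)) NA_character_ else sample$sample_id

  probes <- design$probes
  # segment = probes of one region with no over-spacing break inside
  region_runs <- rle(probes$region_id)
  region_starts <- cumsum(c(1L, region_runs$lengths))
  out <- list()
  for (r in seq_along(region_runs$values)) {
    lo <- region_starts[r]
    hi <- region_starts[r + 1L] - 1L
    idx <- lo:hi
    if (length(idx) > 1L) {
      gap_bp <- probes$start[idx[-1]] - probes$end[idx[-length(idx)]]
      brk <- which(gap_bp > max_spacing)
    } else brk <- integer()
    seg_bounds <- cbind(c(idx[1], idx[brk + 1L]), c(idx[brk], idx[length(idx)]))
    for (s in seq_len(nrow(seg_bounds))) {
      seg <- seg_bounds[s, 1]:seg_bounds[s, 2]
      out[[length(out) + 1L]] <-
        scan_segment(seg, flags[seg], min_positive, max_gaps)
    }
  }
  runs <- do.call(rbind, out)
  if (is.null(runs) || nrow(runs) == 0L)
    return(empty_peaks())
  data.frame(
    sample_id = sid,
    chrom = probes$chrom[runs[, 1]],
    start = probes$start[runs[, 1]],
    end = probes$end[runs[, 2]],
    region_id = probes$region_id[runs[, 1]],
    first_probe = runs[, 1],
    last_probe = runs[, 2],
    n_probes = runs[, 2] - runs[, 1] + 1L,
    n_positive = runs[, 3],
    n_gaps = runs[, 4],
    mean_log2_ratio = vapply(seq_len(nrow(runs)), function(i)
      mean(ratios[runs[i, 1]:runs[i, 2]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

empty_peaks <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), region_id = character(), first_probe = integer(),
             last_probe = integer(), n_probes = integer(),
             n_positive = integer(), n_gaps = integer(),
             mean_log2_ratio = numeric(), stringsAsFactors = FALSE)
}

# Greedy left-to-right scan of one segment. `seg` maps local positions to
# global probe row indices, `f` is the local flag vector. Returns a matrix
# with columns first, last (global), n_positive, n_gaps.
scan_segment <- function(seg, f, min_positive, max_gaps) {
  m <- length(f)
  res <- NULL
  cursor <- 1L
  repeat {
    pos <- which(f[cursor:m])[1]
    if (is.na(pos)) break
    i <- cursor + pos - 1L
    # extend to maximal admissible run starting at i
    last <- i
    gaps <- 0L
    k <- i + 1L
    while (k <= m) {
      if (f[k]) {
        last <- k
        k <- k + 1L
      } else if (gaps < max_gaps && k + 1L <= m && f[k + 1L]) {
        gaps <- gaps + 1L
        last <- k + 1L
        k <- k + 2L
      } else break
    }
    n_pos <- sum(f[i:last])
    if (n_pos >= min_positive) {
      used_gaps <- sum(!f[i:last])
      res <- rbind(res, c(seg[i], seg[last], n_pos, used_gaps))
      cursor <- last + 1L
    } else {
      cursor <- i + 1L
    }
    if (cursor > m) break
  }
  res
}

#' Score a peak's footprint in another sample
#'
#' Evaluates the mean normalized log2 ratio over a peak's member probes in a
#' different (or the same) sample — the quantity compared between treated
#' and control samples by the differential rule.
#'
#' @param peak One peak (a one-row data.frame from [call_peaks()]).
#' @param other A normalized `array_sample` on the same design.
#' @return The mean log2 ratio of `other` over the peak's probes.
#' @export
score_peak_in_sample <- function(peak, other) {
  stopifnot(inherits(other, "array_sample"), other$normalized)
  if (nrow(peak) != 1L) stop("score_peak_in_sample expects a single peak row")
  if (peak$first_probe < 1L || peak$last_probe > length(other$log2_ratio))
    stop("peak probe indices out of range for sample '", other$sample_id, "'")
  mean(other$log2_ratio[peak$first_probe:peak$last_probe])
}

#' Write peaks as BED6 with a TSV sidecar
#'
#' BED score is `1000 * min(1, mean_log2_ratio / 4)`; the sidecar repeats
#' the peaks with `n_positive`, `n_gaps` and `mean_log2_ratio` columns.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param bed_path Output BED path.
#' @param tsv_path Optional sidecar TSV path.
#' @export
write_peaks_bed <- function(peaks, bed_path, tsv_path = NULL) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    paste(peaks$sample_id, peaks$region_id, sep = ":"),
                    round(1000 * pmin(1, pmax(0, peaks$mean_log2_ratio / 4))),
                    ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(peaks, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bed_path)
}
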