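#' Simulate a ground-truth methylome for an array design
#'
#' Places shared methylation peaks (carried by every sample group) into a
#' random subset of regions, then injects differential peaks: hypermethylated
#' peaks present only in the treated group, and hypomethylated peaks realised
#' as shared peaks withdrawn from the treated group (present in control
#' only). Every peak spans at least `config$min_peak_span` probes so it is
#' callable by the default peak-calling rule.
#'
#' @param design A `probe_design`.
#' @param config A [sim_config()]; `peak_density`, `effect_mean`,
#'   `n_differential` and `min_peak_span` drive the draw.
#' @param groups Character vector `c(control, treated)` naming the two
#'   sample groups.
#' @return An object of class `truth_set`: list with
#'   \describe{
#'     \item{peaks}{data.frame `peak_id, region_id, first_index, last_index,
#'       effect, group` (probe indices are region-local, 0-based; `group`
#'       `"all"` for shared peaks).}
#'     \item{differential}{data.frame `peak_id, region_id, direction`
#'       (`hyper`/`hypo`).}
#'     \item{groups, seed}{bookkeeping.}
#'   }
#' @export
simulate_truth_methylome <- function(design, config,
                                     groups = c("control", "treated")) {
  stopifnot(inherits(design, "probe_design"))
  validate_sim_config(config)
  if (nrow(design$probes) == 0L) stop("design is empty")
  if (length(groups) != 2L) stop("exactly two group names required")
  set.seed(split_seed(config$seed, "truth"))

  reg <- design$regions
  reg$n_probes <- as.integer(table(design$probes$region_id)[reg$region_id])
  eligible <- reg$n_probes >= config$min_peak_span

  draw_span <- function(n_probes) {
    span <- resample(seq(config$min_peak_span, n_probes), 1L)
    first <- resample(0:(n_probes - span), 1L)
    c(first, first + span - 1L)
  }

  has_peak <- eligible & (stats::runif(nrow(reg)) < config$peak_density)
  peaks <- lapply(which(has_peak), function(i) {
    sp <- draw_span(reg$n_probes[i])
    data.frame(region_id = reg$region_id[i], first_index = sp[1],
               last_index = sp[2], effect = config$effect_mean,
               group = "all", stringsAsFactors = FALSE)
  })
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(region_id = character(), first_index = integer(),
               last_index = integer(), effect = numeric(),
               group = character(), stringsAsFactors = FALSE)

  n_hyper <- ceiling(config$n_differential / 2)
  n_hypo <- config$n_differential - n_hyper

  # hyper: new peaks in peak-free eligible regions, treated group only
  free <- which(eligible & !has_peak)
  if (length(free) < n_hyper)
    stop("internal error: not enough peak-free regions for ", n_hyper,
         " hypermethylated truth peaks")
  hyper_regions <- if (n_hyper > 0) resample(free, n_hyper) else integer()
  hyper <- lapply(hyper_regions, function(i) {
    sp <- draw_span(reg$n_probes[i])
    data.frame(region_id = reg$region_id[i], first_index = sp[1],
               last_index = sp[2], effect = config$effect_mean,
               group = groups[2], stringsAsFactors = FALSE)
  })

  # hypo: withdraw existing shared peaks from the treated group
  if (nrow(peaks) < n_hypo)
    stop("internal error: not enough shared peaks for ", n_hypo,
         " hypomethylated truth peaks")
  hypo_rows <- if (n_hypo > 0) resample(seq_len(nrow(peaks)), n_hypo)
    else integer()
  peaks$group[hypo_rows] <- groups[1]

  peaks <- rbind(peaks, if (length(hyper)) do.call(rbind, hyper))
  if (nrow(peaks)) {
    peaks <- peaks[order(match(peaks$region_id, reg$region_id)), ]
    peaks$peak_id <- sprintf("truth_%03d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    peaks <- peaks[, c("peak_id", "region_id", "first_index", "last_index",
                       "effect", "group")]
  } else {
    peaks$peak_id <- character()
  }

  differential <- rbind(
    if (n_hypo > 0) data.frame(peak_id = peaks$peak_id[peaks$group == groups[1]],
                               direction = "hypo", stringsAsFactors = FALSE),
    if (n_hyper > 0) data.frame(peak_id = peaks$peak_id[peaks$group == groups[2]],
                                direction = "hyper", stringsAsFactors = FALSE)
  )
  if (is.null(differential))
    differential <- data.frame(peak_id = character(), direction = character(),
                               stringsAsFactors = FALSE)
  differential$region_id <- peaks$region_id[match(differential$peak_id,
                                                  peaks$peak_id)]

  structure(list(peaks = peaks, differential = differential,
                 groups = groups, seed = config$seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d peaks (%d shared, %d hyper, %d hypo), groups %s/%s\n",
              nrow(x$peaks), sum(x$peaks$group == "all"),
              sum(x$differential$direction == "hyper"),
              sum(x$differential$direction == "hypo"),
              x$groups[1], x$groups[2]))
  invisible(x)
}

#' Per-probe truth effect for one sample group
#'
#' @param design A `probe_design`.
#' @param truth A `truth_set`.
#' @param group Group name; peaks with group `"all"` or `group` apply.
#' @return Numeric vector of log2 effects, one per design probe.
#' @export
truth_effect_vector <- function(design, truth, group) {
  eff <- numeric(nrow(design$probes))
  pk <- truth$peaks[truth$peaks$group %in% c("all", group), , drop = FALSE]
  for (i in seq_len(nrow(pk))) {
    sel <- design$probes$region_id == pk$region_id[i] &
      design$probes$index_in_region >= pk$first_index[i] &
      design$probes$index_in_region <= pk$last_index[i]
    eff[sel] <- eff[sel] + pk$effect[i]
  }
  eff
}

#' Write a truth set as JSON
#' @param truth A `truth_set`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
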