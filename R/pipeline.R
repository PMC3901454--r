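#' Pipeline configuration
#'
#' Collects everything an end-to-end run needs: mode, inputs or simulation
#' settings, output directory, and all stage parameters with their module
#' defaults. Comparisons are declared explicitly as (treated_id,
#' control_id) pairs; in simulate mode they default to every treated
#' sample against every control sample.
#'
#' @param mode One of `"simulate"`, `"chip"`, `"bisulfite"`, `"full"`.
#' @param out_dir Output directory (created if missing).
#' @param sim A [sim_config()].
#' @param n_control,n_treated Replicates per group in simulate mode.
#' @param design_tsv,sample_table Inputs for chip mode: probe-design TSV
#'   and a data.frame `sample_id, group, path` of intensity TSVs.
#' @param comparisons data.frame `treated_id, control_id`, or `NULL` for
#'   the simulate-mode default.
#' @param threshold Positivity threshold (log2 units).
#' @param min_positive,max_gaps,max_spacing Peak-calling parameters.
#' @param delta_threshold Differential threshold (log2 units).
#' @param loess_span,loess_iterations Loess parameters.
#' @param transcripts_path,islands_path Optional annotation inputs (BED /
#'   refFlat; BED assumed unless the file ends in `.txt`).
#' @param amplicon_fasta,clone_fastas Bisulfite-mode inputs: amplicon FASTA
#'   and a named list of clone FASTA paths (one per sample group).
#' @param group_probs Simulated bisulfite mode: named list of per-CpG
#'   methylation probabilities, one entry per group.
#' @param n_clones Clones per group in simulated bisulfite mode.
#' @param min_conversion Conversion QC threshold; `0` disables filtering
#'   (the unfiltered setting used when reproducing clone percentages).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "chip", "bisulfite", "full"),
                            out_dir = tempfile("mirachip_run_"),
                            sim = sim_config(),
                            n_control = 4L, n_treated = 3L,
                            design_tsv = NULL, sample_table = NULL,
                            comparisons = NULL,
                            threshold = 1.0, min_positive = 4L,
                            max_gaps = 1L, max_spacing = 500L,
                            delta_threshold = log2(3),
                            loess_span = 0.3, loess_iterations = 3L,
                            transcripts_path = NULL, islands_path = NULL,
                            amplicon_fasta = NULL, clone_fastas = NULL,
                            group_probs = list(control = 0.29,
                                               treated = 0.184),
                            n_clones = 50L, min_conversion = 0) {
  mode <- match.arg(mode)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (mode == "chip") {
    if (is.null(cfg$design_tsv) || is.null(cfg$sample_table))
      stop("chip mode needs design_tsv and sample_table")
    for (p in c(cfg$design_tsv, cfg$sample_table$path))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (mode == "bisulfite" && !is.null(cfg$amplicon_fasta) &&
      !file.exists(cfg$amplicon_fasta))
    stop("input file not found: ", cfg$amplicon_fasta)
  cfg
}

run_log <- function(dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the MIRA-chip pipeline end to end
#'
#' simulate → loess per array → quantile across arrays → positive-probe
#' flagging → peak calling per sample → treated-vs-control differential
#' comparison → annotation → report. In `"chip"` mode, intensities are read
#' from the TSV contract instead of simulated. All randomness derives from
#' `config$sim$seed`, so two runs with the same configuration produce
#' byte-identical data files.
#'
#' @param config A [pipeline_config()].
#' @return A run report (list; also written as `run_report.json`), with the
#'   output paths in `$files`.
#' @export
run_chip_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "run.log"))
  od <- config$out_dir
  files <- character()
  input_checksums <- list()

  if (config$mode %in% c("simulate", "full")) {
    run_log(od, "stage simulate: generating design, truth and ",
            config$n_control + config$n_treated, " samples")
    ex <- simulate_experiment(config$sim, config$n_control, config$n_treated)
    design <- ex$design; truth <- ex$truth; samples <- ex$samples
    write_design(design, file.path(od, "design_regions.bed"),
                 file.path(od, "design_probes.tsv"))
    write_truth(truth, file.path(od, "truth.json"))
    files <- c(files, "design_regions.bed", "design_probes.tsv", "truth.json")
    for (id in names(samples)) {
      p <- file.path(od, paste0("intensities_", id, ".tsv"))
      write_intensities(samples[[id]], design, p)
      files <- c(files, basename(p))
    }
  } else if (config$mode == "chip") {
    run_log(od, "stage read: loading design and intensity tables")
    design <- read_design(config$design_tsv)
    truth <- NULL
    samples <- Map(function(id, g, p) read_intensities(p, id, g),
                   config$sample_table$sample_id,
                   config$sample_table$group,
                   config$sample_table$path)
    names(samples) <- config$sample_table$sample_id
    input_checksums <- as.list(tools::md5sum(
      c(config$design_tsv, config$sample_table$path)))
  } else stop("run_chip_pipeline does not handle mode '", config$mode, "'")

  run_log(od, "stage normalize: loess (span ", config$loess_span,
          ") then quantile across ", length(samples), " arrays")
  samples <- tryCatch(
    quantile_normalize(lapply(samples, loess_normalize,
                              span = config$loess_span,
                              iterations = config$loess_iterations)),
    error = function(e) stop("stage normalize failed: ",
                             conditionMessage(e)))
  write_normalized(samples, design, file.path(od, "normalized.tsv"))
  files <- c(files, "normalized.tsv")

  run_log(od, "stage peaks: threshold ", config$threshold, ", min ",
          config$min_positive, " positives, max ", config$max_gaps, " gap(s)")
  flags <- lapply(samples, flag_positive_probes, threshold = config$threshold)
  peaks <- lapply(names(samples), function(id)
    call_peaks(design, flags[[id]], samples[[id]],
               min_positive = config$min_positive,
               max_gaps = config$max_gaps,
               max_spacing = config$max_spacing))
  names(peaks) <- names(samples)
  for (id in names(peaks)) {
    write_peaks_bed(peaks[[id]], file.path(od, paste0("peaks_", id, ".bed")),
                    file.path(od, paste0("peaks_", id, ".tsv")))
    files <- c(files, paste0("peaks_", id, ".bed"), paste0("peaks_", id, ".tsv"))
  }

  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    groups <- vapply(samples, function(s) s$group, character(1))
    treated_ids <- names(samples)[groups == "treated"]
    control_ids <- names(samples)[groups == "control"]
    comparisons <- expand.grid(treated_id = treated_ids,
                               control_id = control_ids,
                               stringsAsFactors = FALSE)
  }
  if (nrow(comparisons) > 0 && length(samples) < 2)
    stop("at least two samples are required for a comparison")
  run_log(od, "stage differential: ", nrow(comparisons),
          " comparison(s) at |delta| > ", round(config$delta_threshold, 4))
  pair_specs <- lapply(seq_len(nrow(comparisons)), function(i) {
    t_id <- comparisons$treated_id[i]; c_id <- comparisons$control_id[i]
    if (!t_id %in% names(samples) || !c_id %in% names(samples))
      stop("comparison references unknown sample: ", t_id, " vs ", c_id)
    list(treated = samples[[t_id]], control = samples[[c_id]],
         treated_peaks = peaks[[t_id]], control_peaks = peaks[[c_id]])
  })
  summary_tab <- summarize_comparisons(pair_specs, config$delta_threshold)
  all_calls <- list()
  for (s in attr(summary_tab, "comparisons")) {
    fn <- paste0("differential_", gsub("[^A-Za-z0-9]+", "_",
                                       s$comparison_id), ".tsv")
    write_differential(s, file.path(od, fn))
    files <- c(files, fn)
    if (nrow(s$calls)) {
      calls <- s$calls; calls$comparison_id <- s$comparison_id
      all_calls[[length(all_calls) + 1L]] <- calls
    }
  }
  utils::write.table(summary_tab, file.path(od, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "summary.tsv")

  run_log(od, "stage annotate")
  if (!is.null(config$transcripts_path)) {
    dialect <- if (grepl("\\.txt$", config$transcripts_path)) "refflat" else "bed"
    tx <- read_transcript_table(config$transcripts_path, dialect)
    isl <- if (!is.null(config$islands_path))
      read_cpg_islands(config$islands_path) else NULL
  } else if (!is.null(design$regions$kind) &&
             !all(is.na(design$regions$kind))) {
    ann <- design_to_annotation(design)
    tx <- ann$transcripts; isl <- ann$islands
  } else {
    tx <- NULL; isl <- NULL
  }
  calls_tab <- if (length(all_calls)) do.call(rbind, all_calls) else {
    ec <- empty_calls(); ec$comparison_id <- character(); ec
  }
  annotated <- annotate_peaks(calls_tab, tx, isl)
  write_annotated(annotated, file.path(od, "annotated_differential.tsv"))
  files <- c(files, "annotated_differential.tsv")

  report <- list(
    version = as.character(utils::packageVersion("mirachip")),
    mode = config$mode,
    seed = config$sim$seed,
    parameters = list(threshold = config$threshold,
                      min_positive = config$min_positive,
                      max_gaps = config$max_gaps,
                      max_spacing = config$max_spacing,
                      delta_threshold = config$delta_threshold,
                      loess_span = config$loess_span,
                      loess_iterations = config$loess_iterations),
    input_checksums = input_checksums,
    counts = list(
      probes = nrow(design$probes),
      regions = nrow(design$regions),
      samples = length(samples),
      positive_probes = vapply(flags, sum, integer(1)),
      peaks_per_sample = vapply(peaks, nrow, integer(1)),
      differential_calls = stats::setNames(
        summary_tab$n_hyper + summary_tab$n_hypo,
        summary_tab$comparison_id),
      truth_peaks = if (!is.null(truth)) nrow(truth$peaks) else NA,
      truth_differential = if (!is.null(truth)) nrow(truth$differential)
        else NA
    ),
    files = files
  )
  jsonlite::write_json(report, file.path(od, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(od, "done: ", length(files), " data files in ", od)
  invisible(c(report, list(
    design = design, truth = truth, samples = samples, peaks = peaks,
    summary = summary_tab, annotated = annotated)))
}

#' Run the bisulfite verification pipeline
#'
#' Per amplicon: COBRA restriction-site report, clone alignment and CpG
#' calling per sample group, methylation matrix TSV, text lollipop diagram,
#' and a percent-methylation table comparing the groups. In simulate mode
#' the clones are drawn by [simulate_bisulfite_clones()] at the per-group
#' methylation probabilities in `config$group_probs`; otherwise clone FASTA
#' files are read per group. Unalignable clones produce warnings and are
#' dropped; an amplicon with zero alignable clones is an error.
#'
#' @param config A [pipeline_config()] with mode `"bisulfite"` (or
#'   `"simulate"`/`"full"` to simulate clones).
#' @return A run report (list; also written as `run_report.json`).
#' @export
run_bisulfite_report <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  files <- character()
  simulate <- is.null(config$clone_fastas)

  amps <- if (!is.null(config$amplicon_fasta))
    read_amplicon_fasta(config$amplicon_fasta)
  else list(synthetic = random_amplicon("synthetic", 400L,
                                        seed = config$sim$seed))

  pct_rows <- list()
  counts <- list()
  for (amp in amps) {
    cobra <- cobra_site_analysis(amp)
    cobra_tab <- cobra$sites
    cobra_tab$amplicon <- rep(amp$name, nrow(cobra_tab))
    fn <- paste0("cobra_", amp$name, ".tsv")
    utils::write.table(cobra_tab, file.path(od, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, fn)

    groups <- if (simulate) names(config$group_probs)
      else names(config$clone_fastas)
    for (g in groups) {
      if (simulate) {
        sim <- simulate_bisulfite_clones(amp, config$group_probs[[g]],
                                         config$n_clones, config$sim,
                                         group = paste(amp$name, g))
        reads <- sim$reads
        fa <- paste0("clones_", amp$name, "_", g, ".fa")
        write_clone_fasta(reads, file.path(od, fa))
        files <- c(files, fa)
      } else {
        reads <- read_clone_fasta(config$clone_fastas[[g]])
        if (length(reads) == 0L)
          stop("empty clone FASTA for group '", g, "': ",
               config$clone_fastas[[g]])
      }
      calls <- list()
      n_fail <- 0L
      for (i in seq_along(reads)) {
        call <- tryCatch(
          align_and_call_clone(reads[[i]], amp, clone_id = names(reads)[i]),
          error = function(e) {
            warning("dropping clone: ", conditionMessage(e), call. = FALSE)
            NULL
          })
        if (is.null(call)) n_fail <- n_fail + 1L
        else calls[[length(calls) + 1L]] <- call
      }
      if (length(calls) == 0L)
        stop("no clone of group '", g, "' aligned to amplicon '",
             amp$name, "'")
      mm <- methylation_matrix(amp, calls,
                               min_conversion = config$min_conversion)
      mat_fn <- paste0("matrix_", amp$name, "_", g, ".tsv")
      utils::write.table(mm$calls, file.path(od, mat_fn), sep = "\t",
                         quote = FALSE, col.names = FALSE)
      lol_fn <- paste0("lollipop_", amp$name, "_", g, ".txt")
      writeLines(render_lollipop(mm), file.path(od, lol_fn))
      files <- c(files, mat_fn, lol_fn)
      qc_only <- config$min_conversion > 0
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        amplicon = amp$name, group = g, n_clones = length(calls),
        n_unaligned = n_fail,
        n_qc_fail = sum(!vapply(mm$clones, function(c) c$pass_qc,
                                logical(1))),
        percent_methylated = percent_methylation(mm, qc_only = qc_only),
        stringsAsFactors = FALSE)
      counts[[paste(amp$name, g, sep = ":")]] <- length(calls)
    }
  }
  pct <- do.call(rbind, pct_rows)
  utils::write.table(pct, file.path(od, "percent_methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "percent_methylation.tsv")

  report <- list(version = as.character(utils::packageVersion("mirachip")),
                 mode = "bisulfite", seed = config$sim$seed,
                 simulate = simulate,
                 counts = counts, percent_methylation = pct, files = files)
  jsonlite::write_json(report[setdiff(names(report), "percent_methylation")],
                       file.path(od, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
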