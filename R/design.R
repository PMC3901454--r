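#' Generate a synthetic CpG-island plus promoter probe design
#'
#' Emulates the geometry of a NimbleGen-style CpG-island + promoter tiling
#' array: regions alternate between CpG islands and promoters, and each
#' region is tiled by short probes at a fixed start-to-start spacing.
#' All coordinates are 0-based, half-open.
#'
#' @param config A [sim_config()].
#' @return An object of class `probe_design`: a list with
#'   \describe{
#'     \item{probes}{data.frame `probe_id, chrom, start, end, region_id,
#'       index_in_region` in design order.}
#'     \item{regions}{data.frame `region_id, chrom, start, end, kind`
#'       with `kind` in `cpg_island`/`promoter`.}
#'   }
#' @examples
#' d <- generate_array_design(sim_config(n_regions = 4, seed = 7))
#' head(d$probes)
#' @export
generate_array_design <- function(config) {
  validate_sim_config(config)
  set.seed(split_seed(config$seed, "design"))
  n <- config$n_regions
  n_probes <- resample(seq(config$probes_per_region[1],
                           config$probes_per_region[2]),
                       n, replace = TRUE)
  # regions fill chromosomes in blocks of 50 so coordinates stay sorted
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% 50L + 1L)
  kind <- rep_len(c("cpg_island", "promoter"), n)
  region_id <- sprintf("region_%04d", seq_len(n))

  starts <- integer(n)
  ends <- integer(n)
  pos <- config$region_gap
  cur_chrom <- chrom[1]
  probes <- vector("list", n)
  for (i in seq_len(n)) {
    if (chrom[i] != cur_chrom) {
      cur_chrom <- chrom[i]
      pos <- config$region_gap
    }
    starts[i] <- pos
    p_start <- pos + (seq_len(n_probes[i]) - 1L) * config$probe_spacing
    p_end <- p_start + config$probe_length
    ends[i] <- p_end[n_probes[i]]
    probes[[i]] <- data.frame(
      probe_id = sprintf("%s_p%02d", region_id[i], seq_len(n_probes[i]) - 1L),
      chrom = chrom[i],
      start = p_start,
      end = p_end,
      region_id = region_id[i],
      index_in_region = seq_len(n_probes[i]) - 1L,
      stringsAsFactors = FALSE
    )
    pos <- ends[i] + config$region_gap
  }
  design <- list(
    probes = do.call(rbind, probes),
    regions = data.frame(region_id = region_id, chrom = chrom,
                         start = starts, end = ends, kind = kind,
                         stringsAsFactors = FALSE)
  )
  rownames(design$probes) <- NULL
  structure(design, class = "probe_design")
}

n_probes_design <- function(design) nrow(design$probes)

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("probe_design: %d probes in %d regions (%d CpG islands, %d promoters)\n",
              nrow(x$probes), nrow(x$regions),
              sum(x$regions$kind == "cpg_island"),
              sum(x$regions$kind == "promoter")))
  invisible(x)
}

#' Write a probe design to disk
#'
#' Emits the region track as BED (0-based half-open, so no coordinate shift)
#' and the probe table as TSV.
#'
#' @param design A `probe_design`.
#' @param bed_path Output BED path for the region track (or `NULL` to skip).
#' @param tsv_path Output TSV path for the probe table (or `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, bed_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(design, "probe_design"))
  if (!is.null(bed_path)) {
    bed <- data.frame(design$regions$chrom, design$regions$start,
                      design$regions$end,
                      paste(design$regions$region_id, design$regions$kind,
                            sep = "|"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(design$probes[, c("probe_id", "chrom", "start",
                                         "end", "region_id")],
                       tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a probe design from the TSV probe table
#'
#' Accepts the table written by [write_design()] (columns `probe_id, chrom,
#' start, end, region_id`); `index_in_region` and the region table are
#' reconstructed from probe order.
#'
#' @param tsv_path Path to the probe TSV.
#' @return A `probe_design`.
#' @export
read_design <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "region_id")
  if (!all(need %in% names(tab)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  tab$index_in_region <- stats::ave(seq_len(nrow(tab)), tab$region_id,
                                    FUN = function(i) seq_along(i) - 1L)
  regions <- do.call(rbind, lapply(split(tab, tab$region_id), function(g) {
    data.frame(region_id = g$region_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               kind = NA_character_, stringsAsFactors = FALSE)
  }))
  regions <- regions[order(match(regions$region_id, unique(tab$region_id))), ]
  rownames(regions) <- NULL
  structure(list(probes = tab, regions = regions), class = "probe_design")
}
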