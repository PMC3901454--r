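#' Read a transcript table (BED6 or refFlat dialect)
#'
#' BED input is 0-based half-open; the BED name fills both `gene` and
#' `name`. RefFlat-like input (`geneName, name, chrom, strand, txStart,
#' txEnd, ...`) follows the UCSC 0-based convention. Records without a
#' `+`/`-` strand are rejected with a warning — promoter windows are
#' strand-dependent.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"refflat"`.
#' @return data.frame of transcript records: `name, gene, chrom, strand,
#'   tx_start, tx_end` (0-based half-open).
#' @export
read_transcript_table <- function(path, dialect = c("bed", "refflat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    tab <- data.frame(
      name = if (!is.null(gr$name)) gr$name else
        paste0("tx_", seq_along(gr)),
      gene = if (!is.null(gr$name)) gr$name else
        paste0("tx_", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      tx_start = GenomicRanges::start(gr) - 1L,  # back to 0-based
      tx_end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(raw) < 6L)
      stop("refFlat table needs at least 6 columns (geneName, name, chrom, ",
           "strand, txStart, txEnd)")
    bad <- which(is.na(suppressWarnings(as.integer(raw$V5))) |
                   is.na(suppressWarnings(as.integer(raw$V6))))
    if (length(bad))
      stop("malformed refFlat line ", bad[1], ": non-integer txStart/txEnd")
    tab <- data.frame(name = raw$V2, gene = raw$V1, chrom = raw$V3,
                      strand = raw$V4, tx_start = as.integer(raw$V5),
                      tx_end = as.integer(raw$V6), stringsAsFactors = FALSE)
  }
  ok <- tab$strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sum(!ok), " record(s) without a +/- strand rejected")
    tab <- tab[ok, , drop = FALSE]
  }
  if (any(tab$tx_start >= tab$tx_end))
    stop("transcript with tx_start >= tx_end")
  rownames(tab) <- NULL
  tab
}

#' Read CpG island intervals from BED
#'
#' @param path BED path.
#' @return data.frame `chrom, start, end, name` (0-based half-open).
#' @export
read_cpg_islands <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               paste0("cpg_", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Promoter window around a transcript's TSS
#'
#' The promoter is the interval from `upstream` bp before to `downstream`
#' bp after the transcription start site (defaults −2.4 kb/+0.6 kb, the
#' span tiled by CpG-island + promoter arrays). On the `+` strand the TSS
#' is `tx_start`; on the `-` strand it is `tx_end` and the window is
#' reflected. Windows are clipped at coordinate 0.
#'
#' @param transcript One transcript record (one-row data.frame as returned
#'   by [read_transcript_table()]), or a multi-row table for vectorized use.
#' @param upstream,downstream Window extents in bp.
#' @return data.frame `name, gene, chrom, start, end` (0-based half-open),
#'   one row per transcript.
#' @examples
#' tx <- data.frame(name = "NM_1", gene = "G", chrom = "chr1",
#'                  strand = "+", tx_start = 10000, tx_end = 15000)
#' promoter_window(tx)  # [7600, 10600)
#' @export
promoter_window <- function(transcript, upstream = 2400L, downstream = 600L) {
  plus <- transcript$strand == "+"
  tss <- ifelse(plus, transcript$tx_start, transcript$tx_end)
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  data.frame(name = transcript$name, gene = transcript$gene,
             chrom = transcript$chrom,
             start = as.integer(pmax(0L, start)), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Annotate peaks or differential calls
#'
#' Intersects each peak with promoter windows (built from the transcript
#' table via [promoter_window()]) and CpG islands, using half-open interval
#' overlap of at least 1 bp (GenomicRanges). Each peak gains a
#' semicolon-joined, alphabetically ordered gene list, an island list, and
#' a category: `promoter`, `cpg_island`, `both`, or `intergenic`.
#'
#' @param peaks Peak or differential-call data.frame with `chrom, start,
#'   end` (0-based half-open).
#' @param transcripts Transcript table from [read_transcript_table()], or
#'   `NULL`.
#' @param islands CpG-island table from [read_cpg_islands()], or `NULL`.
#' @param upstream,downstream Promoter window extents.
#' @return `peaks` with added columns `genes`, `islands`, `category`.
#' @export
annotate_peaks <- function(peaks, transcripts = NULL, islands = NULL,
                           upstream = 2400L, downstream = 600L) {
  n <- nrow(peaks)
  genes <- character(n)
  isl <- character(n)
  if (n == 0L) {
    peaks$genes <- character(0); peaks$islands <- character(0)
    peaks$category <- character(0)
    return(peaks)
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))

  ann_chroms <- c(if (!is.null(transcripts)) transcripts$chrom,
                  if (!is.null(islands)) islands$chrom)
  missing_chr <- setdiff(unique(peaks$chrom), unique(ann_chroms))
  if (length(missing_chr) && length(ann_chroms))
    warning("chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "),
            "; peaks there fall back to intergenic")

  if (!is.null(transcripts) && nrow(transcripts)) {
    prom <- promoter_window(transcripts, upstream, downstream)
    prom_gr <- GenomicRanges::GRanges(
      prom$chrom, IRanges::IRanges(prom$start + 1L, prom$end))
    hits <- GenomicRanges::findOverlaps(peak_gr, prom_gr)
    for (i in unique(S4Vectors::queryHits(hits))) {
      g <- sort(unique(prom$gene[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]))
      genes[i] <- paste(g, collapse = ";")
    }
  }
  if (!is.null(islands) && nrow(islands)) {
    isl_gr <- GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(islands$start + 1L, islands$end))
    hits <- GenomicRanges::findOverlaps(peak_gr, isl_gr)
    for (i in unique(S4Vectors::queryHits(hits))) {
      nm <- sort(unique(islands$name[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]))
      isl[i] <- paste(nm, collapse = ";")
    }
  }
  peaks$genes <- genes
  peaks$islands <- isl
  peaks$category <- ifelse(genes != "" & isl != "", "both",
                    ifelse(genes != "", "promoter",
                    ifelse(isl != "", "cpg_island", "intergenic")))
  peaks
}

#' Derive annotation tables from a synthetic design
#'
#' Turns a simulated design's promoter regions into transcript records (TSS
#' placed so the tiled region is the −upstream/+downstream window) and its
#' CpG-island regions into an island table, so a simulated experiment can
#' run the annotation stage without external files.
#'
#' @param design A `probe_design` with region `kind` populated.
#' @param upstream,downstream Promoter window extents used for TSS
#'   placement.
#' @return List with `transcripts` and `islands` data.frames.
#' @export
design_to_annotation <- function(design, upstream = 2400L,
                                 downstream = 600L) {
  reg <- design$regions
  prom <- reg[reg$kind %in% "promoter", , drop = FALSE]
  transcripts <- data.frame(
    name = paste0("NM_", prom$region_id),
    gene = toupper(prom$region_id),
    chrom = prom$chrom,
    strand = "+",
    tx_start = prom$start + upstream,
    tx_end = prom$start + upstream + 1000L,
    stringsAsFactors = FALSE
  )
  cg <- reg[reg$kind %in% "cpg_island", , drop = FALSE]
  islands <- data.frame(chrom = cg$chrom, start = cg$start, end = cg$end,
                        name = paste0("CpG:", cg$region_id),
                        stringsAsFactors = FALSE)
  list(transcripts = transcripts, islands = islands)
}

#' Write an annotated peak table as TSV
#' @param annotated Output of [annotate_peaks()].
#' @param path TSV path.
#' @export
write_annotated <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
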