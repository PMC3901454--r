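write_bed6 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

test_that("transcript tables parse from BED and refFlat identically", {
  td <- withr::local_tempdir()
  bed <- write_bed6(data.frame(c("chr1", "chr1", "chr2"),
                               c(1000L, 5000L, 0L),
                               c(3000L, 9000L, 800L),
                               c("GENEA", "GENEB", "GENEC"),
                               0L, c("+", "-", "+")),
                    file.path(td, "tx.bed"))
  tx <- read_transcript_table(bed, "bed")
  expect_equal(nrow(tx), 3)
  expect_equal(tx$tx_start, c(1000, 5000, 0))
  expect_equal(tx$tx_end, c(3000, 9000, 800))
  expect_equal(tx$strand, c("+", "-", "+"))

  rf <- file.path(td, "tx.txt")
  utils::write.table(data.frame(c("GENEA", "GENEB", "GENEC"),
                                c("GENEA", "GENEB", "GENEC"),
                                c("chr1", "chr1", "chr2"),
                                c("+", "-", "+"),
                                c(1000L, 5000L, 0L),
                                c(3000L, 9000L, 800L),
                                0L, 0L, 1L, "", ""),
                     rf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tx2 <- read_transcript_table(rf, "refflat")
  expect_equal(tx2[, c("gene", "chrom", "strand", "tx_start", "tx_end")],
               tx[, c("gene", "chrom", "strand", "tx_start", "tx_end")])

  # strandless records are rejected with a warning
  bad <- write_bed6(data.frame("chr1", 10L, 20L, "X", 0L, "."),
                    file.path(td, "bad.bed"))
  expect_warning(out <- read_transcript_table(bad, "bed"), "strand")
  expect_equal(nrow(out), 0)
})

test_that("promoter windows follow the TSS, reflect with strand, clip at zero", {
  plus <- data.frame(name = "NM_1", gene = "G1", chrom = "chr1",
                     strand = "+", tx_start = 10000, tx_end = 15000)
  w <- promoter_window(plus)
  expect_equal(c(w$start, w$end), c(7600, 10600))
  expect_equal(w$end - w$start, 3000)

  minus <- transform(plus, strand = "-", tx_start = 5000, tx_end = 10000)
  wm <- promoter_window(minus)
  expect_equal(c(wm$start, wm$end), c(9400, 12400))
  # reflection oracle: the minus window is the plus window mirrored about
  # the TSS
  tss <- 10000
  expect_equal(sort(c(tss - (wm$end - tss), tss + (tss - wm$start))),
               c(w$start, w$end))

  near0 <- transform(plus, tx_start = 1000, tx_end = 4000)
  w0 <- promoter_window(near0)
  expect_equal(c(w0$start, w0$end), c(0, 1600))
})

test_that("peak annotation uses half-open overlap and reports sorted gene lists", {
  # both transcripts share TSS 10000, so both promoters are [7600, 10600)
  tx <- data.frame(name = c("NM_1", "NM_2"), gene = c("ZZZ", "AAA"),
                   chrom = "chr1", strand = "+",
                   tx_start = 10000, tx_end = c(15000, 15100))
  isl <- data.frame(chrom = "chr1", start = 7000, end = 7650,
                    name = "CpG:1")
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    start = c(8000, 10600, 7600, 5),
    end = c(8100, 10700, 7650, 50))
  expect_warning(ann <- annotate_peaks(peaks, tx, isl), "chr9")
  # [8000,8100) overlaps promoters of both genes -> alphabetical join
  expect_equal(ann$genes[1], "AAA;ZZZ")
  expect_equal(ann$category[1], "promoter")
  # half-open boundary: a peak starting at 10600 misses [7600, 10600)
  expect_equal(ann$genes[2], "")
  expect_equal(ann$category[2], "intergenic")
  # overlaps both an island and a promoter window
  expect_equal(ann$category[3], "both")
  expect_equal(ann$islands[3], "CpG:1")
  expect_equal(ann$category[4], "intergenic")
})

test_that("interval annotation equals the quadratic all-pairs oracle", {
  set.seed(88)
  n <- 100
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample(0:50000, n))
  peaks$end <- peaks$start + sample(50:2000, n, TRUE)
  tx <- data.frame(name = paste0("NM_", 1:n), gene = paste0("G", 1:n),
                   chrom = sample(c("chr1", "chr2"), n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE),
                   tx_start = sample(0:50000, n))
  tx$tx_end <- tx$tx_start + sample(500:5000, n, TRUE)
  ann <- annotate_peaks(peaks, tx, NULL)
  prom <- promoter_window(tx)
  for (i in seq_len(n)) {
    hit <- prom$chrom == peaks$chrom[i] &
      prom$start < peaks$end[i] & peaks$start[i] < prom$end
    want <- paste(sort(unique(prom$gene[hit])), collapse = ";")
    expect_equal(ann$genes[i], want)
  }
})

test_that("synthetic designs yield self-consistent annotation tables", {
  cfg <- sim_config(n_regions = 12, seed = 6)
  d <- generate_array_design(cfg)
  ann <- design_to_annotation(d)
  expect_equal(nrow(ann$transcripts), sum(d$regions$kind == "promoter"))
  expect_equal(nrow(ann$islands), sum(d$regions$kind == "cpg_island"))
  # every promoter region's probes annotate back to its own gene
  prom_reg <- d$regions$region_id[d$regions$kind == "promoter"][1]
  pk <- d$probes[d$probes$region_id == prom_reg, ][1, c("chrom", "start", "end")]
  out <- annotate_peaks(pk, ann$transcripts, ann$islands)
  expect_match(out$genes, toupper(prom_reg), fixed = TRUE)
})
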