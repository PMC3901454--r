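# Independent oracles and fixture builders shared across tests.

# Build a probe_design directly (bypassing the generator) from region sizes.
# extra_gap_after: global probe indices after which an extra bp gap is added.
toy_design <- function(region_sizes, spacing = 100L, probe_length = 50L,
                       extra_gap_after = integer(), extra_gap = 1000L) {
  probes <- NULL
  pos <- 0L
  global <- 0L
  for (r in seq_along(region_sizes)) {
    n <- region_sizes[r]
    rid <- sprintf("r%02d", r)
    for (i in seq_len(n)) {
      global <- global + 1L
      probes <- rbind(probes, data.frame(
        probe_id = sprintf("%s_p%02d", rid, i - 1L), chrom = "chr1",
        start = pos, end = pos + probe_length, region_id = rid,
        index_in_region = i - 1L, stringsAsFactors = FALSE))
      pos <- pos + spacing
      if (global %in% extra_gap_after) pos <- pos + extra_gap
    }
    pos <- pos + 5000L
  }
  regions <- do.call(rbind, lapply(split(probes, probes$region_id), function(g)
    data.frame(region_id = g$region_id[1], chrom = "chr1",
               start = min(g$start), end = max(g$end), kind = NA_character_,
               stringsAsFactors = FALSE)))
  regions <- regions[order(regions$region_id), ]
  structure(list(probes = probes, regions = regions), class = "probe_design")
}

# A normalized array_sample with prescribed log2 ratios.
ratio_sample <- function(ratios, sample_id = "S", group = "g") {
  array_sample(sample_id, group, mira_raw = 2^as.numeric(ratios),
               input_raw = rep(1, length(ratios)),
               log2_ratio = as.numeric(ratios), normalized = TRUE)
}

# --- exhaustive peak-calling oracle ----------------------------------------
# Valid interval: boundary probes positive; interior negatives are isolated
# (no two adjacent) and number at most max_gaps; >= min_positive positives.
oracle_valid_intervals <- function(f, min_positive, max_gaps) {
  n <- length(f)
  res <- list()
  for (a in seq_len(n)) {
    if (!f[a]) next
    for (b in a:n) {
      if (!f[b]) next
      interior <- if (b > a + 1L) f[(a + 1L):(b - 1L)] else logical(0)
      negs <- which(!interior)
      if (length(negs) > max_gaps) next
      if (length(negs) > 1L && any(diff(negs) == 1L)) next
      if (sum(f[a:b]) < min_positive) next
      res[[length(res) + 1L]] <- c(a, b)
    }
  }
  res
}

# Leftmost-start, then longest, with overlap suppression, within one segment.
oracle_segment_peaks <- function(f, min_positive, max_gaps) {
  iv <- oracle_valid_intervals(f, min_positive, max_gaps)
  out <- NULL
  while (length(iv)) {
    starts <- vapply(iv, `[`, integer(1), 1L)
    ends <- vapply(iv, `[`, integer(1), 2L)
    pick <- which(starts == min(starts))
    pick <- pick[which.max(ends[pick])]
    sel <- iv[[pick]]
    out <- rbind(out, sel)
    keep <- ends < sel[1] | starts > sel[2]
    iv <- iv[keep]
  }
  out
}

# Full oracle over a design: split by region and by bp spacing, then apply
# the exhaustive segment oracle. Returns a matrix of global (first, last)
# probe indices, ordered.
oracle_call_peaks <- function(design, flags, min_positive = 4L,
                              max_gaps = 1L, max_spacing = 500L) {
  probes <- design$probes
  out <- NULL
  for (rid in unique(probes$region_id)) {
    idx <- which(probes$region_id == rid)
    segs <- list(idx[1])
    for (k in seq_along(idx)[-1]) {
      if (probes$start[idx[k]] - probes$end[idx[k - 1L]] > max_spacing)
        segs[[length(segs) + 1L]] <- integer(0)
      segs[[length(segs)]] <- c(segs[[length(segs)]], idx[k])
    }
    for (seg in segs) {
      if (!length(seg)) next
      m <- oracle_segment_peaks(flags[seg], min_positive, max_gaps)
      if (!is.null(m))
        out <- rbind(out, cbind(seg[m[, 1]], seg[m[, 2]]))
    }
  }
  if (!is.null(out)) out <- out[order(out[, 1]), , drop = FALSE]
  out
}

# 99% binomial interval for an observed proportion of n draws at rate p.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p) / n

# Amplicon with exactly n CpGs and no incidental CG at block junctions.
blocked_amplicon <- function(name, n_cpg) {
  amplicon(name, paste(rep("AACGTT", n_cpg), collapse = ""))
}
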