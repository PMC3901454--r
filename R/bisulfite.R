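#' Construct a bisulfite PCR amplicon
#'
#' Represents the genomic top strand of a bisulfite PCR target. CpG
#' positions (0-based index of each CpG's cytosine) and restriction sites
#' are located from the sequence itself.
#'
#' @param name Amplicon name (typically a gene symbol).
#' @param sequence DNA string over A/C/G/T.
#' @param enzyme_motif Restriction motif scanned for `enzyme_sites`
#'   (default TaqalphaI, TCGA).
#' @return An object of class `amplicon`: list with `name`, `sequence`,
#'   `cpg_positions` (0-based), `enzyme_sites` (data.frame `position,
#'   motif`, 0-based).
#' @examples
#' amp <- amplicon("toy", "AATTCGATTACGT")
#' amp$cpg_positions
#' @export
amplicon <- function(name, sequence, enzyme_motif = "TCGA") {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence))
    stop("amplicon sequence must be over A/C/G/T only")
  cpg <- find_motif(sequence, "CG")
  sites <- find_motif(sequence, enzyme_motif)
  structure(list(name = as.character(name), sequence = sequence,
                 cpg_positions = cpg,
                 enzyme_sites = data.frame(position = sites,
                                           motif = rep(enzyme_motif,
                                                       length(sites)),
                                           stringsAsFactors = FALSE)),
            class = "amplicon")
}

# 0-based start positions of every (possibly overlapping) motif occurrence
find_motif <- function(sequence, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
  as.integer(BiocGenerics::start(hits)) - 1L
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon '%s': %d bp, %d CpGs, %d %s site(s)\n",
              x$name, nchar(x$sequence), length(x$cpg_positions),
              nrow(x$enzyme_sites),
              if (nrow(x$enzyme_sites)) x$enzyme_sites$motif[1] else "enzyme"))
  invisible(x)
}

#' In-silico bisulfite conversion
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as
#' thymine after PCR) while 5-methylcytosine resists. Every C of the input
#' not listed in `methylated_positions` becomes T with probability
#' `conversion_rate` (deterministically at 1.0); methylated Cs and all
#' other bases are unchanged. Methylation is only defined at CpG
#' cytosines, so `methylated_positions` must be a subset of them.
#'
#' @param sequence DNA string.
#' @param methylated_positions Integer set of 0-based CpG C positions that
#'   are methylated.
#' @param conversion_rate Per-cytosine conversion success probability.
#' @param seed Optional seed for the stochastic conversion failures.
#' @return The converted DNA string.
#' @examples
#' bisulfite_convert("ACGTCGT", methylated_positions = 1)  # "ACGTTGT"
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer(),
                              conversion_rate = 1.0, seed = NULL) {
  sequence <- toupper(as.character(sequence))
  if (conversion_rate < 0 || conversion_rate > 1)
    stop("conversion_rate must lie in [0, 1]")
  cpg <- find_motif(sequence, "CG")
  methylated_positions <- as.integer(methylated_positions)
  if (length(methylated_positions) && !all(methylated_positions %in% cpg))
    stop("methylated position(s) not at a CpG cytosine: ",
         paste(setdiff(methylated_positions, cpg), collapse = ", "))
  chars <- strsplit(sequence, "")[[1]]
  target <- which(chars == "C")            # 1-based
  target <- setdiff(target, methylated_positions + 1L)
  if (length(target)) {
    if (conversion_rate >= 1) {
      chars[target] <- "T"
    } else if (conversion_rate > 0) {
      if (!is.null(seed)) set.seed(seed)
      conv <- stats::runif(length(target)) < conversion_rate
      chars[target[conv]] <- "T"
    }
  }
  paste(chars, collapse = "")
}

#' COBRA restriction-site analysis of an amplicon
#'
#' COBRA (combined bisulfite restriction analysis) scores methylation by
#' whether a CpG-containing restriction site survives bisulfite conversion:
#' an unmethylated TCGA converts to TTGA and is no longer cleavable, while
#' a methylated site is retained and cut. For each motif occurrence the
#' report states the CpG it depends on and whether it is retained under the
#' given methylation state; expected fragment-length tables are produced
#' for the fully-methylated digest (cut at every site) and the
#' fully-unmethylated case (uncut: one full-length fragment), plus the
#' observed state when `methylated_positions` is supplied. Cuts fall at the
#' T/C boundary of the motif. Fragment lengths always sum to the amplicon
#' length.
#'
#' @param amplicon An [amplicon()].
#' @param enzyme_motif Restriction motif; must contain exactly one CpG
#'   (otherwise retention would not report methylation).
#' @param methylated_positions Optional 0-based methylated CpG positions
#'   defining an observed methylation state.
#' @return An object of class `cobra_report`: list with `sites`
#'   (data.frame `position, cpg_position, retained`), `fragments_methylated`,
#'   `fragments_unmethylated`, and `fragments_observed` (NULL unless a
#'   state was given); all lengths in bp.
#' @export
cobra_site_analysis <- function(amplicon, enzyme_motif = "TCGA",
                                methylated_positions = NULL) {
  stopifnot(inherits(amplicon, "amplicon"))
  cg_in_motif <- find_motif(enzyme_motif, "CG")
  if (length(cg_in_motif) != 1L)
    stop("enzyme motif '", enzyme_motif,
         "' must contain exactly one CpG for methylation-dependent COBRA")
  len <- nchar(amplicon$sequence)
  pos <- find_motif(amplicon$sequence, enzyme_motif)
  cpg_pos <- pos + cg_in_motif
  retained <- if (is.null(methylated_positions)) rep(NA, length(pos)) else
    cpg_pos %in% as.integer(methylated_positions)

  frag <- function(cut_sites) {
    # cut at the CpG boundary inside each retained site
    cuts <- sort(unique(cut_sites + cg_in_motif))
    cuts <- cuts[cuts > 0 & cuts < len]
    diff(c(0L, cuts, len))
  }
  structure(list(
    amplicon_name = amplicon$name,
    enzyme_motif = enzyme_motif,
    sites = data.frame(position = pos, cpg_position = cpg_pos,
                       retained = retained),
    fragments_methylated = frag(pos),
    fragments_unmethylated = len,
    fragments_observed = if (is.null(methylated_positions)) NULL else
      frag(pos[retained])
  ), class = "cobra_report")
}

#' @export
print.cobra_report <- function(x, ...) {
  cat(sprintf("COBRA report for '%s' (%s): %d site(s)\n", x$amplicon_name,
              x$enzyme_motif, nrow(x$sites)))
  if (nrow(x$sites)) print(x$sites)
  cat("fully methylated digest fragments:",
      paste(x$fragments_methylated, collapse = ", "), "bp\n")
  cat("fully unmethylated: uncut,", x$fragments_unmethylated, "bp\n")
  if (!is.null(x$fragments_observed))
    cat("observed state fragments:",
        paste(x$fragments_observed, collapse = ", "), "bp\n")
  invisible(x)
}

#' Simulate bisulfite sequencing clones
#'
#' Each clone independently draws a methylation state at every CpG
#' (Bernoulli with that CpG's probability), then undergoes in-silico
#' bisulfite conversion with failure rate `1 - config$conversion_rate` at
#' unmethylated cytosines — emulating randomly picked, individually
#' sequenced clones of a bisulfite PCR product.
#'
#' @param amplicon An [amplicon()].
#' @param per_cpg_prob Methylation probability per CpG (length = CpG
#'   count, values in \[0, 1\]).
#' @param n_clones Number of clones.
#' @param config A [sim_config()] (supplies `conversion_rate` and `seed`).
#' @param group Label salting the stage seed so groups draw independently.
#' @return List with `reads` (named character vector of clone sequences)
#'   and `truth` (logical matrix, clones x CpGs).
#' @export
simulate_bisulfite_clones <- function(amplicon, per_cpg_prob, n_clones,
                                      config, group = "clones") {
  stopifnot(inherits(amplicon, "amplicon"))
  validate_sim_config(config)
  n_cpg <- length(amplicon$cpg_positions)
  if (length(per_cpg_prob) == 1L) per_cpg_prob <- rep(per_cpg_prob, n_cpg)
  if (length(per_cpg_prob) != n_cpg)
    stop("per_cpg_prob length (", length(per_cpg_prob),
         ") must equal the amplicon CpG count (", n_cpg, ")")
  if (any(per_cpg_prob < 0 | per_cpg_prob > 1))
    stop("configuration error: per_cpg_prob values must lie in [0, 1]")
  set.seed(split_seed(config$seed, paste0("bisulfite:", group)))
  truth <- matrix(stats::runif(n_clones * n_cpg) <
                    rep(per_cpg_prob, each = n_clones),
                  nrow = n_clones)
  reads <- vapply(seq_len(n_clones), function(i) {
    bisulfite_convert(amplicon$sequence,
                      methylated_positions = amplicon$cpg_positions[truth[i, ]],
                      conversion_rate = config$conversion_rate)
  }, character(1))
  names(reads) <- sprintf("%s_clone_%03d", amplicon$name, seq_len(n_clones))
  rownames(truth) <- names(reads)
  list(reads = reads, truth = truth)
}

#' Align a clone read to its amplicon and call CpG methylation
#'
#' Clones are PCR products of a fixed amplicon, so a gapless, full-length
#' alignment against the genomic reference frame suffices; the reverse
#' complement is tried automatically and the better orientation kept. At
#' each CpG cytosine, C is called methylated, T unmethylated, anything else
#' missing. Conversion efficiency is the fraction of non-CpG cytosine
#' positions read as T (C/T positions only). Mismatches at positions not
#' explainable by C-to-T conversion count against alignment quality; if
#' neither orientation's unexplained-mismatch fraction is within
#' `max_mismatch_frac`, the clone is rejected with an error naming it.
#'
#' @param clone_read DNA string, same length as the amplicon.
#' @param amplicon An [amplicon()].
#' @param clone_id Identifier used in the returned call and in errors.
#' @param max_mismatch_frac Maximum tolerated unexplained-mismatch
#'   fraction.
#' @return An object of class `clone_call`: list with `clone_id`,
#'   `per_cpg` (factor vector over methylated/unmethylated/missing),
#'   `conversion_efficiency`, `mismatch_frac`, `orientation`, `pass_qc`
#'   (alignment QC; combined with the conversion filter by [clone_qc()]).
#' @export
align_and_call_clone <- function(clone_read, amplicon,
                                 clone_id = "clone",
                                 max_mismatch_frac = 0.1) {
  stopifnot(inherits(amplicon, "amplicon"))
  clone_read <- toupper(as.character(clone_read))
  ref <- strsplit(amplicon$sequence, "")[[1]]
  if (nchar(clone_read) != length(ref))
    stop("clone '", clone_id, "' length (", nchar(clone_read),
         ") differs from amplicon length (", length(ref),
         "); gapless alignment impossible")

  score <- function(read_chars) {
    mismatch <- read_chars != ref
    explained <- ref == "C" & read_chars == "T"
    sum(mismatch & !explained) / length(ref)
  }
  fwd <- strsplit(clone_read, "")[[1]]
  rev <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(clone_read))),
    "")[[1]]
  sf <- score(fwd); sr <- score(rev)
  if (min(sf, sr) > max_mismatch_frac)
    stop("clone '", clone_id, "' does not align to amplicon '",
         amplicon$name, "' in either orientation (best mismatch fraction ",
         sprintf("%.3f", min(sf, sr)), ")")
  chars <- if (sf <= sr) fwd else rev
  orientation <- if (sf <= sr) "forward" else "reverse"
  mm <- min(sf, sr)

  cpg_i <- amplicon$cpg_positions + 1L
  base <- chars[cpg_i]
  per_cpg <- ifelse(base == "C", "methylated",
             ifelse(base == "T", "unmethylated", "missing"))
  non_cpg_c <- setdiff(which(ref == "C"), cpg_i)
  obs <- chars[non_cpg_c]
  informative <- obs %in% c("C", "T")
  conv_eff <- if (any(informative))
    sum(obs[informative] == "T") / sum(informative) else NA_real_

  structure(list(clone_id = clone_id,
                 per_cpg = per_cpg,
                 conversion_efficiency = conv_eff,
                 mismatch_frac = mm,
                 orientation = orientation,
                 pass_qc = TRUE),
            class = "clone_call")
}

#' Conversion-efficiency QC for a clone call
#'
#' Passes a clone iff its alignment QC held and its bisulfite conversion
#' efficiency reaches `min_conversion`. The motivating analyses applied no
#' conversion filter, so set `min_conversion = 0` (or use
#' `qc_only = FALSE` downstream) when reproducing unfiltered figures.
#'
#' @param call A `clone_call`.
#' @param min_conversion Minimum conversion efficiency in \[0, 1\].
#' @return Logical pass flag (also stored back into the call by
#'   [methylation_matrix()]).
#' @export
clone_qc <- function(call, min_conversion = 0.95) {
  stopifnot(inherits(call, "clone_call"))
  isTRUE(call$pass_qc) &&
    (is.na(call$conversion_efficiency) ||
       call$conversion_efficiency >= min_conversion)
}

#' Assemble clone calls into a methylation matrix
#'
#' @param amplicon An [amplicon()].
#' @param clone_calls List of `clone_call`s for this amplicon.
#' @param min_conversion Conversion QC threshold applied to each clone
#'   (stored in each call's `pass_qc`).
#' @return An object of class `methylation_matrix`: list with `amplicon`,
#'   `clones` (list of calls with `pass_qc` updated), `calls` (character
#'   matrix clones x CpGs) and `percent_methylated` (over all clones,
#'   missing excluded — the unfiltered figure).
#' @export
methylation_matrix <- function(amplicon, clone_calls,
                               min_conversion = 0.95) {
  stopifnot(inherits(amplicon, "amplicon"))
  n_cpg <- length(amplicon$cpg_positions)
  for (i in seq_along(clone_calls)) {
    stopifnot(inherits(clone_calls[[i]], "clone_call"))
    if (length(clone_calls[[i]]$per_cpg) != n_cpg)
      stop("clone call CpG count mismatch for ", clone_calls[[i]]$clone_id)
    clone_calls[[i]]$pass_qc <- clone_qc(clone_calls[[i]], min_conversion)
  }
  calls <- do.call(rbind, lapply(clone_calls, function(c) c$per_cpg))
  if (is.null(calls)) calls <- matrix(character(), ncol = n_cpg)
  rownames(calls) <- vapply(clone_calls, function(c) c$clone_id, character(1))
  mm <- structure(list(amplicon = amplicon, clones = clone_calls,
                       calls = calls, percent_methylated = NA_real_),
                  class = "methylation_matrix")
  if (length(clone_calls))
    mm$percent_methylated <- percent_methylation(mm, qc_only = FALSE)
  mm
}

#' Percent methylation of a clone set
#'
#' `100 * methylated / (methylated + unmethylated)` over the included
#' clones' CpG calls; missing calls are excluded. With `qc_only = TRUE`
#' only clones passing [clone_qc()] contribute.
#'
#' @param matrix A `methylation_matrix`.
#' @param qc_only Restrict to QC-passing clones.
#' @return Percentage in \[0, 100\].
#' @export
percent_methylation <- function(matrix, qc_only = TRUE) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  keep <- if (qc_only)
    vapply(matrix$clones, function(c) isTRUE(c$pass_qc), logical(1))
  else rep(TRUE, length(matrix$clones))
  if (!any(keep)) stop("no clones included (all failed QC or empty set)")
  calls <- matrix$calls[keep, , drop = FALSE]
  n_meth <- sum(calls == "methylated")
  n_unmeth <- sum(calls == "unmethylated")
  if (n_meth + n_unmeth == 0L)
    stop("zero callable CpG sites among included clones")
  100 * n_meth / (n_meth + n_unmeth)
}

#' Render a lollipop diagram of a methylation matrix
#'
#' One text row per clone, one column per CpG in genomic order: filled
#' circle = methylated, open circle = unmethylated, middle dot = missing.
#' The unfiltered percent methylation is printed below.
#'
#' @param matrix A `methylation_matrix`.
#' @param glyphs Named character vector mapping the three call states to
#'   glyphs.
#' @return Character vector of diagram lines (class `lollipop`), printed
#'   with [cat()] by its print method.
#' @export
render_lollipop <- function(matrix,
                            glyphs = c(methylated = "●",
                                       unmethylated = "○",
                                       missing = "·")) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  header <- sprintf("%s (%d CpGs)", matrix$amplicon$name,
                    length(matrix$amplicon$cpg_positions))
  if (length(matrix$clones) == 0L)
    return(structure(c(header, "no clones"), class = "lollipop"))
  rows <- vapply(seq_along(matrix$clones), function(i) {
    paste0(format(matrix$clones[[i]]$clone_id, width = 22), " ",
           paste(glyphs[matrix$calls[i, ]], collapse = ""))
  }, character(1))
  pct <- percent_methylation(matrix, qc_only = FALSE)
  structure(c(header, rows, sprintf("%.1f%% methylated", pct)),
            class = "lollipop")
}

#' @export
print.lollipop <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}

#' Plot a lollipop diagram
#'
#' Base-graphics rendering of a `methylation_matrix`: CpGs at their
#' genomic offsets on the x axis, clones stacked on the y axis; filled
#' points methylated, open points unmethylated.
#'
#' @param x A `methylation_matrix`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.methylation_matrix <- function(x, ...) {
  n_clone <- length(x$clones)
  if (n_clone == 0L) stop("no clones to plot")
  pos <- x$amplicon$cpg_positions
  graphics::plot(NA, xlim = range(pos), ylim = c(0.5, n_clone + 0.5),
                 xlab = "position in amplicon (bp)", ylab = "clone",
                 yaxt = "n", main = x$amplicon$name, ...)
  graphics::axis(2, at = seq_len(n_clone),
                 labels = rownames(x$calls), las = 2, cex.axis = 0.6)
  for (i in seq_len(n_clone)) {
    st <- x$calls[i, ]
    graphics::points(pos[st == "unmethylated"],
                     rep(n_clone - i + 1, sum(st == "unmethylated")),
                     pch = 21, bg = "white")
    graphics::points(pos[st == "methylated"],
                     rep(n_clone - i + 1, sum(st == "methylated")),
                     pch = 19)
  }
  invisible(x)
}

#' FASTA I/O for amplicons and clone reads
#'
#' Thin wrappers over Biostrings: `read_amplicon_fasta()` returns a list of
#' [amplicon()]s (one per FASTA record); `read_clone_fasta()` a named
#' character vector of reads; `write_clone_fasta()` writes reads.
#'
#' @param path FASTA path.
#' @param enzyme_motif Passed to [amplicon()].
#' @return See description.
#' @export
read_amplicon_fasta <- function(path, enzyme_motif = "TCGA") {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty amplicon FASTA: ", path)
  out <- lapply(seq_along(seqs), function(i)
    amplicon(names(seqs)[i], as.character(seqs[[i]]), enzyme_motif))
  names(out) <- names(seqs)
  out
}

#' @rdname read_amplicon_fasta
#' @export
read_clone_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  reads <- as.character(seqs)
  names(reads) <- names(seqs)
  reads
}

#' @rdname read_amplicon_fasta
#' @param reads Named character vector of clone reads.
#' @export
write_clone_fasta <- function(reads, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
  invisible(path)
}

#' Generate a random amplicon sequence
#'
#' Uniform random DNA of the requested length (CpGs and TCGA sites occur at
#' their natural base-composition rates), seeded for reproducibility. Used
#' by the simulate mode of the bisulfite pipeline and in tests.
#'
#' @param name Amplicon name.
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @param enzyme_motif Passed to [amplicon()].
#' @return An [amplicon()].
#' @export
random_amplicon <- function(name = "synthetic", length = 400L, seed = 1L,
                            enzyme_motif = "TCGA") {
  set.seed(split_seed(seed, paste0("amplicon:", name)))
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  amplicon(name, seq, enzyme_motif)
}
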