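test_that("bisulfite conversion follows the chemistry exactly at rate 1", {
  expect_equal(bisulfite_convert("ACGTCGT", methylated_positions = 1),
               "ACGTTGT")
  expect_equal(bisulfite_convert("AGGTTAG"), "AGGTTAG")  # no C at all
  expect_equal(bisulfite_convert("ACGTCGT"), "ATGTTGT")  # nothing methylated
  amp <- amplicon("x", "ACGTCGTACG")
  all_meth <- bisulfite_convert(amp$sequence, amp$cpg_positions)
  expect_equal(all_meth, amp$sequence)  # all CpGs retained, no other C here
  expect_error(bisulfite_convert("ACGT", methylated_positions = 2),
               "not at a CpG")
})

test_that("partial conversion hits the binomial interval", {
  set.seed(10)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  out <- bisulfite_convert(seq, conversion_rate = 0.95, seed = 99)
  cs <- strsplit(seq, "")[[1]] == "C"
  converted <- strsplit(out, "")[[1]][cs] == "T"
  ci <- binom99(sum(cs), 0.95)
  expect_gte(mean(converted), ci[1])
  expect_lte(mean(converted), ci[2])
  # deterministic for a fixed seed
  expect_identical(out, bisulfite_convert(seq, conversion_rate = 0.95,
                                          seed = 99))
})

test_that("COBRA finds TaqalphaI sites and fragment lengths sum to amplicon length", {
  amp <- amplicon("toy", "AATTCGATT")
  rep <- cobra_site_analysis(amp)
  expect_equal(rep$sites$position, 3)
  expect_equal(rep$sites$cpg_position, 4)
  expect_equal(sum(rep$fragments_methylated), 9)
  expect_equal(rep$fragments_unmethylated, 9)

  # site retained iff its CpG is methylated
  obs <- cobra_site_analysis(amp, methylated_positions = 4)
  expect_true(obs$sites$retained)
  expect_equal(length(obs$fragments_observed), 2)
  none <- cobra_site_analysis(amp, methylated_positions = integer())
  expect_false(none$sites$retained)
  expect_equal(none$fragments_observed, 9)  # uncut

  no_site <- amplicon("flat", "AAACGAAACGAAA")
  rep0 <- cobra_site_analysis(no_site)
  expect_equal(nrow(rep0$sites), 0)
  expect_equal(rep0$fragments_methylated, 13)

  expect_error(cobra_site_analysis(amp, enzyme_motif = "GATC"),
               "exactly one CpG")
})

test_that("random fully-methylated amplicons split like the string-split oracle", {
  for (seed in 1:10) {
    amp <- random_amplicon("r", 500L, seed = seed)
    rep <- cobra_site_analysis(amp, methylated_positions = amp$cpg_positions)
    n_sites <- nrow(rep$sites)
    expect_true(all(rep$sites$retained))
    expect_equal(sum(rep$fragments_observed), 500)
    # oracle: splitting the sequence at TCGA yields site_count + 1 pieces
    pieces <- strsplit(paste0("x", gsub("TCGA", "T|CGA", amp$sequence,
                                        fixed = TRUE), "x"), "|",
                       fixed = TRUE)[[1]]
    expect_equal(length(rep$fragments_observed), length(pieces))
    expect_equal(length(rep$fragments_observed), n_sites + 1)
  }
})

test_that("clone simulation draws per-CpG Bernoulli states at the set rates", {
  amp <- blocked_amplicon("prob", 38)
  cfg <- sim_config(conversion_rate = 1, seed = 123)
  sim <- simulate_bisulfite_clones(amp, 1.0, 5, cfg)
  for (read in sim$reads) {
    chars <- strsplit(read, "")[[1]]
    expect_true(all(chars[amp$cpg_positions + 1] == "C"))  # CpGs retained
    non_cpg_c <- setdiff(which(strsplit(amp$sequence, "")[[1]] == "C"),
                         amp$cpg_positions + 1)
    expect_true(all(chars[non_cpg_c] == "T"))
  }
  sim0 <- simulate_bisulfite_clones(amp, 0.0, 5, cfg)
  for (read in sim0$reads)
    expect_true(all(strsplit(read, "")[[1]][amp$cpg_positions + 1] == "T"))

  # 50 clones x 38 CpGs at 0.29: the observed fraction lands in the
  # binomial 99% interval
  sim29 <- simulate_bisulfite_clones(amp, 0.29, 50, cfg)
  frac <- mean(sim29$truth)
  ci <- binom99(50 * 38, 0.29)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  expect_error(simulate_bisulfite_clones(amp, 1.2, 5, cfg), "\\[0, 1\\]")
  expect_error(simulate_bisulfite_clones(amp, rep(0.5, 3), 5, cfg),
               "CpG count")
})

test_that("clone calling round-trips known methylation states", {
  amp <- random_amplicon("rt", 300L, seed = 4)
  all_meth <- bisulfite_convert(amp$sequence, amp$cpg_positions)
  call <- align_and_call_clone(all_meth, amp, "c1")
  expect_true(all(call$per_cpg == "methylated"))
  expect_equal(call$conversion_efficiency, 1.0)
  expect_equal(call$orientation, "forward")

  none <- bisulfite_convert(amp$sequence)
  call0 <- align_and_call_clone(none, amp, "c0")
  expect_true(all(call0$per_cpg == "unmethylated"))

  # reverse-complemented reads are recognised automatically
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(all_meth)))
  call_rc <- align_and_call_clone(rc, amp, "crc")
  expect_equal(call_rc$orientation, "reverse")
  expect_true(all(call_rc$per_cpg == "methylated"))

  # simulated clones with known truth are recovered at every CpG
  cfg <- sim_config(conversion_rate = 1, seed = 55)
  sim <- simulate_bisulfite_clones(amp, 0.5, 50, cfg)
  for (i in seq_along(sim$reads)) {
    call <- align_and_call_clone(sim$reads[[i]], amp, names(sim$reads)[i])
    expect_equal(call$per_cpg == "methylated", unname(sim$truth[i, ]))
  }

  # unrelated sequence in either orientation is rejected by name
  garbage <- paste(rep("A", 300), collapse = "")
  expect_error(align_and_call_clone(garbage, amp, "junk"), "junk")
  expect_error(align_and_call_clone("ACGT", amp, "short"), "length")
})

test_that("conversion QC thresholds behave as documented", {
  call <- structure(list(clone_id = "c", per_cpg = "methylated",
                         conversion_efficiency = 1.0, mismatch_frac = 0,
                         orientation = "forward", pass_qc = TRUE),
                    class = "clone_call")
  expect_true(clone_qc(call))
  call$conversion_efficiency <- 0.90
  expect_false(clone_qc(call))
  expect_true(clone_qc(call, min_conversion = 0))
})

test_that("percent methylation counts calls, ignores missing, respects QC and order", {
  amp <- blocked_amplicon("pm", 5)
  mk_call <- function(id, states, eff = 1) {
    structure(list(clone_id = id, per_cpg = states,
                   conversion_efficiency = eff, mismatch_frac = 0,
                   orientation = "forward", pass_qc = TRUE),
              class = "clone_call")
  }
  calls <- list(
    mk_call("a", c("methylated", "methylated", "methylated",
                   "unmethylated", "unmethylated")),
    mk_call("b", c("methylated", "methylated", "unmethylated",
                   "unmethylated", "missing")),
    mk_call("c", c("methylated", "unmethylated", "unmethylated",
                   "unmethylated", "unmethylated")))
  mm <- methylation_matrix(amp, calls)
  # 6 methylated of 14 callable (one missing): 3 clones x 5 CpGs
  expect_equal(percent_methylation(mm), 100 * 6 / 14)
  expect_equal(mm$percent_methylated, 100 * 6 / 14)

  # invariant to clone order and duplication of the full set
  mm_rev <- methylation_matrix(amp, rev(calls))
  expect_equal(percent_methylation(mm_rev), percent_methylation(mm))
  mm_dup <- methylation_matrix(amp, c(calls, calls))
  expect_equal(percent_methylation(mm_dup), percent_methylation(mm))

  # all-methylated clone set: 100
  all_m <- methylation_matrix(amp, list(mk_call("z", rep("methylated", 5))))
  expect_equal(percent_methylation(all_m), 100)

  # QC-failing clones drop out under qc_only
  calls_qc <- c(calls, list(mk_call("bad", rep("methylated", 5), eff = 0.5)))
  mm_qc <- methylation_matrix(amp, calls_qc)
  expect_equal(percent_methylation(mm_qc, qc_only = TRUE), 100 * 6 / 14)
  expect_gt(percent_methylation(mm_qc, qc_only = FALSE), 100 * 6 / 14)
})

test_that("lollipop rendering maps every call to one glyph", {
  amp <- blocked_amplicon("lp", 2)
  call <- structure(list(clone_id = "c1",
                         per_cpg = c("methylated", "unmethylated"),
                         conversion_efficiency = 1, mismatch_frac = 0,
                         orientation = "forward", pass_qc = TRUE),
                    class = "clone_call")
  mm <- methylation_matrix(amp, list(call))
  lines <- render_lollipop(mm)
  expect_match(lines[2], "●○")
  expect_match(lines[length(lines)], "50.0% methylated")

  empty <- methylation_matrix(amp, list())
  expect_match(render_lollipop(empty)[2], "no clones")

  # glyph counts equal call counts on a random matrix
  cfg <- sim_config(conversion_rate = 1, seed = 9)
  sim <- simulate_bisulfite_clones(amp, 0.5, 20, cfg)
  calls <- lapply(seq_along(sim$reads), function(i)
    align_and_call_clone(sim$reads[[i]], amp, names(sim$reads)[i]))
  mmr <- methylation_matrix(amp, calls)
  body <- render_lollipop(mmr)[2:21]
  n_filled <- sum(vapply(strsplit(body, ""), function(x)
    sum(x == "●"), integer(1)))
  expect_equal(n_filled, sum(mmr$calls == "methylated"))
})

test_that("amplicons and clone reads round-trip through FASTA", {
  td <- withr::local_tempdir()
  amp <- random_amplicon("fa_test", 200L, seed = 2)
  writeLines(c(">fa_test", amp$sequence), file.path(td, "amp.fa"))
  back <- read_amplicon_fasta(file.path(td, "amp.fa"))
  expect_equal(back$fa_test$sequence, amp$sequence)
  expect_equal(back$fa_test$cpg_positions, amp$cpg_positions)

  reads <- c(clone_a = bisulfite_convert(amp$sequence),
             clone_b = bisulfite_convert(amp$sequence, amp$cpg_positions))
  write_clone_fasta(reads, file.path(td, "clones.fa"))
  back_reads <- read_clone_fasta(file.path(td, "clones.fa"))
  expect_equal(back_reads, reads)
})
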