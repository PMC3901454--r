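test_that("array design tiles regions arithmetically and reproducibly", {
  cfg <- sim_config(n_regions = 1, probes_per_region = 5, probe_spacing = 100,
                    probe_length = 50, region_gap = 1000, seed = 7)
  d <- generate_array_design(cfg)
  expect_equal(d$probes$start, c(1000, 1100, 1200, 1300, 1400))
  expect_equal(d$probes$end, d$probes$start + 50)
  expect_equal(d$probes$index_in_region, 0:4)

  cfg <- sim_config(n_regions = 10, probes_per_region = c(8, 12), seed = 7)
  d1 <- generate_array_design(cfg)
  d2 <- generate_array_design(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$regions), 10)
  expect_true(nrow(d1$probes) >= 80 && nrow(d1$probes) <= 120)
  expect_setequal(unique(d1$regions$kind), c("cpg_island", "promoter"))
  d3 <- generate_array_design(sim_config(n_regions = 10,
                                         probes_per_region = c(8, 12),
                                         seed = 8))
  expect_false(identical(d1$probes, d3$probes))

  expect_error(sim_config(n_regions = 0), "positive")
})

test_that("design probes are sorted, non-overlapping and consistently indexed", {
  d <- generate_array_design(sim_config(n_regions = 120, seed = 3))
  expect_true(all(d$probes$start < d$probes$end))
  for (g in split(d$probes, d$probes$region_id)) {
    expect_equal(g$index_in_region, seq_len(nrow(g)) - 1L)
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] >= g$end[-nrow(g)])) # non-overlapping, sorted
  }
  expect_true(all(d$probes$region_id %in% d$regions$region_id))
  for (ch in split(d$regions, d$regions$chrom))
    expect_true(!is.unsorted(ch$start))
})

test_that("truth methylome respects density, span and differential counts", {
  d <- generate_array_design(sim_config(n_regions = 20, seed = 5))
  t0 <- simulate_truth_methylome(d, sim_config(n_regions = 20,
                                               peak_density = 0,
                                               n_differential = 0, seed = 5))
  expect_equal(nrow(t0$peaks), 0)

  t1 <- simulate_truth_methylome(d, sim_config(n_regions = 20,
                                               peak_density = 1,
                                               n_differential = 0, seed = 5))
  expect_equal(nrow(t1$peaks), 20)

  # binomial oracle on the peak count at density 0.5
  cfg <- sim_config(n_regions = 1000, peak_density = 0.5,
                    n_differential = 0, seed = 11)
  dd <- generate_array_design(cfg)
  tt <- simulate_truth_methylome(dd, cfg)
  ci <- binom99(1000, 0.5) * 1000
  expect_gte(nrow(tt$peaks), ci[1])
  expect_lte(nrow(tt$peaks), ci[2])

  # differential bookkeeping and span invariants
  cfg <- sim_config(n_regions = 50, n_differential = 8, seed = 2)
  d8 <- generate_array_design(cfg)
  t8 <- simulate_truth_methylome(d8, cfg)
  expect_equal(nrow(t8$differential), 8)
  expect_equal(sum(t8$differential$direction == "hyper"), 4)
  expect_equal(sum(t8$differential$direction == "hypo"), 4)
  expect_true(all(t8$peaks$last_index - t8$peaks$first_index + 1 >=
                    cfg$min_peak_span))
  hyper <- t8$differential[t8$differential$direction == "hyper", ]
  hypo <- t8$differential[t8$differential$direction == "hypo", ]
  expect_true(all(t8$peaks$group[match(hyper$peak_id, t8$peaks$peak_id)] ==
                    "treated"))
  expect_true(all(t8$peaks$group[match(hypo$peak_id, t8$peaks$peak_id)] ==
                    "control"))
})

test_that("noise-free intensities conserve the injected signal exactly", {
  cfg <- sim_config(n_regions = 12, noise_sd = 0, dye_bias = c(0, 0, 0),
                    effect_mean = 2, peak_density = 0.5, n_differential = 0,
                    seed = 9)
  d <- generate_array_design(cfg)
  tr <- simulate_truth_methylome(d, cfg)
  s <- simulate_sample_intensities(d, tr, "control", cfg)
  eff <- truth_effect_vector(d, tr, "control")
  expect_equal(ma_values(s)$M, eff, tolerance = 1e-12)
  expect_true(all(s$mira_raw > 0) && all(s$input_raw > 0))

  # constant additive dye bias appears verbatim in the raw ratio
  cfgb <- sim_config(n_regions = 12, noise_sd = 0, dye_bias = c(0.5, 0, 0),
                     peak_density = 0, n_differential = 0, seed = 9)
  tb <- simulate_truth_methylome(d, cfgb)
  sb <- simulate_sample_intensities(d, tb, "control", cfgb)
  expect_equal(ma_values(sb)$M, rep(0.5, nrow(d$probes)), tolerance = 1e-12)
})

test_that("off-peak mean raw ratio obeys the CLT bound around the bias", {
  cfg <- sim_config(n_regions = 1000, probes_per_region = 10,
                    noise_sd = 0.3, dye_bias = c(0.7, 0, 0),
                    peak_density = 0, n_differential = 0, seed = 21)
  d <- generate_array_design(cfg)
  tr <- simulate_truth_methylome(d, cfg)
  s <- simulate_sample_intensities(d, tr, "control", cfg)
  m <- ma_values(s)$M
  expect_gte(length(m), 10000)
  expect_lt(abs(mean(m) - 0.7), 3 * 0.3 / sqrt(length(m)))
})

test_that("identical config and seed reproduce samples bit for bit", {
  cfg <- sim_config(n_regions = 15, n_differential = 0, seed = 13)
  ex1 <- simulate_experiment(cfg, n_control = 2, n_treated = 1)
  ex2 <- simulate_experiment(cfg, n_control = 2, n_treated = 1)
  expect_identical(ex1, ex2)
  # replicates share truth but differ in noise
  expect_false(identical(ex1$samples$CON1$mira_raw, ex1$samples$CON2$mira_raw))
})

test_that("design and intensity tables round-trip through TSV", {
  cfg <- sim_config(n_regions = 6, n_differential = 0, seed = 4)
  ex <- simulate_experiment(cfg, n_control = 1, n_treated = 0)
  td <- withr::local_tempdir()
  write_design(ex$design, file.path(td, "reg.bed"), file.path(td, "probes.tsv"))
  d2 <- read_design(file.path(td, "probes.tsv"))
  expect_equal(d2$probes$start, ex$design$probes$start)
  expect_equal(d2$probes$index_in_region, ex$design$probes$index_in_region)

  write_intensities(ex$samples$CON1, ex$design, file.path(td, "int.tsv"))
  s2 <- read_intensities(file.path(td, "int.tsv"), "CON1", "control")
  expect_equal(s2$mira_raw, ex$samples$CON1$mira_raw)
  expect_false(s2$normalized)
})
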