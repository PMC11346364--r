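# The synthetic-data generator: determinism, calibration, injected truth.

test_that("a fixed seed gives byte-identical simulated files", {
  cfg <- sim_config(seed = 9, n_contigs = 1, contig_length = 1e5,
                    n_genes = 3,
                    peaks = data.frame(contig = "ctg1", start = 3e4,
                                       length = 1e4, pi_multiplier = 20,
                                       shared_with_b = FALSE,
                                       balanced = FALSE))
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("simulated GC fraction is within 3 binomial SDs of the target", {
  cfg <- sim_config(seed = 21, n_contigs = 1, contig_length = 5e5,
                    n_genes = 0, gc = 0.41)
  ref <- simulate_genome(cfg)$reference
  gc_obs <- sum(Biostrings::letterFrequency(ref$sequences, c("G", "C"))) /
    ref$total_length
  tol <- 3 * sqrt(0.41 * 0.59 / 5e5)
  expect_lt(abs(gc_obs - 0.41), tol)
})

test_that("gene models are well-formed CDS chains of the configured length", {
  cfg <- sim_config(seed = 2, n_contigs = 1, contig_length = 2e5,
                    n_genes = 10, gene_length = 900)
  gen <- simulate_genome(cfg)
  expect_equal(nrow(gen$genes$genes), 10)
  expect_true(all(gen$genes$genes$cds_length == 900))
  expect_true(all(gen$genes$genes$n_segments == 2))
  # every simulated gene translates as a clean ORF
  dm <- classify_degeneracy(gen$genes, gen$reference)
  expect_length(dm$excluded_genes, 0)
  expect_equal(nrow(dm$map), 10 * 900)
})

test_that("genes that cannot fit raise a hard error", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_length = 3000,
                    n_genes = 10, gene_length = 900)
  expect_error(simulate_genome(cfg), "do not fit")
})

test_that("realized heterozygosity matches the configured rate", {
  cfg <- sim_config(seed = 31, n_contigs = 1, contig_length = 2e6,
                    n_samples_b = 0, n_genes = 0)
  sim <- simulate_dataset(cfg)
  for (s in c("A1", "A2")) {
    het <- individual_heterozygosity(sim$variants, s,
                                     sim$reference$effective_length)
    expect_lt(abs(het - 3.4e-4) / 3.4e-4, 0.12)   # ~3 Poisson SDs at 2 Mb
  }
})

test_that("doubling theta doubles the expected heterozygous-site count", {
  counts <- vapply(1:20, function(s) {
    vapply(c(3.4e-4, 6.8e-4), function(th) {
      cfg <- sim_config(seed = 100 + s, n_contigs = 1, contig_length = 5e5,
                        theta_background = th, n_samples_b = 0, n_genes = 0)
      sim <- simulate_dataset(cfg)
      sum(sim$variants$geno[, "A1"] == 1L)
    }, numeric(1))
  }, numeric(2))
  ratio <- mean(counts[2, ]) / mean(counts[1, ])
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)
})

test_that("samples are forced homozygous inside their ROH tracts", {
  cfg <- sim_config(seed = 4, n_contigs = 1, contig_length = 1e6,
                    n_genes = 0, n_samples_b = 0,
                    roh_tracts = data.frame(sample = "A1", contig = "ctg1",
                                            start = 2e5, length = 5e5))
  sim <- simulate_dataset(cfg)
  vt <- sim$variants
  inside <- vt$sites$pos > 2e5 & vt$sites$pos <= 7e5
  expect_true(any(inside))
  expect_equal(sum(vt$geno[inside, "A1"] == 1L), 0)
  expect_gt(sum(vt$geno[!inside, "A1"] == 1L), 0)
  expect_gt(sum(vt$geno[inside, "A2"] == 1L), 0)   # tract is per-sample
})

test_that("an injected 20x peak exceeds mean + 4 SD of background windows", {
  cfg <- sim_config(seed = 13, n_contigs = 1, contig_length = 1e6,
                    n_genes = 0, n_samples_b = 0,
                    peaks = data.frame(contig = "ctg1", start = 5e5,
                                       length = 1e4, pi_multiplier = 20,
                                       shared_with_b = FALSE,
                                       balanced = FALSE))
  sim <- simulate_dataset(cfg)
  wt <- window_pi(sim$variants, sim$reference, 1e4,
                  samples = c("A1", "A2"))
  bg <- wt$window != 50L
  expect_gt(wt$pi[wt$window == 50L],
            mean(wt$pi[bg]) + 4 * sd(wt$pi[bg]))
})

test_that("tracks pass filters except at declared artifact windows", {
  cfg <- sim_config(seed = 6, n_contigs = 2, contig_length = 2e5,
                    n_genes = 0, n_samples_b = 0)
  sim <- simulate_dataset(cfg)
  wt <- window_pi(sim$variants, sim$reference, 1e4)
  wt <- filter_windows(wt, sim$tracks$mappability, sim$tracks$coverage)
  expect_true(all(wt$status == "pass"))

  cfg2 <- sim_config(seed = 6, n_contigs = 2, contig_length = 2e5,
                     n_genes = 0, n_samples_b = 0,
                     artifact_windows = data.frame(
                       contig = c("ctg1", "ctg2", "ctg2"),
                       window = c(3L, 5L, 11L),
                       type = c("low_map", "low_cov", "high_cov")))
  sim2 <- simulate_dataset(cfg2)
  wt2 <- window_pi(sim2$variants, sim2$reference, 1e4)
  wt2 <- filter_windows(wt2, sim2$tracks$mappability, sim2$tracks$coverage)
  expect_equal(wt2$status[wt2$contig == "ctg1" & wt2$window == 3L], "fail_map")
  expect_equal(wt2$status[wt2$contig == "ctg2" & wt2$window == 5L],
               "fail_cov_low")
  expect_equal(wt2$status[wt2$contig == "ctg2" & wt2$window == 11L],
               "fail_cov_high")
  expect_equal(sum(wt2$status != "pass"), 3)

  # coverage noise model: clean-window mean near the configured 60x
  clean <- wt2$status == "pass"
  expect_lt(abs(mean(wt2$mean_coverage[clean]) - 60),
            3 * 6 / sqrt(sum(clean)))
})

test_that("injected truth is emitted machine-readably", {
  cfg <- sim_config(seed = 8, n_contigs = 1, contig_length = 2e5,
                    n_genes = 0, n_samples_b = 0,
                    peaks = data.frame(contig = "ctg1", start = 5e4,
                                       length = 2e4, pi_multiplier = 10,
                                       shared_with_b = FALSE,
                                       balanced = FALSE),
                    roh_tracts = data.frame(sample = "A2", contig = "ctg1",
                                            start = 1e5, length = 1e5))
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$peaks$window_first, 5L)
  expect_equal(sim$truth$peaks$window_last, 6L)
  d <- tempfile()
  write_simulation(sim, d)
  tr <- read.table(file.path(d, "truth_peaks.tsv"), header = TRUE)
  expect_equal(tr$window_first, 5L)
  tr2 <- read.table(file.path(d, "truth_roh_tracts.tsv"), header = TRUE)
  expect_equal(tr2$sample, "A2")
})
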