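# Windowed diversity, filtration, peaks, polymorphic genes.

test_that("site_pi equals the mean pairwise difference among haplotypes", {
  expect_equal(site_pi(c(A = 2, T = 2)), 2 / 3, tolerance = 1e-12)  # 4/6 pairs
  expect_equal(site_pi(c(A = 4)), 0)
  expect_equal(site_pi(c(A = 1, T = 3)), 0.5)                       # 3/6 pairs
  expect_equal(site_pi(c(A = 1)), 0)   # n < 2: skipped
})

test_that("window_pi spreads site diversity over the window span", {
  ref <- make_ref(c(c1 = strrep("A", 20000)))
  vt <- make_vt(data.frame(contig = "c1", pos = 5000L, ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
                matrix(c(1L, 1L), 1, 2))   # both diploids het: {2,2} alleles
  wt <- window_pi(vt, ref, 1e4)
  expect_equal(wt$pi[1], (2 / 3) / 1e4, tolerance = 1e-12)
  expect_equal(wt$n_snvs, c(1L, 0L))
  expect_equal(wt$pi[2], 0)

  vt_bad <- make_vt(data.frame(contig = "c1", pos = 25000L, ref = "A",
                               alt = "G", stringsAsFactors = FALSE),
                    matrix(c(1L, 1L), 1, 2))
  expect_error(window_pi(vt_bad, ref, 1e4), "beyond contig end")
})

test_that("window_pi matches the pairwise-Hamming oracle on toy windows", {
  set.seed(33)
  ref <- make_ref(c(c1 = strrep("A", 20 * 1000)))
  vt <- random_vt(300, 3, 20 * 1000, missing_rate = 0.1)
  wt <- window_pi(vt, ref, 1000)
  for (w in 0:19) {
    sel <- window_index(vt$sites$pos, 1000) == w
    expect_equal(wt$pi[wt$window == w],
                 oracle_window_pi(vt$geno[sel, , drop = FALSE], 1000),
                 tolerance = 1e-12, label = paste("window", w))
  }
  expect_equal(sum(wt$n_snvs), nrow(vt$sites))   # no site lost or duplicated
})

test_that("pi is invariant under ref/alt relabeling", {
  set.seed(41)
  ref <- make_ref(c(c1 = strrep("A", 5e4)))
  vt <- random_vt(100, 4, 5e4)
  vt_flip <- vt
  vt_flip$geno <- 2L - vt$geno
  expect_equal(window_pi(vt, ref, 1e4)$pi, window_pi(vt_flip, ref, 1e4)$pi)
})

test_that("individual heterozygosity is het count over effective length", {
  set.seed(51)
  vt <- random_vt(500, 2, 1e6)
  expect_equal(individual_heterozygosity(vt, "S1", 1e6),
               sum(vt$geno[, 1] == 1L, na.rm = TRUE) / 1e6)
  vt0 <- vt
  vt0$geno[, 1] <- 0L
  expect_equal(individual_heterozygosity(vt0, "S1", 1e6), 0)
  # 100 het calls over 1 Mb
  vt100 <- vt
  vt100$geno[, 1] <- rep(c(1L, 0L), c(100L, 400L))
  expect_equal(individual_heterozygosity(vt100, "S1", 1e6), 1e-4)
})

test_that("window filters use strict inequalities at printed thresholds", {
  wt <- data.frame(contig = "c1", start = (0:5) * 1e4, end = (1:6) * 1e4,
                   window = 0:5, span = 1e4, terminal = FALSE,
                   n_snvs = 0L, pi = 0)
  mk_track <- function(v) data.frame(contig = "c1", start = (0:5) * 1e4,
                                     end = (1:6) * 1e4, value = v)
  map <- mk_track(c(0.79, 1.0, 0.9, 0.8, 0.9, 0.9))
  cov <- mk_track(c(60, 100, 401, 40, 400, 39.9))
  out <- filter_windows(wt, map, cov)
  expect_equal(out$status, c("fail_map", "pass", "fail_cov_high", "pass",
                             "pass", "fail_cov_low"))

  # a window missing from the tracks fails conservatively
  out2 <- filter_windows(wt, map[-2, ], cov)
  expect_equal(out2$status[2], "fail_map")
})

test_that("peak detection thresholds on mean + k*SD of passing windows", {
  # constant diversity: SD 0, strict '>' finds nothing
  wt <- data.frame(contig = "c1", start = (0:9) * 1e4, end = (1:10) * 1e4,
                   window = 0:9, span = 1e4, terminal = FALSE, n_snvs = 1L,
                   pi = rep(1e-4, 10), status = "pass")
  expect_equal(nrow(detect_peaks(wt)$windows), 0)

  # 999 background windows plus one outlier
  pi <- c(rep(1e-4, 999), 5e-3)
  wt2 <- data.frame(contig = "c1", start = (0:999) * 1e4,
                    end = (1:1000) * 1e4, window = 0:999, span = 1e4,
                    terminal = FALSE, n_snvs = 1L, pi = pi, status = "pass")
  ps <- detect_peaks(wt2, k = 4)
  expect_equal(ps$threshold, mean(pi) + 4 * sd(pi))   # direct recomputation
  expect_equal(ps$windows$window, 999L)
  expect_equal(nrow(ps$regions), 1)

  # mean/SD are computed over passing windows only
  wt3 <- wt2
  wt3$status[1000] <- "fail_map"
  expect_equal(nrow(detect_peaks(wt3)$windows), 0)

  wt4 <- wt2
  wt4$status <- "fail_map"
  expect_error(detect_peaks(wt4), "passing windows")
})

test_that("adjacent peak windows merge into one region", {
  pi <- rep(1e-4, 200)
  pi[c(50, 51, 52, 120)] <- 5e-3
  wt <- data.frame(contig = "c1", start = (0:199) * 1e4, end = (1:200) * 1e4,
                   window = 0:199, span = 1e4, terminal = FALSE, n_snvs = 1L,
                   pi = pi, status = "pass")
  ps <- detect_peaks(wt)
  expect_equal(nrow(ps$windows), 4)
  expect_equal(nrow(ps$regions), 2)
  expect_equal(ps$regions$n_windows, c(3L, 1L))
  expect_equal(ps$regions$start[1], 49 * 1e4)
  expect_equal(ps$regions$end[1], 52 * 1e4)
})

test_that("polymorphic genes are flagged by CDS SNV proportion", {
  seg <- data.frame(gene_id = c("gA", "gB"), contig = "c1", strand = "+",
                    start = c(1001L, 30001L), end = c(1900L, 30900L),
                    phase = 0L, stringsAsFactors = FALSE)
  gm <- make_genes(seg)
  # 12 SNVs in gA's CDS (900 bp -> 0.0133 > 0.01), none in gB
  pos <- seq(1010L, by = 70L, length.out = 12L)
  vt <- make_vt(data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
                matrix(1L, length(pos), 2))
  ps <- fake_peak_set(regions = data.frame(contig = "c1", start = 0,
                                           end = 40000, n_windows = 4L))
  res <- polymorphic_genes(ps, gm, vt)
  expect_equal(res$n_snvs_in_cds, c(12L, 0L))
  expect_equal(res$proportion, c(round(12 / 900, 4), 0))
  expect_equal(res$is_polymorphic, c(TRUE, FALSE))

  # a gene outside every peak region is not evaluated
  ps2 <- fake_peak_set(regions = data.frame(contig = "c1", start = 0,
                                            end = 10000, n_windows = 1L))
  expect_equal(polymorphic_genes(ps2, gm, vt)$gene_id, "gA")

  gm_bad <- gm
  gm_bad$genes$cds_length[1] <- 0L
  expect_error(polymorphic_genes(ps, gm_bad, vt), "zero-length CDS")
})
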