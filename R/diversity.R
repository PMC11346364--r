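# Windowed nucleotide diversity, individual heterozygosity, window
# filtration, peak detection, and per-gene polymorphic-gene summaries.

#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site diversity `(n/(n-1)) * (1 - sum p_a^2)` over the `n`
#' non-missing haplotypes, identical to the mean pairwise difference among
#' them. Sites with fewer than 2 haplotypes are skipped (return 0).
#'
#' @param counts named or unnamed numeric vector of allele counts.
#' @return per-site diversity in `[0, 1]`.
#' @export
site_pi <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(0)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

# per-site diversity for rows of a genotype matrix restricted to some samples
.site_pi_rows <- function(geno) {
  n_hap <- 2 * rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  pi <- numeric(nrow(geno))
  ok <- n_hap >= 2
  p <- alt[ok] / n_hap[ok]
  pi[ok] <- (n_hap[ok] / (n_hap[ok] - 1)) * (1 - p^2 - (1 - p)^2)
  pi
}

#' Windowed nucleotide diversity
#'
#' Sums per-site diversity over the retained SNVs of each non-overlapping
#' window and divides by the full window span (monomorphic sites contribute
#' 0), the convention under which mean + k*SD peak thresholds are defined.
#' Terminal windows keep their actual (shorter) span and are flagged.
#'
#' @param variant_table a `variant_table`.
#' @param reference a `ref_genome` (defines contigs and window grids).
#' @param window_size window width in bp (default 10,000).
#' @param samples samples whose haplotypes enter the diversity computation;
#'   default all samples.
#' @return a window table: data.frame with contig, start, end (0-based
#'   half-open), window (index), span, n_snvs, pi, terminal.
#' @export
window_pi <- function(variant_table, reference, window_size = 1e4,
                      samples = NULL) {
  vt <- variant_table
  samples <- samples %||% vt$samples$sample_id
  ws <- window_size
  grid <- do.call(rbind, lapply(names(reference$sequences), function(ctg) {
    L <- reference$contig_lengths[[ctg]]
    n_win <- max(1L, as.integer(ceiling(L / ws)))
    start <- (seq_len(n_win) - 1) * ws
    data.frame(contig = ctg, start = start, end = pmin(start + ws, L),
               window = seq_len(n_win) - 1L, stringsAsFactors = FALSE)
  }))
  grid$span <- grid$end - grid$start
  grid$terminal <- grid$span < ws
  grid$n_snvs <- 0L
  grid$pi <- 0

  if (nrow(vt$sites)) {
    bad_ctg <- setdiff(unique(vt$sites$contig), names(reference$sequences))
    if (length(bad_ctg))
      stop("variant contig not in reference: ", bad_ctg[1L])
    lens <- reference$contig_lengths[vt$sites$contig]
    if (any(vt$sites$pos > lens))
      stop("variant position beyond contig end at ",
           vt$sites$contig[which(vt$sites$pos > lens)[1L]])
    w <- window_index(vt$sites$pos, ws)
    key <- .win_key(vt$sites$contig, w)
    pi_site <- .site_pi_rows(vt$geno[, samples, drop = FALSE])
    gkey <- .win_key(grid$contig, grid$window)
    cnt <- table(key)
    grid$n_snvs[match(names(cnt), gkey)] <- as.integer(cnt)
    sums <- tapply(pi_site, key, sum)
    grid$pi[match(names(sums), gkey)] <- as.numeric(sums)
    grid$pi <- grid$pi / grid$span
  }
  grid
}

#' Per-individual heterozygosity
#'
#' Fraction of heterozygous genotype calls of one diploid sample over the
#' effective (non-N) genome length.
#'
#' @param variant_table a `variant_table`.
#' @param sample sample name.
#' @param effective_length effective genome length in bp (> 0).
#' @return per-bp heterozygosity.
#' @export
individual_heterozygosity <- function(variant_table, sample, effective_length) {
  .assert_scalar_number(effective_length, "effective_length", 1e-9)
  if (!sample %in% colnames(variant_table$geno))
    stop("unknown sample: ", sample)
  sum(variant_table$geno[, sample] == 1L, na.rm = TRUE) / effective_length
}

#' Filter windows on mappability and coverage
#'
#' Windows with mean mappability below `min_map` or mean coverage outside
#' `[cov_low, cov_high]` are flagged as possible artifacts (repeats,
#' segmental duplications, collapsed assembly). Thresholds are strict
#' inequalities: boundary values pass. Windows with no track data fail
#' conservatively as `fail_map`.
#'
#' @param window_table output of [window_pi()].
#' @param mappability_track,coverage_track data.frames contig/start/end/value.
#' @param min_map mappability threshold (fail when `< min_map`).
#' @param cov_low,cov_high coverage bounds (fail when `< cov_low` or
#'   `> cov_high`).
#' @return the window table with `mean_mappability`, `mean_coverage` and
#'   `status` in pass/fail_map/fail_cov_low/fail_cov_high.
#' @export
filter_windows <- function(window_table, mappability_track, coverage_track,
                           min_map = 0.8, cov_low = 40, cov_high = 400) {
  wt <- window_table
  key <- paste(wt$contig, wt$start)
  wt$mean_mappability <-
    mappability_track$value[match(key, paste(mappability_track$contig,
                                             mappability_track$start))]
  wt$mean_coverage <-
    coverage_track$value[match(key, paste(coverage_track$contig,
                                          coverage_track$start))]
  status <- rep("pass", nrow(wt))
  no_data <- is.na(wt$mean_mappability) | is.na(wt$mean_coverage)
  status[no_data | wt$mean_mappability < min_map] <- "fail_map"
  ok <- status == "pass"
  status[ok & wt$mean_coverage < cov_low] <- "fail_cov_low"
  ok <- status == "pass"
  status[ok & wt$mean_coverage > cov_high] <- "fail_cov_high"
  wt$status <- status
  if (any(no_data))
    attr(wt, "log") <- sprintf("%d window(s) without track data -> fail_map",
                               sum(no_data))
  wt
}

#' Detect nucleotide-diversity peaks
#'
#' A passing window is a peak when its diversity strictly exceeds
#' `mean + k * SD`, with mean and SD computed over passing windows only
#' (failed windows have unreliable diversity). Adjacent peak windows are
#' merged into peak regions.
#'
#' @param window_table a filtered window table (needs a `status` column; an
#'   unfiltered table is treated as all-pass).
#' @param k number of standard deviations above the mean (default 4).
#' @return an object of class `peak_set`: list with `threshold`, `k`,
#'   `mean`, `sd`, `windows` (peak windows), `regions` (merged, 0-based
#'   half-open) and the annotated `window_table`.
#' @export
detect_peaks <- function(window_table, k = 4) {
  wt <- window_table
  if (is.null(wt$status)) wt$status <- "pass"
  pass <- wt$status == "pass"
  if (sum(pass) < 2L)
    stop("fewer than 2 passing windows; cannot set a peak threshold")
  m <- mean(wt$pi[pass])
  s <- sd(wt$pi[pass])
  threshold <- m + k * s
  wt$is_peak <- pass & wt$pi > threshold
  pk <- wt[wt$is_peak, , drop = FALSE]
  regions <- if (nrow(pk)) {
    ord <- order(pk$contig, pk$window)
    pk <- pk[ord, , drop = FALSE]
    new_run <- c(TRUE, pk$contig[-1L] != pk$contig[-nrow(pk)] |
                   diff(pk$window) != 1L)
    run <- cumsum(new_run)
    do.call(rbind, lapply(split(pk, run), function(g) {
      data.frame(contig = g$contig[1L], start = min(g$start),
                 end = max(g$end), n_windows = nrow(g),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               n_windows = integer(0))
  }
  rownames(regions) <- NULL
  out <- list(threshold = threshold, k = k, mean = m, sd = s,
              windows = pk, regions = regions, window_table = wt)
  class(out) <- "peak_set"
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "Diversity peaks: %d window(s) in %d region(s) above mean + %g SD = %.3g\n",
    nrow(x$windows), nrow(x$regions), x$k, x$threshold))
  invisible(x)
}

#' Polymorphic genes within diversity-peak regions
#'
#' For every gene overlapping a peak region, computes the proportion of SNV
#' sites within its protein-coding region (CDS SNV count / CDS length) and
#' flags genes with proportion above `threshold` as polymorphic.
#'
#' @param peak_set a [detect_peaks()] result.
#' @param gene_models a `gene_models`.
#' @param variant_table a `variant_table`; SNV sites polymorphic among
#'   `samples` (default: all) are counted.
#' @param threshold polymorphic-gene cutoff on the CDS SNV proportion.
#' @param samples optional sample subset defining which sites count.
#' @return data.frame gene_id, contig, n_snvs_in_cds, cds_length,
#'   proportion (rounded to 4 decimals for reporting), is_polymorphic.
#' @export
polymorphic_genes <- function(peak_set, gene_models, variant_table,
                              threshold = 0.01, samples = NULL) {
  gm <- gene_models
  if (any(gm$genes$cds_length <= 0)) stop("zero-length CDS")
  vt <- variant_table
  samples <- samples %||% vt$samples$sample_id
  regions <- peak_set$regions
  if (!nrow(regions) || !nrow(gm$genes)) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      n_snvs_in_cds = integer(0), cds_length = integer(0),
                      proportion = numeric(0), is_polymorphic = logical(0)))
  }
  gene_gr <- GenomicRanges::GRanges(gm$genes$contig,
                                    IRanges::IRanges(gm$genes$start,
                                                     gm$genes$end))
  region_gr <- GenomicRanges::GRanges(regions$contig,
                                      IRanges::IRanges(regions$start + 1L,
                                                       regions$end))
  hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gene_gr, region_gr)))
  genes <- gm$genes[sort(hit), , drop = FALSE]
  if (!nrow(genes)) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      n_snvs_in_cds = integer(0), cds_length = integer(0),
                      proportion = numeric(0), is_polymorphic = logical(0)))
  }
  # sites polymorphic among the requested samples
  sub <- vt$geno[, samples, drop = FALSE]
  alt <- rowSums(sub, na.rm = TRUE)
  n_hap <- 2 * rowSums(!is.na(sub))
  segregating <- alt > 0 & alt < n_hap
  sites <- vt$sites[segregating, , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    seg <- gm$cds[gm$cds$gene_id == g$gene_id, , drop = FALSE]
    in_cds <- sites$contig == g$contig &
      vapply(sites$pos, function(p) any(p >= seg$start & p <= seg$end),
             logical(1L))
    n <- sum(in_cds)
    prop <- n / g$cds_length
    data.frame(gene_id = g$gene_id, contig = g$contig, n_snvs_in_cds = n,
               cds_length = g$cds_length, proportion = round(prop, 4L),
               is_polymorphic = prop > threshold, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
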