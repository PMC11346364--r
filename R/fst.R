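# Weir & Cockerham (1984) two-population variance components, weighted
# window F_ST, and the peak-vs-background distribution-shift test.

#' Per-site Weir-Cockerham variance components
#'
#' Two-population estimator from diploid genotype counts, including the
#' heterozygote term: returns the among-population (a), among-individual
#' (b) and within-individual (c) components; the per-site estimate is
#' `a / (a + b + c)`. Sites monomorphic across the pooled sample are flagged
#' non-usable. Negative components are reported as computed.
#'
#' @param geno1,geno2 integer genotype vectors (0/1/2, NA = missing) for the
#'   two populations; each must have at least one non-missing genotype.
#' @return list with `a`, `b`, `c`, `theta` and `usable`.
#' @export
wc_components_site <- function(geno1, geno2) {
  g <- list(geno1[!is.na(geno1)], geno2[!is.na(geno2)])
  n_i <- vapply(g, length, numeric(1))
  if (any(n_i < 1)) stop("each population needs >= 1 non-missing genotype")
  alt <- vapply(g, sum, numeric(1))
  if (sum(alt) == 0 || sum(alt) == 2 * sum(n_i))   # pooled-monomorphic
    return(list(a = 0, b = 0, c = 0, theta = NA_real_, usable = FALSE))
  r <- 2
  p_i <- alt / (2 * n_i)
  h_i <- vapply(g, function(x) mean(x == 1L), numeric(1))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom != 0) a / denom else NA_real_, usable = TRUE)
}

# vectorized variance components over the rows of two genotype matrices
.wc_components_rows <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  a1 <- rowSums(g1, na.rm = TRUE); a2 <- rowSums(g2, na.rm = TRUE)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  p1 <- a1 / (2 * n1); p2 <- a2 / (2 * n2)
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  usable <- n1 >= 1 & n2 >= 1 & p_bar > 0 & p_bar < 1
  data.frame(a = a, b = b, c = cc, usable = usable)
}

#' Weighted window F_ST between two species
#'
#' Per window, the ratio-of-sums (weighted) Weir-Cockerham estimate
#' `sum(a) / sum(a + b + c)` over usable sites; windows with no usable site
#' get `NA`. Only windows with `pass` status are evaluated (failed windows
#' get `NA` and `n_usable_sites` 0).
#'
#' @param variant_table a `variant_table` containing both species.
#' @param window_table a filtered window table ([filter_windows()]).
#' @param species_a,species_b species labels of the two populations as in
#'   `variant_table$samples$species`.
#' @return the window table with `fst` and `n_usable_sites` columns.
#' @export
window_fst <- function(variant_table, window_table,
                       species_a = "A", species_b = "B") {
  vt <- variant_table
  sa <- vt$samples$sample_id[vt$samples$species == species_a]
  sb <- vt$samples$sample_id[vt$samples$species == species_b]
  if (!length(sa) || !length(sb))
    stop("a species has no samples: ", species_a, "/", species_b)
  wt <- window_table
  if (is.null(wt$status)) wt$status <- "pass"
  wt$fst <- NA_real_
  wt$n_usable_sites <- 0L
  if (!nrow(vt$sites)) return(wt)
  comp <- .wc_components_rows(vt$geno[, sa, drop = FALSE],
                              vt$geno[, sb, drop = FALSE])
  ws <- max(wt$end - wt$start)   # terminal windows are shorter
  key <- .win_key(vt$sites$contig, window_index(vt$sites$pos, ws))
  gkey <- .win_key(wt$contig, wt$window)
  use <- comp$usable
  idx <- match(key[use], gkey)
  ok <- !is.na(idx) & wt$status[idx] == "pass"
  if (any(ok)) {
    sum_a <- tapply(comp$a[use][ok], idx[ok], sum)
    sum_abc <- tapply((comp$a + comp$b + comp$c)[use][ok], idx[ok], sum)
    cnt <- tapply(rep(1L, sum(ok)), idx[ok], sum)
    rows <- as.integer(names(sum_a))
    wt$n_usable_sites[rows] <- as.integer(cnt)
    wt$fst[rows] <- ifelse(sum_abc != 0, sum_a / sum_abc, NA_real_)
  }
  wt
}

# exact two-sided Mann-Whitney p-value by enumeration of the rank-sum
# distribution (tie-aware: dynamic programming over doubled midranks)
.mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  rk <- rank(c(x, y))            # midranks; doubling makes them integers
  r2 <- as.integer(round(2 * rk))
  w_obs <- sum(r2[seq_len(n)])
  total <- sum(r2)
  # f[k+1, s+1] = number of n-subsets of the first j items with k elements
  # and doubled-rank sum s
  max_s <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  f <- matrix(0, n + 1L, max_s + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n
    for (k in kmax:1) {
      src <- f[k, ]
      nz <- which(src > 0)
      if (length(nz)) {
        tgt <- nz + v
        keep <- tgt <= max_s + 1L
        f[k + 1L, tgt[keep]] <- f[k + 1L, tgt[keep]] + src[nz[keep]]
      }
    }
  }
  dist <- f[n + 1L, ]
  tot <- sum(dist)
  lo <- sum(dist[seq_len(w_obs + 1L)])        # P(W <= w_obs)
  hi <- sum(dist[(w_obs + 1L):(max_s + 1L)])  # P(W >= w_obs)
  list(p = min(1, 2 * min(lo, hi) / tot),
       U = w_obs / 2 - n * (n + 1) / 2)
}

#' Peak-vs-background F_ST distribution-shift test
#'
#' Two-tailed Mann-Whitney test of window F_ST in diversity-peak windows
#' against background (non-peak passing) windows. Uses exact enumeration of
#' the tie-aware rank-sum distribution when both groups have at most
#' `exact_max` windows, and the normal approximation with tie and continuity
#' correction otherwise. `NA` F_ST windows are removed first.
#'
#' @param fst_windows output of [window_fst()].
#' @param peak_set a [detect_peaks()] result on the same grid.
#' @param exact_max exact-path group-size limit (default 12).
#' @return an object of class `shift_test`: list with `median_peak`,
#'   `median_background`, `U`, `p`, `n_peak`, `n_background`, `method`.
#' @export
peak_background_shift <- function(fst_windows, peak_set, exact_max = 12L) {
  wt <- fst_windows
  peak_keys <- .win_key(peak_set$windows$contig, peak_set$windows$window)
  is_peak <- .win_key(wt$contig, wt$window) %in% peak_keys
  pass <- (wt$status %||% "pass") == "pass"
  x <- wt$fst[is_peak & pass]
  y <- wt$fst[!is_peak & pass]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("a group is empty after NA removal")
  if (length(x) <= exact_max && length(y) <= exact_max) {
    ex <- .mw_exact_p(x, y)
    out <- list(U = ex$U, p = ex$p, method = "exact")
  } else {
    wt_test <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE))
    out <- list(U = unname(wt_test$statistic), p = wt_test$p.value,
                method = "normal approximation")
  }
  out <- c(list(median_peak = median(x), median_background = median(y),
                n_peak = length(x), n_background = length(y)), out)
  class(out) <- "shift_test"
  out
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(paste0(
    "F_ST shift test (two-tailed Mann-Whitney, %s):\n",
    "  median peak %.3f (n=%d) vs background %.3f (n=%d), U = %.1f, p = %.3g\n"),
    x$method, x$median_peak, x$n_peak, x$median_background, x$n_background,
    x$U, x$p))
  invisible(x)
}
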