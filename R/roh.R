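# Two-state HMM detection of runs of homozygosity (ROH) from per-site
# zygosity calls, interval calling, and F_ROH.
#
# States: HW (outbred, Hardy-Weinberg heterozygosity at a default allele
# frequency) and AZ (autozygous; heterozygotes arise only through genotyping
# error). Transition probabilities are per-bp rates scaled by the inter-site
# distance; decoding is Viterbi.

#' ROH model parameters
#'
#' @param default_allele_freq constant allele frequency f used for the HW
#'   emission `P(het) = 2 f (1 - f)` (default 0.4, i.e. P(het) = 0.48).
#' @param error_rate genotyping error rate: `P(het | AZ)`.
#' @param transition_in per-bp probability of entering the AZ state.
#' @param transition_out per-bp probability of leaving the AZ state.
#' @param min_length minimum reported ROH length in bp.
#' @return a validated list of class `roh_params`.
#' @export
roh_params <- function(default_allele_freq = 0.4,
                       error_rate = 1e-3,
                       transition_in = 6.7e-8,
                       transition_out = 5e-9,
                       min_length = 1e5) {
  .assert_scalar_number(default_allele_freq, "default_allele_freq", 1e-12, 1 - 1e-12)
  .assert_scalar_number(error_rate, "error_rate", 1e-12, 1 - 1e-12)
  .assert_scalar_number(transition_in, "transition_in", 1e-30, 1 - 1e-12)
  .assert_scalar_number(transition_out, "transition_out", 1e-30, 1 - 1e-12)
  .assert_scalar_number(min_length, "min_length", 1)
  out <- list(default_allele_freq = default_allele_freq,
              error_rate = error_rate, transition_in = transition_in,
              transition_out = transition_out, min_length = min_length)
  class(out) <- "roh_params"
  out
}

# log probability of a state switch over distance d given a per-bp rate
.log_switch <- function(rate, d) {
  log(-expm1(d * log1p(-rate)))
}

#' Viterbi decoding of the ROH HMM
#'
#' @param site_positions strictly increasing 1-based positions on one contig.
#' @param zygosity character vector, `"het"` or `"hom"`, same length.
#' @param params a [roh_params()].
#' @return character vector of decoded states (`"HW"`/`"AZ"`), empty when
#'   fewer than 2 sites are given.
#' @export
roh_decode <- function(site_positions, zygosity, params = roh_params()) {
  n <- length(site_positions)
  stopifnot(length(zygosity) == n, all(zygosity %in% c("het", "hom")))
  if (n < 2L) return(character(0))
  if (any(diff(site_positions) <= 0))
    stop("site positions must be strictly increasing")
  f <- params$default_allele_freq
  p_het_hw <- 2 * f * (1 - f)
  e <- rbind(HW = log(c(het = p_het_hw, hom = 1 - p_het_hw)),
             AZ = log(c(het = params$error_rate, hom = 1 - params$error_rate)))
  obs <- match(zygosity, c("het", "hom"))
  d <- diff(site_positions)
  l_in <- .log_switch(params$transition_in, d)        # HW -> AZ
  l_stay_hw <- log1p(-exp(l_in))
  l_out <- .log_switch(params$transition_out, d)      # AZ -> HW
  l_stay_az <- log1p(-exp(l_out))

  v <- matrix(-Inf, 2L, n)                            # 1 = HW, 2 = AZ
  bp <- matrix(0L, 2L, n)
  v[, 1L] <- log(0.5) + e[, obs[1L]]
  for (t in 2:n) {
    cand_hw <- c(v[1L, t - 1L] + l_stay_hw[t - 1L],
                 v[2L, t - 1L] + l_out[t - 1L])
    cand_az <- c(v[1L, t - 1L] + l_in[t - 1L],
                 v[2L, t - 1L] + l_stay_az[t - 1L])
    bp[1L, t] <- which.max(cand_hw)
    bp[2L, t] <- which.max(cand_az)
    v[1L, t] <- cand_hw[bp[1L, t]] + e[1L, obs[t]]
    v[2L, t] <- cand_az[bp[2L, t]] + e[2L, obs[t]]
  }
  path <- integer(n)
  path[n] <- which.max(v[, n])
  for (t in n:2) path[t - 1L] <- bp[path[t], t]
  c("HW", "AZ")[path]
}

#' Convert a decoded state path into ROH intervals
#'
#' Maximal AZ runs become intervals spanning the first through last AZ site
#' (0-based half-open: `[first_pos - 1, last_pos)`); intervals shorter than
#' `min_length` are discarded.
#'
#' @param state_path output of [roh_decode()].
#' @param site_positions the positions that were decoded.
#' @param params a [roh_params()].
#' @return data.frame start/end/length/n_sites (one row per kept interval).
#' @export
call_intervals <- function(state_path, site_positions, params = roh_params()) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), n_sites = integer(0))
  if (!length(state_path)) return(empty)
  r <- rle(state_path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  az <- which(r$values == "AZ")
  if (!length(az)) return(empty)
  iv <- data.frame(start = site_positions[starts[az]] - 1,
                   end = as.numeric(site_positions[ends[az]]),
                   n_sites = r$lengths[az])
  iv$length <- iv$end - iv$start
  iv <- iv[iv$length >= params$min_length, c("start", "end", "length",
                                             "n_sites"), drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Genomic fraction in runs of homozygosity
#'
#' `F_ROH`: summed length of ROH intervals (already length-filtered) divided
#' by the total genome length.
#'
#' @param call_set a `roh_calls` object or a data.frame of intervals with a
#'   `length` column.
#' @param genome_length total genome length in bp (> 0).
#' @return list with `f_roh` (full precision) and `f_roh_2dp`.
#' @export
f_roh <- function(call_set, genome_length) {
  .assert_scalar_number(genome_length, "genome_length", 1e-9)
  iv <- if (inherits(call_set, "roh_calls")) call_set$intervals else call_set
  tot <- if (nrow(iv)) sum(iv$length) else 0
  list(f_roh = tot / genome_length, f_roh_2dp = round(tot / genome_length, 2L))
}

# extend decoded AZ runs to the maximal homozygous run containing them.
# Distance-scaled transitions let Viterbi place the state switch where the
# inter-site gap is cheapest, which can strand a few flanking homozygous
# sites outside the run; the maximal homozygous envelope is the boundary
# any decoder would assign, since flanking homozygotes are indistinguishable
# from run members.
.refine_intervals <- function(state_path, site_positions, zygosity) {
  r <- rle(state_path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  az <- which(r$values == "AZ")
  if (!length(az)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), n_sites = integer(0)))
  }
  n <- length(site_positions)
  iv <- lapply(az, function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    while (i0 > 1L && zygosity[i0 - 1L] == "hom") i0 <- i0 - 1L
    while (i1 < n && zygosity[i1 + 1L] == "hom") i1 <- i1 + 1L
    c(i0, i1)
  })
  iv <- do.call(rbind, iv)
  # merge runs that meet after extension
  keep <- c(TRUE, iv[-1L, 1L] > head(iv[, 2L], -1L))
  if (!all(keep)) {
    merged <- list()
    cur <- iv[1L, ]
    for (k in seq_len(nrow(iv))[-1L]) {
      if (iv[k, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], iv[k, 2L])
      else { merged[[length(merged) + 1L]] <- cur; cur <- iv[k, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    iv <- do.call(rbind, merged)
  }
  out <- data.frame(start = site_positions[iv[, 1L]] - 1,
                    end = as.numeric(site_positions[iv[, 2L]]),
                    n_sites = iv[, 2L] - iv[, 1L] + 1L)
  out$length <- out$end - out$start
  out[, c("start", "end", "length", "n_sites")]
}

#' Call runs of homozygosity for one sample
#'
#' Selects the sites informative for the sample's species (segregating
#' within that species) with a non-missing genotype for the sample, decodes
#' the zygosity sequence per contig with the HMM, refines interval
#' boundaries to the maximal homozygous run containing each decoded
#' autozygous run, and reports length-filtered intervals plus F_ROH.
#'
#' @param variant_table a `variant_table`.
#' @param sample sample name.
#' @param genome_length denominator for F_ROH (e.g. total assembly length).
#' @param params a [roh_params()].
#' @param refine_boundaries extend each decoded run across flanking
#'   homozygous sites (default TRUE); with FALSE intervals are exactly the
#'   decoded AZ runs as in [call_intervals()].
#' @return an object of class `roh_calls`: list with `sample`, `intervals`
#'   (contig/start/end/length/n_sites), `f_roh`, `f_roh_2dp`,
#'   `genome_length`, `params`.
#' @export
call_roh <- function(variant_table, sample, genome_length,
                     params = roh_params(), refine_boundaries = TRUE) {
  vt <- variant_table
  if (!sample %in% colnames(vt$geno)) stop("unknown sample: ", sample)
  species <- vt$samples$species[match(sample, vt$samples$sample_id)]
  mates <- vt$samples$sample_id[vt$samples$species == species]
  sub <- vt$geno[, mates, drop = FALSE]
  alt <- rowSums(sub, na.rm = TRUE)
  n_hap <- 2 * rowSums(!is.na(sub))
  informative <- alt > 0 & alt < n_hap & !is.na(vt$geno[, sample])
  iv_all <- list()
  for (ctg in unique(vt$sites$contig[informative])) {
    sel <- informative & vt$sites$contig == ctg
    pos <- vt$sites$pos[sel]
    zyg <- ifelse(vt$geno[sel, sample] == 1L, "het", "hom")
    path <- roh_decode(pos, zyg, params)
    iv <- if (refine_boundaries && length(path)) {
      ref_iv <- .refine_intervals(path, pos, zyg)
      ref_iv[ref_iv$length >= params$min_length, , drop = FALSE]
    } else {
      call_intervals(path, pos, params)
    }
    if (nrow(iv)) iv_all[[ctg]] <- data.frame(contig = ctg, iv,
                                              row.names = NULL,
                                              stringsAsFactors = FALSE)
  }
  intervals <- if (length(iv_all)) do.call(rbind, iv_all) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0), n_sites = integer(0))
  rownames(intervals) <- NULL
  fr <- f_roh(intervals, genome_length)
  out <- list(sample = sample, intervals = intervals, f_roh = fr$f_roh,
              f_roh_2dp = fr$f_roh_2dp, genome_length = genome_length,
              params = params)
  class(out) <- "roh_calls"
  out
}

#' @export
print.roh_calls <- function(x, ...) {
  cat(sprintf(
    "ROH calls for %s: %d interval(s) >= %s bp, F_ROH = %.4f (%.2f)\n",
    x$sample, nrow(x$intervals),
    format(x$params$min_length, big.mark = ","), x$f_roh, x$f_roh_2dp))
  invisible(x)
}
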