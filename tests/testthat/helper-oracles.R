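# Independent brute-force oracles. Each one takes a different computational
# route than the implementation it checks.

# mean pairwise Hamming distance among explicit haplotypes, summed over
# sites and divided by the window span
oracle_window_pi <- function(geno, span) {
  total <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    g <- g[!is.na(g)]
    if (length(g) < 1L) next
    # expand unphased genotypes into allele vectors (assignment irrelevant)
    hap <- unname(unlist(lapply(g, function(x) switch(as.character(x),
                                                      "0" = c(0L, 0L),
                                                      "1" = c(0L, 1L),
                                                      "2" = c(1L, 1L)))))
    n <- length(hap)
    if (n < 2L) next
    diff_pairs <- 0
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        diff_pairs <- diff_pairs + (hap[a] != hap[b])
      }
    }
    total <- total + diff_pairs / choose(n, 2L)
  }
  total / span
}

# Weir & Cockerham variance components via the ANOVA mean-square route
# (MSG/MSI/MSP moment estimators), independent of the closed-form algebra
oracle_wc_anova <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  p_bar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * n1 + 2 * n2)
  ssg <- (sum(g1 == 1L) + sum(g2 == 1L)) / 2
  msg <- ssg / (n1 + n2)
  ssi <- sum(2 * (g1 / 2 - p1)^2) + sum(2 * (g2 / 2 - p2)^2)
  msi <- ssi / ((n1 - 1L) + (n2 - 1L))
  msp <- 2 * n1 * (p1 - p_bar)^2 + 2 * n2 * (p2 - p_bar)^2   # df = r - 1 = 1
  n_c <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  c_comp <- msg
  b_comp <- (msi - msg) / 2
  a_comp <- (msp - msi) / (2 * n_c)
  list(a = a_comp, b = b_comp, c = c_comp,
       theta = a_comp / (a_comp + b_comp + c_comp))
}

# fold class of every position of a spliced CDS by exhaustive substitution
# and translation (Biostrings::translate on codon sets)
oracle_degeneracy <- function(cds) {
  m <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(m) - 2L, 3L * seq_len(m))
  classes <- integer(nchar(cds))
  for (k in seq_len(m)) {
    for (p in 1:3) {
      variants <- vapply(c("A", "C", "G", "T"), function(b) {
        x <- codons[k]
        substr(x, p, p) <- b
        x
      }, character(1L))
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAStringSet(variants),
                              no.init.codon = TRUE)))
      ref_aa <- aa[match(substr(codons[k], p, p), c("A", "C", "G", "T"))]
      f <- sum(aa == ref_aa)
      classes[3L * (k - 1L) + p] <- if (f == 1L) 0L else f
    }
  }
  classes
}

# exhaustive enumeration of all 2^n state paths of the ROH HMM;
# transition/emission model written out directly from its definition
oracle_viterbi <- function(pos, zyg, params) {
  n <- length(pos)
  f <- params$default_allele_freq
  p_het_hw <- 2 * f * (1 - f)
  emis <- rbind(c(log(p_het_hw), log(1 - p_het_hw)),        # HW: het, hom
                c(log(params$error_rate), log(1 - params$error_rate)))
  obs <- ifelse(zyg == "het", 1L, 2L)
  d <- diff(pos)
  p_in <- 1 - (1 - params$transition_in)^d     # HW -> AZ
  p_out <- 1 - (1 - params$transition_out)^d   # AZ -> HW
  tl <- array(NA_real_, c(2L, 2L, n - 1L))
  tl[1L, 1L, ] <- log(1 - p_in);  tl[1L, 2L, ] <- log(p_in)
  tl[2L, 1L, ] <- log(p_out);     tl[2L, 2L, ] <- log(1 - p_out)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp <- apply(paths, 1L, function(s) {
    log(0.5) + sum(emis[cbind(s, obs)]) +
      sum(tl[cbind(s[-n], s[-1L], seq_len(n - 1L))])
  })
  best <- max(lp)
  list(max_logprob = best,
       best_paths = paths[lp > best - 1e-9, , drop = FALSE],
       score = function(states) {   # states as "HW"/"AZ"
         s <- match(states, c("HW", "AZ"))
         log(0.5) + sum(emis[cbind(s, obs)]) +
           sum(tl[cbind(s[-n], s[-1L], seq_len(n - 1L))])
       })
}
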