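# Synthetic genome / genotype / track generator.
#
# The generator emulates the statistical structure the scan assumes: a focal
# species "A" with background heterozygosity of order 3.4e-4/bp against a
# contrast species "B" about 5x higher (16.0e-4/bp), localized diversity
# peaks, fixed inter-species differences outside balanced peaks, ROH tracts,
# and windows with aberrant mappability/coverage for the filters to remove.
# Sites are simulated independently (no linkage): every statistic in scope
# depends only on marginal per-site frequencies.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults mirror the
#' study conditions the scan is designed for: 10-kb windows, focal-species
#' heterozygosity 3.4e-4/bp, contrast species 16.0e-4/bp, inter-species
#' fixed-difference rate 5e-3/bp, two diploid focal individuals against four
#' contrast individuals.
#'
#' @param seed integer root seed; all stages derive sub-seeds from it.
#' @param n_contigs,contig_length genome shape (every contig the same length).
#' @param window_size non-overlapping window width in bp.
#' @param theta_background expected per-bp heterozygosity of each species-A
#'   individual outside peaks and ROH.
#' @param theta_contrast same for species B.
#' @param divergence expected per-bp rate of fixed differences between the
#'   species outside balanced peaks.
#' @param gc genomic GC fraction.
#' @param peaks data.frame with columns `contig`, `start` (0-based),
#'   `length`, `pi_multiplier` (>1), `shared_with_b`, `balanced` (logicals).
#'   Balanced peaks carry shared intermediate-frequency polymorphism and no
#'   fixed differences, mimicking balancing selection.
#' @param roh_tracts data.frame with columns `sample`, `contig`, `start`
#'   (0-based), `length`; the sample is forced homozygous inside the tract.
#' @param n_runs data.frame with columns `contig`, `start` (0-based),
#'   `length` of N gaps to punch into the assembly.
#' @param n_genes,gene_length,intron_length gene models: each gene is a
#'   two-exon CDS chain of `gene_length` coding bp (divisible by 3) split by
#'   one intron; genes are placed without overlap and peaks are seeded with
#'   genes first.
#' @param artifact_windows data.frame with columns `contig`, `window`
#'   (0-based index), `type` in `low_map`/`low_cov`/`high_cov`.
#' @param n_samples_a,n_samples_b diploid individuals per species.
#' @param coverage_mean,coverage_sd normal noise model of the per-window
#'   depth-of-coverage track.
#' @param load_het_0fold,load_het_4fold optional per-site heterozygote
#'   probabilities at 0-fold/4-fold degenerate CDS sites (species A); `NA`
#'   disables the dedicated genetic-load layer.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 1e6,
                       window_size = 1e4,
                       theta_background = 3.4e-4,
                       theta_contrast = 16.0e-4,
                       divergence = 5e-3,
                       gc = 0.41,
                       peaks = NULL,
                       roh_tracts = NULL,
                       n_runs = NULL,
                       n_genes = 20L,
                       gene_length = 900L,
                       intron_length = 120L,
                       artifact_windows = NULL,
                       n_samples_a = 2L,
                       n_samples_b = 4L,
                       coverage_mean = 60,
                       coverage_sd = 6,
                       load_het_0fold = NA,
                       load_het_4fold = NA) {
  .assert_scalar_number(theta_background, "theta_background", 1e-12, 1)
  .assert_scalar_number(theta_contrast, "theta_contrast", 1e-12, 1)
  if (!(theta_background < theta_contrast))
    stop("theta_background must be < theta_contrast")
  .assert_scalar_number(divergence, "divergence", 0, 1)
  .assert_scalar_number(gc, "gc", 0, 1)
  .assert_scalar_number(contig_length, "contig_length", 1)
  .assert_scalar_number(window_size, "window_size", 1)
  if (gene_length %% 3L != 0L || gene_length < 9L)
    stop("gene_length must be a multiple of 3 and >= 9")
  empty_peaks <- data.frame(contig = character(0), start = numeric(0),
                            length = numeric(0), pi_multiplier = numeric(0),
                            shared_with_b = logical(0), balanced = logical(0))
  peaks <- peaks %||% empty_peaks
  if (nrow(peaks)) {
    if (any(peaks$pi_multiplier <= 1)) stop("pi_multiplier must be > 1")
    if (any(peaks$start < 0 | peaks$start + peaks$length > contig_length))
      stop("peak interval outside contig bounds")
  }
  roh_tracts <- roh_tracts %||%
    data.frame(sample = character(0), contig = character(0),
               start = numeric(0), length = numeric(0))
  n_runs <- n_runs %||%
    data.frame(contig = character(0), start = numeric(0), length = numeric(0))
  artifact_windows <- artifact_windows %||%
    data.frame(contig = character(0), window = integer(0), type = character(0))
  if (nrow(artifact_windows) &&
      !all(artifact_windows$type %in% c("low_map", "low_cov", "high_cov")))
    stop("artifact window type must be low_map, low_cov or high_cov")
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = contig_length, window_size = window_size,
              theta_background = theta_background,
              theta_contrast = theta_contrast, divergence = divergence,
              gc = gc, peaks = peaks, roh_tracts = roh_tracts,
              n_runs = n_runs, n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              intron_length = as.integer(intron_length),
              artifact_windows = artifact_windows,
              n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              coverage_mean = coverage_mean, coverage_sd = coverage_sd,
              load_het_0fold = load_het_0fold, load_het_4fold = load_het_4fold)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d contig(s) x %s bp, window %s bp\n",
    "  species A: %d diploids, theta %.2g/bp; species B: %d diploids, theta %.2g/bp\n",
    "  divergence %.2g/bp; %d peak(s); %d ROH tract(s); %d artifact window(s); seed %d\n"),
    x$n_contigs, format(x$contig_length, big.mark = ","),
    format(x$window_size, big.mark = ","),
    x$n_samples_a, x$theta_background, x$n_samples_b, x$theta_contrast,
    x$divergence, nrow(x$peaks), nrow(x$roh_tracts),
    nrow(x$artifact_windows), x$seed))
  invisible(x)
}

# neutral-like minor-allele-count weights (p ~ 1/i, truncated at n_hap/2) and
# the expected per-individual heterozygosity (= expected per-site diversity)
# of a polymorphic site under random placement of the minor copies
.freq_model <- function(n_hap) {
  i <- seq_len(n_hap %/% 2L)
  w <- (1 / i) / sum(1 / i)
  e_het <- sum(w * 2 * i * (n_hap - i) / (n_hap * (n_hap - 1)))
  list(i = i, w = w, e_het = e_het)
}

.stop_codons <- c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, NULL)[[1L]]), collapse = ""))
}

#' Simulate a reference genome and gene models
#'
#' Generates random sequence at the configured GC fraction, punches in the
#' configured N runs, and plants two-exon genes (ATG ... stop, no internal
#' stop codons, canonical GT..AG introns). One gene is seeded inside every
#' declared peak interval before the remaining genes are placed uniformly
#' without overlap.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (a `ref_genome`) and `genes`
#'   (a `gene_models`).
#' @export
simulate_genome <- function(config) {
  set.seed(.sub_seed(config$seed, 0L))
  L <- config$contig_length
  contigs <- paste0("ctg", seq_len(config$n_contigs))
  base_prob <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
                 (1 - config$gc) / 2)
  chr <- setNames(vapply(contigs, function(ctg) {
    paste(sample(c("A", "C", "G", "T"), L, TRUE, base_prob), collapse = "")
  }, character(1L)), contigs)
  for (k in seq_len(nrow(config$n_runs))) {
    nr <- config$n_runs[k, ]
    substr(chr[[nr$contig]], nr$start + 1L, nr$start + nr$length) <-
      strrep("N", nr$length)
  }

  # candidate gene anchor points: peak centers first, then random slots
  span <- config$gene_length + config$intron_length
  occupied <- lapply(setNames(nm = contigs), function(...) {
    cbind(numeric(0), numeric(0))
  })
  blocked <- function(ctg, s, e) {
    occ <- occupied[[ctg]]
    (nrow(occ) && any(s <= occ[, 2L] & e >= occ[, 1L])) ||
      grepl("N", substr(chr[[ctg]], s, e), fixed = TRUE)
  }
  placements <- list()
  n_placed <- 0L
  for (k in seq_len(nrow(config$peaks))) {
    if (n_placed >= config$n_genes) break
    pk <- config$peaks[k, ]
    s <- floor(pk$start + (pk$length - span) / 2) + 1L   # 1-based
    if (pk$length < span || s < 1L || blocked(pk$contig, s, s + span - 1L)) next
    n_placed <- n_placed + 1L
    placements[[n_placed]] <- list(contig = pk$contig, start = s)
    occupied[[pk$contig]] <- rbind(occupied[[pk$contig]], c(s, s + span - 1L))
  }
  tries <- 0L
  while (n_placed < config$n_genes && tries < 1000L * config$n_genes) {
    tries <- tries + 1L
    ctg <- sample(contigs, 1L)
    s <- sample.int(L - span, 1L)
    if (blocked(ctg, s, s + span - 1L)) next
    n_placed <- n_placed + 1L
    placements[[n_placed]] <- list(contig = ctg, start = s)
    occupied[[ctg]] <- rbind(occupied[[ctg]], c(s, s + span - 1L))
  }
  if (n_placed < config$n_genes)
    stop("genes do not fit in contigs (placed ", n_placed, " of ",
         config$n_genes, ")")

  n_codons <- config$gene_length %/% 3L
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
  body_codons <- setdiff(all_codons, .stop_codons)
  cds_rows <- vector("list", n_placed)
  for (g in seq_len(n_placed)) {
    pl <- placements[[g]]
    gid <- sprintf("g%03d", g)
    cds <- paste(c("ATG", sample(body_codons, n_codons - 2L, TRUE),
                   sample(.stop_codons, 1L)), collapse = "")
    split_at <- sample(seq(3L, config$gene_length - 3L), 1L)
    exon1 <- substr(cds, 1L, split_at)
    exon2 <- substr(cds, split_at + 1L, config$gene_length)
    intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                        config$intron_length - 4L, TRUE),
                                 collapse = ""), "AG")
    strand <- sample(c("+", "-"), 1L)
    s <- pl$start
    phase2 <- (3L - split_at %% 3L) %% 3L
    if (strand == "+") {
      genomic <- paste0(exon1, intron, exon2)
      seg <- data.frame(
        gene_id = gid, contig = pl$contig, strand = strand,
        start = c(s, s + split_at + config$intron_length),
        end = c(s + split_at - 1L, s + span - 1L),
        phase = c(0L, phase2), stringsAsFactors = FALSE)
    } else {
      genomic <- paste0(.revcomp(exon2), .revcomp(intron), .revcomp(exon1))
      len2 <- config$gene_length - split_at
      seg <- data.frame(
        gene_id = gid, contig = pl$contig, strand = strand,
        start = c(s, s + len2 + config$intron_length),
        end = c(s + len2 - 1L, s + span - 1L),
        phase = c(phase2, 0L), stringsAsFactors = FALSE)
    }
    substr(chr[[pl$contig]], s, s + span - 1L) <- genomic
    cds_rows[[g]] <- seg
  }
  genes <- .as_gene_models(do.call(rbind, cds_rows) %||% data.frame(
    gene_id = character(0), contig = character(0), strand = character(0),
    start = integer(0), end = integer(0), phase = integer(0)))
  reference <- .as_ref_genome(Biostrings::DNAStringSet(chr))
  list(reference = reference, genes = genes)
}

# draw genotype matrices (minor-copy counts per individual) for sites with
# given minor-allele counts among n_hap haplotypes placed at random;
# equivalent to uniform placement, realised as sequential hypergeometric
# draws of each individual's two haplotypes (vectorised over sites)
.assign_minor <- function(n_hap, i_vec) {
  n_ind <- n_hap %/% 2L
  n <- length(i_vec)
  if (!n) return(matrix(integer(0), 0L, n_ind))
  g <- matrix(0L, n, n_ind)
  rem_minor <- as.integer(i_vec)
  rem_tot <- rep(n_hap, n)
  for (j in seq_len(n_ind)) {
    x <- stats::rhyper(n, rem_minor, rem_tot - rem_minor, 2L)
    g[, j] <- x
    rem_minor <- rem_minor - x
    rem_tot <- rem_tot - 2L
  }
  g
}

# uniformly drawn positions at a per-bp Poisson rate within [lo+1, hi] (1-based)
.draw_positions <- function(lo, hi, rate) {
  n <- rpois(1L, max(hi - lo, 0) * rate)
  if (n == 0L) return(integer(0))
  lo + sample.int(hi - lo, n, replace = TRUE)
}

#' Simulate two-species diploid genotypes
#'
#' Sites are independent. Species-A background polymorphism is calibrated so
#' each individual's expected per-bp heterozygosity equals
#' `theta_background` (and window diversity has the same expectation);
#' species B likewise at `theta_contrast`. Minor-allele counts follow a
#' neutral-like 1/i distribution; inside declared peaks sites are seeded at
#' intermediate frequency (0.5) and at `pi_multiplier` times the background
#' diversity. Balanced peaks carry polymorphism shared by both species and
#' exclude fixed differences; elsewhere fixed inter-species differences occur
#' at rate `divergence`. Samples are forced homozygous inside their ROH
#' tracts. When the genetic-load layer is enabled, extra heterozygotes are
#' placed at 0-fold/4-fold degenerate CDS sites at the configured rates.
#'
#' @param config a [sim_config()].
#' @param reference `ref_genome` from [simulate_genome()].
#' @param gene_models `gene_models` from [simulate_genome()]; required only
#'   for the genetic-load layer.
#' @return a `variant_table` with samples `A1..An` (species `"A"`) and
#'   `B1..Bm` (species `"B"`).
#' @export
simulate_genotypes <- function(config, reference, gene_models = NULL) {
  set.seed(.sub_seed(config$seed, 1L))
  nA <- config$n_samples_a
  nB <- config$n_samples_b
  hapA <- 2L * nA
  hapB <- 2L * nB
  fmA <- .freq_model(hapA)
  rate_a <- config$theta_background / fmA$e_het
  if (nB > 0L) {
    fmB <- .freq_model(hapB)
    rate_b <- config$theta_contrast / fmB$e_het
  }
  contigs <- names(reference$sequences)
  samples <- data.frame(
    sample_id = c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB))),
    species = rep(c("A", "B"), c(nA, nB)), stringsAsFactors = FALSE)

  # accumulate (contig, pos, genoA, genoB) segments as plain matrices
  segs <- list()
  add_seg <- function(ctg, pos, gA = NULL, gB = NULL, fixed = FALSE) {
    if (!length(pos)) return(invisible(NULL))
    if (is.null(gA)) gA <- matrix(0L, length(pos), nA)
    if (is.null(gB)) gB <- matrix(if (fixed) 2L else 0L, length(pos), nB)
    segs[[length(segs) + 1L]] <<- list(contig = rep(ctg, length(pos)),
                                       pos = pos, gA = gA, gB = gB)
    invisible(NULL)
  }
  for (ctg in contigs) {
    L <- reference$contig_lengths[[ctg]]
    pk <- config$peaks[config$peaks$contig == ctg, , drop = FALSE]
    in_any <- function(p, iv) {
      if (!nrow(iv) || !length(p)) return(rep(FALSE, length(p)))
      vapply(p, function(x) any(x > iv$start & x <= iv$start + iv$length),
             logical(1L))
    }

    # species-A background polymorphism (outside peaks)
    posA <- .draw_positions(0, L, rate_a)
    posA <- posA[!in_any(posA, pk)]
    add_seg(ctg, posA,
            gA = .assign_minor(hapA, sample(fmA$i, length(posA), TRUE, fmA$w)))

    # peak polymorphism: intermediate-frequency sites at multiplier x rate
    e_het_half <- 2 * (hapA %/% 2L) * (hapA - hapA %/% 2L) /
      (hapA * (hapA - 1))
    for (k in seq_len(nrow(pk))) {
      p1 <- pk[k, ]
      posP <- .draw_positions(p1$start, p1$start + p1$length,
                              p1$pi_multiplier * config$theta_background /
                                e_het_half)
      if (!length(posP)) next
      gP <- .assign_minor(hapA, rep(hapA %/% 2L, length(posP)))
      if (nB > 0L && (isTRUE(p1$shared_with_b) || isTRUE(p1$balanced))) {
        add_seg(ctg, posP, gA = gP,
                gB = .assign_minor(hapB, rep(hapB %/% 2L, length(posP))))
      } else {
        add_seg(ctg, posP, gA = gP)
      }
    }

    if (nB > 0L) {
      # species-B background polymorphism (genome-wide)
      posB <- .draw_positions(0, L, rate_b)
      add_seg(ctg, posB,
              gB = .assign_minor(hapB, sample(fmB$i, length(posB), TRUE, fmB$w)))

      # fixed differences (A ref / B alt), excluded from balanced peaks
      posD <- .draw_positions(0, L, config$divergence)
      posD <- posD[!in_any(posD, pk[pk$balanced, , drop = FALSE])]
      add_seg(ctg, posD, fixed = TRUE)
    }
  }

  # genetic-load layer at degenerate CDS sites
  if (!is.na(config$load_het_0fold) && !is.na(config$load_het_4fold)) {
    if (is.null(gene_models))
      stop("gene_models required when the load layer is enabled")
    dm <- classify_degeneracy(gene_models, reference)
    deg <- dm$map[dm$map$class %in% c(0L, 4L) & !dm$map$ambiguous, ]
    p <- ifelse(deg$class == 0L, config$load_het_0fold, config$load_het_4fold)
    het <- matrix(rbinom(nrow(deg) * nA, 1L, rep(p, nA)), nrow(deg), nA)
    keep <- rowSums(het) > 0L
    for (ctg in unique(deg$contig[keep])) {
      sel <- keep & deg$contig == ctg
      add_seg(ctg, deg$pos[sel], gA = het[sel, , drop = FALSE])
    }
  }

  if (!length(segs)) {
    return(.as_variant_table(
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      matrix(integer(0), 0L, nA + nB,
             dimnames = list(NULL, samples$sample_id)),
      samples))
  }
  d <- data.frame(contig = unlist(lapply(segs, `[[`, "contig")),
                  pos = unlist(lapply(segs, `[[`, "pos")),
                  stringsAsFactors = FALSE)
  geno <- cbind(do.call(rbind, lapply(segs, `[[`, "gA")),
                do.call(rbind, lapply(segs, `[[`, "gB")))
  colnames(geno) <- samples$sample_id
  keep <- !duplicated(paste(d$contig, d$pos))
  d <- d[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  storage.mode(geno) <- "integer"

  # ref allele = reference base; alt = a random different base
  ref <- character(nrow(d))
  for (ctg in unique(d$contig)) {
    sel <- d$contig == ctg
    ref[sel] <- strsplit(as.character(Biostrings::extractAt(
      reference$sequences[[ctg]],
      IRanges::IRanges(d$pos[sel], d$pos[sel]))), NULL) |>
      vapply(function(x) x[1L], character(1L))
  }
  ok <- ref %in% c("A", "C", "G", "T")   # sites inside N runs are dropped
  d <- d[ok, , drop = FALSE]
  geno <- geno[ok, , drop = FALSE]
  ref <- ref[ok]
  # alt = one of the three non-reference bases, by table lookup
  alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt <- alt_tab[cbind(match(ref, rownames(alt_tab)),
                       sample.int(3L, length(ref), replace = TRUE))]

  # force homozygosity inside ROH tracts
  for (k in seq_len(nrow(config$roh_tracts))) {
    tr <- config$roh_tracts[k, ]
    sel <- d$contig == tr$contig & d$pos > tr$start &
      d$pos <= tr$start + tr$length
    geno[sel & geno[, tr$sample] == 1L, tr$sample] <- 0L
  }
  poly <- rowSums(geno, na.rm = TRUE) > 0L   # drop sites now monomorphic
  .as_variant_table(
    data.frame(contig = d$contig, pos = d$pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)[poly, , drop = FALSE],
    geno[poly, , drop = FALSE], samples)
}

#' Simulate mappability and coverage tracks
#'
#' Clean windows get mappability near 1.0 and coverage drawn from
#' Normal(`coverage_mean`, `coverage_sd`); declared artifact windows are
#' overridden to mappability 0.5, coverage 20 or coverage 600 by type, so
#' that exactly those windows fail the downstream filters.
#'
#' @param config a [sim_config()].
#' @param reference `ref_genome` from [simulate_genome()].
#' @return list with `mappability` and `coverage` tracks (data.frames
#'   contig/start/end/value, 0-based half-open windows).
#' @export
simulate_tracks <- function(config, reference) {
  set.seed(.sub_seed(config$seed, 2L))
  ws <- config$window_size
  rows <- lapply(names(reference$sequences), function(ctg) {
    L <- reference$contig_lengths[[ctg]]
    n_win <- ceiling(L / ws)
    start <- (seq_len(n_win) - 1L) * ws
    data.frame(contig = ctg, start = start, end = pmin(start + ws, L),
               window = seq_len(n_win) - 1L, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  mp <- pmin(1, pmax(0, 1 - abs(rnorm(nrow(grid), 0, 0.01))))
  cv <- pmax(1, rnorm(nrow(grid), config$coverage_mean, config$coverage_sd))
  aw <- config$artifact_windows
  for (k in seq_len(nrow(aw))) {
    sel <- grid$contig == aw$contig[k] & grid$window == aw$window[k]
    if (aw$type[k] == "low_map") mp[sel] <- 0.5
    if (aw$type[k] == "low_cov") cv[sel] <- 20
    if (aw$type[k] == "high_cov") cv[sel] <- 600
  }
  map <- data.frame(grid[, c("contig", "start", "end")], value = mp)
  cov <- data.frame(grid[, c("contig", "start", "end")], value = cv)
  list(mappability = map, coverage = cov)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_genotypes()]
#' and [simulate_tracks()] and collecting the injected truth (peak windows,
#' ROH tracts, artifact windows) for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with `reference`, `genes`, `variants`, `tracks`, `truth`
#'   and the `config` itself.
#' @export
simulate_dataset <- function(config) {
  gen <- simulate_genome(config)
  variants <- simulate_genotypes(config, gen$reference, gen$genes)
  tracks <- simulate_tracks(config, gen$reference)
  ws <- config$window_size
  truth_peaks <- if (nrow(config$peaks)) {
    data.frame(contig = config$peaks$contig,
               window_first = as.integer(config$peaks$start %/% ws),
               window_last = as.integer(
                 (config$peaks$start + config$peaks$length - 1) %/% ws),
               pi_multiplier = config$peaks$pi_multiplier,
               shared_with_b = config$peaks$shared_with_b,
               balanced = config$peaks$balanced)
  } else {
    data.frame(contig = character(0), window_first = integer(0),
               window_last = integer(0), pi_multiplier = numeric(0),
               shared_with_b = logical(0), balanced = logical(0))
  }
  list(reference = gen$reference, genes = gen$genes, variants = variants,
       tracks = tracks,
       truth = list(peaks = truth_peaks, roh_tracts = config$roh_tracts,
                    artifact_windows = config$artifact_windows),
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, GFF3, VCF, two BedGraph tracks and machine-readable truth
#' TSVs into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference$sequences,
                              file.path(dir, "reference.fa"))
  write_gene_models_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_variant_vcf(sim$variants, file.path(dir, "genotypes.vcf"))
  write_track_bedgraph(sim$tracks$mappability,
                       file.path(dir, "mappability.bedgraph"))
  write_track_bedgraph(sim$tracks$coverage, file.path(dir, "coverage.bedgraph"))
  for (nm in names(sim$truth)) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
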