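# Degeneracy classification, load ratio, effect categories.

test_that("canonical codons classify as expected", {
  set.seed(81)
  tg <- make_toy_gene("ATGGGATAA", strand = "+", split_at = 3L)
  dm <- classify_degeneracy(tg$genes, tg$reference)
  # ATG: all three positions 0-fold; GGA: 0, 0, 4-fold
  expect_equal(dm$map$class[1:3], c(0L, 0L, 0L))
  expect_equal(dm$map$class[4:6], c(0L, 0L, 4L))
  expect_equal(dm$map$class, oracle_degeneracy(tg$cds))
})

test_that("degeneracy map matches the substitution-translation oracle", {
  set.seed(82)
  for (i in 1:10) {
    cds <- random_cds(sample(10:40, 1))
    strand <- sample(c("+", "-"), 1)
    split_at <- sample(seq(3L, nchar(cds) - 3L), 1)
    tg <- make_toy_gene(cds, strand = strand, split_at = split_at)
    dm <- classify_degeneracy(tg$genes, tg$reference)
    # map rows are emitted in translation order
    expect_equal(dm$map$class, oracle_degeneracy(cds),
                 label = sprintf("gene %d (%s, split %d)", i, strand,
                                 split_at))
    expect_equal(sum(dm$totals), nchar(cds))
  }
})

test_that("genes with internal stop codons are excluded and reported", {
  set.seed(83)
  cds <- random_cds(12)
  substr(cds, 16, 18) <- "TAA"   # internal stop at codon 6
  tg <- make_toy_gene(cds, strand = "+", split_at = 9L)
  dm <- classify_degeneracy(tg$genes, tg$reference)
  expect_equal(dm$excluded_genes, "g1")
  expect_equal(nrow(dm$map), 0)
})

test_that("effect classification follows the impact table", {
  set.seed(84)
  # + strand gene, exon1 = ATG TAC GAA, exon2 = CTG TGG TGG TAA
  cds <- paste0("ATGTACGAACTG", "TGGTGG", "TAA")
  tg <- make_toy_gene(cds, strand = "+", split_at = 9L)
  s <- tg$cds_start
  intron <- 30L
  # codon 2 TAC -> TAA: stop gained (genomic pos s+5, third codon base)
  expect_equal(classify_effect(list(contig = "c1", pos = s + 5L,
                                    ref = "C", alt = "A"),
                               tg$genes, tg$reference), "High")
  # codon 3 GAA -> GAT (Glu -> Asp): missense (third base, still in exon 1)
  expect_equal(classify_effect(list(contig = "c1", pos = s + 8L,
                                    ref = "A", alt = "T"),
                               tg$genes, tg$reference), "Moderate")
  # codon 4 CTG -> CTA (Leu -> Leu): synonymous (base 12, in exon 2)
  expect_equal(classify_effect(list(contig = "c1", pos = s + intron + 11L,
                                    ref = "G", alt = "A"),
                               tg$genes, tg$reference), "Low")
  # start codon ATG -> ACG: start lost
  expect_equal(classify_effect(list(contig = "c1", pos = s + 1L,
                                    ref = "T", alt = "C"),
                               tg$genes, tg$reference), "High")
  # first intronic base after exon 1: splice donor
  expect_equal(classify_effect(list(contig = "c1", pos = s + 9L,
                                    ref = "G", alt = "C"),
                               tg$genes, tg$reference), "High")
  # intergenic: modifier
  ref5 <- lowdivscan:::.ref_base(tg$reference, "c1", 5L)
  expect_equal(classify_effect(list(contig = "c1", pos = 5L, ref = ref5,
                                    alt = setdiff(c("A", "C", "G", "T"),
                                                  ref5)[1]),
                               tg$genes, tg$reference), "Modifier")
  # alt equal to ref is rejected
  expect_error(classify_effect(list(contig = "c1", pos = s + 5L,
                                    ref = "C", alt = "C"),
                               tg$genes, tg$reference), "equals reference")
})

test_that("effect categories are consistent with degeneracy classes", {
  set.seed(85)
  tg <- make_toy_gene(random_cds(30), strand = "-", split_at = 33L)
  dm <- classify_degeneracy(tg$genes, tg$reference)
  idx <- lowdivscan:::.cds_index(tg$genes, tg$reference)
  n_cod <- idx$n_codons[1]
  cand <- which(dm$map$class %in% c(0L, 4L) &
                  idx$codon_idx > 1L & idx$codon_idx < n_cod)
  for (k in sample(cand, min(40L, length(cand)))) {
    pos <- dm$map$pos[k]
    ref <- lowdivscan:::.ref_base(tg$reference, "c1", pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      eff <- classify_effect(list(contig = "c1", pos = pos, ref = ref,
                                  alt = alt), tg$genes, tg$reference)
      if (dm$map$class[k] == 4L) {
        expect_equal(eff, "Low")                     # 4-fold: never changes AA
      } else {
        expect_true(eff %in% c("Moderate", "High"))  # 0-fold: always changes
      }
    }
  }
})

test_that("load ratio counts heterozygotes at 0/4-fold sites", {
  set.seed(86)
  tg <- make_toy_gene(random_cds(60), strand = "+", split_at = 60L)
  dm <- classify_degeneracy(tg$genes, tg$reference)
  p0 <- dm$map$pos[dm$map$class == 0L]
  p4 <- dm$map$pos[dm$map$class == 4L]
  pos <- sort(c(sample(p0, 10), sample(p4, 5)))
  vt <- make_vt(data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
                matrix(1L, length(pos), 1))
  lr <- load_ratio(dm, vt, "S1")
  expect_equal(lr$het0, 10)
  expect_equal(lr$het4, 5)
  expect_equal(lr$ratio, (10 / length(p0)) / (5 / length(p4)))

  # swapping which class is labelled 0 vs 4 inverts the ratio
  dm_swap <- dm
  dm_swap$map$class <- ifelse(dm$map$class == 0L, 4L,
                              ifelse(dm$map$class == 4L, 0L, dm$map$class))
  lr_swap <- load_ratio(dm_swap, vt, "S1")
  expect_equal(lr_swap$ratio, 1 / lr$ratio, tolerance = 1e-12)

  # no coding heterozygote: NA ratio with a warning
  vt0 <- vt
  vt0$geno[, 1] <- 0L
  expect_warning(lr0 <- load_ratio(dm, vt0, "S1"), "undefined")
  expect_true(is.na(lr0$ratio))
  expect_equal(lr0$het0, 0)
})

test_that("simulated load layer recovers the configured 0/4-fold rate ratio", {
  cfg <- sim_config(seed = 87, n_contigs = 1, contig_length = 5e5,
                    n_genes = 60, n_samples_b = 0,
                    load_het_0fold = 0.1, load_het_4fold = 0.2)
  sim <- simulate_dataset(cfg)
  dm <- classify_degeneracy(sim$genes, sim$reference)
  lr <- load_ratio(dm, sim$variants, "A1")
  expect_gt(lr$het0 + lr$het4, 2000)
  expect_lt(abs(lr$ratio - 0.5) / 0.5, 0.15)
})

test_that("effect spectrum tabulates heterozygous SNVs only", {
  set.seed(88)
  # build a gene and hand-picked het variants: 1 High + 2 Moderate + 7 Low
  tg <- make_toy_gene(random_cds(120), strand = "+", split_at = 180L)
  dm <- classify_degeneracy(tg$genes, tg$reference)
  idx <- lowdivscan:::.cds_index(tg$genes, tg$reference)
  pos_low <- sample(dm$map$pos[dm$map$class == 4L], 7)
  pos_mod <- sample(dm$map$pos[dm$map$class == 0L & idx$codon_pos == 2L &
                                 idx$codon_idx > 1L], 2)
  splice_pos <- tg$genes$cds$end[1] + 1L   # splice donor
  pos <- c(splice_pos, pos_mod, pos_low)
  ref <- vapply(pos, function(p)
    lowdivscan:::.ref_base(tg$reference, "c1", p), character(1))
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1), USE.NAMES = FALSE)
  ord <- order(pos)
  geno <- matrix(c(rep(1L, length(pos)), rep(0L, length(pos))), ncol = 2)
  vt <- make_vt(data.frame(contig = "c1", pos = pos[ord], ref = ref[ord],
                           alt = alt[ord], stringsAsFactors = FALSE),
                geno)
  sp <- effect_spectrum(vt, "S1", tg$genes, tg$reference)
  expect_equal(unname(sp$counts[c("High", "Moderate", "Low")]),
               c(1L, 2L, 7L))
  expect_equal(unname(sp$ratios), c(0.1, 0.2, 0.7))
  # every classified SNV falls in exactly one of the four categories
  expect_equal(sum(sp$counts), length(pos))

  # the hom-ref sample has no heterozygous SNVs at all
  sp0 <- effect_spectrum(vt, "S2", tg$genes, tg$reference)
  expect_equal(sum(sp0$counts), 0)
  expect_true(all(is.na(sp0$ratios)))
})

test_that("a higher 0-fold rate yields a higher Moderate fraction", {
  cfg_hi <- sim_config(seed = 89, n_contigs = 1, contig_length = 3e5,
                       n_genes = 30, n_samples_b = 0,
                       load_het_0fold = 0.10, load_het_4fold = 0.05)
  cfg_lo <- sim_config(seed = 89, n_contigs = 1, contig_length = 3e5,
                       n_genes = 30, n_samples_b = 0,
                       load_het_0fold = 0.02, load_het_4fold = 0.10)
  sim_hi <- simulate_dataset(cfg_hi)
  sim_lo <- simulate_dataset(cfg_lo)
  sp_hi <- effect_spectrum(sim_hi$variants, "A1", sim_hi$genes,
                           sim_hi$reference)
  sp_lo <- effect_spectrum(sim_lo$variants, "A1", sim_lo$genes,
                           sim_lo$reference)
  expect_gt(sp_hi$ratios[["Moderate"]], sp_lo$ratios[["Moderate"]])
})
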