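# In-code fixture builders shared across test files.

make_ref <- function(seqs) {
  lowdivscan:::.as_ref_genome(Biostrings::DNAStringSet(seqs))
}

make_genes <- function(cds) {
  lowdivscan:::.as_gene_models(cds)
}

make_vt <- function(sites, geno, species = NULL) {
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%d", seq_len(ncol(geno)))
  species <- species %||% rep("A", ncol(geno))
  lowdivscan:::.as_variant_table(
    sites, geno,
    data.frame(sample_id = colnames(geno), species = species,
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fake_peak_set <- function(regions = NULL, windows = NULL) {
  structure(list(regions = regions %||%
                   data.frame(contig = character(0), start = numeric(0),
                              end = numeric(0), n_windows = integer(0)),
                 windows = windows %||%
                   data.frame(contig = character(0), window = integer(0))),
            class = "peak_set")
}

# random variant table on one contig: n_sites sites, n_ind diploids,
# genotypes uniform over 0/1/2 with optional missingness
random_vt <- function(n_sites, n_ind, contig_len, missing_rate = 0,
                      species = NULL, contig = "c1") {
  pos <- sort(sample.int(contig_len, n_sites))
  geno <- matrix(sample(0:2, n_sites * n_ind, TRUE), n_sites, n_ind)
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  sites <- data.frame(contig = contig, pos = pos,
                      ref = sample(c("A", "C", "G", "T"), n_sites, TRUE),
                      alt = "N", stringsAsFactors = FALSE)
  sites$alt <- ifelse(sites$ref == "A", "G", "A")
  make_vt(sites, geno, species = species)
}

# a toy two-exon gene planted into a random sequence; returns the reference,
# the gene models and the spliced CDS string, mirroring the planted layout
make_toy_gene <- function(cds, strand = "+", split_at = NULL,
                          intron_length = 30L, offset = 100L,
                          flank = 200L, gene_id = "g1", contig = "c1") {
  L <- nchar(cds)
  stopifnot(L %% 3L == 0L)
  split_at <- split_at %||% (3L * (L %/% 6L))
  revcomp <- lowdivscan:::.revcomp
  exon1 <- substr(cds, 1L, split_at)
  exon2 <- substr(cds, split_at + 1L, L)
  intron <- paste0("GT", strrep("A", intron_length - 4L), "AG")
  span <- L + intron_length
  phase2 <- (3L - split_at %% 3L) %% 3L
  s <- offset + 1L
  if (strand == "+") {
    genomic <- paste0(exon1, intron, exon2)
    seg <- data.frame(gene_id = gene_id, contig = contig, strand = strand,
                      start = c(s, s + split_at + intron_length),
                      end = c(s + split_at - 1L, s + span - 1L),
                      phase = c(0L, phase2), stringsAsFactors = FALSE)
  } else {
    len2 <- L - split_at
    genomic <- paste0(revcomp(exon2), revcomp(intron), revcomp(exon1))
    seg <- data.frame(gene_id = gene_id, contig = contig, strand = strand,
                      start = c(s, s + len2 + intron_length),
                      end = c(s + len2 - 1L, s + span - 1L),
                      phase = c(phase2, 0L), stringsAsFactors = FALSE)
  }
  before <- paste(sample(c("A", "C", "G", "T"), offset, TRUE), collapse = "")
  after <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  ref <- make_ref(setNames(paste0(before, genomic, after), contig))
  list(reference = ref, genes = make_genes(seg), cds = cds,
       cds_start = s, span = span)
}

# random CDS string: ATG + non-stop codons + one stop
random_cds <- function(n_codons) {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
  body <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(body, n_codons - 2L, TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}
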