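# Readers and writers for the standard formats the scan touches.
#
# Coordinate conventions: interval objects (windows, peak regions, ROH
# intervals, BED, BedGraph) are 0-based half-open; point coordinates of
# variant sites and CDS segments are 1-based inclusive, as in VCF/GFF3.

#' Read a reference genome from FASTA
#'
#' Loads a (possibly N-gapped) assembly, uppercases it, converts IUPAC
#' ambiguity codes other than A/C/G/T to N, and records the N-run mask.
#' The effective length is the total length minus the number of N sites;
#' it is the denominator of per-bp heterozygosity.
#'
#' @param fasta_path path to a FASTA file.
#' @return an object of class `ref_genome`: a list with `sequences`
#'   (named [Biostrings::DNAStringSet]), `n_mask` (per-contig data.frame of
#'   0-based half-open N runs), `contig_lengths`, `total_length` and
#'   `effective_length`.
#' @export
read_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  # first token of the header is the contig name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig name in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1L])
  .as_ref_genome(seqs)
}

# build a ref_genome from an in-memory DNAStringSet
.as_ref_genome <- function(seqs) {
  nm <- names(seqs)
  chr <- toupper(as.character(seqs))
  chr <- vapply(chr, function(s) gsub("[^ACGT]", "N", s), character(1L),
                USE.NAMES = FALSE)
  names(chr) <- nm
  seqs <- Biostrings::DNAStringSet(chr)
  n_mask <- lapply(chr, function(s) {
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) {
      data.frame(start = integer(0), end = integer(0))
    } else {
      data.frame(start = as.integer(m) - 1L,
                 end = as.integer(m) - 1L + attr(m, "match.length"))
    }
  })
  lens <- Biostrings::width(seqs)
  n_count <- sum(vapply(n_mask, function(d) sum(d$end - d$start), numeric(1)))
  out <- list(sequences = seqs,
              n_mask = n_mask,
              contig_lengths = setNames(as.numeric(lens), names(seqs)),
              total_length = sum(as.numeric(lens)),
              effective_length = sum(as.numeric(lens)) - n_count)
  class(out) <- "ref_genome"
  out
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Reference genome:", length(x$sequences), "contig(s),",
      format(x$total_length, big.mark = ","), "bp total,",
      format(x$effective_length, big.mark = ","), "bp effective (non-N)\n")
  invisible(x)
}

# reference base(s) at 1-based positions
.ref_base <- function(reference, contig, pos) {
  s <- reference$sequences[[contig]]
  as.character(Biostrings::extractAt(s, IRanges::IRanges(pos, pos)))
}

#' Read gene models (CDS chains) from GFF3
#'
#' Keeps `CDS` features, grouped into genes by their `Parent` attribute
#' (falling back to `ID` when no parent is given). Coordinates are kept
#' 1-based inclusive as in GFF3.
#'
#' @param gff_path path to a GFF3 file with CDS features carrying phase.
#' @return an object of class `gene_models`: a list with `cds` (data.frame
#'   gene_id/contig/strand/start/end/phase) and `genes` (data.frame
#'   gene_id/contig/strand/start/end/cds_length/n_segments).
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gff_path)
  parent <- as.character(gr$Parent)
  parent[parent == "character(0)" | is.na(parent) | parent == ""] <-
    as.character(gr$ID)[parent == "character(0)" | is.na(parent) | parent == ""]
  cds <- data.frame(
    gene_id = sub("^(transcript|mRNA|gene):", "", parent),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    phase = as.integer(gr$phase),
    stringsAsFactors = FALSE)
  .as_gene_models(cds)
}

.as_gene_models <- function(cds) {
  if (!all(cds$strand %in% c("+", "-")))
    stop("CDS strand must be '+' or '-'")
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  # non-overlap within gene
  by_gene <- split(cds, cds$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("overlapping CDS segments within gene ", g$gene_id[1L])
  }
  genes <- do.call(rbind, lapply(by_gene, function(g) {
    data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
               strand = g$strand[1L], start = min(g$start), end = max(g$end),
               cds_length = sum(g$end - g$start + 1L),
               n_segments = nrow(g), stringsAsFactors = FALSE)
  })) %||% data.frame(gene_id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), cds_length = integer(0),
                      n_segments = integer(0))
  rownames(genes) <- NULL
  out <- list(cds = cds, genes = genes)
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "gene(s),",
      sum(x$genes$cds_length), "bp of CDS\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' @param gene_models a `gene_models` object.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gene_models$genes))) {
    g <- gene_models$genes[i, ]
    writeLines(sprintf("%s\tlowdivscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start, g$end, g$strand, g$gene_id), con)
    seg <- gene_models$cds[gene_models$cds$gene_id == g$gene_id, ]
    writeLines(sprintf("%s\tlowdivscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
                       seg$contig, seg$start, seg$end, seg$strand, seg$phase,
                       seg$gene_id, seg$gene_id), con)
  }
  invisible(path)
}

#' Read diploid genotypes from VCF
#'
#' Parses a VCF with GT fields, retaining only bi-allelic SNVs. Multi-allelic
#' and indel records are dropped and counted in the parse log
#' (`attr(x, "log")`). Genotypes are treated as unphased; only zygosity is
#' used downstream.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param sample_species named character vector mapping sample name to
#'   species label; every name must be present in the VCF.
#' @param reference optional `ref_genome`; when given, the REF allele of each
#'   retained record is checked against the reference sequence.
#' @return an object of class `variant_table`: a list with `sites`
#'   (data.frame contig/pos/ref/alt, pos 1-based), `geno` (integer matrix,
#'   sites x samples, 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing) and
#'   `samples` (data.frame sample_id/species).
#' @export
read_genotypes <- function(vcf_path, sample_species, reference = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1L, drop = FALSE]
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(names(sample_species), vcf_samples)
  if (length(missing_samples))
    stop("sample(s) absent from VCF: ", paste(missing_samples, collapse = ", "))
  gt <- gt[, names(sample_species), drop = FALSE]

  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_snv <- !is_multi & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  log <- list(n_records = nrow(fix),
              n_multiallelic = sum(is_multi),
              n_non_snv = sum(!is_snv & !is_multi),
              n_kept = sum(is_snv))
  fix <- fix[is_snv, , drop = FALSE]
  gt <- gt[is_snv, , drop = FALSE]

  # GT is the first colon-separated subfield
  gt_codes <- sub(":.*$", "", gt)
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  geno[gt_codes %in% c("0/0", "0|0")] <- 0L
  geno[gt_codes %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt_codes %in% c("1/1", "1|1")] <- 2L

  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  vt <- .as_variant_table(sites, geno,
                          data.frame(sample_id = names(sample_species),
                                     species = unname(sample_species),
                                     stringsAsFactors = FALSE))
  if (!is.null(reference)) {
    for (ctg in unique(vt$sites$contig)) {
      sel <- vt$sites$contig == ctg
      obs <- strsplit(as.character(Biostrings::extractAt(
        reference$sequences[[ctg]],
        IRanges::IRanges(vt$sites$pos[sel], vt$sites$pos[sel]))), NULL)
      obs <- unlist(obs)
      bad <- obs != vt$sites$ref[sel]
      if (any(bad))
        stop("REF allele mismatch with reference at ", ctg, ":",
             vt$sites$pos[sel][bad][1L])
    }
  }
  attr(vt, "log") <- log
  vt
}

.as_variant_table <- function(sites, geno, samples) {
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  if (anyDuplicated(paste(sites$contig, sites$pos)))
    stop("positions must be strictly increasing within contig (duplicate site)")
  out <- list(sites = sites, geno = geno, samples = samples)
  class(out) <- "variant_table"
  out
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x$sites), "bi-allelic SNV site(s),",
      nrow(x$samples), "sample(s) [",
      paste(sprintf("%s:%d", names(table(x$samples$species)),
                    as.integer(table(x$samples$species))), collapse = ", "),
      "]\n")
  invisible(x)
}

#' Write a variant table as VCF 4.2
#'
#' Minimal writer used by the simulator: fixed columns plus unphased GT.
#'
#' @param variant_table a `variant_table`.
#' @param path output path (plain text).
#' @export
write_variant_vcf <- function(variant_table, path) {
  vt <- variant_table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lowdivscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$samples$sample_id),
                     collapse = "\t")), con)
  if (nrow(vt$sites)) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(vt$geno), ncol(vt$geno))
    ok <- !is.na(vt$geno)
    gt[ok] <- code[vt$geno[ok] + 1L]
    lines <- paste(vt$sites$contig, vt$sites$pos, ".", vt$sites$ref,
                   vt$sites$alt, ".", "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a window table as BED
#'
#' Intervals are emitted 0-based half-open with the per-window diversity,
#' SNV count and filter status as extra columns.
#'
#' @param window_table data.frame with columns contig/start/end/pi/n_snvs/status.
#' @param path output path.
#' @export
write_window_bed <- function(window_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tpi\tn_snvs\tstatus", con)
  if (nrow(window_table)) {
    writeLines(paste(window_table$contig,
                     format(window_table$start, scientific = FALSE, trim = TRUE),
                     format(window_table$end, scientific = FALSE, trim = TRUE),
                     format(window_table$pi, digits = 10, trim = TRUE),
                     window_table$n_snvs, window_table$status,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a window BED written by [write_window_bed()]
#'
#' @param path path to the BED file.
#' @return data.frame with contig/start/end/pi/n_snvs/status.
#' @export
read_window_bed <- function(path) {
  cols <- c("contig", "start", "end", "pi", "n_snvs", "status")
  first <- readLines(path, n = 2L)
  if (length(first) < 2L)
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), pi = numeric(0),
                      n_snvs = integer(0), status = character(0)))
  d <- read.table(path, sep = "\t", comment.char = "#",
                  col.names = cols, stringsAsFactors = FALSE)
  d
}

#' Write a per-window track as BedGraph
#'
#' @param track data.frame with contig/start/end/value (0-based half-open).
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  write.table(track[, c("contig", "start", "end", "value")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BedGraph track
#'
#' @param path path to a 4-column BedGraph (no track line).
#' @return data.frame with contig/start/end/value.
#' @export
read_track_bedgraph <- function(path) {
  read.table(path, sep = "\t", col.names = c("contig", "start", "end", "value"),
             stringsAsFactors = FALSE)
}
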