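# Degenerate-site classification, the 0-fold/4-fold heterozygosity load
# ratio, and High/Moderate/Low coding-effect categorisation of SNVs.

.BASES <- c("A", "C", "G", "T")

# fold class of each codon position for all 64 codons: number of bases at
# that position encoding the same amino acid (1 -> class 0)
.codon_degeneracy_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc_map <- Biostrings::GENETIC_CODE
    codons <- names(gc_map)
    m <- matrix(0L, length(codons), 3L, dimnames = list(codons, NULL))
    for (cod in codons) {
      for (p in 1:3) {
        variants <- vapply(.BASES, function(b) {
          x <- strsplit(cod, NULL)[[1L]]
          x[p] <- b
          paste(x, collapse = "")
        }, character(1L))
        f <- sum(gc_map[variants] == gc_map[[cod]])
        m[cod, p] <- if (f == 1L) 0L else f
      }
    }
    tab <<- m
    tab
  }
})

# per-CDS-position index: genomic position, gene, codon index/offset, codon
# string (in reading frame) and strand; skips genes whose CDS is not a clean
# ORF (phase-trimmed length not divisible by 3 handled by trimming)
.cds_index <- function(gene_models, reference) {
  gc_map <- Biostrings::GENETIC_CODE
  rows <- list()
  excluded <- character(0)
  n_partial <- 0L
  for (gid in gene_models$genes$gene_id) {
    seg <- gene_models$cds[gene_models$cds$gene_id == gid, , drop = FALSE]
    strand <- seg$strand[1L]
    ctg <- seg$contig[1L]
    if (strand == "+") {
      pos <- unlist(lapply(seq_len(nrow(seg)),
                           function(i) seg$start[i]:seg$end[i]))
      first_phase <- seg$phase[1L]
    } else {
      ord <- order(seg$start, decreasing = TRUE)
      pos <- unlist(lapply(ord, function(i) seg$end[i]:seg$start[i]))
      first_phase <- seg$phase[ord[1L]]
    }
    if (first_phase > 0L) pos <- pos[-seq_len(first_phase)]
    extra <- length(pos) %% 3L
    if (extra) {                       # incomplete terminal codon
      pos <- pos[seq_len(length(pos) - extra)]
      n_partial <- n_partial + extra
    }
    if (!length(pos)) next
    base <- strsplit(as.character(Biostrings::extractAt(
      reference$sequences[[ctg]], IRanges::IRanges(sort(pos), sort(pos)))),
      NULL)
    base <- vapply(base, `[`, character(1L), 1L)
    names(base) <- as.character(sort(pos))
    base <- base[as.character(pos)]    # translation order
    if (strand == "-") base <- chartr("ACGT", "TGCA", base)
    n_cod <- length(pos) %/% 3L
    codon <- vapply(seq_len(n_cod), function(k) {
      paste(base[(3L * k - 2L):(3L * k)], collapse = "")
    }, character(1L))
    if (any(!codon %in% names(gc_map))) { excluded <- c(excluded, gid); next }
    aa <- gc_map[codon]
    if (any(aa[-n_cod] == "*")) {      # internal stop codon
      excluded <- c(excluded, gid)
      next
    }
    rows[[gid]] <- data.frame(
      contig = ctg, pos = pos, gene_id = gid, strand = strand,
      codon_idx = rep(seq_len(n_cod), each = 3L),
      codon_pos = rep(1:3, n_cod),
      codon = rep(codon, each = 3L),
      n_codons = n_cod, stringsAsFactors = FALSE)
  }
  idx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), gene_id = character(0),
               strand = character(0), codon_idx = integer(0),
               codon_pos = integer(0), codon = character(0),
               n_codons = integer(0))
  rownames(idx) <- NULL
  key <- paste(idx$contig, idx$pos)
  idx$ambiguous <- key %in% key[duplicated(key)]
  attr(idx, "excluded_genes") <- unique(excluded)
  attr(idx, "n_partial_codon_sites") <- n_partial
  idx
}

#' Classify CDS positions by codon fold-degeneracy
#'
#' A CDS position is f-fold degenerate when exactly f of the 4 possible
#' bases at that codon position encode the same amino acid (f = 1 is the
#' conventional class 0: every change is nonsynonymous). Minus-strand codons
#' are read on the reverse complement; genes with internal stop codons are
#' excluded and reported; positions belonging to the CDS of more than one
#' gene are marked ambiguous.
#'
#' @param gene_models a `gene_models`.
#' @param reference a `ref_genome`.
#' @return an object of class `degeneracy_map`: list with `map` (data.frame
#'   contig/pos/gene_id/class/ambiguous), `totals` (counts per class over
#'   unambiguous positions), `per_gene`, `excluded_genes` and
#'   `n_partial_codon_sites`.
#' @export
classify_degeneracy <- function(gene_models, reference) {
  idx <- .cds_index(gene_models, reference)
  deg <- .codon_degeneracy_table()
  cls <- integer(nrow(idx))
  if (nrow(idx))
    cls <- deg[cbind(match(idx$codon, rownames(deg)), idx$codon_pos)]
  map <- data.frame(contig = idx$contig, pos = idx$pos,
                    gene_id = idx$gene_id, class = cls,
                    ambiguous = idx$ambiguous, stringsAsFactors = FALSE)
  un <- map[!map$ambiguous, , drop = FALSE]
  totals <- setNames(vapply(c(0L, 2L, 3L, 4L),
                            function(k) sum(un$class == k), integer(1L)),
                     c("fold0", "fold2", "fold3", "fold4"))
  per_gene <- do.call(rbind, lapply(split(map, map$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L],
               fold0 = sum(g$class == 0L), fold2 = sum(g$class == 2L),
               fold3 = sum(g$class == 3L), fold4 = sum(g$class == 4L),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  out <- list(map = map, totals = totals, per_gene = per_gene,
              excluded_genes = attr(idx, "excluded_genes"),
              n_partial_codon_sites = attr(idx, "n_partial_codon_sites"))
  class(out) <- "degeneracy_map"
  out
}

#' @export
print.degeneracy_map <- function(x, ...) {
  cat("Degeneracy map:", nrow(x$map), "CDS position(s); ",
      paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", "),
      "\n")
  if (length(x$excluded_genes))
    cat("  excluded (internal stop):",
        paste(x$excluded_genes, collapse = ", "), "\n")
  invisible(x)
}

#' 0-fold/4-fold heterozygosity load ratio
#'
#' Counts one sample's heterozygous calls at unambiguous 0-fold and 4-fold
#' degenerate CDS positions and forms the per-site-normalised ratio
#' `(het0 / n 0-fold sites) / (het4 / n 4-fold sites)`, a proxy for the
#' efficacy of purifying selection: the more nonsynonymous heterozygosity
#' survives relative to synonymous, the heavier the genetic load.
#'
#' @param degeneracy_map a [classify_degeneracy()] result.
#' @param variant_table a `variant_table`.
#' @param sample sample name.
#' @return list with `het0`, `het4`, `n0_sites`, `n4_sites`, `ratio`
#'   (NA with a warning when no 4-fold heterozygote exists).
#' @export
load_ratio <- function(degeneracy_map, variant_table, sample) {
  vt <- variant_table
  if (!sample %in% colnames(vt$geno)) stop("unknown sample: ", sample)
  het <- vt$sites[!is.na(vt$geno[, sample]) & vt$geno[, sample] == 1L, ,
                  drop = FALSE]
  map <- degeneracy_map$map
  map <- map[!map$ambiguous, , drop = FALSE]
  key0 <- paste(map$contig, map$pos)[map$class == 0L]
  key4 <- paste(map$contig, map$pos)[map$class == 4L]
  hk <- paste(het$contig, het$pos)
  het0 <- sum(hk %in% key0)
  het4 <- sum(hk %in% key4)
  n0 <- length(key0)
  n4 <- length(key4)
  if (het4 == 0) {
    warning("no heterozygous 4-fold site for sample ", sample,
            "; ratio undefined")
    ratio <- NA_real_
  } else {
    ratio <- (het0 / n0) / (het4 / n4)
  }
  list(het0 = het0, het4 = het4, n0_sites = n0, n4_sites = n4, ratio = ratio)
}

# vectorized effect classification of SNVs against a CDS index
.classify_effects <- function(sites, idx, splice_keys, reference) {
  gc_map <- Biostrings::GENETIC_CODE
  out <- rep("Modifier", nrow(sites))
  skey <- paste(sites$contig, sites$pos)
  out[skey %in% splice_keys] <- "High"
  hit <- match(skey, paste(idx$contig, idx$pos))
  in_cds <- !is.na(hit) & out == "Modifier"
  if (any(in_cds)) {
    h <- idx[hit[in_cds], , drop = FALSE]
    alt <- sites$alt[in_cds]
    alt_cod <- ifelse(h$strand == "-", chartr("ACGT", "TGCA", alt), alt)
    codon_alt <- h$codon
    substr(codon_alt, h$codon_pos, h$codon_pos) <- alt_cod
    aa_ref <- gc_map[h$codon]
    aa_alt <- gc_map[codon_alt]
    cat_cds <- ifelse(
      h$codon_idx == 1L & h$codon == "ATG" & codon_alt != "ATG",
      "High",                                              # start lost
      ifelse(aa_ref != "*" & aa_alt == "*", "High",        # stop gained
      ifelse(aa_ref == "*" & aa_alt != "*", "High",        # stop lost
      ifelse(aa_ref == aa_alt, "Low", "Moderate"))))
    out[in_cds] <- cat_cds
  }
  out
}

# genomic keys of the 2 intronic bases flanking every CDS junction
.splice_site_keys <- function(gene_models) {
  keys <- character(0)
  for (gid in gene_models$genes$gene_id) {
    seg <- gene_models$cds[gene_models$cds$gene_id == gid, , drop = FALSE]
    if (nrow(seg) < 2L) next
    for (i in seq_len(nrow(seg) - 1L)) {
      int_start <- seg$end[i] + 1L
      int_end <- seg$start[i + 1L] - 1L
      if (int_end < int_start) next
      p <- unique(c(int_start, min(int_start + 1L, int_end),
                    max(int_end - 1L, int_start), int_end))
      keys <- c(keys, paste(seg$contig[1L], p))
    }
  }
  keys
}

#' Functional-effect category of a single SNV
#'
#' SnpEff-style impact classes: `High` for stop gained, start lost, stop
#' lost and variants within the 2 intronic bases flanking a CDS junction
#' (splice donor/acceptor); `Moderate` for missense; `Low` for synonymous
#' and stop-retained; `Modifier` for everything non-coding.
#'
#' @param variant one-row data.frame (or list) with contig, pos, ref, alt.
#' @param gene_models a `gene_models`.
#' @param reference a `ref_genome`.
#' @return one of `"High"`, `"Moderate"`, `"Low"`, `"Modifier"`.
#' @export
classify_effect <- function(variant, gene_models, reference) {
  v <- as.data.frame(variant, stringsAsFactors = FALSE)
  if (v$alt == v$ref) stop("variant allele equals reference")
  ref_obs <- .ref_base(reference, v$contig, v$pos)
  if (ref_obs != v$ref)
    stop("variant ref allele does not match reference at ", v$contig, ":",
         v$pos)
  idx <- .cds_index(gene_models, reference)
  idx <- idx[!idx$ambiguous, , drop = FALSE]
  .classify_effects(v, idx, .splice_site_keys(gene_models), reference)
}

#' Coding-effect spectrum of one sample's heterozygous SNVs
#'
#' Classifies every heterozygous SNV of a sample and tabulates the four
#' impact categories; ratios are normalised over the coding classes
#' High/Moderate/Low only (Modifier excluded), as in load comparisons
#' between genomes.
#'
#' @param variant_table a `variant_table`.
#' @param sample sample name.
#' @param gene_models a `gene_models`.
#' @param reference a `ref_genome`.
#' @return list with `counts` (named High/Moderate/Low/Modifier) and
#'   `ratios` (High/Moderate/Low fractions; NaN-free only when a coding
#'   het SNV exists).
#' @export
effect_spectrum <- function(variant_table, sample, gene_models, reference) {
  vt <- variant_table
  if (!sample %in% colnames(vt$geno)) stop("unknown sample: ", sample)
  het <- vt$sites[!is.na(vt$geno[, sample]) & vt$geno[, sample] == 1L, ,
                  drop = FALSE]
  idx <- .cds_index(gene_models, reference)
  idx <- idx[!idx$ambiguous, , drop = FALSE]
  cats <- if (nrow(het))
    .classify_effects(het, idx, .splice_site_keys(gene_models), reference)
  else character(0)
  lv <- c("High", "Moderate", "Low", "Modifier")
  counts <- setNames(vapply(lv, function(k) sum(cats == k), integer(1L)), lv)
  coding <- sum(counts[c("High", "Moderate", "Low")])
  ratios <- if (coding > 0) counts[c("High", "Moderate", "Low")] / coding
  else setNames(rep(NA_real_, 3L), c("High", "Moderate", "Low"))
  list(counts = counts, ratios = ratios)
}
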