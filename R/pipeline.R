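# End-to-end orchestration: simulate -> scan -> fst -> load -> roh ->
# overlap, with persisted intermediates and a consolidated report.

#' Run the full genome-scan pipeline on a simulated dataset
#'
#' Executes the stages in dependency order on a dataset simulated from
#' `config` (or on a pre-built dataset): windowed diversity of the focal
#' species, mappability/coverage filtration, peak detection, polymorphic
#' genes, per-sample heterozygosity, degeneracy and load summaries, window
#' F_ST with the peak-vs-background shift test, ROH calling with F_ROH, the
#' contrast-species peak scan and the shared-peak Monte Carlo test. Stages
#' needing the contrast species are skipped with a notice when it has no
#' samples. The report is deterministic for a fixed config.
#'
#' @param config a [sim_config()]; ignored when `dataset` is supplied.
#' @param dataset optional result of [simulate_dataset()].
#' @param out_dir optional directory; when given, every intermediate table
#'   is persisted (window BED, peak BED, F_ST TSV, ROH BED, report TSVs).
#' @param k_sd peak threshold in SDs above the mean.
#' @param min_map,cov_low,cov_high window filter thresholds.
#' @param polymorphic_threshold CDS SNV proportion cutoff for polymorphic
#'   genes.
#' @param roh a [roh_params()].
#' @param mc_reps Monte Carlo replicates for the shared-peak test.
#' @return an object of class `lowdiv_report`.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         out_dir = NULL, k_sd = 4, min_map = 0.8,
                         cov_low = 40, cov_high = 400,
                         polymorphic_threshold = 0.01,
                         roh = roh_params(), mc_reps = 1e5) {
  sim <- dataset %||% simulate_dataset(config)
  config <- sim$config
  vt <- sim$variants
  ref <- sim$reference
  ws <- config$window_size
  samples_a <- vt$samples$sample_id[vt$samples$species == "A"]
  samples_b <- vt$samples$sample_id[vt$samples$species == "B"]
  notices <- character(0)

  # focal-species diversity scan
  wt <- window_pi(vt, ref, ws, samples = samples_a)
  wt <- filter_windows(wt, sim$tracks$mappability, sim$tracks$coverage,
                       min_map = min_map, cov_low = cov_low,
                       cov_high = cov_high)
  peaks_a <- detect_peaks(wt, k = k_sd)
  poly_genes <- polymorphic_genes(peaks_a, sim$genes, vt,
                                  threshold = polymorphic_threshold,
                                  samples = samples_a)

  het <- vapply(vt$samples$sample_id, function(s)
    individual_heterozygosity(vt, s, ref$effective_length), numeric(1))

  dmap <- classify_degeneracy(sim$genes, ref)
  load <- lapply(setNames(nm = samples_a), function(s)
    suppressWarnings(load_ratio(dmap, vt, s)))
  spectrum <- lapply(setNames(nm = samples_a), function(s)
    effect_spectrum(vt, s, sim$genes, ref))

  roh_calls <- lapply(setNames(nm = samples_a), function(s)
    call_roh(vt, s, ref$total_length, roh))

  fst <- NULL
  shift <- NULL
  overlap <- NULL
  peaks_b <- NULL
  if (length(samples_b)) {
    fst <- window_fst(vt, peaks_a$window_table)
    shift <- tryCatch(peak_background_shift(fst, peaks_a),
                      error = function(e) {
                        notices <<- c(notices, paste("shift test skipped:",
                                                     conditionMessage(e)))
                        NULL
                      })
    wt_b <- window_pi(vt, ref, ws, samples = samples_b)
    wt_b <- filter_windows(wt_b, sim$tracks$mappability, sim$tracks$coverage,
                           min_map = min_map, cov_low = cov_low,
                           cov_high = cov_high)
    peaks_b <- detect_peaks(wt_b, k = k_sd)
    n_pass <- sum(wt$status == "pass")
    shared <- shared_peak_count(peaks_a, peaks_b)
    if (nrow(peaks_a$windows) && nrow(peaks_b$windows)) {
      overlap <- mc_overlap_pvalue(n_pass, nrow(peaks_a$windows),
                                   nrow(peaks_b$windows), shared,
                                   n_reps = mc_reps,
                                   seed = .sub_seed(config$seed, 3L))
    } else {
      notices <- c(notices, "overlap test skipped: a species has no peaks")
    }
  } else {
    notices <- c(notices,
                 "fst/overlap stages skipped: no contrast-species samples")
  }

  report <- list(config = config, heterozygosity = het,
                 window_table = peaks_a$window_table, peaks = peaks_a,
                 peaks_contrast = peaks_b, polymorphic_genes = poly_genes,
                 degeneracy = dmap, load = load, spectrum = spectrum,
                 roh = roh_calls, fst = fst, shift = shift,
                 overlap = overlap, notices = notices,
                 thresholds = list(window_size = ws, k_sd = k_sd,
                                   min_map = min_map, cov_low = cov_low,
                                   cov_high = cov_high,
                                   polymorphic_threshold = polymorphic_threshold,
                                   roh_min_length = roh$min_length,
                                   mc_reps = mc_reps),
                 version = as.character(utils::packageVersion("lowdivscan")))
  class(report) <- "lowdiv_report"
  if (!is.null(out_dir)) .persist_report(report, sim, out_dir)
  report
}

.persist_report <- function(report, sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_simulation(sim, file.path(out_dir, "input"))
  wt <- report$window_table
  write_window_bed(wt, file.path(out_dir, "windows.bed"))
  write.table(report$peaks$regions, file.path(out_dir, "peak_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$polymorphic_genes,
              file.path(out_dir, "polymorphic_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$fst))
    write.table(report$fst[, c("contig", "start", "end", "fst",
                               "n_usable_sites")],
                file.path(out_dir, "window_fst.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  roh_df <- do.call(rbind, lapply(report$roh, function(r)
    if (nrow(r$intervals)) data.frame(sample = r$sample, r$intervals)))
  if (!is.null(roh_df))
    write.table(roh_df, file.path(out_dir, "roh_intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.lowdiv_report <- function(x, ...) {
  cat("Low-diversity genome scan report (package version", x$version, ")\n")
  cat("\nPer-sample heterozygosity (/bp):\n")
  print(signif(x$heterozygosity, 3))
  cat(sprintf("\nWindows: %d total, %d pass;",
              nrow(x$window_table), sum(x$window_table$status == "pass")))
  cat(sprintf(" peaks: %d window(s) in %d region(s), threshold %.3g\n",
              nrow(x$peaks$windows), nrow(x$peaks$regions),
              x$peaks$threshold))
  cat(sprintf("Polymorphic genes: %d of %d peak-region gene(s)\n",
              sum(x$polymorphic_genes$is_polymorphic),
              nrow(x$polymorphic_genes)))
  for (s in names(x$roh)) print(x$roh[[s]])
  if (!is.null(x$shift)) print(x$shift)
  if (!is.null(x$overlap)) print(x$overlap)
  for (n in x$notices) cat("NOTE:", n, "\n")
  invisible(x)
}

#' @export
summary.lowdiv_report <- function(object, ...) {
  x <- object
  load_ratios <- vapply(x$load, function(l) l$ratio %||% NA_real_, numeric(1))
  out <- list(
    heterozygosity = x$heterozygosity,
    n_windows = nrow(x$window_table),
    n_pass = sum(x$window_table$status == "pass"),
    n_peak_windows = nrow(x$peaks$windows),
    n_peak_regions = nrow(x$peaks$regions),
    peak_threshold = x$peaks$threshold,
    n_polymorphic_genes = sum(x$polymorphic_genes$is_polymorphic),
    load_ratio = load_ratios,
    f_roh = vapply(x$roh, `[[`, numeric(1), "f_roh"),
    shift_p = if (!is.null(x$shift)) x$shift$p else NA_real_,
    overlap_p = if (!is.null(x$overlap)) x$overlap$p_monte_carlo_ge
                else NA_real_)
  class(out) <- "summary.lowdiv_report"
  out
}

#' @export
print.summary.lowdiv_report <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Plot a genome-scan report
#'
#' Three panels: the windowed diversity track with the peak threshold, the
#' window F_ST distribution in peak versus background windows, and the ROH
#' length histogram.
#'
#' @param x a `lowdiv_report`.
#' @param ... ignored.
#' @export
plot.lowdiv_report <- function(x, ...) {
  op <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  wt <- x$window_table
  idx <- seq_len(nrow(wt))
  plot(idx, wt$pi, type = "h", col = ifelse(wt$is_peak, "red", "grey40"),
       xlab = "window (genome order)", ylab = expression(pi),
       main = "Windowed nucleotide diversity")
  abline(h = x$peaks$threshold, lty = 2, col = "blue")
  if (!is.null(x$fst)) {
    pk <- .win_key(x$peaks$windows$contig, x$peaks$windows$window)
    grp <- ifelse(.win_key(x$fst$contig, x$fst$window) %in% pk,
                  "peak", "background")
    ok <- !is.na(x$fst$fst) & x$fst$status == "pass"
    boxplot(x$fst$fst[ok] ~ grp[ok], xlab = "", ylab = expression(F[ST]),
            main = "Window F_ST: peak vs background")
  } else {
    plot.new(); title("no contrast species: F_ST panel skipped")
  }
  lens <- unlist(lapply(x$roh, function(r) r$intervals$length))
  if (length(lens)) {
    hist(lens / 1e3, breaks = 20, xlab = "ROH length (kb)", main = "ROH lengths")
  } else {
    plot.new(); title("no ROH called")
  }
  invisible(x)
}
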