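# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Window index of a 1-based position
#'
#' Maps a 1-based point coordinate (VCF convention) onto the non-overlapping
#' window grid. Windows are 0-based half-open internally, so position `p`
#' falls in window `floor((p - 1) / window_size)`.
#'
#' @param pos integer vector of 1-based positions.
#' @param window_size window width in bp.
#' @return 0-based integer window indices.
#' @export
window_index <- function(pos, window_size) {
  stopifnot(window_size >= 1)
  as.integer((pos - 1L) %/% window_size)
}

# contig + window index -> stable key
.win_key <- function(contig, index) paste(contig, index, sep = ":")

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# derive a bounded sub-seed from a root seed (kept below 2^31)
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}
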