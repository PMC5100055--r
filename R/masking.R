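## Symmetric DUST soft-masking of simple repeats, applied to contigs before
## the all-vs-all comparison so that low-complexity sequence cannot produce
## spurious high-identity hits. The masking is encoded as lowercase; masked
## positions are excluded from alignment seeding but remain alignable inside
## extensions.

#' DUST masking parameters
#'
#' Defaults mirror the published defaults of the standard DUST masker
#' (window 64 nt, score level 20, linker 1 nt).
#'
#' @param window window length in nt (>= 3).
#' @param level score threshold; a window is low-complexity when its
#'   normalised triplet-count score exceeds `level`.
#' @param linker masked intervals separated by `<= linker` unmasked
#'   positions are merged.
#' @return object of class `mask_params`.
#' @export
mask_params <- function(window = 64L, level = 20, linker = 1L) {
  window <- as.integer(window); linker <- as.integer(linker)
  if (window < 3L) stop("'window' must be >= 3")
  if (level < 1) stop("'level' must be >= 1")
  if (linker < 0L) stop("'linker' must be >= 0")
  structure(list(window = window, level = level, linker = linker),
            class = "mask_params")
}

#' Soft-mask low-complexity intervals in a nucleotide sequence
#'
#' Computes the symmetric DUST triplet-count score
#' `S = 10 * sum(c_t * (c_t - 1) / 2) / (m - 1)` over every sliding window
#' (`c_t` = count of triplet `t` among the window's `m` counted triplets;
#' triplets touching an ambiguous base are skipped) and lowercases every
#' position covered by a window with `S > level`, merging intervals
#' separated by at most `linker` positions. Existing lowercase (previous
#' masking) is preserved and unioned with the new mask.
#'
#' @param sequence character vector of nucleotide sequences (upper or mixed
#'   case).
#' @param params [mask_params()].
#' @return character vector of the same lengths with masked positions in
#'   lowercase. Sequences shorter than 3 nt are returned unchanged with a
#'   warning.
#' @export
dust_mask <- function(sequence, params = mask_params()) {
  stopifnot(inherits(params, "mask_params"))
  if (any(nchar(sequence) < 3L)) {
    warning("sequence(s) shorter than 3 nt returned unmasked")
  }
  vapply(sequence, function(s) {
    if (nchar(s) < 3L) return(s)
    m <- dust_mask_core(s, params$window, params$level, params$linker)
    if (!any(m)) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    v[m] <- tolower(v[m])
    paste(v, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Soft-mask every contig of a contig table
#'
#' @param contigs contig table (see [read_contigs()]).
#' @param params [mask_params()].
#' @return the contig table with masked `sequence` column.
#' @export
mask_contigs <- function(contigs, params = mask_params()) {
  contigs$sequence <- dust_mask(contigs$sequence, params)
  contigs
}

#' Masked intervals of a (possibly soft-masked) sequence
#'
#' @param sequence single sequence string.
#' @return two-column integer matrix of 1-based inclusive `start`, `end`
#'   lowercase intervals.
#' @export
masked_intervals <- function(sequence) {
  low <- grepl("[a-z]", strsplit(sequence, "", fixed = TRUE)[[1L]])
  r <- rle(low)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  cbind(start = s[r$values], end = e[r$values])
}
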