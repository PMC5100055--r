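## Structural classification of Silicon Transporter proteins. Full SITs
## carry 10 transmembrane domains (TMDs) and two EGXQ-GRQ motif pairs, one
## before/at TMD2-3 and one at TMD7-8; SIT-Ls are the 5-TMD, one-pair
## "half" architecture. TMDs are predicted with a Kyte-Doolittle sliding
## window; motifs with the documented variant patterns (E[GA]X[QKMH];
## GRQ/GRH/GQS; the xQxxxQx motif of TMD4).

## Kyte-Doolittle hydropathy scale; X (unknown residue) scores 0.
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0,
  `*` = 0)

#' Transmembrane-domain prediction parameters
#'
#' A transparent hydropathy-window predictor (standard Kyte-Doolittle
#' scale): a window of 19 residues with mean hydropathy `>= 1.6` is the
#' classic criterion for a membrane-spanning helix.
#'
#' @param window odd window length in residues (>= 7).
#' @param threshold mean-hydropathy cutoff.
#' @param min_gap predicted runs separated by fewer than `min_gap`
#'   residues are merged.
#' @param min_len runs shorter than this many residues are dropped.
#' @return object of class `tmd_params`.
#' @export
tmd_params <- function(window = 19L, threshold = 1.6, min_gap = 5L,
                       min_len = 7L) {
  window <- as.integer(window)
  if (window < 7L || window %% 2L == 0L) stop("'window' must be odd and >= 7")
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  structure(list(window = window, threshold = threshold,
                 min_gap = as.integer(min_gap), min_len = as.integer(min_len)),
            class = "tmd_params")
}

#' Predict transmembrane domains by hydropathy
#'
#' Computes the centred sliding-window mean Kyte-Doolittle hydropathy at
#' every position with a full window, takes maximal runs of positions with
#' mean `>= threshold`, merges runs separated by fewer than `min_gap`
#' residues, and drops runs shorter than `min_len`.
#'
#' @param seq protein sequence (any case).
#' @param params [tmd_params()].
#' @return two-column integer matrix of 1-based inclusive TMD intervals
#'   (zero rows when none). Sequences shorter than the window return no
#'   TMDs with a warning.
#' @export
predict_tmds <- function(seq, params = tmd_params()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- cbind(start = integer(), end = integer())
  if (L < params$window) {
    warning("sequence shorter than the hydropathy window: no TMDs predicted")
    return(empty)
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  kd <- kyte_doolittle[res]
  if (anyNA(kd)) {
    stop("unknown residue '", res[is.na(kd)][1L], "' at position ",
         which(is.na(kd))[1L])
  }
  w <- params$window
  h <- (w - 1L) %/% 2L
  means <- as.numeric(stats::filter(kd, rep(1 / w, w), sides = 2L))
  ## tolerance guards the exact-boundary case against summation-order noise
  above <- !is.na(means) & means >= params$threshold - 1e-9
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(iv) == 0L) return(empty)
  ## merge runs separated by < min_gap residues
  merged <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      gap <- iv[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap < params$min_gap) {
        merged[nrow(merged), 2L] <- iv[i, 2L]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
  }
  merged <- merged[merged[, 2L] - merged[, 1L] + 1L >= params$min_len, ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Scan a protein for EGXQ, GRQ and xQxxxQx motifs
#'
#' Patterns cover the documented variants: the EGXQ class is
#' `E[GA]X[QKMH]` (X = any residue; A-for-G and K/M/H-for-Q variants); the
#' GRQ class is GRQ, GRH or GQS; the xQxxxQx class is a glutamine pair
#' spaced four residues apart. Overlapping matches are all reported.
#'
#' @param seq protein sequence (case folded internally).
#' @return data.frame with `class`, `start` (1-based), `text`.
#' @export
scan_motifs <- function(seq) {
  seq <- toupper(seq)
  scan1 <- function(class, lookahead, len) {
    m <- gregexpr(lookahead, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) {
      return(data.frame(class = character(), start = integer(),
                        text = character(), stringsAsFactors = FALSE))
    }
    data.frame(class = class, start = as.integer(m),
               text = substring(seq, m, m + len - 1L),
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan1("EGXQ", "(?=E[GA].[QKMH])", 4L),
               scan1("GRQ", "(?=G(?:RQ|RH|QS))", 3L),
               scan1("xQxxxQx", "(?=Q...Q)", 5L))
  rownames(out) <- NULL
  out
}

#' Pair EGXQ and GRQ motifs across consecutive TMDs
#'
#' A motif pair is an EGXQ hit just before or inside TMD `n` together with
#' a GRQ hit around TMD `n + 1` (the geometry of the conserved pairs at
#' TMD2/3 and TMD7/8): the EGXQ start must lie in
#' `[start(TMD_n) - margin, end(TMD_n)]` and the GRQ start in
#' `[start(TMD_{n+1}) - margin, end(TMD_{n+1}) + margin]`. Assignment is
#' greedy left-to-right and each motif hit joins at most one pair.
#'
#' @param motifs [scan_motifs()] result.
#' @param tmds TMD interval matrix ([predict_tmds()]).
#' @param margin anchoring margin in residues.
#' @return data.frame with `egxq_start`, `grq_start`, `tmd_index` (the
#'   anchoring TMD number `n`).
#' @export
pair_motifs <- function(motifs, tmds, margin = 15L) {
  empty <- data.frame(egxq_start = integer(), grq_start = integer(),
                      tmd_index = integer(), stringsAsFactors = FALSE)
  K <- nrow(tmds)
  if (K < 2L) return(empty)
  eg <- sort(motifs$start[motifs$class == "EGXQ"])
  gr <- sort(motifs$start[motifs$class == "GRQ"])
  used_eg <- logical(length(eg)); used_gr <- logical(length(gr))
  rows <- list()
  for (n in 1:(K - 1L)) {
    i <- which(!used_eg & eg >= tmds[n, 1L] - margin & eg <= tmds[n, 2L])
    j <- which(!used_gr & gr >= tmds[n + 1L, 1L] - margin &
                 gr <= tmds[n + 1L, 2L] + margin)
    if (length(i) && length(j)) {
      used_eg[i[1L]] <- TRUE; used_gr[j[1L]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        egxq_start = eg[i[1L]], grq_start = gr[j[1L]], tmd_index = n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Classify a protein as SIT, SIT-L or unclassified
#'
#' Strict mode applies the definitions directly: SIT = 10 TMDs and 2
#' EGXQ-GRQ pairs; SIT-L = 5 TMDs and 1 pair. Tolerant mode (default)
#' absorbs predictor disagreement about marginal helices: SIT = 2 pairs
#' and 8-12 TMDs, SIT-L = 1 pair and 4-6 TMDs; anything else is
#' unclassified, with a diagnostic note for near-misses (e.g. transporters
#' truncated in assembly).
#'
#' @param seq protein sequence.
#' @param params [tmd_params()].
#' @param mode `"tolerant"` or `"strict"`.
#' @param margin motif anchoring margin, see [pair_motifs()].
#' @return object of class `transporter_call`: list with `protein_id`,
#'   `tmds`, `motifs`, `pairs`, `n_tmds`, `n_pairs`, `label`, `notes`.
#' @export
classify_transporter <- function(seq, params = tmd_params(),
                                 mode = c("tolerant", "strict"),
                                 margin = 15L) {
  mode <- match.arg(mode)
  tmds <- suppressWarnings(predict_tmds(seq, params))
  motifs <- scan_motifs(seq)
  pairs <- pair_motifs(motifs, tmds, margin)
  n_tmds <- nrow(tmds); n_pairs <- nrow(pairs)
  notes <- character()
  if (mode == "strict") {
    label <- if (n_tmds == 10L && n_pairs == 2L) "SIT"
    else if (n_tmds == 5L && n_pairs == 1L) "SIT-L"
    else "unclassified"
  } else {
    label <- if (n_pairs == 2L && n_tmds >= 8L && n_tmds <= 12L) "SIT"
    else if (n_pairs == 1L && n_tmds >= 4L && n_tmds <= 6L) "SIT-L"
    else "unclassified"
    if (label == "unclassified" && n_pairs >= 1L) {
      notes <- c(notes, sprintf(
        "%d pair(s), %d TMDs: possible truncated or atypical transporter",
        n_pairs, n_tmds))
    }
  }
  ## conserved-residue annotations (descriptive only, never decisional)
  if (n_tmds >= 3L) {
    loop <- substr(toupper(seq), tmds[2L, 2L] + 1L, tmds[3L, 1L] - 1L)
    if (grepl("[RK]", loop)) notes <- c(notes, "R/K between TMD2 and TMD3")
  }
  if (n_tmds >= 5L &&
      grepl("E", substr(toupper(seq), tmds[5L, 1L], tmds[5L, 2L]))) {
    notes <- c(notes, "E in TMD5")
  }
  if (n_tmds >= 8L &&
      grepl("T", substr(toupper(seq), tmds[8L, 1L], tmds[8L, 2L]))) {
    notes <- c(notes, "T in TMD8")
  }
  structure(list(tmds = tmds, motifs = motifs, pairs = pairs,
                 n_tmds = n_tmds, n_pairs = n_pairs, label = label,
                 notes = notes, mode = mode),
            class = "transporter_call")
}

#' @export
print.transporter_call <- function(x, ...) {
  cat(sprintf("Transporter call: %s (%d TMDs, %d EGXQ-GRQ pairs, %s mode)\n",
              x$label, x$n_tmds, x$n_pairs, x$mode))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Classify every protein of a protein table
#'
#' @param proteins data.frame with `protein_id` and `sequence` (e.g. from
#'   [read_proteins()] or [read_fasta()] with `id` renamed).
#' @param params,mode,margin see [classify_transporter()].
#' @return data.frame with `protein_id`, `label`, `n_tmds`, `n_pairs`,
#'   `notes`.
#' @export
classify_proteins <- function(proteins, params = tmd_params(),
                              mode = "tolerant", margin = 15L) {
  calls <- lapply(proteins$sequence, classify_transporter, params = params,
                  mode = mode, margin = margin)
  data.frame(protein_id = proteins$protein_id %||% proteins$id,
             label = vapply(calls, `[[`, character(1L), "label"),
             n_tmds = vapply(calls, `[[`, integer(1L), "n_tmds"),
             n_pairs = vapply(calls, `[[`, integer(1L), "n_pairs"),
             notes = vapply(calls, function(c) paste(c$notes, collapse = "; "),
                            character(1L)),
             stringsAsFactors = FALSE)
}

#' Split a full SIT into its N- and C-terminal halves
#'
#' SIT architecture is a duplication-fusion of two 5-TMD units; for
#' phylogenetic comparison with SIT-Ls, full SITs are split at a point in
#' the loop between TMD5 and TMD6 (the midpoint between the end of TMD5
#' and the start of TMD6).
#'
#' @param seq protein sequence of a SIT-labelled call.
#' @param tmds its TMD interval matrix (`>= 6` rows).
#' @return list with `n_half`, `c_half`, `split_position`;
#'   `paste0(n_half, c_half)` reproduces the input.
#' @export
split_sit <- function(seq, tmds) {
  if (nrow(tmds) < 6L) {
    stop("splitting requires at least 6 predicted TMDs (got ", nrow(tmds), ")")
  }
  split_position <- unname((tmds[5L, 2L] + tmds[6L, 1L])) %/% 2L
  list(n_half = substr(seq, 1L, split_position),
       c_half = substr(seq, split_position + 1L, nchar(seq)),
       split_position = split_position)
}
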