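## All-vs-all cross-project comparison: for every pair of contigs from
## different sequencing projects, at most one top-scoring gapless local
## alignment. Contaminant copies are near-identical, so gapless alignments
## (match +1 / mismatch -1, x-drop extension from exact uppercase k-mer
## seeds, both subject strands) suffice and keep the scoring exactly
## reproducible by a brute-force diagonal scan.

#' Alignment parameters
#'
#' `min_score` defaults to 64, the raw-score cutoff of the original
#' procedure's aligner; with `match = +1`, `mismatch = -1` the score equals
#' matches minus mismatches, so percent identity and score are mutually
#' consistent.
#'
#' @param seed_k exact-match seed length (4..15).
#' @param match,mismatch per-column scores.
#' @param xdrop extension drop-off.
#' @param min_score minimum reported alignment score.
#' @return object of class `align_params`.
#' @export
align_params <- function(seed_k = 12L, match = 1L, mismatch = -1L,
                         xdrop = 10L, min_score = 64L) {
  seed_k <- as.integer(seed_k)
  if (seed_k < 4L || seed_k > 15L) stop("'seed_k' must be in 4..15")
  if (min_score < 1L) stop("'min_score' must be >= 1")
  if (match <= 0L || mismatch >= 0L) stop("need match > 0 and mismatch < 0")
  structure(list(seed_k = seed_k, match = as.integer(match),
                 mismatch = as.integer(mismatch), xdrop = as.integer(xdrop),
                 min_score = as.integer(min_score)),
            class = "align_params")
}

hits_from_core <- function(core, project, contig_id) {
  if (nrow(core) == 0L) {
    return(data.frame(
      q_project = character(), q_contig = character(),
      s_project = character(), s_contig = character(),
      pident = numeric(), aln_len = integer(), mismatch = integer(),
      gapopen = integer(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(), evalue = numeric(),
      score = integer(), strand = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    q_project = project[core$q_idx], q_contig = contig_id[core$q_idx],
    s_project = project[core$s_idx], s_contig = contig_id[core$s_idx],
    pident = core$pident, aln_len = core$aln_len,
    mismatch = core$aln_len - core$matches, gapopen = 0L,
    q_start = core$q_start, q_end = core$q_end,
    s_start = core$s_start, s_end = core$s_end,
    evalue = 0, score = core$score, strand = core$strand,
    stringsAsFactors = FALSE)
}

#' Align one cross-project contig pair
#'
#' Returns every qualifying gapless local alignment between the two contigs
#' (at most one per strand and diagonal, the best-scoring one).
#'
#' @param a,b single-row contig records (`project`, `contig_id`,
#'   `sequence`) from different projects.
#' @param params [align_params()].
#' @return hit table (possibly zero rows).
#' @export
align_pair <- function(a, b, params = align_params()) {
  if (a$project == b$project) stop("align_pair requires contigs from different projects")
  core <- all_vs_all_core(c(a$sequence, b$sequence), c(1L, 2L),
                          params$seed_k, params$match, params$mismatch,
                          params$xdrop, params$min_score)
  h <- hits_from_core(core, c(a$project, b$project),
                      c(a$contig_id, b$contig_id))
  sort_hits(h)
}

#' Reduce a hit list to the top-scoring hit per unordered contig pair
#'
#' Hits are first put in canonical orientation (query = lexicographically
#' smaller `(project, contig)`); then exactly one hit is kept per unordered
#' contig pair: the maximum-score one, ties broken by higher `pident`,
#' longer `aln_len`, then lexicographic ids. Output order is canonical and
#' independent of input order.
#'
#' @param hits hit table (both orientations and multiple local alignments
#'   per pair allowed).
#' @return hit table with one row per unordered contig pair.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  swap <- paste(hits$q_project, hits$q_contig, sep = "\x1f") >
    paste(hits$s_project, hits$s_contig, sep = "\x1f")
  if (any(swap)) {
    h <- hits[swap, ]
    hits[swap, c("q_project", "q_contig", "s_project", "s_contig")] <-
      h[, c("s_project", "s_contig", "q_project", "q_contig")]
    hits[swap, c("q_start", "q_end", "s_start", "s_end")] <-
      h[, c("s_start", "s_end", "q_start", "q_end")]
  }
  o <- order(hits$q_project, hits$q_contig, hits$s_project, hits$s_contig,
             -hits$score, -hits$pident, -hits$aln_len)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$q_project, hits$q_contig, hits$s_project, hits$s_contig,
               sep = "\x1f")
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

sort_hits <- function(hits) {
  o <- order(hits$q_project, hits$q_contig, hits$s_project, hits$s_contig,
             -hits$score, hits$strand, hits$q_start)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' All-vs-all comparison of two or more projects
#'
#' Runs the seed-and-extend aligner over every cross-project contig pair
#' (within-project comparisons are never performed) and keeps the
#' top-scoring hit per unordered contig pair. Deterministic: permuting the
#' input yields the same canonicalised output.
#'
#' @param contigs contig table covering `>= 2` projects (sequences should
#'   already be soft-masked; see [mask_contigs()]).
#' @param params [align_params()].
#' @return hit table of best hits per contig pair.
#' @export
all_vs_all <- function(contigs, params = align_params()) {
  if (length(unique(contigs$project)) < 2L) {
    stop("decontamination requires >=2 projects")
  }
  o <- order(contigs$project, contigs$contig_id)
  contigs <- contigs[o, , drop = FALSE]
  core <- all_vs_all_core(contigs$sequence,
                          as.integer(factor(contigs$project)),
                          params$seed_k, params$match, params$mismatch,
                          params$xdrop, params$min_score)
  h <- hits_from_core(core, contigs$project, contigs$contig_id)
  best_hits(h)
}
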