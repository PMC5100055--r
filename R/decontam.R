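## The cross-contamination decision procedure. For each pair of sequencing
## projects: qualify best-hits by length, build a 1%-binned percent-identity
## histogram, detect the contamination threshold from the shape of the
## histogram (contaminant copies peak at 100% identity or slightly lower;
## genuine cross-species hits sit around a lower identity), flag the
## contig pairs above the threshold, and arbitrate each flagged pair by
## expression (RPKM) before purging.

#' Decontamination configuration
#'
#' Defaults are the thresholds of the published procedure: hits qualify at
#' `>= 150` nt aligned or `>= 50%` of the shorter contig; a flagged contig
#' is rescued when its RPKM is `>= 10x` the partner's, or `>= 10000`
#' regardless of the partner.
#'
#' @param min_hit_len minimum alignment length (nt) for qualification.
#' @param min_frac_of_shorter alternative qualification: alignment length as
#'   a fraction of the shorter contig.
#' @param rpkm_ratio RPKM ratio at or above which the higher-expression
#'   contig is retained and the partner discarded.
#' @param rpkm_retain absolute RPKM at or above which a contig is always
#'   retained.
#' @param excluded_pairs character vector of `"projectA|projectB"` unordered
#'   project pairs to skip entirely (same-species pairs sequenced under
#'   different names, for which cross-matches are expected).
#' @param arbitration if `FALSE`, expression data is ignored and every
#'   flagged contig pair is discarded (`default_both`).
#' @param bin_rounding identity-to-bin rule; `"half-up"` (the package's
#'   normative choice) rounds `pident` half-up to an integer bin so that
#'   near-perfect copies (e.g. 1 error in 300 nt, 99.67%) land in the
#'   100-adjacent mass.
#' @param threshold_inclusive if `FALSE` (normative), the threshold bin
#'   itself is retained as "true" and only bins strictly above it are
#'   contaminant.
#' @return object of class `decontam_config`.
#' @export
decontam_config <- function(min_hit_len = 150L, min_frac_of_shorter = 0.5,
                            rpkm_ratio = 10, rpkm_retain = 10000,
                            excluded_pairs = character(),
                            arbitration = TRUE,
                            bin_rounding = c("half-up", "floor"),
                            threshold_inclusive = FALSE) {
  if (min_hit_len < 1L) stop("'min_hit_len' must be >= 1")
  if (min_frac_of_shorter <= 0 || min_frac_of_shorter > 1) {
    stop("'min_frac_of_shorter' must be in (0, 1]")
  }
  if (rpkm_ratio <= 1) stop("'rpkm_ratio' must be > 1")
  if (rpkm_retain <= 0) stop("'rpkm_retain' must be > 0")
  structure(list(min_hit_len = as.integer(min_hit_len),
                 min_frac_of_shorter = min_frac_of_shorter,
                 rpkm_ratio = rpkm_ratio, rpkm_retain = rpkm_retain,
                 excluded_pairs = excluded_pairs,
                 arbitration = isTRUE(arbitration),
                 bin_rounding = match.arg(bin_rounding),
                 threshold_inclusive = isTRUE(threshold_inclusive)),
            class = "decontam_config")
}

#' Does a hit qualify for the identity histogram?
#'
#' A matching contig pair is only considered when the alignment spans
#' `>= min_hit_len` nt or at least `min_frac_of_shorter` of the shorter
#' contig (inclusive OR: either arm suffices).
#'
#' @param aln_len alignment length(s), nt.
#' @param len_q,len_s full lengths of the two contigs.
#' @param cfg [decontam_config()].
#' @return logical vector.
#' @export
qualify_hit <- function(aln_len, len_q, len_s, cfg = decontam_config()) {
  shorter <- pmin(len_q, len_s)
  if (any(aln_len > shorter)) {
    stop("corrupt hit: alignment longer than the shorter contig (aln_len ",
         aln_len[aln_len > shorter][1L], " > ", shorter[aln_len > shorter][1L], ")")
  }
  aln_len >= cfg$min_hit_len | aln_len >= cfg$min_frac_of_shorter * shorter
}

#' Assign percent identities to 1%-wide integer bins
#'
#' @param pident numeric identities in \[0, 100\].
#' @param rounding `"half-up"` or `"floor"`.
#' @return integer bins in 0..100.
#' @export
pident_bin <- function(pident, rounding = "half-up") {
  b <- if (rounding == "floor") floor(pident) else floor(pident + 0.5)
  as.integer(pmin(pmax(b, 0), 100))
}

#' Build the percent-identity histogram of one project pair
#'
#' @param pident identities of the pair's qualified hits.
#' @param pair unordered project pair label (`"A|B"`), recorded on the
#'   result.
#' @param rounding bin rule, see [pident_bin()].
#' @return object of class `pair_histogram`: list with `pair`, `counts`
#'   (named integer vector over bins `0..100`, zeros included) and
#'   `n_hits`.
#' @export
build_pair_histogram <- function(pident, pair = NA_character_,
                                 rounding = "half-up") {
  bins <- pident_bin(pident, rounding)
  counts <- tabulate(bins + 1L, nbins = 101L)
  names(counts) <- 0:100
  structure(list(pair = pair, counts = counts, n_hits = length(pident)),
            class = "pair_histogram")
}

#' Detect the contamination threshold of a pair histogram
#'
#' The pair shows cross-contamination only if the count at 100% identity
#' exceeds the count at 99%. Bins then descend from 99% in 1% steps until
#' three consecutive bins are found whose lower two each hold at least as
#' many hits as the bin before them; the first bin of that triple is the
#' threshold between contaminant and "true" hits. If the scan exhausts
#' without such a triple (no true-hit plateau), every populated bin below
#' 100 is treated as contaminant (`fallback_used`).
#'
#' @param h [build_pair_histogram()] result, or a bare counts vector over
#'   bins 0..100.
#' @return list (`threshold_result`) with `pair`, `contaminated`,
#'   `threshold_bin` (NA when uncontaminated), `fallback_used`. Hits in
#'   bins strictly greater than `threshold_bin` form the contaminant set.
#' @export
detect_threshold <- function(h) {
  if (inherits(h, "pair_histogram")) {
    counts <- h$counts; pair <- h$pair
  } else {
    counts <- h; pair <- NA_character_
  }
  stopifnot(length(counts) == 101L)
  cnt <- function(b) counts[[b + 1L]]
  res <- structure(list(pair = pair, contaminated = FALSE,
                        threshold_bin = NA_integer_, fallback_used = FALSE),
                   class = "threshold_result")
  if (cnt(100) <= cnt(99)) return(res)
  res$contaminated <- TRUE
  for (b in 99:2) {
    if (cnt(b - 1) >= cnt(b) && cnt(b - 2) >= cnt(b - 1)) {
      res$threshold_bin <- b
      return(res)
    }
  }
  populated <- which(counts > 0L) - 1L
  res$threshold_bin <- max(0L, min(populated) - 1L)
  res$fallback_used <- TRUE
  warning("histogram scan exhausted for pair ", pair,
          ": flagging all populated bins below 100")
  res
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * read_count / (contig_length_nt * project_total_reads)`.
#'
#' @param read_count mapped reads on the contig.
#' @param contig_length_nt contig length (nt, `>= 1`).
#' @param project_total_reads total mapped reads of the project (`>= 1`).
#' @return numeric RPKM.
#' @export
compute_rpkm <- function(read_count, contig_length_nt, project_total_reads) {
  if (any(contig_length_nt < 1)) stop("contig length must be >= 1 nt")
  if (any(project_total_reads < 1)) stop("project total reads must be >= 1")
  if (any(read_count < 0)) stop("read count must be non-negative")
  1e9 * read_count / (contig_length_nt * project_total_reads)
}

#' Arbitrate one flagged contig pair by expression
#'
#' By default both members of a contaminant-flagged pair are discarded.
#' When one contig's RPKM is at least `rpkm_ratio` times the other's, the
#' high-expression contig is retained (it is the likely true source) and
#' the partner discarded; a partner RPKM of exactly 0 counts as satisfying
#' the ratio for a positive-RPKM contig. Independently, any contig with
#' RPKM `>= rpkm_retain` is retained: very highly conserved, highly
#' expressed genes may legitimately match at high identity without a 10x
#' expression gap.
#'
#' @param rpkm_a,rpkm_b RPKM of the two flagged contigs.
#' @param cfg [decontam_config()].
#' @return list with `status_a`, `status_b` (`"retained"`/`"discarded"`)
#'   and `reason_a`, `reason_b`.
#' @export
arbitrate_pair <- function(rpkm_a, rpkm_b, cfg = decontam_config()) {
  status <- c("discarded", "discarded")
  reason <- c("default_both", "default_both")
  if (cfg$arbitration) {
    ratio_ok <- function(x, y) {
      (y > 0 && x >= cfg$rpkm_ratio * y) || (y == 0 && x > 0)
    }
    if (ratio_ok(rpkm_a, rpkm_b)) {
      status <- c("retained", "discarded")
      reason <- c("rpkm_ratio_winner", "rpkm_ratio_loser")
    } else if (ratio_ok(rpkm_b, rpkm_a)) {
      status <- c("discarded", "retained")
      reason <- c("rpkm_ratio_loser", "rpkm_ratio_winner")
    }
    if (rpkm_a >= cfg$rpkm_retain && status[1L] == "discarded") {
      status[1L] <- "retained"; reason[1L] <- "rpkm_high_expression"
    }
    if (rpkm_b >= cfg$rpkm_retain && status[2L] == "discarded") {
      status[2L] <- "retained"; reason[2L] <- "rpkm_high_expression"
    }
  }
  list(status_a = status[1L], status_b = status[2L],
       reason_a = reason[1L], reason_b = reason[2L])
}

## RPKM per contig from a count table + contig lengths; returns named vector
## keyed by "project|contig".
rpkm_table <- function(counts, contigs) {
  totals <- attr(counts, "project_totals")
  if (is.null(totals)) {
    stop("count table lacks 'project_totals' (read it with read_counts_table)")
  }
  lens <- setNames(contigs$length, make_seq_id(contigs$project, contigs$contig_id))
  key <- make_seq_id(counts$project, counts$contig_id)
  unknown <- !(key %in% names(lens))
  if (any(unknown)) {
    stop("count row(s) for unknown contig: ", key[unknown][1L])
  }
  setNames(compute_rpkm(counts$read_count, lens[key],
                        totals[counts$project]), key)
}

#' Run the full cross-contamination decision procedure
#'
#' Pipeline order: excluded same-species pairs are dropped, hits are
#' qualified by length, per-pair identity histograms are built and
#' thresholds detected, hits above the threshold flag their two contigs,
#' each flagged pair is arbitrated by RPKM, and decisions are aggregated
#' per contig with discard dominating across pairs.
#'
#' @param contigs contig table (all projects).
#' @param hits best-hits table (one hit per unordered contig pair; see
#'   [best_hits()]).
#' @param counts count table from [read_counts_table()], or `NULL` when
#'   `cfg$arbitration` is `FALSE`.
#' @param cfg [decontam_config()].
#' @return object of class `decontam_result`: list with
#'   \describe{
#'     \item{decisions}{per-contig data.frame: `project`, `contig_id`,
#'       `status`, `reason`, `evidence` (per-pair identities of flagged
#'       hits).}
#'     \item{thresholds}{per-project-pair data.frame: `pair`, `n_hits`
#'       (qualified), `contaminated`, `threshold_bin`, `fallback_used`,
#'       `n_flagged`.}
#'     \item{histograms}{named list of `pair_histogram` objects.}
#'     \item{project_summary}{per-project contig counts in/flagged/discarded/
#'       retained-by-exception.}
#'   }
#' @export
run_decontam <- function(contigs, hits, counts = NULL,
                         cfg = decontam_config()) {
  if (length(unique(contigs$project)) < 2L) {
    stop("decontamination requires >=2 projects")
  }
  if (cfg$arbitration && is.null(counts)) {
    stop("expression counts are required when arbitration is enabled ",
         "(pass counts or set arbitration = FALSE)")
  }

  lens <- setNames(contigs$length,
                   make_seq_id(contigs$project, contigs$contig_id))
  qk <- make_seq_id(hits$q_project, hits$q_contig)
  sk <- make_seq_id(hits$s_project, hits$s_contig)
  if (any(!(qk %in% names(lens))) || any(!(sk %in% names(lens)))) {
    stop("hit references a contig absent from the contig table")
  }

  excl <- if (length(cfg$excluded_pairs)) {
    ep <- strsplit(cfg$excluded_pairs, "|", fixed = TRUE)
    vapply(ep, function(p) pair_key(p[1L], p[2L]), character(1L))
  } else character()

  pk <- pair_key(hits$q_project, hits$s_project)
  keep <- !(pk %in% excl)
  hits <- hits[keep, , drop = FALSE]
  pk <- pk[keep]; qk <- qk[keep]; sk <- sk[keep]

  qual <- if (nrow(hits)) {
    qualify_hit(hits$aln_len, lens[qk], lens[sk], cfg)
  } else logical()
  hits <- hits[qual, , drop = FALSE]
  pk <- pk[qual]; qk <- qk[qual]; sk <- sk[qual]

  pair_lab <- pair_label(hits$q_project, hits$s_project)
  bins <- pident_bin(hits$pident, cfg$bin_rounding)

  pairs <- sort(unique(pair_lab))
  histograms <- list()
  thr_rows <- vector("list", length(pairs))
  flagged <- logical(nrow(hits))
  for (i in seq_along(pairs)) {
    sel <- pair_lab == pairs[i]
    h <- build_pair_histogram(hits$pident[sel], pairs[i], cfg$bin_rounding)
    histograms[[pairs[i]]] <- h
    th <- detect_threshold(h)
    fl <- if (th$contaminated) {
      if (cfg$threshold_inclusive) sel & bins >= th$threshold_bin
      else sel & bins > th$threshold_bin
    } else rep(FALSE, length(sel))
    flagged <- flagged | fl
    thr_rows[[i]] <- data.frame(
      pair = pairs[i], n_hits = h$n_hits, contaminated = th$contaminated,
      threshold_bin = th$threshold_bin, fallback_used = th$fallback_used,
      n_flagged = sum(fl), stringsAsFactors = FALSE)
  }
  thresholds <- if (length(thr_rows)) do.call(rbind, thr_rows) else
    data.frame(pair = character(), n_hits = integer(),
               contaminated = logical(), threshold_bin = integer(),
               fallback_used = logical(), n_flagged = integer())

  ## arbitration of flagged contig pairs
  all_keys <- make_seq_id(contigs$project, contigs$contig_id)
  status <- setNames(rep("retained", nrow(contigs)), all_keys)
  reason <- setNames(rep("not_flagged", nrow(contigs)), all_keys)
  evidence <- setNames(rep("", nrow(contigs)), all_keys)
  n_flagged_contig <- setNames(rep(FALSE, nrow(contigs)), all_keys)

  if (any(flagged)) {
    rpkm <- if (cfg$arbitration) {
      rpkm_table(counts, contigs)
    } else NULL
    fh <- which(flagged)
    for (i in fh) {
      a <- qk[i]; b <- sk[i]
      n_flagged_contig[c(a, b)] <- TRUE
      ev <- sprintf("%s:%.2f", pair_lab[i], hits$pident[i])
      evidence[a] <- if (nzchar(evidence[a])) paste(evidence[a], ev, sep = ";") else ev
      evidence[b] <- if (nzchar(evidence[b])) paste(evidence[b], ev, sep = ";") else ev
      if (cfg$arbitration) {
        if (!(a %in% names(rpkm))) stop("no expression record for flagged contig ", a)
        if (!(b %in% names(rpkm))) stop("no expression record for flagged contig ", b)
        arb <- arbitrate_pair(rpkm[[a]], rpkm[[b]], cfg)
      } else {
        arb <- list(status_a = "discarded", status_b = "discarded",
                    reason_a = "default_both", reason_b = "default_both")
      }
      ## discard dominates across pair decisions
      for (side in 1:2) {
        k <- c(a, b)[side]
        st <- c(arb$status_a, arb$status_b)[side]
        rs <- c(arb$reason_a, arb$reason_b)[side]
        if (st == "discarded") {
          status[k] <- "discarded"; reason[k] <- rs
        } else if (status[k] != "discarded") {
          status[k] <- "retained"
          if (reason[k] %in% c("not_flagged")) reason[k] <- rs
        }
      }
    }
  }

  decisions <- data.frame(project = contigs$project,
                          contig_id = contigs$contig_id,
                          status = unname(status), reason = unname(reason),
                          evidence = unname(evidence),
                          stringsAsFactors = FALSE)
  o <- order(decisions$project, decisions$contig_id)
  decisions <- decisions[o, , drop = FALSE]
  rownames(decisions) <- NULL

  proj <- sort(unique(contigs$project))
  dec_key <- make_seq_id(decisions$project, decisions$contig_id)
  project_summary <- data.frame(
    project = proj,
    contigs_in = vapply(proj, function(p) sum(contigs$project == p), integer(1L)),
    n_flagged = vapply(proj, function(p) {
      sum(n_flagged_contig[dec_key[decisions$project == p]])
    }, integer(1L)),
    n_discarded = vapply(proj, function(p) {
      sum(decisions$status == "discarded" & decisions$project == p)
    }, integer(1L)),
    n_retained_exception = vapply(proj, function(p) {
      sum(decisions$project == p & decisions$status == "retained" &
            decisions$reason %in% c("rpkm_ratio_winner", "rpkm_high_expression"))
    }, integer(1L)),
    stringsAsFactors = FALSE)
  rownames(project_summary) <- NULL

  structure(list(decisions = decisions, thresholds = thresholds,
                 histograms = histograms, project_summary = project_summary,
                 config = cfg),
            class = "decontam_result")
}

#' @export
print.decontam_result <- function(x, ...) {
  cat("Cross-contamination decisions over",
      nrow(x$project_summary), "projects,",
      nrow(x$thresholds), "project pairs\n")
  cat("  contaminated pairs:", sum(x$thresholds$contaminated), "\n")
  cat("  contigs discarded:", sum(x$decisions$status == "discarded"),
      "of", nrow(x$decisions), "\n")
  invisible(x)
}

#' Partition contigs (and their proteins) into retained and purged sets
#'
#' @param contigs contig table of one or more projects.
#' @param decisions decision table from [run_decontam()].
#' @param proteins optional protein table ([read_proteins()]); proteins
#'   whose source contig is discarded are purged with it. A protein whose
#'   `contig_id` is unknown is retained with a warning (fail-open) and
#'   counted in the report.
#' @return list with `retained_nt`, `purged_nt`, `retained_aa`,
#'   `purged_aa` (NULL when no proteins) and a `report` data.frame; the
#'   two nucleotide sets are an exact, order-preserving partition of the
#'   input.
#' @export
purge <- function(contigs, decisions, proteins = NULL) {
  dk <- make_seq_id(decisions$project, decisions$contig_id)
  ck <- make_seq_id(contigs$project, contigs$contig_id)
  if (any(!(ck %in% dk))) {
    stop("decisions do not cover contig ", ck[!(ck %in% dk)][1L])
  }
  disc <- dk[decisions$status == "discarded"]
  drop_nt <- ck %in% disc
  retained_nt <- contigs[!drop_nt, , drop = FALSE]
  purged_nt <- contigs[drop_nt, , drop = FALSE]
  rownames(retained_nt) <- rownames(purged_nt) <- NULL

  retained_aa <- purged_aa <- NULL
  n_orphan <- 0L
  if (!is.null(proteins)) {
    pk <- make_seq_id(proteins$project, proteins$contig_id)
    orphan <- !(pk %in% ck)
    n_orphan <- sum(orphan)
    if (n_orphan > 0L) {
      warning(n_orphan, " protein(s) with unknown source contig retained")
    }
    drop_aa <- (pk %in% disc) & !orphan
    retained_aa <- proteins[!drop_aa, , drop = FALSE]
    purged_aa <- proteins[drop_aa, , drop = FALSE]
    rownames(retained_aa) <- rownames(purged_aa) <- NULL
  }
  report <- data.frame(
    what = c("contigs", "proteins"),
    n_in = c(nrow(contigs), if (is.null(proteins)) NA_integer_ else nrow(proteins)),
    n_retained = c(nrow(retained_nt),
                   if (is.null(proteins)) NA_integer_ else nrow(retained_aa)),
    n_purged = c(nrow(purged_nt),
                 if (is.null(proteins)) NA_integer_ else nrow(purged_aa)),
    n_orphan = c(NA_integer_, if (is.null(proteins)) NA_integer_ else n_orphan),
    stringsAsFactors = FALSE)
  list(retained_nt = retained_nt, purged_nt = purged_nt,
       retained_aa = retained_aa, purged_aa = purged_aa, report = report)
}
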