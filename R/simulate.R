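## Synthetic multi-project assemblies with known cross-contamination.
## The generator emulates the data structure the decision procedure
## assumes: within each project pair, contaminant copies produce a hit
## peak at or just below 100% identity, while shared orthologs produce a
## "true" hit mass around a much lower identity, and contaminant copies
## carry a small fraction of the donor's read support.

#' Simulation parameters
#'
#' Defaults define the package's standard study conditions: 4 projects of
#' 200 contigs with log-normal lengths (median ~1000 nt, clamped to
#' 300..5000), 20% of contigs in cross-project ortholog families at ~85%
#' pairwise identity, and 5% of contigs copied into one other project at
#' ~99.5% identity with read counts scaled to 2% of the donor's.
#'
#' @param n_projects number of sequencing projects.
#' @param contigs_per_project native contigs per project (contaminant
#'   copies are added on top).
#' @param length_meanlog,length_sdlog,length_min,length_max log-normal
#'   contig length law (nt) and clamp.
#' @param ortholog_fraction fraction of native contigs that belong to
#'   two-project ortholog families.
#' @param ortholog_divergence per-site substitution probability applied to
#'   each family member relative to the family ancestor (each substitution
#'   changes the base), so pairwise member identity is roughly
#'   `(1 - divergence/2)^2` ~ 85% at the default 0.15.
#' @param contamination_rate fraction of each project's contigs copied
#'   into one other project.
#' @param contaminant_error per-site substitution probability of the
#'   contaminant copy relative to its donor (~99.5% identity at 0.005).
#' @param rpkm_meanlog,rpkm_sdlog log-normal law of native contig RPKM.
#' @param contaminant_count_scale contaminant read count as a fraction of
#'   the donor's read count.
#' @param reads_per_project nominal total mapped reads per project (the
#'   realised total is the column sum of the simulated counts).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_projects = 4L, contigs_per_project = 200L,
                       length_meanlog = log(1000), length_sdlog = 0.45,
                       length_min = 300L, length_max = 5000L,
                       ortholog_fraction = 0.2, ortholog_divergence = 0.15,
                       contamination_rate = 0.05, contaminant_error = 0.005,
                       rpkm_meanlog = log(100), rpkm_sdlog = 1,
                       contaminant_count_scale = 0.02,
                       reads_per_project = 2e6) {
  for (p in c(ortholog_fraction, ortholog_divergence, contamination_rate,
              contaminant_error, contaminant_count_scale)) {
    if (p < 0 || p > 1) stop("probabilities/rates must be in [0, 1]")
  }
  structure(as.list(environment())[c(
    "n_projects", "contigs_per_project", "length_meanlog", "length_sdlog",
    "length_min", "length_max", "ortholog_fraction", "ortholog_divergence",
    "contamination_rate", "contaminant_error", "rpkm_meanlog", "rpkm_sdlog",
    "contaminant_count_scale", "reads_per_project")],
    class = "sim_params")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## substitute each site with probability p, always to a different base
mutate_seq <- function(seq, p) {
  if (p <= 0) return(list(seq = seq, n_sub = 0L))
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  list(seq = paste(v, collapse = ""), n_sub = length(hit))
}

#' Simulate multi-project assemblies with contamination ground truth
#'
#' Generates per-project contigs (unique background + diverged ortholog
#' families), injects contaminant copies across projects, and derives a
#' mapped-read-count table. Deterministic under a fixed seed.
#'
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return list (`sim_data`) with
#'   \describe{
#'     \item{contigs}{contig table over all projects (contaminant copies
#'       included).}
#'     \item{counts}{count table with `"project_totals"` attribute, ready
#'       for [run_decontam()].}
#'     \item{truth}{data.frame of injected contaminants: `donor_project`,
#'       `donor_contig`, `recipient_project`, `recipient_contig`,
#'       `identity` (realised %).}
#'     \item{params, seed}{echo of the generation conditions.}
#'   }
#' @export
simulate_projects <- function(params = sim_params(), seed = 1L) {
  with_seed(seed, {
    np <- params$n_projects
    npc <- params$contigs_per_project
    projects <- sprintf("P%d", seq_len(np))

    draw_len <- function(n) {
      l <- round(rlnorm(n, params$length_meanlog, params$length_sdlog))
      pmin(pmax(l, params$length_min), params$length_max)
    }

    contigs <- list()
    idx <- setNames(rep(0L, np), projects)
    add_contig <- function(project, seq) {
      idx[project] <<- idx[project] + 1L
      id <- sprintf("c%04d", idx[[project]])
      contigs[[length(contigs) + 1L]] <<- data.frame(
        project = project, contig_id = id, sequence = seq,
        length = nchar(seq), stringsAsFactors = FALSE)
      id
    }

    ## ortholog families spanning two projects each
    n_fam <- round(params$ortholog_fraction * npc * np / 2)
    for (f in seq_len(n_fam)) {
      members <- sample(projects, 2L)
      anc <- random_seq(draw_len(1L))
      for (p in members) {
        add_contig(p, mutate_seq(anc, params$ortholog_divergence / 2)$seq)
      }
    }
    ## unique background contigs up to the per-project quota
    for (p in projects) {
      while (idx[[p]] < npc) add_contig(p, random_seq(draw_len(1L)))
    }
    contigs <- do.call(rbind, contigs)

    ## native expression levels and read counts
    rpkm <- rlnorm(nrow(contigs), params$rpkm_meanlog, params$rpkm_sdlog)
    contigs_key <- make_seq_id(contigs$project, contigs$contig_id)
    read_count <- round(rpkm * contigs$length * params$reads_per_project / 1e9)

    ## contaminant injection
    truth <- list()
    n_cont <- round(params$contamination_rate * npc)
    if (n_cont < 1L) warning("no contaminants injected")
    extra <- list()
    extra_counts <- integer()
    for (p in projects) {
      if (n_cont < 1L) break
      native <- which(contigs$project == p)
      donors <- sample(native, n_cont)
      for (d in donors) {
        recipient <- sample(setdiff(projects, p), 1L)
        mut <- mutate_seq(contigs$sequence[d], params$contaminant_error)
        idx[recipient] <- idx[recipient] + 1L
        rid <- sprintf("c%04d", idx[[recipient]])
        extra[[length(extra) + 1L]] <- data.frame(
          project = recipient, contig_id = rid, sequence = mut$seq,
          length = nchar(mut$seq), stringsAsFactors = FALSE)
        extra_counts <- c(extra_counts,
                          round(params$contaminant_count_scale * read_count[d]))
        truth[[length(truth) + 1L]] <- data.frame(
          donor_project = p, donor_contig = contigs$contig_id[d],
          recipient_project = recipient, recipient_contig = rid,
          identity = 100 * (1 - mut$n_sub / contigs$length[d]),
          stringsAsFactors = FALSE)
      }
    }
    if (length(extra)) {
      contigs <- rbind(contigs, do.call(rbind, extra))
      read_count <- c(read_count, extra_counts)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(donor_project = character(), donor_contig = character(),
                 recipient_project = character(),
                 recipient_contig = character(), identity = numeric(),
                 stringsAsFactors = FALSE)

    counts <- data.frame(project = contigs$project,
                         contig_id = contigs$contig_id,
                         read_count = as.integer(read_count),
                         stringsAsFactors = FALSE)
    attr(counts, "project_totals") <-
      tapply(as.numeric(counts$read_count), counts$project, sum)[projects]

    structure(list(contigs = contigs, counts = counts, truth = truth,
                   params = params, seed = as.integer(seed)),
              class = "sim_data")
  })
}

#' Write a simulation to disk
#'
#' One FASTA per project, a count table, and the truth TSV, all in the
#' package's interchange formats.
#'
#' @param sim [simulate_projects()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in unique(sim$contigs$project)) {
    write_fasta(sim$contigs[sim$contigs$project == p, ],
                file.path(dir, paste0(p, ".fasta")))
  }
  write_counts_table(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a decision table against simulation truth
#'
#' Positives are the injected recipient contigs. Precision is
#' `TP / (TP + FP)` over discarded contigs and recall `TP / (TP + FN)`
#' over the truth set. Donor contigs are never counted as false
#' positives: when expression arbitration cannot separate a pair, the
#' procedure deliberately discards both members, and the donor loss is
#' accounted separately.
#'
#' @param decisions decision table from [run_decontam()].
#' @param truth truth table from [simulate_projects()].
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `donors_discarded`. `precision` is `NA` when nothing is discarded.
#' @export
evaluate_decisions <- function(decisions, truth) {
  dk <- make_seq_id(decisions$project, decisions$contig_id)
  pos <- make_seq_id(truth$recipient_project, truth$recipient_contig)
  don <- make_seq_id(truth$donor_project, truth$donor_contig)
  if (length(pos) && any(!(pos %in% dk))) {
    stop("truth recipient absent from decision table: ",
         pos[!(pos %in% dk)][1L])
  }
  disc <- dk[decisions$status == "discarded"]
  tp <- sum(pos %in% disc)
  fn <- length(pos) - tp
  fp <- length(setdiff(disc, union(pos, don)))
  list(precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       recall = if (length(pos)) tp / length(pos) else NA_real_,
       tp = tp, fp = fp, fn = fn,
       donors_discarded = sum(don %in% disc))
}

#' Canonical SIT / SIT-L protein fixtures
#'
#' Builds idealised transporter proteins to the structural definitions:
#' a full SIT (ten 21-residue hydrophobic stretches separated by
#' 15-residue hydrophilic loops, EGXQ-GRQ pairs anchored at TMD2/3 and
#' TMD7/8, an xQxxxQx motif inside TMD4), a SIT-L (five stretches, one
#' pair), and negative controls (the motif set without any hydrophobic
#' stretch; the stretches without any motif). Deterministic.
#'
#' @return data.frame with `protein_id` and `sequence`.
#' @export
make_canonical_fixtures <- function() {
  tm <- "LIVLLAVILVALLIVALLIVL"    # 21 aa, strongly hydrophobic
  tm_q <- "LIVLLAVIQAVLQIVALLIVL"  # TMD4 variant carrying Q...Q (xQxxxQx)
  loop_plain <- "DSDKRTDSNEDKRTS"  # 15 aa, hydrophilic, no motif patterns
  loop_egxq <- "DSDKRTDSNEGAQTS"   # EGXQ (EGAQ variant) near the loop end,
                                   # just before the following TMD
  loop_grq <- "DKRTDSNEDKRTGRQ"    # GRQ at the loop end, at the face of the
                                   # following TMD
  nterm <- "MDSTNKRDSETSDKRTNSDE"  # 20 aa hydrophilic termini
  cterm <- "DSKRTNSDETSDKRTNSDEK"

  sit <- paste0(nterm,
                tm, loop_egxq,   # TMD1; EGXQ before TMD2
                tm, loop_grq,    # TMD2; GRQ at the face of TMD3
                tm, loop_plain,  # TMD3
                tm_q, loop_plain,# TMD4 with xQxxxQx
                tm, loop_plain,  # TMD5
                tm, loop_egxq,   # TMD6; EGXQ before TMD7
                tm, loop_grq,    # TMD7; GRQ at the face of TMD8
                tm, loop_plain,  # TMD8
                tm, loop_plain,  # TMD9
                tm, cterm)       # TMD10

  sitl <- paste0(nterm,
                 tm, loop_egxq,   # TMD1; EGXQ before TMD2
                 tm, loop_grq,    # TMD2; GRQ at the face of TMD3
                 tm, loop_plain,  # TMD3
                 tm_q, loop_plain,# TMD4
                 tm, cterm)       # TMD5
  motifs_only <- paste0(nterm, "EGAQ", loop_plain, "GRQ", loop_plain,
                        "QAAAQ", cterm)
  tmds_only <- paste0(nterm, paste(rep(paste0(tm, loop_plain), 5L),
                                   collapse = ""), cterm)
  data.frame(
    protein_id = c("canonical_SIT", "canonical_SITL", "motifs_no_tmds",
                   "tmds_no_motifs"),
    sequence = c(sit, sitl, motifs_only, tmds_only),
    stringsAsFactors = FALSE)
}
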