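## Readers/writers for the interchange formats used throughout the package:
## FASTA (nucleotide and protein, lowercase = soft-masked), 12-column tabular
## hit files, TSV count tables with "*" project-total rows, and newick trees
## with numeric internal-node support labels. All coordinates are 1-based
## inclusive; project labels travel inside sequence ids as "project|contig".

#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA, preserving the case of every residue
#' (lowercase encodes soft-masked positions in nucleotide data). Sequence ids
#' are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` (A, C, G, T, N, either case) or
#'   `"protein"` (the 20 standard residues plus X, either case, `*` allowed
#'   as a trailing stop).
#' @return A data.frame with columns `id`, `sequence`, `length`, one row per
#'   record in file order. An empty file yields zero rows with a warning.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", lines))) {
    if (any(nzchar(trimws(lines)))) stop("not FASTA (no '>' header): ", path)
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  seqs <- as.character(set)
  pat <- if (alphabet == "nucleotide") "[^ACGTNacgtn]" else
    "[^ACDEFGHIKLMNPQRSTVWYXacdefghiklmnpqrstvwyx*]"
  bad <- regexpr(pat, seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal ", alphabet, " character '",
         substr(seqs[i], bad[i], bad[i]), "' in record '", ids[i],
         "' at position ", bad[i])
  }
  data.frame(id = ids, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id` and `sequence` (case
#'   preserved), or a contig table with `project`/`contig_id` columns, in
#'   which case ids are written as `"project|contig"`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.null(records$id)) {
    records$id <- make_seq_id(records$project, records$contig_id)
  }
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a project's contigs from FASTA
#'
#' @param path FASTA path.
#' @param project project label; if `NULL`, ids must carry it as
#'   `"project|contig"`.
#' @return Contig table: data.frame with columns `project`, `contig_id`,
#'   `sequence`, `length`.
#' @export
read_contigs <- function(path, project = NULL) {
  fa <- read_fasta(path, "nucleotide")
  if (is.null(project)) {
    pc <- split_seq_id(fa$id)
  } else {
    ids <- fa$id
    pre <- paste0(project, "|")
    carries <- startsWith(ids, pre)   # ids may already be "project|contig"
    ids[carries] <- substring(ids[carries], nchar(pre) + 1L)
    pc <- data.frame(project = rep(project, nrow(fa)), contig_id = ids,
                     stringsAsFactors = FALSE)
  }
  out <- data.frame(project = pc$project, contig_id = pc$contig_id,
                    sequence = fa$sequence, length = fa$length,
                    stringsAsFactors = FALSE)
  key <- make_seq_id(out$project, out$contig_id)
  if (anyDuplicated(key)) stop("duplicate (project, contig_id): ",
                               key[duplicated(key)][1L])
  out
}

#' Read predicted proteins from FASTA
#'
#' Protein ids are linked to their source contig: by default the contig id is
#' the protein id with a trailing `".p<N>"` / `"_p<N>"` ORF suffix removed
#' (identity if no suffix).
#'
#' @param path FASTA path.
#' @param project project label; if `NULL`, parsed from `"project|id"` ids.
#' @param contig_of function mapping protein id to source contig id.
#' @return data.frame with columns `project`, `protein_id`, `contig_id`,
#'   `sequence`.
#' @export
read_proteins <- function(path, project = NULL,
                          contig_of = function(id) sub("[._]p[0-9]+$", "", id)) {
  fa <- read_fasta(path, "protein")
  if (is.null(project)) {
    pc <- split_seq_id(fa$id)
    project <- pc$project
    pid <- pc$contig_id
  } else {
    project <- rep(project, nrow(fa))
    pid <- fa$id
  }
  data.frame(project = project, protein_id = pid,
             contig_id = contig_of(pid), sequence = fa$sequence,
             stringsAsFactors = FALSE)
}

## ---- tabular hits -------------------------------------------------------

hit_columns <- c("q_project", "q_contig", "s_project", "s_contig",
                 "pident", "aln_len", "mismatch", "gapopen",
                 "q_start", "q_end", "s_start", "s_end",
                 "evalue", "score", "strand")

#' Read a 12-column tabular hit file
#'
#' Ingests the standard `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore` layout produced by local aligners, with
#' project labels encoded in sequence ids as `"project|contig"`. Rows whose
#' query and subject belong to the same project are dropped (the
#' decontamination procedure compares projects, never contigs within one);
#' the number dropped is stored in the `"n_dropped_same_project"` attribute.
#' Subject strand is inferred from `sstart > send` and subject coordinates
#' are normalised to the forward strand.
#'
#' @param path path to the tab-separated hit file; `#`-comment lines skipped.
#' @return Hit table (data.frame) with columns
#'   `q_project, q_contig, s_project, s_contig, pident, aln_len, mismatch,
#'   gapopen, q_start, q_end, s_start, s_end, evalue, score, strand`.
#' @export
read_hits_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed hit row (", nf[nf != 12L][1L], " fields, expected 12) at line ",
         lineno[nf != 12L][1L], " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop("non-numeric field in hit row at line ", lineno[bad], " of ", path)
  }
  q <- split_seq_id(m[, 1L])
  s <- split_seq_id(m[, 2L])
  same <- q$project == s$project
  n_dropped <- sum(same)
  sstart <- num[, 7L]; send <- num[, 8L]
  strand <- ifelse(sstart > send, "-", "+")
  hits <- data.frame(
    q_project = q$project, q_contig = q$contig_id,
    s_project = s$project, s_contig = s$contig_id,
    pident = num[, 1L], aln_len = as.integer(num[, 2L]),
    mismatch = as.integer(num[, 3L]), gapopen = as.integer(num[, 4L]),
    q_start = as.integer(num[, 5L]), q_end = as.integer(num[, 6L]),
    s_start = as.integer(pmin(sstart, send)),
    s_end = as.integer(pmax(sstart, send)),
    evalue = num[, 9L], score = num[, 10L], strand = strand,
    stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("pident outside [0,100] at line ",
         lineno[which(hits$pident < 0 | hits$pident > 100)[1L]])
  }
  hits <- hits[!same, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_dropped_same_project") <- n_dropped
  hits
}

#' Write a hit table in 12-column tabular layout
#'
#' Inverse of [read_hits_table()]: minus-strand hits are written with
#' `sstart > send`.
#'
#' @param hits hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  minus <- hits$strand == "-"
  ss <- ifelse(minus, hits$s_end, hits$s_start)
  se <- ifelse(minus, hits$s_start, hits$s_end)
  out <- data.frame(
    qseqid = make_seq_id(hits$q_project, hits$q_contig),
    sseqid = make_seq_id(hits$s_project, hits$s_contig),
    pident = format(hits$pident, trim = TRUE),
    length = hits$aln_len,
    mismatch = hits$mismatch %||% (hits$aln_len - round(hits$pident * hits$aln_len / 100)),
    gapopen = hits$gapopen %||% 0L,
    qstart = hits$q_start, qend = hits$q_end, sstart = ss, send = se,
    evalue = hits$evalue %||% 0, bitscore = hits$score,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- count tables -------------------------------------------------------

#' Read a per-contig mapped-read-count table
#'
#' TSV with header `project contig_id read_count`. Each project's total
#' mapped reads is given by a companion row whose `contig_id` is `"*"`
#' (the convention used by mapping statistics tools).
#'
#' @param path TSV path.
#' @return data.frame with columns `project`, `contig_id`, `read_count`
#'   (total rows removed) carrying a named numeric attribute
#'   `"project_totals"`.
#' @export
read_counts_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  need <- c("project", "contig_id", "read_count")
  if (!all(need %in% names(tab))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$read_count < 0)) {
    bad <- tab[tab$read_count < 0, ][1L, ]
    stop("negative read count for ", bad$project, "|", bad$contig_id)
  }
  is_total <- tab$contig_id == "*"
  totals <- setNames(as.numeric(tab$read_count[is_total]),
                     tab$project[is_total])
  counts <- tab[!is_total, need, drop = FALSE]
  missing <- setdiff(unique(counts$project), names(totals))
  if (length(missing)) {
    stop("no project_total_reads ('*' row) for project(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(totals <= 0)) {
    stop("project_total_reads must be positive for: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  rownames(counts) <- NULL
  attr(counts, "project_totals") <- totals
  counts
}

#' Write a count table (with `"*"` total rows)
#'
#' @param counts data.frame with `project`, `contig_id`, `read_count`.
#' @param path output path.
#' @param totals named numeric of per-project totals; defaults to the
#'   table's `"project_totals"` attribute, else per-project column sums.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path, totals = NULL) {
  totals <- totals %||% attr(counts, "project_totals") %||%
    tapply(counts$read_count, counts$project, sum)
  tot <- data.frame(project = names(totals), contig_id = "*",
                    read_count = as.numeric(totals), stringsAsFactors = FALSE)
  out <- rbind(counts[, c("project", "contig_id", "read_count")], tot)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- newick trees -------------------------------------------------------

#' Parse a newick string into a support-annotated tree
#'
#' Numeric internal-node labels (the convention of standard maximum
#' likelihood programs for bootstrap values) are interpreted as support in
#' \[0, 100\]; non-numeric or absent labels give absent support.
#'
#' @param text newick string.
#' @return An `ape::phylo` tree; supports are available via
#'   [tree_supports()].
#' @export
parse_newick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' in newick at character ", i)
  }
  if (depth != 0L) stop("unbalanced '(' in newick: ", depth,
                        " unclosed at end of string")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error (no tree in string)")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  tr
}

#' Internal-node support values of a tree
#'
#' @param tree `phylo` object.
#' @return numeric vector of length `tree$Nnode` (NA where absent), indexed
#'   by internal node number minus `Ntip(tree)`.
#' @export
tree_supports <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  length(sup) <- n
  sup
}

#' Write a tree as newick
#'
#' @param tree `phylo` object.
#' @param file optional path; if missing, the newick string is returned.
#' @return newick string (or `file`, invisibly).
#' @export
write_newick <- function(tree, file = "") {
  ape::write.tree(tree, file = file)
}
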