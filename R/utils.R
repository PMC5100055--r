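## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package simulators are
#' deterministic under a caller-supplied seed without disturbing the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Canonical label for an unordered project pair.
pair_key <- function(p1, p2) {
  paste(pmin(p1, p2), pmax(p1, p2), sep = "\x1f")
}

pair_label <- function(p1, p2) {
  paste(pmin(p1, p2), pmax(p1, p2), sep = "|")
}

## "project|contig" interchange ids.
make_seq_id <- function(project, contig_id) paste(project, contig_id, sep = "|")

split_seq_id <- function(id) {
  pos <- regexpr("|", id, fixed = TRUE)
  bad <- pos < 0L
  if (any(bad)) {
    stop("sequence id(s) without 'project|contig' structure: ",
         paste(utils::head(id[bad], 3L), collapse = ", "))
  }
  data.frame(project = substr(id, 1L, pos - 1L),
             contig_id = substr(id, pos + 1L, nchar(id)),
             stringsAsFactors = FALSE)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
}
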