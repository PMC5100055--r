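## Phylogenetic contamination screen. Given an existing support-annotated
## housekeeping-gene tree, a query contig is at risk of being
## contaminant-derived when it branches, with bootstrap support above the
## threshold, inside a clade composed purely of a foreign group and away
## from the expected framework sequences. Contigs branching with
## prokaryotes are excepted: bacterial co-culture contamination is common
## and is not evidence against the query sequence itself.

#' Tree-screen configuration
#'
#' @param support_threshold bootstrap support above which (strictly) a
#'   bipartition counts as well supported; default 70.
#' @param group_map named character vector mapping each framework leaf
#'   label to a group label (e.g. `"stramenopile"`, `"choanoflagellate"`,
#'   `"prokaryote"`). The query leaf itself needs no mapping.
#' @param expected_group the group the query is supposed to branch with.
#' @param exception_groups groups whose association does not flag the
#'   query (default `"prokaryote"`).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(support_threshold = 70, group_map,
                          expected_group,
                          exception_groups = "prokaryote") {
  if (is.null(names(group_map))) stop("'group_map' must be a named vector")
  structure(list(support_threshold = support_threshold,
                 group_map = group_map, expected_group = expected_group,
                 exception_groups = exception_groups),
            class = "screen_config")
}

## All non-trivial bipartitions of the tree, expressed as the leaf set on
## the query's side minus the query, with the support of the split. In a
## rooted binary parse the two root-adjacent edges encode the same split,
## possibly with two labels; the label attached to the clade containing
## the query takes precedence (it is "the support with which the query
## branches there"), the complement node's label is the fallback.
query_side_splits <- function(tree, query) {
  ntip <- length(tree$tip.label)
  sup <- tree_supports(tree)
  all_leaves <- tree$tip.label
  splits <- list()
  if (tree$Nnode < 2L) return(splits)
  for (node in (ntip + 2L):(ntip + tree$Nnode)) {  # skip the root
    clade <- ape::extract.clade(tree, node)$tip.label
    has_query <- query %in% clade
    side <- if (has_query) clade else setdiff(all_leaves, clade)
    others <- sort(setdiff(side, query))
    if (length(others) == 0L || length(others) == ntip - 1L) next
    key <- paste(others, collapse = "\x1f")
    s <- sup[node - ntip]
    if (is.null(splits[[key]])) {
      splits[[key]] <- list(others = others, support = s,
                            from_query_clade = has_query)
    } else if ((has_query && !splits[[key]]$from_query_clade &&
                !is.na(s)) ||
               (has_query == splits[[key]]$from_query_clade &&
                is.na(splits[[key]]$support))) {
      splits[[key]]$support <- s
      splits[[key]]$from_query_clade <- has_query
    } else if (!has_query && is.na(splits[[key]]$support) && !is.na(s)) {
      splits[[key]]$support <- s
    }
  }
  splits[order(vapply(splits, function(x) length(x$others), integer(1L)))]
}

#' Screen a query leaf against a support-annotated tree
#'
#' Walks the bipartitions containing the query from the tip outward
#' (smallest query-side leaf set first). At each well-supported split
#' (support strictly greater than the threshold): if the query's side
#' contains any leaf of the expected group, the query is `"clean"`; if all
#' its non-query leaves belong to one foreign group, the query is
#' `"flagged"` (or `"exception"` when that group is an exception group,
#' e.g. prokaryotes); a well-supported side mixing several foreign groups
#' is not discriminating and the walk continues. With no discriminating
#' well-supported split the verdict is `"clean"`. Because the rule is
#' evaluated on bipartitions, it is invariant under re-rooting.
#'
#' @param tree `phylo` tree with numeric internal-node support labels
#'   (see [parse_newick()]).
#' @param query query leaf label.
#' @param cfg [screen_config()].
#' @return `"flagged"`, `"clean"` or `"exception"`.
#' @export
screen_query <- function(tree, query, cfg) {
  if (!(query %in% tree$tip.label)) stop("query leaf not in tree: ", query)
  if (length(tree$tip.label) < 3L) stop("tree must have >= 3 leaves")
  others_all <- setdiff(tree$tip.label, query)
  unmapped <- setdiff(others_all, names(cfg$group_map))
  if (length(unmapped)) {
    stop("leaf/leaves without group mapping: ",
         paste(unmapped, collapse = ", "))
  }
  for (sp in query_side_splits(tree, query)) {
    s <- sp$support
    if (is.na(s) || s <= cfg$support_threshold) next
    groups <- unique(unname(cfg$group_map[sp$others]))
    if (cfg$expected_group %in% groups) return("clean")
    if (length(groups) == 1L) {
      return(if (groups %in% cfg$exception_groups) "exception" else "flagged")
    }
  }
  "clean"
}
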