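#' Filtering configuration
#'
#' @param min_term_size terms annotating fewer than this many genes are
#'   discarded before redundancy filtering (default 10). Strict `<`: a term
#'   of exactly this size survives.
#' @param max_representative_size optional cap on the size of terms allowed
#'   to represent others. Unset (`NULL`) by default. When set, a term larger
#'   than the cap never represents another term: keeping only smaller
#'   representatives leaves more specific terms in the filtered output.
#' @param top_n_plot number of representative terms shown in the figures;
#'   default and maximum 50.
#' @param keep_oversized_as_self when `max_representative_size` is set,
#'   oversized terms are by default removed from the output entirely
#'   (recorded in `oversized_ids`). Set `TRUE` to instead keep each oversized
#'   term as a representative of itself only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_term_size = 10L,
                          max_representative_size = NULL,
                          top_n_plot = 50L,
                          keep_oversized_as_self = FALSE) {
  min_term_size <- as.integer(min_term_size)
  top_n_plot <- as.integer(top_n_plot)
  if (is.na(min_term_size) || min_term_size < 1L) {
    stop("min_term_size must be an integer >= 1", call. = FALSE)
  }
  if (is.na(top_n_plot) || top_n_plot < 1L || top_n_plot > 50L) {
    stop("top_n_plot must be between 1 and 50", call. = FALSE)
  }
  if (!is.null(max_representative_size)) {
    max_representative_size <- as.integer(max_representative_size)
    if (is.na(max_representative_size) ||
        max_representative_size < min_term_size) {
      stop("max_representative_size must be >= min_term_size", call. = FALSE)
    }
  }
  structure(list(min_term_size = min_term_size,
                 max_representative_size = max_representative_size,
                 top_n_plot = top_n_plot,
                 keep_oversized_as_self = isTRUE(keep_oversized_as_self)),
            class = "filter_config")
}

#' Merge ranked enrichment results
#'
#' Deduplicates the union of the input lists. Each term receives the best
#' (minimum) rank it has in any input result, alongside its per-source
#' ranks. Entries are ordered by processing order: best rank ascending, ties
#' broken by first appearance when the input lists are scanned position by
#' position in the order given (rank 1 of list 1, rank 1 of list 2, ...,
#' rank 2 of list 1, ...). This order is the order in which the redundancy
#' filter later considers terms.
#'
#' @param lists a list of [ranked_term_list] objects with unique aliases.
#' @return Object of class `merged_ranking`: `term_ids` (processing order),
#'   `best_rank` (named integer), `ranks` (term x source integer matrix,
#'   `NA` where a term is absent from a source), `aliases`,
#'   `list_lengths` (named, per source).
#' @export
merge_rankings <- function(lists) {
  if (inherits(lists, "ranked_term_list")) lists <- list(lists)
  if (length(lists) < 1L) stop("at least one ranked list is required", call. = FALSE)
  stopifnot(all(vapply(lists, inherits, logical(1L), "ranked_term_list")))
  aliases <- vapply(lists, `[[`, character(1L), "alias")
  if (anyDuplicated(aliases)) {
    stop("duplicate source alias: ", aliases[duplicated(aliases)][1L],
         call. = FALSE)
  }
  # interleaved first-appearance scan: position 1 of every list, then 2, ...
  max_len <- max(vapply(lists, function(l) length(l$term_ids), integer(1L)))
  appearance <- character(0L)
  for (pos in seq_len(max_len)) {
    for (l in lists) {
      if (pos <= length(l$term_ids)) appearance <- c(appearance, l$term_ids[[pos]])
    }
  }
  all_ids <- unique(appearance)
  ranks <- matrix(NA_integer_, nrow = length(all_ids), ncol = length(lists),
                  dimnames = list(all_ids, aliases))
  for (j in seq_along(lists)) {
    ids_j <- lists[[j]]$term_ids
    ranks[ids_j, j] <- seq_along(ids_j)
  }
  best <- apply(ranks, 1L, min, na.rm = TRUE)
  ord <- order(best, match(all_ids, unique(appearance)), method = "radix")
  term_ids <- all_ids[ord]
  structure(list(term_ids = term_ids,
                 best_rank = stats::setNames(as.integer(best[ord]), term_ids),
                 ranks = ranks[term_ids, , drop = FALSE],
                 aliases = aliases,
                 list_lengths = stats::setNames(
                   vapply(lists, function(l) length(l$term_ids), integer(1L)),
                   aliases)),
            class = "merged_ranking")
}

#' @export
print.merged_ranking <- function(x, ...) {
  cat("<merged_ranking> ", length(x$term_ids), " unique terms from ",
      length(x$aliases), " source(s): ", paste(x$aliases, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

subset_merged <- function(merged, keep_ids) {
  keep <- merged$term_ids %in% keep_ids
  structure(list(term_ids = merged$term_ids[keep],
                 best_rank = merged$best_rank[keep],
                 ranks = merged$ranks[keep, , drop = FALSE],
                 aliases = merged$aliases,
                 list_lengths = merged$list_lengths),
            class = "merged_ranking")
}

#' Remove undersized and unannotated terms
#'
#' Terms annotating fewer than `min_size` genes carry little specific
#' information and are dropped before redundancy filtering. Terms present in
#' the enrichment results but absent from the GMT cannot be size- or
#' coverage-checked and are set aside with a warning. The relative order of
#' the surviving terms is preserved.
#'
#' @param merged a [merge_rankings] result.
#' @param annotations an [annotation_collection].
#' @param min_size integer >= 1; strict `<` threshold.
#' @return List with `merged` (the filtered `merged_ranking`),
#'   `undersized_ids` and `unannotated_ids`.
#' @export
remove_undersized <- function(merged, annotations, min_size = 10L) {
  stopifnot(inherits(merged, "merged_ranking"),
            inherits(annotations, "annotation_collection"))
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 1L) {
    stop("min_size must be an integer >= 1", call. = FALSE)
  }
  known <- merged$term_ids %in% names(annotations$gene_sets)
  unannotated <- merged$term_ids[!known]
  if (length(unannotated) > 0L) {
    warning(length(unannotated),
            " term(s) in the enrichment results are absent from the GMT ",
            "and were set aside (e.g. ", unannotated[1L], ")", call. = FALSE)
  }
  known_ids <- merged$term_ids[known]
  sizes <- term_sizes(annotations, known_ids)
  undersized <- known_ids[sizes < min_size]
  survivors <- known_ids[sizes >= min_size]
  list(merged = subset_merged(merged, survivors),
       undersized_ids = undersized,
       unannotated_ids = unannotated)
}

#' Does one term cover another?
#'
#' Term `other` covers term `candidate` when `other` annotates at least the
#' same genes: its gene set is a superset of (or equal to) the candidate's.
#'
#' @param candidate_id,other_id term IDs present in `annotations`.
#' @param annotations an [annotation_collection].
#' @return `TRUE` or `FALSE`.
#' @export
is_covered <- function(candidate_id, other_id, annotations) {
  sets <- annotations$gene_sets
  for (id in c(candidate_id, other_id)) {
    if (!id %in% names(sets)) stop("unknown term ID: ", id, call. = FALSE)
  }
  all(sets[[candidate_id]] %in% sets[[other_id]])
}

#' Redundancy filtering by subset coverage
#'
#' The core summarization step. Terms are walked in processing order (best
#' rank first). A term is discarded when an earlier surviving term covers
#' all of its genes; the earliest such survivor becomes its representative.
#' Otherwise the term starts a new representative group. Representation is
#' flat: a discarded term always maps directly to a surviving
#' representative, never to another discarded term. Terms with equal gene
#' sets are covered by whichever comes first in processing order.
#'
#' When `max_representative_size` is set, a term larger than the cap never
#' represents another term; by default such oversized terms are removed from
#' the output entirely (see [filter_config]).
#'
#' @param merged a `merged_ranking` that has already passed
#'   [remove_undersized] (every term present in `annotations`).
#' @param annotations an [annotation_collection].
#' @param config a [filter_config].
#' @param undersized_ids,unannotated_ids carried through into the outcome
#'   ledger for bookkeeping (defaults: empty).
#' @return Object of class `filter_outcome`: `groups` (ordered list, each
#'   with `representative_id` and `represented_ids`), `undersized_ids`,
#'   `unannotated_ids`, `oversized_ids`, `aliases`, `merged` (the input
#'   ranking, for report generation).
#' @export
filter_redundant <- function(merged, annotations, config = filter_config(),
                             undersized_ids = character(0L),
                             unannotated_ids = character(0L)) {
  stopifnot(inherits(merged, "merged_ranking"),
            inherits(annotations, "annotation_collection"),
            inherits(config, "filter_config"))
  sets <- annotations$gene_sets
  missing <- setdiff(merged$term_ids, names(sets))
  if (length(missing) > 0L) {
    stop("term absent from annotations (run remove_undersized first): ",
         missing[1L], call. = FALSE)
  }
  max_rep <- config$max_representative_size
  rep_ids <- character(0L)      # surviving representatives, processing order
  rep_can_cover <- logical(0L)  # FALSE for oversized self-only reps
  represented <- list()         # parallel to rep_ids
  oversized <- character(0L)
  for (id in merged$term_ids) {
    genes <- sets[[id]]
    assigned <- FALSE
    for (j in seq_along(rep_ids)) {
      if (!rep_can_cover[j]) next
      if (all(genes %in% sets[[rep_ids[j]]])) {
        represented[[j]] <- c(represented[[j]], id)
        assigned <- TRUE
        break
      }
    }
    if (assigned) next
    oversize <- !is.null(max_rep) && length(genes) > max_rep
    if (oversize && !config$keep_oversized_as_self) {
      oversized <- c(oversized, id)
    } else {
      rep_ids <- c(rep_ids, id)
      rep_can_cover <- c(rep_can_cover, !oversize)
      represented[[length(rep_ids)]] <- character(0L)
    }
  }
  groups <- lapply(seq_along(rep_ids), function(j) {
    list(representative_id = rep_ids[j], represented_ids = represented[[j]])
  })
  structure(list(groups = groups,
                 undersized_ids = undersized_ids,
                 unannotated_ids = unannotated_ids,
                 oversized_ids = oversized,
                 aliases = merged$aliases,
                 merged = merged),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  n_repr <- sum(vapply(x$groups, function(g) length(g$represented_ids), integer(1L)))
  cat("<filter_outcome> ", length(x$groups), " representative group(s), ",
      n_repr, " represented, ", length(x$undersized_ids), " undersized, ",
      length(x$unannotated_ids), " unannotated, ",
      length(x$oversized_ids), " oversized\n", sep = "")
  invisible(x)
}

#' Representative term IDs of a filtering outcome
#'
#' @param outcome a `filter_outcome`.
#' @return Character vector in processing order.
#' @export
representatives <- function(outcome) {
  stopifnot(inherits(outcome, "filter_outcome"))
  vapply(outcome$groups, `[[`, character(1L), "representative_id")
}

#' Represented-term counts per representative
#'
#' @param outcome a `filter_outcome`.
#' @return Named integer vector in processing order.
#' @export
represented_counts <- function(outcome) {
  stopifnot(inherits(outcome, "filter_outcome"))
  stats::setNames(
    vapply(outcome$groups, function(g) length(g$represented_ids), integer(1L)),
    representatives(outcome))
}
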