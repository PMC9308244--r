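#' Run the full summarization pipeline
#'
#' Wires the whole method together: read the GMT and the ranked enrichment
#' results, merge them with best-rank deduplication, drop undersized and
#' unannotated terms, apply subset-coverage redundancy filtering, and write
#' the five output artifacts (`<base>-Summary.tsv`, `<base>-Detailed.tsv`,
#' `<base>.html`, a rank-quartile heatmap and a represented-count barplot,
#' each as both PNG and SVG). Stage counts (merged, undersized, unannotated,
#' oversized, representatives) are logged via [message()].
#'
#' @param gmt_path path to the GMT annotation file.
#' @param result_paths paths to one or more ranked enrichment results (one
#'   term ID per line, most significant first). Their order fixes the
#'   tie-break order in merging and the column order in reports.
#' @param aliases optional source labels, one per result path (default: file
#'   base names); must be unique.
#' @param output_dir directory for all outputs (created if needed).
#' @param min_term_size,max_representative_size,top_n_plot,keep_oversized_as_self
#'   see [filter_config].
#' @param base_name prefix for output file names (default `"enrichsum"`).
#' @param quiet suppress stage-count messages.
#' @return Invisibly, a list with `outcome` (the `filter_outcome`), `ranks`,
#'   `quartiles`, `correlation` (or `NULL` when fewer than 3
#'   representatives) and `files` (named vector of written paths).
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("T1\tparent\tg1\tg2\tg3\tg4\tg5\tg6\tg7\tg8\tg9\tg10",
#'              "T2\tchild\tg1\tg2\tg3\tg4\tg5\tg6\tg7\tg8\tg9\tg10"), gmt)
#' res <- tempfile(fileext = ".txt")
#' writeLines(c("T1", "T2"), res)
#' out <- run_enrichsum(gmt, res, aliases = "demo",
#'                      output_dir = tempfile(), min_term_size = 1)
#' representatives(out$outcome)
#' @export
run_enrichsum <- function(gmt_path, result_paths, aliases = NULL,
                          output_dir, min_term_size = 10L,
                          max_representative_size = NULL, top_n_plot = 50L,
                          keep_oversized_as_self = FALSE,
                          base_name = "enrichsum", quiet = FALSE) {
  config <- filter_config(min_term_size, max_representative_size, top_n_plot,
                          keep_oversized_as_self)
  if (length(result_paths) < 1L) {
    stop("at least one enrichment result file is required", call. = FALSE)
  }
  if (is.null(aliases)) {
    aliases <- tools::file_path_sans_ext(basename(result_paths))
  }
  if (length(aliases) != length(result_paths)) {
    stop("aliases must match the number of result files", call. = FALSE)
  }
  if (anyDuplicated(aliases)) {
    stop("duplicate source alias: ", aliases[duplicated(aliases)][1L],
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)

  annotations <- parse_gmt(gmt_path)
  say("read GMT: ", length(annotations), " terms, ",
      length(collection_universe(annotations)), " genes")
  lists <- Map(read_ranked_terms, result_paths, aliases)
  names(lists) <- NULL
  for (l in lists) say("read '", l$alias, "': ", length(l$term_ids), " terms")

  merged <- merge_rankings(lists)
  say("merged: ", length(merged$term_ids), " unique terms")
  sized <- remove_undersized(merged, annotations, config$min_term_size)
  say("undersized (< ", config$min_term_size, " genes): ",
      length(sized$undersized_ids), "; unannotated: ",
      length(sized$unannotated_ids), "; remaining: ",
      length(sized$merged$term_ids))
  outcome <- filter_redundant(sized$merged, annotations, config,
                              undersized_ids = sized$undersized_ids,
                              unannotated_ids = sized$unannotated_ids)
  say("representative terms: ", length(outcome$groups),
      if (length(outcome$oversized_ids) > 0L)
        paste0("; oversized removed: ", length(outcome$oversized_ids)) else "")

  ranks <- group_source_ranks(outcome, lists)
  quartiles <- assign_quartiles(ranks, lists)
  files <- write_reports(outcome, ranks, annotations, output_dir, base_name)
  if (length(outcome$groups) > 0L) {
    for (ext in c("png", "svg")) {
      hm <- file.path(output_dir, paste0(base_name, "-Heatmap.", ext))
      bp <- file.path(output_dir, paste0(base_name, "-Barplot.", ext))
      render_heatmap(quartiles, config$top_n_plot, hm)
      render_barplot(outcome, config$top_n_plot, bp)
      files <- c(files, stats::setNames(c(hm, bp),
                                        paste(c("heatmap", "barplot"), ext,
                                              sep = "_")))
    }
  } else {
    say("no representative terms; figures skipped")
  }
  correlation <- NULL
  if (length(outcome$groups) >= 3L) {
    correlation <- size_representation_correlation(outcome, annotations)
    say(sprintf("term size vs represented count: Spearman rho = %.3f (p = %.3g)",
                correlation$rho, correlation$p))
  }
  invisible(list(outcome = outcome, ranks = ranks, quartiles = quartiles,
                 correlation = correlation, files = files))
}
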