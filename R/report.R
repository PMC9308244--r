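#' Best rank of each representative group in each source
#'
#' For every representative group (the representative plus the terms it
#' represents) and every input result, the group's rank in that source is
#' the best (minimum) rank over group members present in the source; `NA`
#' when no member appears there. Using the best rank over the whole group
#' keeps a representative visible in a source where only terms it represents
#' were enriched.
#'
#' @param outcome a `filter_outcome` produced from `lists`.
#' @param lists the same [ranked_term_list] collection the outcome was
#'   computed from (aliases must match).
#' @return Integer matrix, representatives x sources, `NA` for absent.
#' @export
group_source_ranks <- function(outcome, lists) {
  stopifnot(inherits(outcome, "filter_outcome"))
  if (inherits(lists, "ranked_term_list")) lists <- list(lists)
  aliases <- vapply(lists, `[[`, character(1L), "alias")
  if (!identical(unname(aliases), unname(outcome$aliases))) {
    stop("source aliases do not match the ones the outcome was built from",
         call. = FALSE)
  }
  reps <- representatives(outcome)
  out <- matrix(NA_integer_, nrow = length(reps), ncol = length(lists),
                dimnames = list(reps, aliases))
  for (j in seq_along(lists)) {
    pos <- stats::setNames(seq_along(lists[[j]]$term_ids), lists[[j]]$term_ids)
    for (i in seq_along(outcome$groups)) {
      members <- c(outcome$groups[[i]]$representative_id,
                   outcome$groups[[i]]$represented_ids)
      r <- pos[members]
      r <- r[!is.na(r)]
      if (length(r) > 0L) out[i, j] <- min(r)
    }
  }
  out
}

#' Quartile of a rank within a source list
#'
#' The quartile of rank r in a list of length L is `ceiling(4 r / L)`,
#' clipped to 1..4: ranks in the top quarter of a result map to Q1, the
#' bottom quarter to Q4. In the degenerate single-term list the formula
#' yields Q4 and that value is kept. `NA` (group absent from the source)
#' propagates.
#'
#' @param ranks matrix from [group_source_ranks].
#' @param lists the [ranked_term_list] collection defining list lengths.
#' @return Integer matrix of quartiles 1-4, `NA` for absent.
#' @export
assign_quartiles <- function(ranks, lists) {
  if (inherits(lists, "ranked_term_list")) lists <- list(lists)
  aliases <- vapply(lists, `[[`, character(1L), "alias")
  lens <- vapply(lists, function(l) length(l$term_ids), integer(1L))
  stopifnot(identical(colnames(ranks), unname(aliases)))
  out <- ranks
  for (j in seq_len(ncol(ranks))) {
    q <- ceiling(4 * ranks[, j] / lens[j])
    out[, j] <- as.integer(pmin(4, pmax(1, q)))
  }
  out
}

summary_table <- function(outcome, ranks, annotations) {
  reps <- representatives(outcome)
  n_rep <- represented_counts(outcome)
  df <- data.frame(
    representative_id = reps,
    description = unname(annotations$descriptions[reps]),
    term_size = unname(term_sizes(annotations, reps)),
    n_represented = unname(n_rep),
    stringsAsFactors = FALSE
  )
  if (length(reps) == 0L) {
    df <- df[0L, , drop = FALSE]
  }
  rank_df <- as.data.frame(ranks[, , drop = FALSE])
  names(rank_df) <- paste0("rank_", colnames(ranks))
  if (nrow(rank_df) == nrow(df)) df <- cbind(df, rank_df)
  rownames(df) <- NULL
  df
}

detailed_table <- function(outcome, ranks, annotations) {
  rows <- list()
  per_term_rank <- outcome$merged$ranks
  for (g in outcome$groups) {
    members <- c(g$representative_id, g$represented_ids)
    role <- c("representative", rep("represented", length(g$represented_ids)))
    for (i in seq_along(members)) {
      id <- members[i]
      row <- data.frame(
        representative_id = g$representative_id,
        term_id = id,
        role = role[i],
        description = unname(annotations$descriptions[id]),
        term_size = unname(term_sizes(annotations, id)),
        stringsAsFactors = FALSE
      )
      r <- per_term_rank[id, , drop = FALSE]
      rdf <- as.data.frame(r)
      names(rdf) <- paste0("rank_", colnames(per_term_rank))
      rownames(rdf) <- NULL
      rows[[length(rows) + 1L]] <- cbind(row, rdf)
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(representative_id = character(0L), term_id = character(0L),
                     role = character(0L), description = character(0L),
                     term_size = integer(0L), stringsAsFactors = FALSE)
    for (a in colnames(per_term_rank)) df[[paste0("rank_", a)]] <- integer(0L)
    return(df)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_html <- function(outcome, annotations, base_name) {
  head <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", html_escape(base_name), " representative terms</title>"),
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto;}",
    "details{margin:0.3em 0;padding:0.2em 0.5em;border-left:3px solid #4878a8;}",
    "summary{cursor:pointer;} .size{color:#666;font-size:smaller;}",
    "ul{margin:0.2em 0 0.4em 1.5em;}</style></head><body>",
    paste0("<h1>Representative terms (", length(outcome$groups), ")</h1>"),
    "<p>Click a representative term to see the terms it represents.</p>")
  body <- character(0L)
  for (g in outcome$groups) {
    id <- g$representative_id
    desc <- annotations$descriptions[[id]]
    size <- length(annotations$gene_sets[[id]])
    label <- paste0(html_escape(id),
                    if (nzchar(desc)) paste0(" &mdash; ", html_escape(desc)) else "",
                    " <span class=\"size\">(", size, " genes, represents ",
                    length(g$represented_ids), ")</span>")
    if (length(g$represented_ids) == 0L) {
      body <- c(body, paste0("<details><summary>", label,
                             "</summary><ul><li><em>no represented terms</em></li></ul></details>"))
    } else {
      items <- vapply(g$represented_ids, function(t) {
        d <- annotations$descriptions[[t]]
        paste0("<li>", html_escape(t),
               if (nzchar(d)) paste0(" &mdash; ", html_escape(d)) else "",
               " <span class=\"size\">(", length(annotations$gene_sets[[t]]),
               " genes)</span></li>")
      }, character(1L))
      body <- c(body, paste0("<details><summary>", label, "</summary><ul>"),
                items, "</ul></details>")
    }
  }
  c(head, body, "</body></html>")
}

#' Write the tabular and HTML reports
#'
#' Writes `<base>-Summary.tsv` (one row per representative: ID, description,
#' term size, number of represented terms, per-source group rank),
#' `<base>-Detailed.tsv` (additionally one row per represented term under
#' its representative, with each term's own per-source ranks) and
#' `<base>.html` (representatives in outcome order with expandable
#' represented-term sublists; fully self-contained, no external resources).
#'
#' @param outcome a `filter_outcome`.
#' @param ranks matrix from [group_source_ranks].
#' @param annotations the [annotation_collection] used for filtering.
#' @param out_dir output directory (created if needed).
#' @param base_name prefix for the output file names.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_reports <- function(outcome, ranks, annotations, out_dir,
                          base_name = "enrichsum") {
  stopifnot(inherits(outcome, "filter_outcome"),
            inherits(annotations, "annotation_collection"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- c(
    summary = file.path(out_dir, paste0(base_name, "-Summary.tsv")),
    detailed = file.path(out_dir, paste0(base_name, "-Detailed.tsv")),
    html = file.path(out_dir, paste0(base_name, ".html"))
  )
  utils::write.table(summary_table(outcome, ranks, annotations),
                     paths[["summary"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(detailed_table(outcome, ranks, annotations),
                     paths[["detailed"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  writeLines(report_html(outcome, annotations, base_name), paths[["html"]],
             useBytes = TRUE)
  invisible(paths)
}

quartile_palette <- c(Q1 = "#b2182b", Q2 = "#ef8a62", Q3 = "#fddbc7",
                      Q4 = "#f7f7f7", absent = "#c8c8c8")

# SVG goes through the cairo device so no extra device package is needed
save_plot <- function(path, plot, width, height) {
  dev <- if (grepl("\\.svg$", path, ignore.case = TRUE)) grDevices::svg
  suppressMessages(ggplot2::ggsave(path, plot, device = dev, width = width,
                                   height = height, limitsize = FALSE))
}

#' Rank-quartile heatmap of the top representative terms
#'
#' Rows are the first `top_n` representatives in outcome order (most
#' significant first, top row first), columns the input results in input
#' order. Cells are colored by the quartile of the group's best rank in each
#' source; groups absent from a source get a distinct neutral color.
#'
#' @param quartiles matrix from [assign_quartiles].
#' @param top_n number of representatives to plot (1-50); clamped to the
#'   number available.
#' @param path output image path; format from the extension (`.png`,
#'   `.svg`, `.pdf`).
#' @return The ggplot object, invisibly.
#' @export
render_heatmap <- function(quartiles, top_n = 50L, path = NULL) {
  top_n <- max(1L, min(as.integer(top_n), 50L, nrow(quartiles)))
  m <- quartiles[seq_len(top_n), , drop = FALSE]
  df <- expand.grid(representative = rownames(m), source = colnames(m),
                    stringsAsFactors = FALSE)
  df$quartile <- as.vector(m)
  df$quartile <- ifelse(is.na(df$quartile), "absent", paste0("Q", df$quartile))
  df$quartile <- factor(df$quartile, levels = names(quartile_palette))
  df$representative <- factor(df$representative, levels = rev(rownames(m)))
  df$source <- factor(df$source, levels = colnames(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$source,
                                        y = .data$representative,
                                        fill = .data$quartile)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = quartile_palette, drop = FALSE,
                               name = "rank quartile") +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Top ", top_n, " representative terms")) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!is.null(path)) {
    h <- max(2.5, 0.22 * top_n + 1.2)
    w <- max(4, 1.1 * ncol(m) + 3.5)
    save_plot(path, p, width = w, height = h)
  }
  invisible(p)
}

#' Barplot of represented-term counts
#'
#' Horizontal bars: how many terms each of the first `top_n` representatives
#' (outcome order) represents. A representative that represents nothing gets
#' a zero-height bar.
#'
#' @param outcome a `filter_outcome`.
#' @param top_n number of representatives to plot (1-50); clamped.
#' @param path output image path; format from the extension.
#' @return The ggplot object, invisibly.
#' @export
render_barplot <- function(outcome, top_n = 50L, path = NULL) {
  counts <- represented_counts(outcome)
  top_n <- max(1L, min(as.integer(top_n), 50L, length(counts)))
  counts <- counts[seq_len(top_n)]
  df <- data.frame(representative = factor(names(counts),
                                           levels = rev(names(counts))),
                   n_represented = as.integer(counts))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_represented,
                                        y = .data$representative)) +
    ggplot2::geom_col(fill = "#4878a8") +
    ggplot2::labs(x = "number of represented terms", y = NULL,
                  title = paste0("Top ", top_n, " representative terms")) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(path)) {
    h <- max(2.5, 0.22 * top_n + 1.2)
    save_plot(path, p, width = 6.5, height = h)
  }
  invisible(p)
}

#' Correlation between term size and number of represented terms
#'
#' Larger, more general terms cover more gene sets, so they are expected to
#' represent more terms. This computes Spearman's rank correlation between
#' the number of genes each representative annotates and the number of terms
#' it represents.
#'
#' @param outcome a `filter_outcome` with at least 3 representatives.
#' @param annotations the [annotation_collection] used for filtering.
#' @return List with `rho` and `p` (two-sided). When either variable has no
#'   variance the correlation is undefined: `rho` and `p` are `NA` and a
#'   warning is raised.
#' @export
size_representation_correlation <- function(outcome, annotations) {
  stopifnot(inherits(outcome, "filter_outcome"),
            inherits(annotations, "annotation_collection"))
  reps <- representatives(outcome)
  if (length(reps) < 3L) {
    stop("correlation needs at least 3 representatives, got ", length(reps),
         call. = FALSE)
  }
  sizes <- as.numeric(term_sizes(annotations, reps))
  counts <- as.numeric(represented_counts(outcome))
  if (stats::var(sizes) == 0 || stats::var(counts) == 0) {
    warning("size/represented-count correlation undefined (zero variance)",
            call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(sizes, counts, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
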