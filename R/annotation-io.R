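#' Construct an annotation collection
#'
#' An annotation collection maps term identifiers to the sets of genes they
#' annotate, as parsed from a GMT (Gene Matrix Transposed) file. It is the
#' coverage oracle for the filtering step: term A "covers" term B when A's
#' gene set is a superset of B's.
#'
#' @param gene_sets named list; one character vector of gene identifiers per
#'   term. Names are the term IDs. Duplicate genes within a term are collapsed.
#' @param descriptions named character vector of free-text term labels.
#'   Missing entries default to the empty string.
#' @return An object of class `annotation_collection` with elements
#'   `gene_sets` (named list of unique gene-ID vectors) and `descriptions`
#'   (named character vector, same names).
#' @export
annotation_collection <- function(gene_sets, descriptions = NULL) {
  ids <- names(gene_sets)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every term must have a non-empty ID", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  gene_sets <- lapply(gene_sets, function(g) {
    g <- unique(trimws(as.character(g)))
    g <- g[nzchar(g)]
    if (length(g) == 0L) stop("term with empty gene set", call. = FALSE)
    g
  })
  desc <- stats::setNames(rep("", length(ids)), ids)
  if (!is.null(descriptions)) {
    common <- intersect(names(descriptions), ids)
    desc[common] <- as.character(descriptions[common])
    desc[is.na(desc)] <- ""
  }
  structure(list(gene_sets = gene_sets, descriptions = desc),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("<annotation_collection> ", length(x$gene_sets), " terms, ",
      length(collection_universe(x)), " genes in universe\n", sep = "")
  invisible(x)
}

#' @export
length.annotation_collection <- function(x) length(x$gene_sets)

#' Universe of an annotation collection
#'
#' The union of all member gene sets.
#'
#' @param collection an `annotation_collection`.
#' @return Character vector of unique gene identifiers.
#' @export
collection_universe <- function(collection) {
  unique(unlist(collection$gene_sets, use.names = FALSE))
}

#' Term sizes
#'
#' Number of genes annotated by each requested term. This is the quantity
#' compared against the minimum term size and maximum representative term
#' size thresholds.
#'
#' @param collection an `annotation_collection`.
#' @param ids term IDs; defaults to all terms.
#' @return Named integer vector of gene counts.
#' @export
term_sizes <- function(collection, ids = names(collection$gene_sets)) {
  missing <- setdiff(ids, names(collection$gene_sets))
  if (length(missing) > 0L) {
    stop("unknown term ID: ", missing[1L], call. = FALSE)
  }
  vapply(collection$gene_sets[ids], length, integer(1L))
}

#' Parse a GMT file
#'
#' Reads a Gene Matrix Transposed file: one term per line, tab-separated
#' fields `ID<TAB>description<TAB>gene1<TAB>gene2...`. Gene fields are
#' trimmed of surrounding whitespace; empty trailing fields are ignored;
#' duplicate genes within one line are collapsed. Identifiers are compared
#' as exact strings (no case folding): GMT dialects differ and silent case
#' merging can conflate distinct genes.
#'
#' @param path path to a GMT file.
#' @return An [annotation_collection].
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  gene_sets <- vector("list", length(lines))
  ids <- character(length(lines))
  descs <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields_trim <- trimws(fields)
    # empty trailing fields (e.g. a final tab) are ignored, but the first two
    # columns are positional and must exist
    n_eff <- length(fields_trim)
    while (n_eff > 2L && !nzchar(fields_trim[n_eff])) n_eff <- n_eff - 1L
    genes <- fields_trim[seq_len(n_eff)][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(fields_trim) < 3L || length(genes) == 0L) {
      stop("malformed GMT line ", line_no[i],
           ": expected ID, description and at least one gene", call. = FALSE)
    }
    id <- fields_trim[1L]
    if (!nzchar(id)) {
      stop("malformed GMT line ", line_no[i], ": empty term ID", call. = FALSE)
    }
    if (id %in% ids[seq_len(i - 1L)]) {
      stop("duplicate term ID in GMT: ", id, call. = FALSE)
    }
    ids[i] <- id
    descs[i] <- fields_trim[2L]
    gene_sets[[i]] <- unique(genes)
  }
  names(gene_sets) <- ids
  annotation_collection(gene_sets, stats::setNames(descs, ids))
}

#' Write an annotation collection to a GMT file
#'
#' One line per term: ID, description, then genes in lexicographic order so
#' output is deterministic regardless of internal set ordering.
#'
#' @param collection an [annotation_collection]; must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  if (length(collection) == 0L) stop("cannot write an empty collection", call. = FALSE)
  ids <- names(collection$gene_sets)
  lines <- vapply(ids, function(id) {
    genes <- sort(collection$gene_sets[[id]], method = "radix")
    paste(c(id, collection$descriptions[[id]], genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a ranked term list
#'
#' One enrichment result: term IDs ordered from most to least significant.
#' Significance values themselves are not carried; the 1-based position of a
#' term is its rank.
#'
#' @param term_ids character vector of term IDs in significance order.
#' @param alias short source label used in reports and as column name.
#' @return Object of class `ranked_term_list` with elements `alias` and
#'   `term_ids`.
#' @export
ranked_term_list <- function(term_ids, alias) {
  term_ids <- as.character(term_ids)
  if (length(alias) != 1L || !nzchar(alias)) {
    stop("alias must be a single non-empty string", call. = FALSE)
  }
  if (anyDuplicated(term_ids)) {
    stop("duplicate term ID in ranked list '", alias, "': ",
         term_ids[duplicated(term_ids)][1L], call. = FALSE)
  }
  structure(list(alias = alias, term_ids = term_ids), class = "ranked_term_list")
}

#' @export
print.ranked_term_list <- function(x, ...) {
  cat("<ranked_term_list> '", x$alias, "', ", length(x$term_ids), " terms\n",
      sep = "")
  invisible(x)
}

#' Read a ranked enrichment result from disk
#'
#' One term ID per line, ordered from most to least significant. Blank lines
#' and lines starting with `#` are skipped. Lines may carry extra
#' tab-separated columns; only the first column is read.
#'
#' @param path path to the result file.
#' @param alias source label attached to the list; defaults to the file base
#'   name without extension.
#' @return A [ranked_term_list].
#' @export
read_ranked_terms <- function(path, alias = NULL) {
  if (!file.exists(path)) stop("result file not found: ", path, call. = FALSE)
  if (is.null(alias)) alias <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("result file '", path, "' contains no term IDs", call. = FALSE)
  }
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1L), 1L)
  ids <- trimws(ids)
  ranked_term_list(ids, alias)
}
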