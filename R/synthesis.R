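# Synthetic annotation collections and enrichment inputs.
#
# Real hierarchical annotation databases (GO, Reactome) have the containment
# property that makes coverage filtering meaningful: an ancestor term
# annotates every gene annotated by its descendants. The generator below
# emulates exactly that property -- disjoint root gene sets, each child a
# random subset of its parent -- so the filtering, reporting and ORA code
# can be exercised end to end with no external data.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a hierarchical annotation collection
#'
#' Builds a forest of terms over a synthetic gene universe. Root terms
#' partition the universe into disjoint gene sets; every child term's gene
#' set is a random fraction of its parent's, so each ancestor annotates at
#' least the genes of all its descendants -- the structure that drives
#' redundancy in real enrichment results. Deterministic under a fixed seed.
#'
#' @param universe_size number of genes in the universe (default 2000).
#' @param n_roots number of disjoint root terms (default 5).
#' @param depth number of hierarchy levels including the roots; `depth = 1`
#'   gives mutually disjoint roots only (default 4).
#' @param branching children per internal term (default 3).
#' @param child_fraction fraction in (0,1) of the parent's genes inherited by
#'   each child (default 0.5).
#' @param seed integer RNG seed.
#' @return An [annotation_collection]. Term descriptions record the level
#'   and the parent, e.g. `"level 2; parent T0001"`.
#' @export
generate_ontology <- function(universe_size = 2000L, n_roots = 5L,
                              depth = 4L, branching = 3L,
                              child_fraction = 0.5, seed = 1L) {
  stopifnot(universe_size >= 1L, n_roots >= 1L, depth >= 1L, branching >= 1L)
  if (!(child_fraction > 0 && child_fraction < 1)) {
    stop("child_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  root_size <- universe_size %/% n_roots
  if (floor(root_size * child_fraction^(depth - 1L)) < 1L) {
    stop("parameters imply empty gene sets at depth ", depth, call. = FALSE)
  }
  genes <- sprintf("g%05d", seq_len(universe_size))
  with_seed(seed, {
    shuffled <- sample(genes)
    gene_sets <- list()
    descs <- character(0L)
    next_id <- 1L
    new_id <- function() {
      id <- sprintf("T%04d", next_id)
      next_id <<- next_id + 1L
      id
    }
    # roots: disjoint chunks of the shuffled universe (remainder spread over
    # the first roots so the whole universe is annotated)
    sizes <- rep(root_size, n_roots)
    extra <- universe_size - root_size * n_roots
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    offsets <- cumsum(c(0L, sizes[-n_roots]))
    frontier <- character(0L)
    for (r in seq_len(n_roots)) {
      id <- new_id()
      gene_sets[[id]] <- shuffled[(offsets[r] + 1L):(offsets[r] + sizes[r])]
      descs[id] <- "level 1; root"
      frontier <- c(frontier, id)
    }
    if (depth > 1L) {
      for (lev in 2L:depth) {
        next_frontier <- character(0L)
        for (parent in frontier) {
          pg <- gene_sets[[parent]]
          child_size <- floor(length(pg) * child_fraction)
          if (child_size < 1L) {
            stop("parameters imply empty gene sets at depth ", lev,
                 call. = FALSE)
          }
          for (b in seq_len(branching)) {
            id <- new_id()
            gene_sets[[id]] <- sample(pg, child_size)
            descs[id] <- paste0("level ", lev, "; parent ", parent)
            next_frontier <- c(next_frontier, id)
          }
        }
        frontier <- next_frontier
      }
    }
    annotation_collection(gene_sets, descs)
  })
}

#' Generate an artificial query gene list
#'
#' Emulates the construction used to benchmark summarization on enrichable
#' inputs: pick, uniformly at random, a source term annotating more than
#' `min_source_term_size` genes (say it annotates n genes); take
#' `floor(n/2)` of its genes and add `ceiling(n/2)` genes sampled from the
#' rest of the universe (everything outside the already-chosen genes), for a
#' query of size exactly n with no duplicates. A fully random list would
#' rarely be enriched in anything; seeding half of it from one term
#' guarantees a recoverable signal.
#'
#' @param annotations an [annotation_collection].
#' @param seed integer RNG seed.
#' @param min_source_term_size only terms annotating strictly more than this
#'   many genes are eligible sources (default 100).
#' @return List with `genes` (the query, length n), `source_id` (the chosen
#'   term) and `n`.
#' @export
generate_artificial_query <- function(annotations, seed = 1L,
                                      min_source_term_size = 100L) {
  stopifnot(inherits(annotations, "annotation_collection"))
  sizes <- term_sizes(annotations)
  eligible <- names(sizes)[sizes > min_source_term_size]
  if (length(eligible) == 0L) {
    stop("no term annotates more than ", min_source_term_size, " genes",
         call. = FALSE)
  }
  universe <- collection_universe(annotations)
  with_seed(seed, {
    source_id <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    src_genes <- annotations$gene_sets[[source_id]]
    n <- length(src_genes)
    n_src <- n %/% 2L
    n_rand <- n - n_src
    chosen <- sample(src_genes, n_src)
    pool <- setdiff(universe, chosen)
    if (length(pool) < n_rand) {
      stop("universe too small to draw ", n_rand, " additional genes",
           call. = FALSE)
    }
    list(genes = c(chosen, sample(pool, n_rand)), source_id = source_id, n = n)
  })
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts the query genes falling in a term of size K,
#' for a query of size n drawn from a universe of N genes: the standard
#' over-representation p-value. Computed in log space via [stats::phyper]
#' for numerical stability. All arguments are vectorized.
#'
#' @param k observed overlap between query and term.
#' @param K term size (genes annotated by the term).
#' @param n query size.
#' @param N universe size.
#' @return Upper-tail probabilities; `k = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) {
    stop("infeasible hypergeometric arguments (need 0 <= k <= min(K, n), ",
         "K <= N, n <= N)", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against an annotation collection
#'
#' Tests every term for over-representation of the query genes with the
#' hypergeometric upper tail (background = the collection universe),
#' applies Bonferroni correction over the number of tested terms, keeps the
#' terms with adjusted p below `alpha`, and returns them ordered by
#' ascending raw p (ties broken by term ID for determinism). Significance
#' values are deliberately omitted from the result: the filtering step
#' consumes rank order only, matching its input contract.
#'
#' @param query character vector of gene IDs; genes absent from the universe
#'   are dropped with a warning.
#' @param annotations an [annotation_collection].
#' @param alpha significance level applied to Bonferroni-adjusted p-values
#'   (default 0.05).
#' @param alias source label for the resulting list (default `"ora"`).
#' @return A [ranked_term_list] (possibly with zero terms).
#' @export
run_ora <- function(query, annotations, alpha = 0.05, alias = "ora") {
  stopifnot(inherits(annotations, "annotation_collection"),
            alpha > 0, alpha < 1)
  query <- unique(as.character(query))
  universe <- collection_universe(annotations)
  unknown <- setdiff(query, universe)
  if (length(unknown) > 0L) {
    warning(length(unknown), " query gene(s) absent from the annotation ",
            "universe were dropped", call. = FALSE)
    query <- setdiff(query, unknown)
  }
  if (length(query) == 0L) {
    stop("no query genes remain after removing unknown genes", call. = FALSE)
  }
  ids <- names(annotations$gene_sets)
  K <- term_sizes(annotations)
  k <- vapply(annotations$gene_sets, function(g) sum(query %in% g), integer(1L))
  p_raw <- hypergeom_tail(k, K, length(query), length(universe))
  p_adj <- pmin(1, p_raw * length(ids))
  sig <- ids[p_adj < alpha]
  ord <- order(p_raw[sig], sig, method = "radix")
  ranked_term_list(sig[ord], alias)
}
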